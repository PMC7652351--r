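#' Specification for synthetic vaccine-design inputs
#'
#' Describes a self-contained synthetic data set with the statistical
#' structure the design method assumes: a panel of related pathogen
#' sequences derived from a common ancestor by independent per-site
#' substitution (low mutation rates yield the conserved-region structure
#' that mosaic designs exploit), MHC alleles with per-locus frequencies,
#' log-normal IC50 binding affinities with a controlled fraction of strong
#' binders, and a random proteasomal cleavage matrix with an optional
#' sequence motif. The same seed always produces bit-identical data; each
#' generator uses its own derived stream so adding one generator call does
#' not shift the others' output.
#'
#' @param seed Integer master seed.
#' @param n_pathogens Number of pathogen sequences.
#' @param seq_length Sequence length in residues.
#' @param mutation_rate Per-site substitution probability away from the
#'   ancestral sequence, in \eqn{[0, 1]}.
#' @param n_alleles Number of MHC alleles, spread round-robin over `loci`.
#' @param loci Locus labels (default the three classical class I loci).
#' @param locus_total Total allele frequency per locus (must be \eqn{\le 1};
#'   the remainder is carried by alleles outside the panel).
#' @param ic50_meanlog,ic50_sdlog Log-normal parameters of the IC50
#'   distribution (nM).
#' @param binder_fraction Fraction of epitope-allele pairs forced to be
#'   binders (IC50 at most `binder_threshold`).
#' @param binder_threshold Binder cutoff in nM (default 500).
#' @param pssm_sd Standard deviation of the cleavage matrix entries.
#' @param motif_strength Added \eqn{\psi} at offset \eqn{-1} for
#'   `motif_residues`, emulating the proteasome's preference for cleaving
#'   after hydrophobic and basic residues.
#' @param motif_residues Residues carrying the cleavage motif.
#' @return A list of class `ev_synth_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_pathogens = 20L,
                           seq_length = 50L,
                           mutation_rate = 0.05,
                           n_alleles = 6L,
                           loci = c("A", "B", "C"),
                           locus_total = 0.8,
                           ic50_meanlog = log(10000),
                           ic50_sdlog = 2,
                           binder_fraction = 0.1,
                           binder_threshold = 500,
                           pssm_sd = 0.3,
                           motif_strength = 1,
                           motif_residues = c("A", "F", "K", "L", "R", "Y")) {
  stopifnot(
    n_pathogens >= 1, seq_length >= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    binder_fraction >= 0, binder_fraction <= 1,
    locus_total >= 0, locus_total <= 1
  )
  structure(
    list(
      seed = as.integer(seed),
      n_pathogens = as.integer(n_pathogens),
      seq_length = as.integer(seq_length),
      mutation_rate = mutation_rate,
      n_alleles = as.integer(n_alleles),
      loci = loci,
      locus_total = locus_total,
      ic50_meanlog = ic50_meanlog,
      ic50_sdlog = ic50_sdlog,
      binder_fraction = binder_fraction,
      binder_threshold = binder_threshold,
      pssm_sd = pssm_sd,
      motif_strength = motif_strength,
      motif_residues = motif_residues
    ),
    class = "ev_synth_spec"
  )
}

#' Generate a synthetic antigen set
#'
#' Draws one ancestral sequence uniformly over the 20 residues, then derives
#' each pathogen by independent per-site substitution at the specified
#' mutation rate (substitutions are uniform over the 19 alternative
#' residues).
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `id`, `sequence`.
#' @export
generate_antigens <- function(spec) {
  withr::with_seed(spec$seed + 1L, {
    ancestor <- sample(AA_RESIDUES, spec$seq_length, replace = TRUE)
    seqs <- vapply(seq_len(spec$n_pathogens), function(i) {
      s <- ancestor
      mut <- runif(spec$seq_length) < spec$mutation_rate
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(a) {
          sample(setdiff(AA_RESIDUES, a), 1L)
        }, character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    tibble(
      id = sprintf("P%03d", seq_len(spec$n_pathogens)),
      sequence = seqs
    )
  })
}

#' Generate a synthetic MHC allele panel
#'
#' Distributes alleles round-robin across loci and draws per-locus
#' frequencies on a scaled simplex summing to `locus_total`, so the diploid
#' population-coverage formula is always valid.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `allele`, `frequency`, `locus`.
#' @export
generate_alleles <- function(spec) {
  withr::with_seed(spec$seed + 4L, {
    locus <- rep(spec$loci, length.out = spec$n_alleles)
    freq <- numeric(spec$n_alleles)
    for (l in unique(locus)) {
      i <- which(locus == l)
      raw <- runif(length(i))
      freq[i] <- raw / sum(raw) * spec$locus_total
    }
    tibble(
      allele = sprintf(
        "%s*%02d", locus,
        stats::ave(seq_along(locus), locus, FUN = seq_along)
      ),
      frequency = freq,
      locus = locus
    )
  })
}

#' Generate synthetic binding affinities
#'
#' Draws an IC50 for every epitope-allele pair from a log-normal
#' distribution: a Bernoulli(`binder_fraction`) subset of pairs is drawn
#' from the distribution truncated to at most `binder_threshold` nM
#' (binders), the rest from the distribution truncated above it. Scores are
#' derived with [ic50_to_immunogenicity()].
#'
#' @param spec A [synthetic_spec()].
#' @param catalog Epitope catalog providing the epitope set.
#' @param alleles Allele panel, e.g. from [generate_alleles()].
#' @return An affinity tibble: `epitope`, `allele`, `ic50`,
#'   `immunogenicity`, `binder`.
#' @export
generate_affinities <- function(spec, catalog, alleles) {
  if (nrow(catalog) == 0L) {
    abort("`catalog` must contain at least one epitope.", class = "ev_error")
  }
  grid <- tidyr::expand_grid(epitope = catalog$epitope, allele = alleles$allele)
  withr::with_seed(spec$seed + 2L, {
    n <- nrow(grid)
    is_binder <- runif(n) < spec$binder_fraction
    f_thr <- plnorm(spec$binder_threshold, spec$ic50_meanlog, spec$ic50_sdlog)
    q <- ifelse(is_binder,
      runif(n, 0, f_thr),
      runif(n, f_thr, 1)
    )
    ic50 <- qlnorm(q, spec$ic50_meanlog, spec$ic50_sdlog)
    ic50 <- pmin(pmax(ic50, 0.01), 1e6)
    grid |>
      mutate(
        ic50 = ic50,
        immunogenicity = ic50_to_immunogenicity(ic50),
        binder = ic50 <= spec$binder_threshold
      )
  })
}

#' Generate a synthetic cleavage matrix
#'
#' Independent zero-mean Gaussian entries, plus `motif_strength` added at
#' offset \eqn{-1} for the motif residues so that junctions preceded by
#' those residues score systematically higher.
#'
#' @param spec A [synthetic_spec()].
#' @return A 20 x 6 cleavage matrix (see [read_pssm()]).
#' @export
generate_pssm <- function(spec) {
  withr::with_seed(spec$seed + 3L, {
    m <- matrix(rnorm(20L * 6L, 0, spec$pssm_sd), 20L, 6L,
      dimnames = list(AA_RESIDUES, as.character(-4:1))
    )
    m[spec$motif_residues, "-1"] <- m[spec$motif_residues, "-1"] + spec$motif_strength
    m
  })
}

#' Generate and write a complete synthetic fixture bundle
#'
#' Produces antigens, the allele panel, per-epitope-allele affinities and a
#' cleavage matrix from one spec, and writes them as a file bundle
#' (`antigens.fasta`, `alleles.csv`, `affinities.csv`, `pssm.txt`) that the
#' readers in this package and the command-line interface consume.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [synthetic_spec()].
#' @param epitope_length Epitope length used to derive the catalog.
#' @return Invisibly, a named list of the file paths.
#' @export
write_fixture_bundle <- function(dir, spec = synthetic_spec(), epitope_length = 9L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  antigens <- generate_antigens(spec)
  catalog <- extract_epitopes(antigens, epitope_length)
  alleles <- generate_alleles(spec)
  affinity <- generate_affinities(spec, catalog, alleles)
  pssm <- generate_pssm(spec)

  paths <- list(
    antigens = file.path(dir, "antigens.fasta"),
    alleles = file.path(dir, "alleles.csv"),
    affinities = file.path(dir, "affinities.csv"),
    pssm = file.path(dir, "pssm.txt")
  )
  write_antigens(antigens, paths$antigens)
  write_alleles(alleles, paths$alleles)
  write_affinities(affinity, paths$affinities)
  write_pssm(pssm, paths$pssm)
  invisible(paths)
}
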