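#' Read and write antigen sequences (FASTA)
#'
#' Thin tidy wrappers around Biostrings' FASTA support (plain or gzipped
#' input). Record ids are the first whitespace-delimited token of each
#' header.
#'
#' @param path FASTA file path.
#' @param antigens A data frame with columns `id`, `sequence`.
#' @return `read_antigens()` returns a tibble with columns `id`,
#'   `sequence`; writers return their path invisibly.
#' @export
read_antigens <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id(s) in %s.", path), class = "ev_error")
  }
  tibble(id = ids, sequence = unname(as.character(set)))
}

#' @rdname read_antigens
#' @export
write_antigens <- function(antigens, path) {
  set <- Biostrings::AAStringSet(setNames(antigens$sequence, antigens$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gapped multiple sequence alignment (FASTA)
#'
#' @param path Aligned FASTA path (gap character `-`).
#' @return A tibble with columns `id`, `sequence`; all sequences are
#'   checked to have equal length.
#' @export
read_alignment <- function(path) {
  aln <- read_antigens(path)
  if (length(unique(nchar(aln$sequence))) > 1L) {
    abort(sprintf("sequences in %s are not aligned (unequal lengths).", path),
      class = "ev_error"
    )
  }
  aln
}

#' Read and write epitope-allele affinity tables
#'
#' Long-format CSV with one row per scored epitope-allele pair. Recognized
#' columns: `epitope`, `allele`, `ic50` (alias `ic50_nM`), and optionally
#' `immunogenicity` and `rank`. The immunogenicity score is taken from the
#' requested source: transformed from IC50, flipped from the percentile
#' rank, or used as provided.
#'
#' @param path CSV path.
#' @param score_source One of `"ic50"`, `"rank"`, `"precomputed"`.
#' @param affinity Affinity tibble to write.
#' @return `read_affinities()` returns the affinity tibble with columns
#'   `epitope`, `allele`, `ic50`, `immunogenicity`, `binder`.
#' @export
read_affinities <- function(path, score_source = c("ic50", "rank", "precomputed")) {
  score_source <- match.arg(score_source)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("ic50_nM" %in% names(df) && !"ic50" %in% names(df)) {
    df <- dplyr::rename(df, ic50 = "ic50_nM")
  }
  assert_affinity(df)
  if (!"ic50" %in% names(df)) df$ic50 <- NA_real_
  df$immunogenicity <- switch(score_source,
    ic50 = ic50_to_immunogenicity(df$ic50),
    rank = rank_to_immunogenicity(df[["rank"]]),
    precomputed = {
      if (!"immunogenicity" %in% names(df)) {
        abort(sprintf("%s has no `immunogenicity` column.", path), class = "ev_error")
      }
      df$immunogenicity
    }
  )
  binder_indicators(as_tibble(df))
}

#' @rdname read_affinities
#' @export
write_affinities <- function(affinity, path) {
  readr::write_csv(affinity, path, progress = FALSE)
  invisible(path)
}

#' Read and write MHC allele tables
#'
#' CSV with columns `allele`, `frequency`, `locus`. Frequencies are
#' validated on read: they must lie in \eqn{[0, 1]} and sum to at most 1
#' within each locus (a person carries two alleles per locus, so the
#' per-locus frequencies form a sub-probability vector).
#'
#' @param path CSV path.
#' @param alleles Allele tibble to write.
#' @export
read_alleles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_alleles(df)
  as_tibble(df)
}

#' @rdname read_alleles
#' @export
write_alleles <- function(alleles, path) {
  readr::write_csv(alleles, path, progress = FALSE)
  invisible(path)
}

#' Read and write pairwise edge-weight tables
#'
#' CSV with columns `from`, `to`, `weight` holding externally computed
#' directed edge weights (for example from a spacer-design framework);
#' consumed verbatim by `build_design_graph(kind = "custom")`. The reserved
#' label `"s"` denotes the polypeptide terminus.
#'
#' @param path CSV path.
#' @param edge_table Edge table to write.
#' @export
read_edge_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("from", "to", "weight") %in% names(df))) {
    abort(sprintf("%s must have columns from, to, weight.", path), class = "ev_error")
  }
  as_tibble(df)
}

#' @rdname read_edge_table
#' @export
write_edge_table <- function(edge_table, path) {
  readr::write_csv(edge_table, path, progress = FALSE)
  invisible(path)
}

#' Read and write epitope catalogs
#'
#' CSV with columns `epitope`, `conservation` and `pathogens`
#' (semicolon-joined antigen ids). The full antigen panel is carried in a
#' `# pathogens:` comment header so that coverage denominators survive the
#' round trip.
#'
#' @param path CSV path.
#' @param catalog An `ev_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  header <- sprintf(
    "# pathogens: %s\n# epitope_length: %d",
    paste(pathogen_ids(catalog), collapse = ";"),
    attr(catalog, "epitope_length") %||% NA_integer_
  )
  body <- catalog |>
    mutate(pathogens = vapply(.data$pathogens, paste, character(1), collapse = ";")) |>
    as_tibble()
  writeLines(header, path)
  readr::write_csv(body, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  meta <- readLines(path, n = 2L, warn = FALSE)
  ids <- strsplit(sub("^# pathogens: ", "", meta[1]), ";", fixed = TRUE)[[1]]
  len <- as.integer(sub("^# epitope_length: ", "", meta[2]))
  df <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  df$pathogens <- strsplit(df$pathogens, ";", fixed = TRUE)
  new_catalog(df, pathogen_ids = ids, epitope_length = len)
}

#' Load and cross-validate a full input bundle
#'
#' Reads antigens, affinities, alleles and (optionally) a cleavage matrix,
#' an edge table and an aligned FASTA; derives the epitope catalog; and
#' cross-validates the pieces: affinity rows whose epitope does not occur in
#' any antigen are dropped with a warning, and per-locus allele frequencies
#' are checked. This mirrors the shape of the published supplementary data
#' sets (sequence FASTA, epitope/affinity table, allele table).
#'
#' @param antigens_path FASTA of antigen sequences.
#' @param affinities_path Affinity CSV (see [read_affinities()]).
#' @param alleles_path Allele CSV.
#' @param pssm_path Optional cleavage-matrix file.
#' @param edge_table_path Optional pairwise edge-weight CSV.
#' @param alignment_path Optional aligned FASTA.
#' @param epitope_length Epitope length for catalog extraction.
#' @param score_source Immunogenicity source passed to [read_affinities()].
#' @return A list of class `ev_bundle` with elements `antigens`, `catalog`,
#'   `affinity`, `alleles`, and optional `pssm`, `edge_table`, `alignment`.
#' @export
load_inputs <- function(antigens_path, affinities_path, alleles_path,
                        pssm_path = NULL, edge_table_path = NULL,
                        alignment_path = NULL, epitope_length = 9L,
                        score_source = "ic50") {
  antigens <- read_antigens(antigens_path)
  catalog <- extract_epitopes(antigens, epitope_length)
  affinity <- read_affinities(affinities_path, score_source)
  alleles <- read_alleles(alleles_path)

  unknown <- setdiff(unique(affinity$epitope), catalog$epitope)
  if (length(unknown)) {
    warn(sprintf(
      "dropping %d affinity row(s) for %d epitope(s) absent from the antigens.",
      sum(affinity$epitope %in% unknown), length(unknown)
    ))
    affinity <- affinity[!affinity$epitope %in% unknown, ]
  }

  structure(
    list(
      antigens = antigens,
      catalog = catalog,
      affinity = affinity,
      alleles = alleles,
      pssm = if (!is.null(pssm_path)) read_pssm(pssm_path),
      edge_table = if (!is.null(edge_table_path)) read_edge_table(edge_table_path),
      alignment = if (!is.null(alignment_path)) read_alignment(alignment_path)
    ),
    class = "ev_bundle"
  )
}

#' Write a solution (or report) bundle with a manifest
#'
#' Writes the artifacts appropriate for the object — solution JSON plus a
#' FASTA of assembled polypeptides for an `ev_solution`, a CSV for metric
#' and frontier tables, a TSV for positional tracks — then a
#' `manifest.json` listing each file with its MD5 checksum and the package
#' version. Outputs are bit-stable given identical inputs, seed and solver.
#'
#' @param x An `ev_solution`, `ev_metrics`, `ev_pareto`, `ev_shuffle` or
#'   `ev_tracks` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_outputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  if (inherits(x, "ev_solution")) {
    sol_path <- file.path(dir, "solution.json")
    write_solution(x, sol_path)
    fa_path <- file.path(dir, "polypeptides.fasta")
    polys <- x$polypeptides
    write_antigens(
      tibble(
        id = sprintf("tour_%d", seq_along(polys)),
        sequence = ifelse(polys == "", "X", polys)
      ),
      fa_path
    )
    files <- c(sol_path, fa_path)
  } else if (inherits(x, "ev_pareto")) {
    p <- file.path(dir, "pareto.csv")
    readr::write_csv(as_tibble(x)[, setdiff(names(x), "solution")], p, progress = FALSE)
    files <- p
  } else if (inherits(x, "ev_tracks")) {
    p <- file.path(dir, "tracks.tsv")
    readr::write_tsv(as_tibble(x), p, progress = FALSE)
    files <- p
  } else if (inherits(x, "ev_shuffle")) {
    p <- file.path(dir, "shuffle.csv")
    readr::write_csv(as_tibble(x), p, progress = FALSE)
    files <- p
  } else if (is.data.frame(x)) {
    p <- file.path(dir, "metrics.csv")
    readr::write_csv(as_tibble(x), p, progress = FALSE)
    files <- p
  } else {
    abort("don't know how to write this object.", class = "ev_error")
  }

  manifest <- list(
    package = "evdesign",
    version = as.character(utils::packageVersion("evdesign")),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Read and write vaccine solutions as JSON
#'
#' @param solution An `ev_solution`.
#' @param path JSON file path.
#' @return `read_solution()` returns the solution as an `ev_solution` (the
#'   config is restored as a plain list).
#' @export
write_solution <- function(solution, path) {
  payload <- list(
    kind = solution$kind,
    status = solution$status,
    objective = solution$objective,
    immunogenicity = solution$immunogenicity,
    cleavage_score = solution$cleavage_score,
    tours = solution$tours,
    polypeptides = solution$polypeptides,
    tour_weights = solution$tour_weights,
    covered_pathogens = solution$covered_pathogens,
    covered_alleles = solution$covered_alleles,
    h = if (is.finite(solution$h)) solution$h else "Inf",
    config = unclass(solution$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tours <- p$tours
  if (is.matrix(tours)) {
    # equal-length tours simplify to a matrix with one row per tour
    tours <- lapply(seq_len(nrow(tours)), function(i) tours[i, ])
  } else if (!is.list(tours)) {
    tours <- list(tours)
  }
  tours <- lapply(tours, as.character)
  structure(
    list(
      tours = tours,
      polypeptides = as.character(p$polypeptides),
      kind = p$kind,
      tour_weights = as.numeric(p$tour_weights),
      tour_sizes = lengths(tours),
      objective = p$objective,
      immunogenicity = p$immunogenicity,
      cleavage_score = p$cleavage_score,
      covered_pathogens = as.character(p$covered_pathogens),
      covered_alleles = as.character(p$covered_alleles),
      status = p$status,
      h = if (identical(p$h, "Inf")) Inf else as.numeric(p$h),
      config = p$config
    ),
    class = "ev_solution"
  )
}
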