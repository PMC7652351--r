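#' Transform IC50 binding affinities to immunogenicity scores
#'
#' Converts a predicted half-maximal inhibitory concentration (IC50, in
#' nanomolar; lower is stronger binding) into a per-epitope-allele
#' immunogenicity score on \eqn{[0, 1]} via the log transform
#' \deqn{i = \mathrm{clamp}\left(1 - \frac{\log \mathrm{IC50}}{\log c},\ 0,\ 1\right)}
#' with cap \eqn{c} = 50000 nM, the conventional upper bound reported by MHC
#' binding predictors. The transform is monotonically decreasing in IC50:
#' 1 nM or stronger maps to 1, the cap or weaker maps to 0.
#'
#' @param ic50_nM Positive IC50 value(s) in nanomolar.
#' @param cap Affinity (nM) mapped to score 0 (default 50000).
#' @return Numeric score(s) in \eqn{[0, 1]}.
#' @examples
#' ic50_to_immunogenicity(c(1, 500, 50000))
#' @export
ic50_to_immunogenicity <- function(ic50_nM, cap = 50000) {
  if (any(is.na(ic50_nM)) || any(ic50_nM <= 0)) {
    abort("IC50 values must be positive.", class = "ev_error_invalid_measurement")
  }
  pmin(pmax(1 - log(ic50_nM) / log(cap), 0), 1)
}

#' Transform percentile ranks to immunogenicity scores
#'
#' Binding predictors often report a percentile rank in \eqn{[0, 100]} where
#' small ranks indicate strong binders. Since the design problem is cast as a
#' maximization, the rank is flipped so that 100 represents the largest
#' immunogenicity: `100 - rank`.
#'
#' @param rank Percentile rank(s) in \eqn{[0, 100]}.
#' @return `100 - rank`.
#' @export
rank_to_immunogenicity <- function(rank) {
  if (any(is.na(rank)) || any(rank < 0) || any(rank > 100)) {
    abort("ranks must lie in [0, 100].", class = "ev_error_invalid_measurement")
  }
  100 - rank
}

#' Mark epitope-allele pairs as binders
#'
#' Sets the binder indicator for each scored epitope-allele pair: a pair is a
#' binder iff its IC50 is at most `threshold_nM` (boundary inclusive, 500 nM
#' by default, the standard binding cutoff). Pairs without an IC50
#' measurement are non-binders.
#'
#' @param affinity A data frame with columns `epitope`, `allele` and `ic50`
#'   (nM; `NA` allowed for unmeasured pairs).
#' @param threshold_nM Positive binding threshold in nanomolar.
#' @return The affinity tibble with a logical `binder` column (re)computed.
#' @export
binder_indicators <- function(affinity, threshold_nM = 500) {
  assert_affinity(affinity)
  assert_scalar_number(threshold_nM, "threshold_nM")
  if (threshold_nM <= 0) {
    abort("`threshold_nM` must be positive.", class = "ev_error")
  }
  affinity |>
    mutate(binder = !is.na(.data$ic50) & .data$ic50 <= threshold_nM)
}

assert_affinity <- function(affinity, need = c("epitope", "allele")) {
  if (!is.data.frame(affinity) || !all(need %in% names(affinity))) {
    abort(
      sprintf(
        "`affinity` must be a data frame with columns %s.",
        paste0("`", need, "`", collapse = ", ")
      ),
      class = "ev_error"
    )
  }
  invisible(affinity)
}

assert_alleles <- function(alleles) {
  if (!is.data.frame(alleles) ||
    !all(c("allele", "frequency", "locus") %in% names(alleles))) {
    abort(
      "`alleles` must be a data frame with columns `allele`, `frequency`, `locus`.",
      class = "ev_error"
    )
  }
  if (anyDuplicated(alleles$allele)) {
    abort("allele names must be unique.", class = "ev_error")
  }
  if (any(alleles$frequency < 0 | alleles$frequency > 1)) {
    abort("allele frequencies must lie in [0, 1].", class = "ev_error_invalid_frequencies")
  }
  locus_tot <- tapply(alleles$frequency, alleles$locus, sum)
  if (any(locus_tot > 1 + 1e-9)) {
    abort(
      sprintf(
        "allele frequencies within locus %s sum to more than 1.",
        paste(names(locus_tot)[locus_tot > 1 + 1e-9], collapse = ", ")
      ),
      class = "ev_error_invalid_frequencies"
    )
  }
  invisible(alleles)
}

# Population-weighted immunogenicity of each epitope:
#   reward(v) = sum_a p_a * i_va
# Alleles scored in `affinity` but absent from the frequency table contribute
# nothing (a warning is emitted once). Epitopes absent from `affinity` get 0.
epitope_rewards <- function(epitopes, affinity, alleles) {
  assert_affinity(affinity, c("epitope", "allele", "immunogenicity"))
  assert_alleles(alleles)
  orphan <- setdiff(unique(affinity$allele), alleles$allele)
  if (length(orphan)) {
    warn(sprintf(
      "allele(s) without frequency contribute 0 to immunogenicity: %s",
      paste(orphan, collapse = ", ")
    ))
  }
  scored <- affinity |>
    inner_join(alleles[, c("allele", "frequency")], by = "allele") |>
    group_by(.data$epitope) |>
    summarise(reward = sum(.data$frequency * .data$immunogenicity), .groups = "drop")
  out <- setNames(rep(0, length(epitopes)), epitopes)
  hit <- intersect(epitopes, scored$epitope)
  out[hit] <- scored$reward[match(hit, scored$epitope)]
  out
}

#' Vaccine immunogenicity
#'
#' Total immunogenicity of a set of epitopes under the linear model
#' \deqn{I(P) = \sum_{v \in P} \sum_{a \in A} p_a \, i_{va}}
#' where \eqn{p_a} is the population frequency of MHC allele \eqn{a} and
#' \eqn{i_{va}} the immunogenicity of epitope \eqn{v} presented on \eqn{a}.
#' Each epitope contributes independently, so \eqn{I} is additive over
#' disjoint epitope sets and non-decreasing under epitope addition.
#'
#' @param epitopes Character vector of epitope sequences (may be empty).
#' @param affinity Affinity table with columns `epitope`, `allele`,
#'   `immunogenicity`; every requested epitope must appear in it.
#' @param alleles Allele table with columns `allele`, `frequency`, `locus`.
#' @return A single non-negative number.
#' @export
vaccine_immunogenicity <- function(epitopes, affinity, alleles) {
  if (length(epitopes) == 0L) {
    return(0)
  }
  assert_affinity(affinity, c("epitope", "allele", "immunogenicity"))
  unknown <- setdiff(epitopes, unique(affinity$epitope))
  if (length(unknown)) {
    abort(
      sprintf(
        "epitope(s) not in affinity table: %s",
        paste(unknown, collapse = ", ")
      ),
      class = "ev_error_unknown_epitope"
    )
  }
  sum(epitope_rewards(unique(epitopes), affinity, alleles))
}
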