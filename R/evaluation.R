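#' Population coverage of a vaccine
#'
#' Probability that a person drawn from the target population carries at
#' least one MHC allele binding at least one vaccine epitope. People carry
#' two alleles per locus (hence the squared term):
#' \deqn{1 - \prod_{i=1}^{m} \Big(1 - \sum_{a \in A_i} y_a p_a\Big)^2}
#' where \eqn{A_i} is the set of alleles of locus \eqn{i}, \eqn{p_a} the
#' allele frequency, and \eqn{y_a = 1} iff some selected epitope binds
#' allele \eqn{a} (IC50 of at most 500 nM unless the affinity table already
#' carries binder indicators).
#'
#' @param epitopes Character vector of vaccine epitopes (may be empty).
#' @param affinity Affinity table with `epitope`, `allele` and `binder` (or
#'   `ic50`, from which binders are derived at 500 nM).
#' @param alleles Allele table (`allele`, `frequency`, `locus`); per-locus
#'   frequencies must sum to at most 1.
#' @return A probability in \eqn{[0, 1]}.
#' @examples
#' alleles <- tibble::tibble(allele = "A1", frequency = 0.5, locus = "A")
#' affinity <- tibble::tibble(epitope = "ACDEFGHIK", allele = "A1", ic50 = 50)
#' population_coverage("ACDEFGHIK", affinity, alleles) # 1 - 0.25 = 0.75
#' @export
population_coverage <- function(epitopes, affinity, alleles) {
  assert_alleles(alleles)
  aff <- affinity
  if (!"binder" %in% names(aff)) {
    aff <- binder_indicators(aff)
  }
  bound <- unique(aff$allele[aff$binder & aff$epitope %in% epitopes])
  covered_frequency_product(alleles, bound)
}

# shared closed form: product over loci of (1 - covered frequency)^2
covered_frequency_product <- function(alleles, covered_alleles) {
  per_locus <- alleles |>
    group_by(.data$locus) |>
    summarise(
      p = sum(.data$frequency[.data$allele %in% covered_alleles]),
      .groups = "drop"
    )
  1 - prod((1 - per_locus$p)^2)
}

#' Pathogen coverage of a vaccine
#'
#' Number (and fraction) of distinct pathogen sequences containing at least
#' one vaccine epitope.
#'
#' @param epitopes Character vector of vaccine epitopes (may be empty).
#' @param catalog Epitope catalog containing them.
#' @return A one-row tibble with columns `count` and `fraction`.
#' @export
pathogen_coverage <- function(epitopes, catalog) {
  ns <- n_pathogens(catalog)
  if (length(epitopes) == 0L) {
    return(tibble(count = 0L, fraction = 0))
  }
  tau <- incidence_matrix(catalog, unique(epitopes))
  count <- sum(colSums(tau) > 0)
  tibble(count = count, fraction = count / ns)
}

#' Mean epitope conservation of a vaccine
#'
#' Average over the vaccine epitopes of the fraction of pathogen sequences
#' containing each epitope.
#'
#' @inheritParams pathogen_coverage
#' @return A number in \eqn{[0, 1]}.
#' @export
mean_conservation <- function(epitopes, catalog) {
  if (length(epitopes) == 0L) {
    abort("mean conservation is undefined for an empty epitope set.",
      class = "ev_error"
    )
  }
  idx <- match(epitopes, catalog$epitope)
  if (anyNA(idx)) {
    abort(
      sprintf(
        "epitope(s) not in catalog: %s",
        paste(epitopes[is.na(idx)], collapse = ", ")
      ),
      class = "ev_error_unknown_epitope"
    )
  }
  mean(catalog$conservation[idx]) / n_pathogens(catalog)
}

#' Evaluate a vaccine with the standard metric panel
#'
#' Computes immunogenicity, absolute and relative population coverage,
#' pathogen coverage, and mean epitope conservation for a design. Relative
#' population coverage divides by the panel maximum — the coverage obtained
#' if every allele in the table were bound — so 100% relative coverage
#' corresponds to the panel's theoretical ceiling.
#'
#' @param x An `ev_solution` or a character vector of epitopes.
#' @inheritParams design_vaccine
#' @return A one-row tibble of class `ev_metrics`.
#' @export
evaluate_vaccine <- function(x, affinity, alleles, catalog) {
  epitopes <- if (inherits(x, "ev_solution")) {
    unlist(x$tours, use.names = FALSE)
  } else {
    as.character(x)
  }
  pc <- pathogen_coverage(epitopes, catalog)
  pop <- population_coverage(epitopes, affinity, alleles)
  pop_max <- covered_frequency_product(alleles, alleles$allele)
  out <- tibble(
    n_epitopes = length(epitopes),
    immunogenicity = vaccine_immunogenicity(
      intersect(epitopes, unique(affinity$epitope)), affinity, alleles
    ),
    population_coverage = pop,
    population_coverage_relative = if (pop_max > 0) pop / pop_max else NA_real_,
    pathogens_covered = pc$count,
    pathogen_coverage = pc$fraction,
    mean_conservation = if (length(epitopes)) {
      mean_conservation(epitopes, catalog)
    } else {
      NA_real_
    }
  )
  class(out) <- c("ev_metrics", class(out))
  out
}
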