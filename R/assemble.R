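#' Assemble a polypeptide from an ordered epitope tour
#'
#' For mixtures and string-of-beads designs the epitopes are concatenated in
#' tour order. For mosaics, consecutive epitopes are merged at their longest
#' suffix-prefix overlap, so the resulting length equals the tour's
#' edge-weight sum in the mosaic graph, and every tour epitope occurs as a
#' substring of the output.
#'
#' @param tour Ordered character vector of epitopes (may be empty).
#' @param kind Design kind (see [build_design_graph()]).
#' @return A single amino-acid string (`""` for an empty tour).
#' @examples
#' assemble_polypeptide(c("ACDEFGHIK", "EFGHIKLMN"), "mosaic") # "ACDEFGHIKLMN"
#' @export
assemble_polypeptide <- function(tour,
                                 kind = c(
                                   "mixture", "string_of_beads",
                                   "mosaic", "custom"
                                 )) {
  kind <- match.arg(kind)
  if (length(tour) == 0L) {
    return("")
  }
  if (kind != "mosaic") {
    return(paste(tour, collapse = ""))
  }
  out <- tour[1L]
  for (i in seq_along(tour)[-1L]) {
    added <- overlap_weight(tour[i - 1L], tour[i])
    l <- nchar(tour[i]) - added
    out <- paste0(out, substring(tour[i], l + 1L))
  }
  out
}

#' Re-check a vaccine solution against the design constraints
#'
#' Independently re-derives constraint satisfaction from the tours alone
#' (not from solver variables) and reports one named violation per failed
#' constraint, using the constraint labels of the ILP formulation:
#'
#' * `C1` — a tour contains an epitope that is not a graph vertex
#' * `C3` — an epitope is used by more than one tour (or repeated)
#' * `C4` — a tour is empty (every tour must leave the terminus)
#' * `C5` — a tour's edge-weight sum exceeds the budget `h`
#' * `C6` — a tour visits more than `max_epitopes` epitopes
#' * `C7b` — fewer than `min_pathogen_cover` pathogens are covered
#' * `C8b` — fewer than `min_allele_cover` alleles are covered
#' * `C9` — average epitope conservation is below `min_conservation`
#'
#' @param solution An `ev_solution`, or a bare list of ordered epitope
#'   character vectors (one per tour) for hand-built checks.
#' @inheritParams design_vaccine
#' @return A tibble with columns `constraint` and `message`; zero rows means
#'   the solution is valid.
#' @export
validate_solution <- function(solution, graph, config, affinity, alleles, catalog) {
  tours <- if (inherits(solution, "ev_solution")) solution$tours else solution
  if (!is.list(tours)) {
    abort("`solution` must be an ev_solution or a list of epitope vectors.",
      class = "ev_error"
    )
  }
  inst <- prepare_instance(graph, affinity, alleles, catalog)
  h <- effective_h(graph, config)
  violations <- list()
  add <- function(constraint, message) {
    violations[[length(violations) + 1L]] <<- tibble(
      constraint = constraint, message = message
    )
  }

  selected <- unlist(tours, use.names = FALSE)
  unknown <- setdiff(selected, graph$epitopes)
  if (length(unknown)) {
    add("C1", sprintf(
      "epitope(s) not in the design graph: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  known_tours <- lapply(tours, function(tr) intersect(tr, graph$epitopes))

  dup <- unique(selected[duplicated(selected)])
  if (length(dup)) {
    add("C3", sprintf(
      "epitope(s) used more than once: %s",
      paste(dup, collapse = ", ")
    ))
  }
  if (any(lengths(tours) == 0L)) {
    add("C4", sprintf(
      "%d empty tour(s); every tour must leave the terminus.",
      sum(lengths(tours) == 0L)
    ))
  }
  if (is.finite(h)) {
    tw <- vapply(known_tours, function(tr) tour_weight(graph, tr), numeric(1))
    over <- which(tw > h + 1e-9)
    if (length(over)) {
      add("C5", sprintf(
        "tour(s) %s exceed the edge-weight budget h = %g.",
        paste(over, collapse = ", "), h
      ))
    }
  }
  over_k <- which(lengths(tours) > config$max_epitopes)
  if (length(over_k)) {
    add("C6", sprintf(
      "tour(s) %s exceed the vertex budget k = %d.",
      paste(over_k, collapse = ", "), config$max_epitopes
    ))
  }

  sel_idx <- match(intersect(selected, graph$epitopes), inst$epitopes)
  n_cov_s <- if (length(sel_idx)) {
    sum(colSums(inst$tau_s[sel_idx, , drop = FALSE]) > 0)
  } else {
    0L
  }
  if (n_cov_s < config$min_pathogen_cover) {
    add("C7b", sprintf(
      "only %d of the required %d pathogens are covered.",
      n_cov_s, config$min_pathogen_cover
    ))
  }
  n_cov_a <- if (length(sel_idx)) {
    sum(colSums(inst$tau_a[sel_idx, , drop = FALSE]) > 0)
  } else {
    0L
  }
  if (n_cov_a < config$min_allele_cover) {
    add("C8b", sprintf(
      "only %d of the required %d alleles are covered.",
      n_cov_a, config$min_allele_cover
    ))
  }
  if (config$min_conservation > 0 && length(sel_idx)) {
    gamma <- config$min_conservation * inst$n_pathogens
    if (sum(inst$conscount[sel_idx] - gamma) < -1e-9) {
      add("C9", sprintf(
        "average conservation %.3f is below the required %.3f.",
        mean(inst$conscount[sel_idx]) / inst$n_pathogens,
        config$min_conservation
      ))
    }
  }

  if (length(violations)) bind_rows(violations) else tibble(constraint = character(), message = character())
}
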