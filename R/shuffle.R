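#' Shuffle experiment: does epitope ordering matter for cleavage?
#'
#' Randomly permutes the epitopes of a single-tour string-of-beads vaccine
#' and compares the cleavage score of each permuted construct with the
#' original. For an ordering-optimal vaccine (such as any point returned by
#' [pareto_frontier()], whose augmentation term enforces the best cleavage
#' among orderings of its epitope set) every decrease is non-negative: no
#' shuffled construct can beat the optimized ordering. The number of
#' junction cleavage sites — junctions whose edge weight is negative — is
#' reported per permutation, with a maximum of one less than the number of
#' epitopes.
#'
#' @param solution An `ev_solution` with a single string-of-beads (or
#'   custom-weight) tour of at least two epitopes.
#' @param graph The design graph the solution was produced on.
#' @param permutations Number of random permutations (default 50).
#' @param seed Optional integer seed for reproducible permutations.
#' @return A tibble of class `ev_shuffle` with one row per permutation:
#'   `permutation`, `cleavage_score`, `decrease` (original minus permuted
#'   score), `cleavage_sites`. The original tour's score and site count are
#'   kept in attributes `original_score` and `original_sites`.
#' @export
shuffle_experiment <- function(solution, graph, permutations = 50, seed = NULL) {
  tours <- if (!is.null(solution$tours)) solution$tours else solution
  if (!is.list(tours) || length(tours) != 1L) {
    abort("`solution` must contain exactly one tour.", class = "ev_error")
  }
  if (graph$kind %in% c("mixture", "mosaic")) {
    abort("the shuffle experiment needs junction cleavage weights (string_of_beads or custom).",
      class = "ev_error"
    )
  }
  tour <- tours[[1L]]
  m <- length(tour)
  if (m < 2L) {
    abort("the tour must contain at least two epitopes.", class = "ev_error")
  }

  junction_stats <- function(ordering) {
    ew <- tour_edge_weights(graph, ordering)
    junctions <- ew[-c(1L, length(ew))] # drop the two terminus edges
    list(score = cleavage_score(ew), sites = sum(junctions < 0))
  }
  orig <- junction_stats(tour)

  draw <- function() {
    purrr::map(seq_len(permutations), function(b) {
      perm <- tour[sample.int(m)]
      st <- junction_stats(perm)
      tibble(
        permutation = b,
        cleavage_score = st$score,
        decrease = orig$score - st$score,
        cleavage_sites = st$sites
      )
    })
  }
  rows <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- bind_rows(rows)
  structure(out,
    class = c("ev_shuffle", class(tibble())),
    original_score = orig$score,
    original_sites = orig$sites
  )
}
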