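#' Exhaustive reference solver for small design problems
#'
#' Enumerates every assignment of epitopes to tours (each tour non-empty,
#' vertex-disjoint, within the vertex budget), finds the minimum-weight
#' ordering of each tour by trying all permutations, applies every
#' constraint of the design problem, and returns the true optimum. This is
#' an independent oracle for [design_vaccine()]: the design problem is
#' NP-hard, so enumeration is only feasible at toy scale, and the function
#' refuses instances beyond its guard limits.
#'
#' Ties between equal-objective optima are broken by the lexicographically
#' smallest tour encoding, making the result deterministic.
#'
#' @inheritParams design_vaccine
#' @param guard Maximum number of epitopes accepted (default 9); at most 2
#'   tours are supported.
#' @return An `ev_solution` (status `"optimal"`). Raises `ev_infeasible` if
#'   no assignment satisfies the constraints, matching [design_vaccine()].
#' @export
brute_force_design <- function(graph, config, affinity, alleles, catalog,
                               guard = 9) {
  m <- length(graph$epitopes)
  if (m > guard) {
    abort(
      sprintf("instance has %d epitopes; the enumeration guard is %d.", m, guard),
      class = "ev_error_guard"
    )
  }
  if (config$n_tours > 2) {
    abort("brute force supports at most 2 tours.", class = "ev_error_guard")
  }
  inst <- prepare_instance(graph, affinity, alleles, catalog)
  h <- effective_h(graph, config)
  obj_w <- objective_weights(config)
  n <- config$n_tours
  k <- config$max_epitopes
  gamma <- config$min_conservation * inst$n_pathogens

  best_obj <- -Inf
  best_tours <- NULL
  best_key <- NULL

  # every labelling of epitopes with 0 (unused) or a tour index 1..n
  n_assign <- (n + 1L)^m
  for (code in seq_len(n_assign) - 1L) {
    lab <- integer(m)
    c0 <- code
    for (i in seq_len(m)) {
      lab[i] <- c0 %% (n + 1L)
      c0 <- c0 %/% (n + 1L)
    }
    sizes <- tabulate(lab, nbins = n)
    if (any(sizes == 0L) || any(sizes > k)) next

    tours <- vector("list", n)
    feasible <- TRUE
    for (t in seq_len(n)) {
      members <- graph$epitopes[lab == t]
      ord <- min_tour_weight(graph, members)
      if (is.finite(h) && ord$weight > h + 1e-9) {
        feasible <- FALSE
        break
      }
      tours[[t]] <- ord$tour
    }
    if (!feasible) next

    sel_idx <- which(lab > 0L)
    if (sum(colSums(inst$tau_s[sel_idx, , drop = FALSE]) > 0) <
      config$min_pathogen_cover) {
      next
    }
    if (sum(colSums(inst$tau_a[sel_idx, , drop = FALSE]) > 0) <
      config$min_allele_cover) {
      next
    }
    if (sum(inst$conscount[sel_idx] - gamma) < -1e-9) next

    objective <- obj_w[["immunogenicity"]] * sum(inst$rewards[sel_idx]) +
      obj_w[["coverage"]] * sum(colSums(inst$tau_s[sel_idx, , drop = FALSE]) > 0) +
      obj_w[["conservation"]] * sum(inst$conscount[sel_idx]) / inst$n_pathogens
    key <- paste(vapply(tours, paste, character(1), collapse = ","), collapse = "|")
    if (objective > best_obj + 1e-12 ||
      (abs(objective - best_obj) <= 1e-12 && (is.null(best_key) || key < best_key))) {
      best_obj <- objective
      best_tours <- tours
      best_key <- key
    }
  }

  if (is.null(best_tours)) {
    abort("the design problem is infeasible under the given constraints.",
      class = "ev_infeasible"
    )
  }
  finish_solution(graph, config, inst, best_tours,
    status = "optimal", obj_w = obj_w, h = h
  )
}
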