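#' Trace the immunogenicity-cleavage Pareto frontier
#'
#' Treats string-of-beads design as a bi-objective problem — maximize the
#' vaccine immunogenicity \eqn{I(P)} and the cleavage score (the negative
#' total edge weight) simultaneously — and sweeps the frontier with the
#' augmented \eqn{\epsilon}-constraint method:
#'
#' 1. Two lexicographic solves establish the payoff range of the cleavage
#'    score: its value at the immunogenicity optimum, and its own maximum
#'    (refined by a second solve maximizing immunogenicity at that level).
#' 2. \eqn{\epsilon} is swept over `n_points` evenly spaced levels across
#'    that range (endpoints included).
#' 3. At each level the program maximizes
#'    \eqn{I(P) + \delta \cdot \mathrm{cleavage}} subject to cleavage score
#'    \eqn{\ge \epsilon}. The small augmentation term \eqn{\delta} discards
#'    weakly efficient solutions; in particular, each returned tour carries
#'    the best cleavage score achievable with its own epitope set, since
#'    reordering a set changes cleavage but not immunogenicity.
#' 4. Duplicate and dominated points are dropped.
#'
#' @inheritParams design_vaccine
#' @param n_points Number of \eqn{\epsilon} levels (default 11).
#' @param delta Augmentation coefficient; the default,
#'   \eqn{10^{-3} \cdot \mathrm{range}(I) / \mathrm{range}(\mathrm{cleavage})},
#'   keeps the term sub-dominant to any immunogenicity difference.
#' @return A tibble of class `ev_pareto`, sorted by `epsilon`, with columns
#'   `epsilon`, `immunogenicity`, `cleavage_score`, `n_epitopes`, `epitopes`
#'   (semicolon-joined) and a `solution` list column. The points are
#'   mutually non-dominated and immunogenicity is non-increasing in
#'   `epsilon`.
#' @export
pareto_frontier <- function(graph, config, affinity, alleles, catalog,
                            n_points = 11, delta = NULL) {
  if (graph$kind %in% c("mixture", "mosaic")) {
    abort(
      "the cleavage frontier needs meaningful junction weights (string_of_beads or custom graphs).",
      class = "ev_error"
    )
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L) {
    abort("`n_points` must be a positive integer.", class = "ev_error")
  }

  # payoff table via lexicographic solves
  p_imm <- solve_design(graph, config, affinity, alleles, catalog)
  imax <- p_imm$immunogenicity
  tol_i <- 1e-9 * max(1, abs(imax))
  p_imm <- solve_design(graph, config, affinity, alleles, catalog,
    imin = imax - tol_i, w_cleav = 1,
    override_weights = c(immunogenicity = 0, coverage = 0, conservation = 0)
  )
  c_lo <- p_imm$cleavage_score

  p_clv <- solve_design(graph, config, affinity, alleles, catalog,
    w_cleav = 1,
    override_weights = c(immunogenicity = 0, coverage = 0, conservation = 0)
  )
  c_hi <- p_clv$cleavage_score
  tol_c <- 1e-9 * max(1, abs(c_hi))
  p_clv <- solve_design(graph, config, affinity, alleles, catalog,
    wmax = -c_hi + tol_c, w_cleav = 0
  )
  imin_val <- p_clv$immunogenicity

  if (c_hi < c_lo) c_hi <- c_lo # numerically degenerate payoff
  crange <- c_hi - c_lo
  irange <- imax - imin_val
  if (is.null(delta)) {
    delta <- if (crange > 1e-12) 1e-3 * max(irange, 1e-9) / crange else 1e-6
  }

  eps <- if (n_points == 1L || crange <= 1e-12) {
    c_lo
  } else {
    seq(c_lo, c_hi, length.out = n_points)
  }

  points <- purrr::map(eps, function(e) {
    sol <- solve_design(graph, config, affinity, alleles, catalog,
      wmax = -e + tol_c, w_cleav = delta
    )
    tibble(
      epsilon = e,
      immunogenicity = sol$immunogenicity,
      cleavage_score = sol$cleavage_score,
      n_epitopes = sum(sol$tour_sizes),
      epitopes = paste(sort(unlist(sol$tours)), collapse = ";"),
      solution = list(sol)
    )
  })
  pts <- bind_rows(points)

  # collapse duplicates, then drop dominated points
  pts <- pts[!duplicated(round(cbind(pts$immunogenicity, pts$cleavage_score), 9)), ]
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any(
      pts$immunogenicity >= pts$immunogenicity[i] + 1e-9 &
        pts$cleavage_score >= pts$cleavage_score[i] - 1e-9 |
        pts$immunogenicity >= pts$immunogenicity[i] - 1e-9 &
          pts$cleavage_score >= pts$cleavage_score[i] + 1e-9
    )
  }, logical(1))
  pts <- pts[keep, ]
  pts <- pts[order(pts$epsilon), ]

  structure(pts,
    class = c("ev_pareto", class(tibble())),
    delta = delta,
    payoff = c(
      immunogenicity_max = imax, immunogenicity_at_best_cleavage = imin_val,
      cleavage_at_best_immunogenicity = c_lo, cleavage_max = c_hi
    )
  )
}
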