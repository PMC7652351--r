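#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a vaccine solution into one row per selected epitope
#'
#' @param x An `ev_solution`.
#' @param ... Unused.
#' @return A tibble with columns `tour`, `position`, `epitope`.
#' @method tidy ev_solution
#' @export
tidy.ev_solution <- function(x, ...) {
  purrr::map2(seq_along(x$tours), x$tours, function(t, tr) {
    if (!length(tr)) {
      return(NULL)
    }
    tibble(tour = t, position = seq_along(tr), epitope = tr)
  }) |>
    bind_rows()
}

#' One-row summary of a vaccine solution
#'
#' @param x An `ev_solution`.
#' @param ... Unused.
#' @method glance ev_solution
#' @export
glance.ev_solution <- function(x, ...) {
  tibble(
    kind = x$kind,
    status = x$status,
    objective = x$objective,
    immunogenicity = x$immunogenicity,
    cleavage_score = x$cleavage_score,
    n_tours = length(x$tours),
    n_epitopes = sum(x$tour_sizes),
    total_weight = sum(x$tour_weights),
    pathogens_covered = length(x$covered_pathogens),
    alleles_covered = length(x$covered_alleles)
  )
}

#' Tidy a Pareto frontier (drops the solution objects)
#'
#' @param x An `ev_pareto`.
#' @param ... Unused.
#' @method tidy ev_pareto
#' @export
tidy.ev_pareto <- function(x, ...) {
  as_tibble(x)[, setdiff(names(x), "solution")]
}

#' One-row summary of a Pareto frontier
#'
#' @param x An `ev_pareto`.
#' @param ... Unused.
#' @method glance ev_pareto
#' @export
glance.ev_pareto <- function(x, ...) {
  tibble(
    n_points = nrow(x),
    immunogenicity_max = max(x$immunogenicity),
    immunogenicity_min = min(x$immunogenicity),
    cleavage_score_max = max(x$cleavage_score),
    cleavage_score_min = min(x$cleavage_score),
    delta = attr(x, "delta")
  )
}

#' Plot the immunogenicity-cleavage Pareto frontier
#'
#' @param object An `ev_pareto`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ev_pareto
#' @export
autoplot.ev_pareto <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cleavage_score,
    y = .data$immunogenicity
  )) +
    ggplot2::geom_step(direction = "vh", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Cleavage score",
      y = "Immunogenicity",
      title = "Pareto frontier: immunogenicity vs junction cleavage"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cleavage-score decreases of a shuffle experiment
#'
#' @param object An `ev_shuffle`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ev_shuffle
#' @export
autoplot.ev_shuffle <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$decrease)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Cleavage-score decrease vs optimized ordering",
      y = "Permutations",
      title = "Random epitope permutations never beat the optimized ordering"
    ) +
    ggplot2::theme_minimal()
}

#' Plot positional coverage and immunogenicity tracks
#'
#' @param object An `ev_tracks` tibble from [positional_coverage()].
#' @param ... Unused.
#' @return A ggplot with the normalized coverage count and the potential
#'   immunogenicity per alignment column.
#' @method autoplot ev_tracks
#' @export
autoplot.ev_tracks <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(
      c("normalized_count", "potential_immunogenicity"),
      names_to = "track", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Alignment column", y = NULL) +
    ggplot2::theme_minimal()
}
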