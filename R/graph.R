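#' Build the design graph for a vaccine kind
#'
#' Assembles the complete weighted directed graph on which the vaccine
#' design problem is solved. Vertices are the candidate epitopes plus a
#' terminus vertex `s` representing the N- and C-termini of each
#' polypeptide; the edge weights depend on the design kind:
#'
#' * `mixture` — epitopes are delivered separately, ordering is meaningless:
#'   all weights are 0 and the edge-weight budget is unbounded.
#' * `string_of_beads` — epitopes are concatenated; each inter-epitope edge
#'   carries the cleavage junction weight of [cleavage_edge_weight()], and
#'   edges touching the terminus weigh 0.
#' * `mosaic` — epitopes are merged at their longest suffix-prefix overlap;
#'   edges carry [overlap_weight()], so the weight of a full tour equals the
#'   length of the assembled mosaic polypeptide in amino acids.
#' * `custom` — weights are loaded verbatim from `edge_table` (e.g.
#'   precomputed weights for spacer-joined epitope pairs); rows with
#'   `from`/`to` equal to the reserved label `"s"` set terminus edges,
#'   which default to 0 when absent.
#'
#' @param epitopes Character vector of distinct epitope sequences.
#' @param kind One of `"mixture"`, `"string_of_beads"`, `"mosaic"`,
#'   `"custom"`.
#' @param pssm Cleavage matrix, required for `string_of_beads`.
#' @param edge_table Data frame with columns `from`, `to`, `weight`,
#'   required for `custom`; must contain every ordered epitope pair.
#' @param h Edge-weight budget per tour (`Inf` allowed; forced to `Inf` for
#'   mixtures). For mosaics, `h` is the maximum polypeptide length.
#' @param K,beta Junction scoring parameters passed to
#'   [cleavage_edge_weight()].
#' @return An object of class `ev_graph`: the dense weight matrix over the
#'   terminus (first row/column, labelled `"s"`) and all epitopes, the
#'   design `kind`, and the budget `h`.
#' @export
build_design_graph <- function(epitopes,
                               kind = c("mixture", "string_of_beads", "mosaic", "custom"),
                               pssm = NULL, edge_table = NULL, h = Inf,
                               K = 2, beta = 0.1) {
  kind <- match.arg(kind)
  if (length(epitopes) == 0L) {
    abort("`epitopes` must be non-empty.", class = "ev_error")
  }
  if (anyDuplicated(epitopes)) {
    abort("`epitopes` must be distinct.", class = "ev_error")
  }
  m <- length(epitopes)
  labels <- c(DEPOT_LABEL, epitopes)
  w <- matrix(0, m + 1L, m + 1L, dimnames = list(labels, labels))
  diag(w) <- NA_real_

  if (kind == "mixture") {
    h <- Inf
  } else if (kind == "string_of_beads") {
    if (is.null(pssm)) {
      abort("string-of-beads graphs require a cleavage `pssm`.", class = "ev_error")
    }
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) {
          w[i + 1L, j + 1L] <- cleavage_edge_weight(
            epitopes[i], epitopes[j], pssm,
            K = K, beta = beta
          )
        }
      }
    }
  } else if (kind == "mosaic") {
    w[1L, -1L] <- nchar(epitopes)
    w[-1L, 1L] <- 0
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) {
          w[i + 1L, j + 1L] <- overlap_weight(epitopes[i], epitopes[j])
        }
      }
    }
  } else { # custom
    if (is.null(edge_table)) {
      abort("custom graphs require an `edge_table`.", class = "ev_error")
    }
    if (!all(c("from", "to", "weight") %in% names(edge_table))) {
      abort("`edge_table` must have columns `from`, `to`, `weight`.", class = "ev_error")
    }
    need <- expand.grid(from = epitopes, to = epitopes, stringsAsFactors = FALSE)
    need <- need[need$from != need$to, ]
    key <- paste(edge_table$from, edge_table$to, sep = "\r")
    missing <- !(paste(need$from, need$to, sep = "\r") %in% key)
    if (any(missing)) {
      abort(
        sprintf(
          "edge table is missing %d required epitope pair(s), e.g. %s -> %s",
          sum(missing), need$from[missing][1], need$to[missing][1]
        ),
        class = "ev_error_missing_edge"
      )
    }
    idx <- function(v) ifelse(v == DEPOT_LABEL, 1L, match(v, epitopes) + 1L)
    keep <- (edge_table$from %in% c(epitopes, DEPOT_LABEL)) &
      (edge_table$to %in% c(epitopes, DEPOT_LABEL)) &
      (edge_table$from != edge_table$to)
    et <- edge_table[keep, ]
    w[cbind(idx(et$from), idx(et$to))] <- et$weight
  }

  if (any(!is.finite(w[upper.tri(w) | lower.tri(w)]))) {
    abort("all edge weights must be finite.", class = "ev_error")
  }

  structure(
    list(epitopes = epitopes, kind = kind, w = w, h = h),
    class = "ev_graph"
  )
}

#' @export
print.ev_graph <- function(x, ...) {
  cat(sprintf(
    "# Design graph (%s): %d epitopes + terminus, h = %s\n",
    x$kind, length(x$epitopes), format(x$h)
  ))
  invisible(x)
}

# Ordered edge weights of the closed tour s -> v1 -> ... -> vm -> s,
# including both terminus edges.
tour_edge_weights <- function(graph, tour) {
  if (length(tour) == 0L) {
    return(numeric())
  }
  idx <- match(tour, graph$epitopes)
  if (anyNA(idx)) {
    abort(
      sprintf(
        "epitope(s) not in graph: %s",
        paste(tour[is.na(idx)], collapse = ", ")
      ),
      class = "ev_error_unknown_epitope"
    )
  }
  path <- c(1L, idx + 1L, 1L)
  graph$w[cbind(path[-length(path)], path[-1L])]
}

tour_weight <- function(graph, tour) sum(tour_edge_weights(graph, tour))

# All permutations of seq_len(n), in lexicographic order. n is tiny here
# (tour sizes), so the recursive construction is fine.
permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Minimum closed-tour weight over all orderings of `epitopes`, with the
# lexicographically first minimizing ordering. Exhaustive; used by the
# brute-force oracle and the shuffle analysis.
min_tour_weight <- function(graph, epitopes) {
  if (length(epitopes) == 0L) {
    return(list(weight = 0, tour = character()))
  }
  perms <- permutations(length(epitopes))
  best <- Inf
  best_tour <- NULL
  for (r in seq_len(nrow(perms))) {
    tour <- epitopes[perms[r, ]]
    wsum <- tour_weight(graph, tour)
    if (wsum < best - 1e-12) {
      best <- wsum
      best_tour <- tour
    }
  }
  list(weight = best, tour = best_tour)
}
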