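#' Positional entropy of an aligned antigen set
#'
#' Shannon entropy (bits) of the residue distribution in each alignment
#' column, quantifying sequence variation along the antigen. Columns whose
#' consensus symbol is a gap are dropped before smoothing (they describe
#' insertions carried by a minority of sequences); consensus ties are broken
#' by a fixed residue order for determinism. The smoothed track is a
#' centered moving average over the retained columns, truncated at the track
#' ends.
#'
#' @param alignment A data frame with columns `id` and `sequence`:
#'   equal-length gapped sequences (gap `-`).
#' @param window Odd moving-average window in columns (default 9, one
#'   epitope length).
#' @param gaps Whether gap characters inside retained columns count as a
#'   21st symbol (`"include"`, default) or are dropped from the column
#'   distribution (`"exclude"`).
#' @return A tibble with one row per retained column: `column` (original
#'   alignment coordinate), `consensus`, `entropy`, `smoothed_entropy`.
#' @export
positional_entropy <- function(alignment, window = 9L,
                               gaps = c("include", "exclude")) {
  gaps <- match.arg(gaps)
  if (!is.data.frame(alignment) || nrow(alignment) == 0L) {
    abort("`alignment` must be a non-empty data frame with `id` and `sequence`.",
      class = "ev_error"
    )
  }
  widths <- nchar(alignment$sequence)
  if (length(unique(widths)) != 1L) {
    abort("aligned sequences must all have the same length.", class = "ev_error")
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1L) {
    abort("`window` must be a positive integer.", class = "ev_error")
  }

  chars <- do.call(rbind, seq_chars(alignment$sequence))
  symbols <- c(AA_ALPHABET, "-")
  per_col <- purrr::map(seq_len(ncol(chars)), function(j) {
    col <- chars[, j]
    counts <- table(factor(col, levels = symbols))
    consensus <- symbols[which.max(counts)]
    obs <- if (gaps == "exclude") col[col != "-"] else col
    p <- as.numeric(table(factor(obs, levels = symbols)))
    p <- p[p > 0] / length(obs)
    tibble(
      column = j,
      consensus = consensus,
      entropy = -sum(p * log2(p))
    )
  })
  track <- bind_rows(per_col) |>
    filter(.data$consensus != "-")

  # centered moving average with truncated edges
  n <- nrow(track)
  half <- window %/% 2L
  track$smoothed_entropy <- vapply(seq_len(n), function(i) {
    mean(track$entropy[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  track
}

#' Positional coverage and potential immunogenicity tracks
#'
#' Maps every occurrence of each vaccine epitope in each (ungapped) pathogen
#' sequence through the gapped alignment, and accumulates per alignment
#' column: the number of epitope occurrences covering the column, a
#' max-normalized variant of that count, and the *potential immunogenicity*
#' — the summed population-weighted immunogenicity of all epitopes covering
#' the column. Together with [positional_entropy()] these tracks show which
#' antigen regions a vaccine concentrates on and how variable they are.
#'
#' @inheritParams positional_entropy
#' @param epitopes Character vector of vaccine epitopes; every epitope must
#'   occur in at least one pathogen sequence.
#' @param affinity,alleles Used to weight epitopes by their immunogenicity.
#' @param catalog Epitope catalog (defines the epitope length).
#' @return A tibble with one row per alignment column: `column`,
#'   `coverage_count`, `normalized_count`, `potential_immunogenicity`.
#' @export
positional_coverage <- function(alignment, epitopes, affinity, alleles, catalog) {
  if (!is.data.frame(alignment) || nrow(alignment) == 0L) {
    abort("`alignment` must be a non-empty data frame.", class = "ev_error")
  }
  widths <- unique(nchar(alignment$sequence))
  if (length(widths) != 1L) {
    abort("aligned sequences must all have the same length.", class = "ev_error")
  }
  epitopes <- unique(epitopes)
  rewards <- epitope_rewards(epitopes, affinity, alleles)

  counts <- numeric(widths)
  immuno <- numeric(widths)
  seen <- setNames(logical(length(epitopes)), epitopes)

  for (r in seq_len(nrow(alignment))) {
    chars <- seq_chars(alignment$sequence[r])[[1]]
    nongap <- which(chars != "-")
    plain <- paste(chars[nongap], collapse = "")
    np <- length(nongap)
    for (e in epitopes) {
      L <- nchar(e)
      if (np < L) next
      starts <- seq_len(np - L + 1L)
      hits <- starts[substring(plain, starts, starts + L - 1L) == e]
      for (st in hits) {
        cols <- nongap[st:(st + L - 1L)]
        counts[cols] <- counts[cols] + 1
        immuno[cols] <- immuno[cols] + rewards[[e]]
        seen[[e]] <- TRUE
      }
    }
  }
  if (length(epitopes) && !all(seen)) {
    abort(
      sprintf(
        "epitope(s) absent from every pathogen sequence: %s",
        paste(names(seen)[!seen], collapse = ", ")
      ),
      class = "ev_error"
    )
  }

  out <- tibble(
    column = seq_len(widths),
    coverage_count = counts,
    normalized_count = if (max(counts) > 0) counts / max(counts) else counts,
    potential_immunogenicity = immuno
  )
  class(out) <- c("ev_tracks", class(out))
  out
}
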