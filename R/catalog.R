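#' Extract candidate epitopes from antigen sequences
#'
#' Slides a window of `length` residues over every antigen and collects each
#' distinct window as a candidate epitope, together with the set of antigens
#' (pathogen sequences) that contain it. An epitope occurring at several
#' positions of the same antigen counts once towards that antigen: incidence
#' is binary. Windows containing the ambiguity code `'X'` are excluded, since
#' binding and cleavage predictors cannot score ambiguous residues.
#'
#' The *conservation* of an epitope is the number of antigens containing it;
#' highly conserved epitopes mark slowly mutating regions of the pathogen.
#'
#' @param antigens A data frame with columns `id` (unique antigen identifiers)
#'   and `sequence` (uppercase amino-acid sequences over the 20 canonical
#'   residues, plus optional `X`).
#' @param length Epitope length in residues (default 9, the typical length of
#'   an MHC class I ligand).
#' @return A tibble of class `ev_catalog`, sorted lexicographically by
#'   epitope, with columns `epitope`, `conservation` (number of antigens
#'   containing the epitope) and `pathogens` (list column of antigen ids).
#'   The full antigen panel is kept in the `pathogen_ids` attribute, so that
#'   coverage fractions are computed against all input antigens, including
#'   those too short to contribute an epitope.
#' @examples
#' antigens <- tibble::tibble(
#'   id = c("s1", "s2"),
#'   sequence = c("ACDEFGHIKL", "CDEFGHIKLM")
#' )
#' extract_epitopes(antigens)
#' @export
extract_epitopes <- function(antigens, length = 9L) {
  if (!is.data.frame(antigens) || !all(c("id", "sequence") %in% names(antigens))) {
    abort("`antigens` must be a data frame with columns `id` and `sequence`.",
      class = "ev_error"
    )
  }
  if (nrow(antigens) == 0L) {
    abort("no input sequences", class = "ev_error_no_input")
  }
  if (anyDuplicated(antigens$id)) {
    abort("antigen ids must be unique.", class = "ev_error")
  }
  if (any(is.na(antigens$sequence)) || any(nchar(antigens$sequence) == 0L)) {
    abort("antigen sequences must be non-empty.", class = "ev_error")
  }
  length <- as.integer(length)
  if (is.na(length) || length < 1L) {
    abort("`length` must be a positive integer.", class = "ev_error")
  }
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), antigens$sequence)
  if (any(bad)) {
    abort(
      sprintf(
        "antigen(s) %s contain characters outside the amino-acid alphabet.",
        paste(antigens$id[bad], collapse = ", ")
      ),
      class = "ev_error"
    )
  }

  occ <- purrr::map2(antigens$id, antigens$sequence, function(id, seq) {
    n <- nchar(seq)
    if (n < length) {
      return(NULL)
    }
    starts <- seq_len(n - length + 1L)
    windows <- substring(seq, starts, starts + length - 1L)
    windows <- unique(windows[!grepl("X", windows, fixed = TRUE)])
    if (!base::length(windows)) {
      return(NULL)
    }
    tibble(pathogen = id, epitope = windows)
  })
  occ <- bind_rows(occ)

  if (nrow(occ) == 0L) {
    cat <- tibble(
      epitope = character(),
      conservation = integer(),
      pathogens = list()
    )
  } else {
    cat <- occ |>
      group_by(.data$epitope) |>
      summarise(
        conservation = dplyr::n(),
        pathogens = list(.data$pathogen),
        .groups = "drop"
      ) |>
      arrange(.data$epitope)
  }

  new_catalog(cat, pathogen_ids = antigens$id, epitope_length = length)
}

new_catalog <- function(df, pathogen_ids, epitope_length) {
  structure(
    as_tibble(df),
    class = c("ev_catalog", class(as_tibble(df))),
    pathogen_ids = pathogen_ids,
    epitope_length = as.integer(epitope_length)
  )
}

#' Antigen panel of an epitope catalog
#'
#' @param catalog An `ev_catalog`.
#' @return For `pathogen_ids()`, the character vector of antigen ids the
#'   catalog was built from; for `n_pathogens()`, its length.
#' @export
pathogen_ids <- function(catalog) {
  ids <- attr(catalog, "pathogen_ids")
  if (is.null(ids)) {
    abort(
      "catalog has lost its `pathogen_ids` attribute; rebuild it with `extract_epitopes()` or `read_catalog()`.",
      class = "ev_error"
    )
  }
  ids
}

#' @rdname pathogen_ids
#' @export
n_pathogens <- function(catalog) length(pathogen_ids(catalog))

#' @export
print.ev_catalog <- function(x, ...) {
  cat(sprintf(
    "# Epitope catalog: %d epitopes (length %d) from %d antigens\n",
    nrow(x), attr(x, "epitope_length") %||% NA_integer_, n_pathogens(x)
  ))
  NextMethod()
}

# Incidence indicators for a subset of epitopes as a logical matrix
# (epitope x pathogen). Internal.
incidence_matrix <- function(catalog, epitopes = catalog$epitope) {
  ids <- pathogen_ids(catalog)
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
  m <- matrix(FALSE, nrow = length(epitopes), ncol = length(ids),
    dimnames = list(epitopes, ids)
  )
  for (i in seq_along(idx)) {
    m[i, catalog$pathogens[[idx[i]]]] <- TRUE
  }
  m
}
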