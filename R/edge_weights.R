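#' Mosaic overlap edge weight
#'
#' Length added to a growing mosaic polypeptide when epitope `v_j` is
#' appended after `v_i`, merging the two at their longest suffix-prefix
#' overlap:
#' \deqn{w(e_{ij}) = |v_j| - \max\{l : \mathrm{suffix}_l(v_i) = \mathrm{prefix}_l(v_j)\}}
#' Edges touching the terminus vertex get the boundary values: leaving the
#' terminus costs the full length of the entered epitope, returning to it
#' costs nothing. Pass `NA` (or the reserved label `"s"`) for the terminus.
#'
#' @param v_i,v_j Epitope sequences, or `NA`/`"s"` for the terminus (at most
#'   one of the two).
#' @return A non-negative integer. Zero iff `v_j` is completely absorbed by
#'   `v_i` (identical epitopes).
#' @examples
#' overlap_weight("ACDEFGHIK", "EFGHIKLMN") # overlap 6, weight 3
#' @export
overlap_weight <- function(v_i, v_j) {
  di <- is_depot(v_i)
  dj <- is_depot(v_j)
  if (di && dj) {
    abort("at most one of `v_i`, `v_j` may be the terminus.", class = "ev_error")
  }
  if (di) {
    return(nchar(v_j))
  }
  if (dj) {
    return(0L)
  }
  ni <- nchar(v_i)
  nj <- nchar(v_j)
  for (l in seq(min(ni, nj), 0L)) {
    if (l == 0L || substr(v_i, ni - l + 1L, ni) == substr(v_j, 1L, l)) {
      return(nj - l)
    }
  }
}

#' Read and write proteasomal cleavage matrices
#'
#' A cleavage position-specific scoring matrix gives the log-likelihood
#' contribution \eqn{\psi(a, i)} of residue \eqn{a} at offset
#' \eqn{i \in \{-4, \dots, +1\}} relative to a putative cleavage site (the
#' P4-P2' window around the scissile bond). Files are whitespace-delimited:
#' a header row of offsets `-4 ... 1`, then one row per residue.
#'
#' @param path File path.
#' @param pssm A 20 x 6 numeric matrix with residue rownames and offset
#'   colnames `-4` to `1`.
#' @return `read_pssm()` returns the matrix; `write_pssm()` its path,
#'   invisibly.
#' @export
read_pssm <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- rownames(df)
  assert_pssm(m)
  m
}

#' @rdname read_pssm
#' @export
write_pssm <- function(pssm, path) {
  assert_pssm(pssm)
  utils::write.table(pssm, path, quote = FALSE, col.names = NA)
  invisible(path)
}

assert_pssm <- function(pssm) {
  offsets <- as.character(-4:1)
  if (!is.matrix(pssm) || !all(AA_RESIDUES %in% rownames(pssm)) ||
    !all(offsets %in% colnames(pssm))) {
    abort(
      "`pssm` must be a numeric matrix with all 20 residue rows and offset columns -4..1.",
      class = "ev_error"
    )
  }
  if (any(!is.finite(pssm[AA_RESIDUES, offsets]))) {
    abort("`pssm` must contain only finite values.", class = "ev_error")
  }
  invisible(pssm)
}

#' Proteasomal cleavage site score
#'
#' Log-likelihood that the proteasome cleaves `sequence` at position `k`,
#' i.e. at the bond before the residue with 0-based index `k`:
#' \deqn{\phi_C(s, k) = \sum_{i=-4}^{+1} \psi(s_{k+i}, i)}
#' The scoring window spans four residues left and two residues right of the
#' bond, so `k` must satisfy \eqn{4 \le k \le |s| - 2}. A positive score
#' marks a likely cleavage site.
#'
#' @param sequence Peptide sequence (uppercase residues).
#' @param k Cleavage position: 0-based index of the residue following the
#'   bond.
#' @param pssm Cleavage matrix, see [read_pssm()].
#' @return The cleavage score (a real number).
#' @export
cleavage_site_score <- function(sequence, k, pssm) {
  assert_pssm(pssm)
  n <- nchar(sequence)
  if (k - 4 < 0 || k + 1 > n - 1) {
    abort(
      sprintf("cleavage window out of bounds at position %d (sequence length %d).", k, n),
      class = "ev_error_window"
    )
  }
  offs <- -4:1
  res <- substring(sequence, k + offs + 1L, k + offs + 1L)
  sum(pssm[cbind(res, as.character(offs))])
}

#' Cleavage junction edge weight
#'
#' Weight of the string-of-beads edge joining epitope `e_i` to epitope
#' `e_j`: the negative cleavage score at the junction, plus a small penalty
#' rewarding *low* cleavage at the `K` positions on either side of it
#' (off-site cleavage would destroy the flanking epitopes):
#' \deqn{w(e_{ij}) = -\phi_C(e_i e_j, \ell) + \beta \sum_{k=1}^{K}
#'   \left[\phi_C(e_i e_j, \ell - k) + \phi_C(e_i e_j, \ell + k)\right]}
#' with \eqn{\ell = |e_i|} the junction position. Defaults `K = 2`,
#' `beta = 0.1`. A negative weight marks a junction cleavage site.
#'
#' @param e_i,e_j Epitope sequences.
#' @param pssm Cleavage matrix.
#' @param K Number of flanking off-site positions on each side.
#' @param beta Off-site penalty weight in \eqn{[0, 1]}.
#' @return The edge weight (a real number; lower is better).
#' @export
cleavage_edge_weight <- function(e_i, e_j, pssm, K = 2, beta = 0.1) {
  l <- nchar(e_i)
  s <- paste0(e_i, e_j)
  phi <- function(k) cleavage_site_score(s, k, pssm)
  w <- -phi(l)
  if (K > 0) {
    for (k in seq_len(K)) {
      w <- w + beta * (phi(l - k) + phi(l + k))
    }
  }
  w
}

#' Cleavage score of a tour
#'
#' The negative sum of a tour's edge weights. For a string-of-beads design
#' this is the construct's overall cleavage score: higher means the epitope
#' junctions are more likely to be cleaved correctly.
#'
#' @param weights Numeric vector of edge weights (possibly empty).
#' @return `-sum(weights)`.
#' @export
cleavage_score <- function(weights) -sum(weights)
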