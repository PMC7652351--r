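#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows n row_number across
#' @importFrom stats setNames rnorm runif rbinom qlnorm plnorm
#' @importFrom utils head tail
NULL

# The 20 canonical residues, in the fixed order used for deterministic
# tie-breaking throughout the package.
AA_RESIDUES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Symbols admitted in antigen sequences ('X' = ambiguous residue).
AA_ALPHABET <- c(AA_RESIDUES, "X")

# Reserved label for the polypeptide terminus vertex in edge tables and
# graph dimnames. Cannot collide with an epitope (epitopes are uppercase).
DEPOT_LABEL <- "s"

is_depot <- function(x) is.na(x) | x == DEPOT_LABEL

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "ev_error")
  }
}

# Split sequences into character matrices / vectors.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

#' Size of the sequential enumeration search space
#'
#' Number of candidate designs a stage-wise method would have to enumerate to
#' explore all ordered selections of `k` epitopes out of `n_epitopes`,
#' computed as \eqn{(N - k)^{k+1}}. With a candidate pool in the tens of
#' thousands this is astronomically large, which is why the joint
#' selection-and-assembly problem is solved as an integer linear program
#' instead of by enumeration.
#'
#' @param n_epitopes Size of the candidate epitope pool.
#' @param k Number of epitopes in the vaccine.
#' @return A double (the count overflows integer storage immediately).
#' @examples
#' search_space_size(13500, 10)
#' @export
search_space_size <- function(n_epitopes, k) {
  assert_scalar_number(n_epitopes, "n_epitopes")
  assert_scalar_number(k, "k")
  (n_epitopes - k)^(k + 1)
}
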