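# Shared fixture builders and independent oracles. Everything here is
# generated in code; no data files.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# --- small deterministic fixtures -------------------------------------------

toy_antigens <- function() {
  tibble::tibble(
    id = c("s1", "s2"),
    sequence = c("ACDEFGHIKL", "CDEFGHIKLM")
  )
}

# Single-allele affinity table with explicit immunogenicity scores.
toy_affinity <- function(epitopes, scores, allele = "A*01", binder = TRUE) {
  tibble::tibble(
    epitope = epitopes,
    allele = allele,
    ic50 = NA_real_,
    immunogenicity = scores,
    binder = binder
  )
}

toy_alleles <- function(frequency = 1, locus = "A", allele = "A*01") {
  tibble::tibble(allele = allele, frequency = frequency, locus = locus)
}

# Catalog in which each epitope is its own single-pathogen antigen.
catalog_of <- function(epitopes) {
  extract_epitopes(tibble::tibble(
    id = sprintf("p%02d", seq_along(epitopes)),
    sequence = epitopes
  ), length = nchar(epitopes[1]))
}

# A uniform cleavage matrix: every residue contributes `value` at every
# offset, so every cleavage site scores 6 * value.
constant_pssm <- function(value = 0) {
  matrix(value, 20, 6, dimnames = list(AA20, as.character(-4:1)))
}

# --- synthetic instance shared by the solver tests --------------------------

# Returns catalog/affinity/alleles/pssm plus the `n_epitopes` epitopes with
# the largest reward (deterministic for a given seed).
synth_instance <- function(seed = 11, n_epitopes = 6, n_pathogens = 8,
                           seq_length = 30, mutation_rate = 0.08,
                           binder_fraction = 0.3) {
  spec <- synthetic_spec(
    seed = seed, n_pathogens = n_pathogens, seq_length = seq_length,
    mutation_rate = mutation_rate, binder_fraction = binder_fraction,
    n_alleles = 4
  )
  antigens <- generate_antigens(spec)
  catalog <- extract_epitopes(antigens)
  alleles <- generate_alleles(spec)
  affinity <- generate_affinities(spec, catalog, alleles)
  pssm <- generate_pssm(spec)
  rewards <- affinity |>
    dplyr::inner_join(alleles[, c("allele", "frequency")], by = "allele") |>
    dplyr::group_by(epitope) |>
    dplyr::summarise(reward = sum(frequency * immunogenicity), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(reward), epitope)
  list(
    spec = spec, antigens = antigens, catalog = catalog,
    alleles = alleles, affinity = affinity, pssm = pssm,
    epitopes = head(rewards$epitope, n_epitopes)
  )
}

# --- hand-built cocktail instance -------------------------------------------

# Eight pathogens, each carrying exactly one private 9-mer epitope, so a
# single tour of k epitopes covers at most k pathogens. Full coverage of the
# 8 pathogens therefore needs a cocktail.
cocktail_instance <- function() {
  epitopes <- vapply(1:8, function(i) {
    paste(rep(AA20[i], 9), collapse = "")
  }, character(1))
  antigens <- tibble::tibble(
    id = sprintf("path%d", 1:8),
    sequence = epitopes
  )
  catalog <- extract_epitopes(antigens)
  affinity <- toy_affinity(epitopes, scores = seq(0.9, 0.2, length.out = 8))
  alleles <- toy_alleles(frequency = 0.5)
  graph <- build_design_graph(epitopes, "mixture")
  list(
    graph = graph, catalog = catalog, affinity = affinity,
    alleles = alleles, epitopes = epitopes
  )
}

# --- hand-built bi-objective instance ---------------------------------------

# Six epitopes on a custom graph engineered so the exact Pareto frontier has
# four points whose cleavage scores (-10, -5, 0, 10) are widely separated:
# an evenly spaced epsilon grid cannot miss any of them. Rewards 10/9/8
# (cleavage-hostile epitopes, pairwise weight 5) vs 1/1/1 (cleavage-friendly,
# pairwise weight -5).
pareto_instance <- function() {
  epitopes <- vapply(1:6, function(i) {
    paste(rep(AA20[i + 8], 9), collapse = "")
  }, character(1))
  rewards <- c(10, 9, 8, 1, 1, 1)
  pairs <- expand.grid(i = 1:6, j = 1:6)
  pairs <- pairs[pairs$i != pairs$j, ]
  weight <- ifelse(pairs$i >= 4 & pairs$j >= 4, -5, 5)
  edge_table <- tibble::tibble(
    from = epitopes[pairs$i], to = epitopes[pairs$j], weight = weight
  )
  graph <- build_design_graph(epitopes, "custom", edge_table = edge_table)
  list(
    graph = graph,
    catalog = catalog_of(epitopes),
    affinity = toy_affinity(epitopes, rewards),
    alleles = toy_alleles(frequency = 1),
    epitopes = epitopes
  )
}

# --- independent oracles -----------------------------------------------------

# Longest suffix-prefix overlap by brute-force scan over every l.
naive_overlap_weight <- function(a, b) {
  best <- 0L
  for (l in seq_len(min(nchar(a), nchar(b)))) {
    if (substr(a, nchar(a) - l + 1, nchar(a)) == substr(b, 1, l)) best <- l
  }
  nchar(b) - best
}

# All permutations of 1..n (independent of the package's own generator).
oracle_perms <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  out <- list()
  for (sub in oracle_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Closed-tour weight s -> tour -> s straight from the graph matrix.
oracle_tour_weight <- function(graph, tour) {
  idx <- match(tour, graph$epitopes) + 1L
  path <- c(1L, idx, 1L)
  sum(graph$w[cbind(path[-length(path)], path[-1L])])
}

# Best (maximum) cleavage score over all orderings of an epitope set.
oracle_best_cleavage <- function(graph, epitopes) {
  m <- length(epitopes)
  best <- -Inf
  for (p in oracle_perms(m)) {
    best <- max(best, -oracle_tour_weight(graph, epitopes[p]))
  }
  best
}

# Exact Pareto set (immunogenicity, best cleavage score) over all single
# tours of at most k epitopes, by exhaustive subset enumeration.
oracle_pareto_set <- function(graph, affinity, alleles, k) {
  m <- length(graph$epitopes)
  rewards <- setNames(affinity$immunogenicity * alleles$frequency[1], affinity$epitope)
  pts <- list()
  for (code in 1:(2^m - 1)) {
    members <- graph$epitopes[bitwAnd(code, 2^(seq_len(m) - 1)) > 0]
    if (length(members) > k) next
    pts[[length(pts) + 1L]] <- c(
      immunogenicity = sum(rewards[members]),
      cleavage = oracle_best_cleavage(graph, members)
    )
  }
  pts <- do.call(rbind, pts)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any(pts[, 1] >= pts[i, 1] & pts[, 2] >= pts[i, 2] &
      (pts[, 1] > pts[i, 1] | pts[, 2] > pts[i, 2]))
  }, logical(1))
  unique(round(pts[keep, , drop = FALSE], 9))
}

expect_no_violations <- function(violations) {
  expect_equal(nrow(violations), 0L)
}
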