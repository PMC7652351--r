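test_that("generators are bit-identical under the same seed and independent across ops", {
  spec <- synthetic_spec(seed = 90)
  expect_identical(generate_antigens(spec), generate_antigens(spec))
  expect_identical(generate_alleles(spec), generate_alleles(spec))
  expect_identical(generate_pssm(spec), generate_pssm(spec))
  cat1 <- extract_epitopes(generate_antigens(spec))
  all1 <- generate_alleles(spec)
  expect_identical(
    generate_affinities(spec, cat1, all1),
    generate_affinities(spec, cat1, all1)
  )
})

test_that("zero mutation rate yields identical sequences, full conservation", {
  spec <- synthetic_spec(seed = 91, n_pathogens = 12, seq_length = 40, mutation_rate = 0)
  ant <- generate_antigens(spec)
  expect_equal(length(unique(ant$sequence)), 1L)
  cat_ <- extract_epitopes(ant)
  expect_true(all(cat_$conservation == 12L))
})

test_that("pairwise identity matches the substitution model expectation", {
  # two sequences agree at a site iff neither mutated, or both mutated to
  # the same of the 19 alternatives: p = (1-mu)^2 + mu^2/19
  mu <- 0.5
  spec <- synthetic_spec(
    seed = 92, n_pathogens = 20, seq_length = 60,
    mutation_rate = mu
  )
  ant <- generate_antigens(spec)
  chars <- do.call(rbind, strsplit(ant$sequence, ""))
  idents <- c()
  for (i in 1:19) {
    for (j in (i + 1):20) {
      idents <- c(idents, mean(chars[i, ] == chars[j, ]))
    }
  }
  expected <- (1 - mu)^2 + mu^2 / 19
  expect_lt(abs(mean(idents) - expected), 0.03)
})

test_that("allele frequencies form valid per-locus sub-simplexes", {
  spec <- synthetic_spec(seed = 93, n_alleles = 7, locus_total = 0.8)
  al <- generate_alleles(spec)
  expect_equal(nrow(al), 7L)
  expect_false(anyDuplicated(al$allele) > 0)
  tot <- tapply(al$frequency, al$locus, sum)
  expect_true(all(abs(tot - 0.8) < 1e-12))
})

test_that("binder fractions behave at the extremes and in the middle", {
  spec0 <- synthetic_spec(seed = 94, n_pathogens = 3, seq_length = 20, binder_fraction = 0)
  ant <- generate_antigens(spec0)
  cat_ <- extract_epitopes(ant)
  al <- generate_alleles(spec0)
  aff0 <- generate_affinities(spec0, cat_, al)
  expect_false(any(aff0$binder))
  expect_equal(population_coverage(cat_$epitope, aff0, al), 0)

  spec1 <- synthetic_spec(seed = 94, n_pathogens = 3, seq_length = 20, binder_fraction = 1)
  aff1 <- generate_affinities(spec1, cat_, al)
  expect_true(all(aff1$binder))

  # empirical fraction within the binomial 99% interval
  spec <- synthetic_spec(seed = 95, n_pathogens = 10, seq_length = 30, binder_fraction = 0.1)
  ant <- generate_antigens(spec)
  cat_ <- extract_epitopes(ant)
  al <- generate_alleles(spec)
  aff <- generate_affinities(spec, cat_, al)
  n <- nrow(aff)
  expect_gte(n, 300L)
  lo <- qbinom(0.005, n, 0.1)
  hi <- qbinom(0.995, n, 0.1)
  expect_gte(sum(aff$binder), lo)
  expect_lte(sum(aff$binder), hi)
  # binder indicators consistent with the threshold
  expect_equal(aff$binder, aff$ic50 <= 500)
  expect_equal(aff$immunogenicity, ic50_to_immunogenicity(aff$ic50))
})

test_that("the cleavage motif raises junction scores after motif residues", {
  spec <- synthetic_spec(seed = 96, motif_strength = 2)
  pssm <- generate_pssm(spec)
  motif_mean <- mean(pssm[spec$motif_residues, "-1"])
  other_mean <- mean(pssm[setdiff(AA20, spec$motif_residues), "-1"])
  expect_gt(motif_mean - other_mean, 1) # strength 2, entry noise sd 0.3

  # difference of mean cleavage scores over junctions that differ only in
  # the residue preceding the bond
  base <- "ACDEFGHIK"
  with_motif <- cleavage_site_score(paste0(substr(base, 1, 8), "L", "CDEFGHIK"), 9, pssm)
  without <- cleavage_site_score(paste0(substr(base, 1, 8), "G", "CDEFGHIK"), 9, pssm)
  expect_equal(with_motif - without, pssm["L", "-1"] - pssm["G", "-1"])
})

test_that("design and evaluation agree on immunogenicity (round trip)", {
  inst <- synth_instance(seed = 97, n_epitopes = 6)
  g <- build_design_graph(inst$epitopes, "mixture")
  cfg <- design_config(n_tours = 1, max_epitopes = 3)
  sol <- design_vaccine(g, cfg, inst$affinity, inst$alleles, inst$catalog)
  eps <- unlist(sol$tours)
  expect_equal(
    sol$immunogenicity,
    vaccine_immunogenicity(eps, inst$affinity, inst$alleles),
    tolerance = 1e-9
  )
  m <- evaluate_vaccine(sol, inst$affinity, inst$alleles, inst$catalog)
  expect_equal(m$immunogenicity, sol$immunogenicity, tolerance = 1e-9)
})

test_that("epitopes from a half panel overlap the full panel far beyond chance", {
  spec <- synthetic_spec(seed = 98, n_pathogens = 20, seq_length = 60, mutation_rate = 0.02)
  ant <- generate_antigens(spec)
  full <- extract_epitopes(ant)$epitope
  half1 <- extract_epitopes(ant[1:10, ])$epitope
  half2 <- extract_epitopes(ant[11:20, ])$epitope
  # subsample epitopes are a subset of the full set and recover a large part
  # of it; unrelated random sequences would share essentially nothing
  # (the chance of two random 9-mers colliding is 20^-9)
  expect_true(all(half1 %in% full))
  expect_gt(length(half1) / length(full), 0.2)
  jaccard <- length(intersect(half1, half2)) / length(union(half1, half2))
  expect_gt(jaccard, 0.1)
})
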