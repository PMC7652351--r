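test_that("population coverage follows the diploid closed form", {
  aff <- tibble::tibble(
    epitope = "ACDEFGHIK", allele = c("A*01", "B*01"),
    ic50 = c(50, 600)
  )
  one_locus <- tibble::tibble(allele = "A*01", frequency = 0.5, locus = "A")
  expect_equal(population_coverage(character(), aff, one_locus), 0)
  expect_equal(population_coverage("ACDEFGHIK", aff, one_locus), 0.75)

  # two loci, one covered allele each at p = 0.5: 1 - 0.5^2 * 0.5^2
  two_loci <- tibble::tibble(
    allele = c("A*01", "B*01"), frequency = 0.5, locus = c("A", "B")
  )
  aff2 <- tibble::tibble(
    epitope = "ACDEFGHIK", allele = c("A*01", "B*01"), ic50 = c(50, 499)
  )
  expect_equal(population_coverage("ACDEFGHIK", aff2, two_loci), 0.9375)
  # B*01 at 600 nM is not a binder: only locus A contributes
  expect_equal(population_coverage("ACDEFGHIK", aff, two_loci), 0.75)
})

test_that("invalid locus frequencies are signalled", {
  bad <- tibble::tibble(
    allele = c("A*01", "A*02"), frequency = c(0.7, 0.6), locus = "A"
  )
  aff <- tibble::tibble(epitope = "e", allele = "A*01", ic50 = 50)
  expect_error(
    population_coverage("e", aff, bad),
    class = "ev_error_invalid_frequencies"
  )
})

test_that("population coverage is monotone under epitope addition", {
  inst <- synth_instance(seed = 67, n_epitopes = 8)
  vals <- vapply(1:8, function(m) {
    population_coverage(inst$epitopes[1:m], inst$affinity, inst$alleles)
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("pathogen coverage counts the union of covered sequences", {
  antigens <- tibble::tibble(
    id = c("s1", "s2", "s3", "s4"),
    sequence = c(
      "AAAAAAAAACCCCCCCCC", # e1
      "AAAAAAAAADDDDDDDDD", # e1, e2
      "DDDDDDDDDEEEEEEEEE", # e2
      "FFFFFFFFFGGGGGGGGG"
    )
  )
  catalog <- extract_epitopes(antigens)
  e1 <- "AAAAAAAAA"
  e2 <- "DDDDDDDDD"
  expect_equal(pathogen_coverage(character(), catalog)$count, 0L)
  pc <- pathogen_coverage(c(e1, e2), catalog)
  expect_equal(pc$count, 3L)
  expect_equal(pc$fraction, 0.75)
  full <- extract_epitopes(tibble::tibble(id = c("a", "b"), sequence = "ACDEFGHIK"))
  expect_equal(pathogen_coverage("ACDEFGHIK", full)$fraction, 1)
})

test_that("mean conservation averages per-epitope incidence fractions", {
  antigens <- tibble::tibble(
    id = paste0("s", 1:4),
    sequence = c(
      "AAAAAAAAACCCCCCCCC",
      "AAAAAAAAA",
      "CCCCCCCCCAAAAAAAAA",
      "CCCCCCCCCAAAAAAAAA"
    )
  )
  catalog <- extract_epitopes(antigens)
  # AAAAAAAAA in 4/4, CCCCCCCCC in 3/4
  expect_equal(mean_conservation("AAAAAAAAA", catalog), 1)
  expect_equal(mean_conservation(c("AAAAAAAAA", "CCCCCCCCC"), catalog), 0.875)
  expect_error(mean_conservation(character(), catalog), class = "ev_error")
  expect_error(
    mean_conservation("WWWWWWWWW", catalog),
    class = "ev_error_unknown_epitope"
  )
})

test_that("the metric panel reports relative population coverage against the panel maximum", {
  inst <- synth_instance(seed = 71, n_epitopes = 5)
  m <- evaluate_vaccine(inst$epitopes[1:3], inst$affinity, inst$alleles, inst$catalog)
  expect_equal(nrow(m), 1L)
  pop_max <- 1 - prod(
    (1 - tapply(inst$alleles$frequency, inst$alleles$locus, sum))^2
  )
  expect_equal(
    m$population_coverage_relative,
    m$population_coverage / pop_max
  )
  expect_equal(
    m$immunogenicity,
    vaccine_immunogenicity(inst$epitopes[1:3], inst$affinity, inst$alleles)
  )
})

test_that("positional entropy matches hand-computed columns and drops gap consensus", {
  tr <- positional_entropy(tibble::tibble(
    id = paste0("r", 1:4),
    sequence = c("AAAA", "AACA", "CCCA", "GCGA")
  ), window = 1)
  # col1 A,A,C,G -> 1.5 bits; col2 A,A,C,C -> 1 bit; col3 A,C,C,G -> 1.5; col4 all A -> 0
  expect_equal(tr$entropy, c(1.5, 1, 1.5, 0))
  expect_equal(tr$smoothed_entropy, tr$entropy) # window 1 is the identity

  gappy <- tibble::tibble(
    id = paste0("r", 1:4),
    sequence = c("-A", "-A", "-C", "AC")
  )
  tg <- positional_entropy(gappy, window = 1)
  expect_equal(tg$column, 2L) # gap-consensus column dropped
  expect_equal(tg$entropy, 1)
  # excluding gaps changes nothing here (retained column has no gaps)
  expect_equal(positional_entropy(gappy, window = 1, gaps = "exclude")$entropy, 1)
})

test_that("entropy smoothing is a truncated centered moving average", {
  aln <- tibble::tibble(
    id = c("a", "b"),
    sequence = c("AAAA", "ACAC")
  )
  tr <- positional_entropy(aln, window = 3)
  expect_equal(tr$entropy, c(0, 1, 0, 1))
  expect_equal(tr$smoothed_entropy, c(0.5, 1 / 3, 2 / 3, 0.5))
})

test_that("positional coverage maps epitopes through gapped coordinates", {
  aln <- tibble::tibble(
    id = c("s1", "s2"),
    sequence = c(
      "ACDEFGHIKLMN",
      "ACDEF--GHIKL" # the epitope spans the gap in aligned coordinates
    )
  )
  antigens <- tibble::tibble(
    id = aln$id, sequence = gsub("-", "", aln$sequence)
  )
  catalog <- extract_epitopes(antigens)
  aff <- toy_affinity("ACDEFGHIK", 0.5)
  tracks <- positional_coverage(aln, "ACDEFGHIK", aff, toy_alleles(), catalog)
  # s1: columns 1..9; s2: columns 1-5 and 8-11
  expect_equal(tracks$coverage_count, c(2, 2, 2, 2, 2, 1, 1, 2, 2, 1, 1, 0))
  expect_equal(max(tracks$normalized_count), 1)
  expect_equal(
    tracks$potential_immunogenicity,
    tracks$coverage_count * 0.5
  )
  # empty vaccine: all-zero tracks
  zero <- positional_coverage(aln, character(), aff, toy_alleles(), catalog)
  expect_true(all(zero$coverage_count == 0))
  expect_error(
    positional_coverage(aln, "WWWWWWWWW", toy_affinity("WWWWWWWWW", 1), toy_alleles(), catalog),
    class = "ev_error"
  )
})

test_that("the sequential-enumeration search space is astronomically large", {
  expect_equal(search_space_size(100, 3), 97^4)
})
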