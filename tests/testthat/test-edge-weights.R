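test_that("overlap weight implements the suffix-prefix merge cost", {
  expect_equal(overlap_weight(NA, "ACDEFGHIK"), 9L)
  expect_equal(overlap_weight("s", "ACDEFGHIK"), 9L) # reserved terminus label
  expect_equal(overlap_weight("ACDEFGHIK", NA), 0L)
  expect_equal(overlap_weight("ACDEFGHIK", "EFGHIKLMN"), 3L)
  expect_equal(overlap_weight("ACDEFGHIK", "ACDEFGHIK"), 0L) # full absorption
  expect_error(overlap_weight(NA, NA), class = "ev_error")
})

test_that("overlap weight agrees with a brute-force scan on random string pairs", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      a <- paste(sample(AA20[1:4], sample(5:9, 1), replace = TRUE), collapse = "")
      b <- paste(sample(AA20[1:4], sample(5:9, 1), replace = TRUE), collapse = "")
      w <- overlap_weight(a, b)
      expect_identical(w, naive_overlap_weight(a, b))
      expect_gte(w, 0L)
      expect_lte(w, nchar(b))
      if (a != b && nchar(a) == nchar(b)) expect_gte(w, 1L)
    }
  })
})

test_that("cleavage site score sums matrix contributions over the -4..+1 window", {
  expect_equal(cleavage_site_score("AAAAAA", 4, constant_pssm(0)), 0)
  # psi(A, i) = i: offsets -4..+1 sum to -9
  ramp <- constant_pssm(0)
  ramp["A", ] <- -4:1
  expect_equal(cleavage_site_score("AAAAAA", 4, ramp), -9)
  expect_error(
    cleavage_site_score("AAAAAA", 2, ramp),
    class = "ev_error_window"
  )
  expect_error(
    cleavage_site_score("AAAAAA", 5, ramp),
    class = "ev_error_window"
  )
})

test_that("junction edge weight combines on-site and off-site cleavage", {
  # constant phi = 1 at every position: w = -1 + 0.1 * 4 = -0.6
  unit <- constant_pssm(1 / 6)
  e1 <- "ACDEFGHIK"
  e2 <- "LMNPQRSTV"
  expect_equal(cleavage_edge_weight(e1, e2, unit), -0.6)
  # beta = 0 collapses to the negated junction score
  withr::with_seed(8, {
    pssm <- generate_pssm(synthetic_spec(seed = 8))
    expect_equal(
      cleavage_edge_weight(e1, e2, pssm, K = 2, beta = 0),
      -cleavage_site_score(paste0(e1, e2), 9, pssm)
    )
    # defaults are K = 2, beta = 0.1
    expect_equal(
      cleavage_edge_weight(e1, e2, pssm),
      cleavage_edge_weight(e1, e2, pssm, K = 2, beta = 0.1)
    )
  })
})

test_that("mixture graphs are weightless and unbudgeted", {
  g <- build_design_graph(c("ACDEFGHIK", "CDEFGHIKL", "DEFGHIKLM"), "mixture", h = 5)
  off_diag <- g$w[upper.tri(g$w) | lower.tri(g$w)]
  expect_true(all(off_diag == 0))
  expect_equal(length(off_diag), 12L)
  expect_identical(g$h, Inf)
})

test_that("string-of-beads graphs zero the terminus edges and need a matrix", {
  eps <- c("ACDEFGHIK", "CDEFGHIKL", "LMNPQRSTV")
  expect_error(build_design_graph(eps, "string_of_beads"), class = "ev_error")
  pssm <- generate_pssm(synthetic_spec(seed = 2))
  g <- build_design_graph(eps, "string_of_beads", pssm = pssm)
  expect_true(all(g$w[1, -1] == 0))
  expect_true(all(g$w[-1, 1] == 0))
  expect_equal(
    g$w[2, 3],
    cleavage_edge_weight("ACDEFGHIK", "CDEFGHIKL", pssm)
  )
})

test_that("mosaic graphs carry overlap weights with the terminus boundary cases", {
  g <- build_design_graph(c("ACDEFGHIK", "EFGHIKLMN"), "mosaic")
  expect_equal(unname(g$w[1, 2:3]), c(9, 9))
  expect_equal(unname(g$w[2:3, 1]), c(0, 0))
  expect_equal(g$w["ACDEFGHIK", "EFGHIKLMN"], 3)
  expect_equal(g$w["EFGHIKLMN", "ACDEFGHIK"], 9)
})

test_that("custom graphs load user weights verbatim and reject missing pairs", {
  eps <- c("ACDEFGHIK", "EFGHIKLMN")
  et <- tibble::tibble(
    from = c(eps[1], eps[2], "s", "s", eps[1]),
    to = c(eps[2], eps[1], eps[1], eps[2], "s"),
    weight = c(-1.5, 2.5, 3, 4, 5)
  )
  g <- build_design_graph(eps, "custom", edge_table = et)
  expect_equal(g$w[2, 3], -1.5)
  expect_equal(g$w[3, 2], 2.5)
  expect_equal(unname(g$w[1, 2:3]), c(3, 4))
  expect_equal(unname(g$w[2:3, 1]), c(5, 0)) # absent terminus edge defaults to 0
  expect_error(
    build_design_graph(eps, "custom", edge_table = et[1, ]),
    class = "ev_error_missing_edge"
  )
})

test_that("mosaic tour weight equals assembled polypeptide length", {
  inst <- synth_instance(seed = 13, n_epitopes = 6)
  g <- build_design_graph(inst$epitopes, "mosaic")
  withr::with_seed(99, {
    for (rep in 1:10) {
      tour <- sample(inst$epitopes, sample(1:4, 1))
      w <- sum(evdesign:::tour_edge_weights(g, tour))
      poly <- assemble_polypeptide(tour, "mosaic")
      expect_equal(w, nchar(poly))
      for (e in tour) expect_true(grepl(e, poly, fixed = TRUE))
    }
  })
})

test_that("cleavage score is the negated edge-weight sum", {
  expect_equal(cleavage_score(numeric()), 0)
  expect_equal(cleavage_score(c(-1.2, -0.8)), 2)
  expect_equal(cleavage_score(c(0.5, -0.5)), 0)
})

test_that("cleavage matrices round-trip through their text format", {
  pssm <- generate_pssm(synthetic_spec(seed = 21))
  path <- withr::local_tempfile(fileext = ".txt")
  write_pssm(pssm, path)
  back <- read_pssm(path)
  expect_equal(back[AA20, as.character(-4:1)], pssm[AA20, as.character(-4:1)])
})
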