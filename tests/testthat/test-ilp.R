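test_that("a vertex budget of one selects the single best epitope", {
  inst <- synth_instance(seed = 17, n_epitopes = 6)
  g <- build_design_graph(inst$epitopes, "mixture")
  cfg <- design_config(n_tours = 1, max_epitopes = 1)
  sol <- design_vaccine(g, cfg, inst$affinity, inst$alleles, inst$catalog)
  expect_equal(sum(sol$tour_sizes), 1L)
  best <- max(vapply(
    inst$epitopes,
    function(e) vaccine_immunogenicity(e, inst$affinity, inst$alleles),
    numeric(1)
  ))
  expect_equal(sol$objective, best, tolerance = 1e-9)
  bf <- brute_force_design(g, cfg, inst$affinity, inst$alleles, inst$catalog)
  expect_equal(bf$objective, sol$objective, tolerance = 1e-9)
})

test_that("unsatisfiable allele coverage is reported as infeasible by both solvers", {
  inst <- synth_instance(seed = 23, n_epitopes = 5)
  # no epitope binds anything: binder fraction 0
  aff <- dplyr::mutate(inst$affinity, binder = FALSE)
  g <- build_design_graph(inst$epitopes, "mixture")
  cfg <- design_config(n_tours = 1, max_epitopes = 3, min_allele_cover = 1)
  expect_error(
    design_vaccine(g, cfg, aff, inst$alleles, inst$catalog),
    class = "ev_infeasible"
  )
  expect_error(
    brute_force_design(g, cfg, aff, inst$alleles, inst$catalog),
    class = "ev_infeasible"
  )
})

test_that("relaxing the budgets never decreases the optimum", {
  inst <- synth_instance(seed = 29, n_epitopes = 6)
  g <- build_design_graph(inst$epitopes, "mosaic")
  obj_at <- function(k, h) {
    cfg <- design_config(n_tours = 1, max_epitopes = k, max_weight = h)
    design_vaccine(g, cfg, inst$affinity, inst$alleles, inst$catalog)$objective
  }
  by_k <- vapply(1:3, obj_at, numeric(1), h = 27)
  expect_true(all(diff(by_k) >= -1e-9))
  by_h <- vapply(c(12, 18, 27), function(h) obj_at(3, h), numeric(1))
  expect_true(all(diff(by_h) >= -1e-9))
})

test_that("validate_solution names the violated design constraints", {
  ck <- cocktail_instance()
  cfg <- design_config(
    n_tours = 2, max_epitopes = 2,
    min_pathogen_cover = 3, min_allele_cover = 1
  )
  ok <- design_vaccine(ck$graph, cfg, ck$affinity, ck$alleles, ck$catalog)
  expect_no_violations(
    validate_solution(ok, ck$graph, cfg, ck$affinity, ck$alleles, ck$catalog)
  )

  eps <- ck$epitopes
  viol <- function(tours, config = cfg) {
    validate_solution(tours, ck$graph, config, ck$affinity, ck$alleles, ck$catalog)$constraint
  }
  # same epitope in two tours
  expect_true("C3" %in% viol(list(eps[1], c(eps[1], eps[2]))))
  # oversize tour
  expect_true("C6" %in% viol(list(eps[1:3], eps[4])))
  # insufficient pathogen coverage
  expect_true("C7b" %in% viol(
    list(eps[1], eps[2]),
    design_config(n_tours = 2, max_epitopes = 2, min_pathogen_cover = 5)
  ))
  # insufficient allele coverage (the panel's only allele is bound, ask for 2)
  expect_true("C8b" %in% viol(
    list(eps[1], eps[2]),
    design_config(n_tours = 2, max_epitopes = 2, min_allele_cover = 2)
  ))
  # conservation below the floor: every epitope sits in 1 of 8 pathogens
  expect_true("C9" %in% viol(
    list(eps[1], eps[2]),
    design_config(n_tours = 2, max_epitopes = 2, min_conservation = 0.5)
  ))
  # empty tour
  expect_true("C4" %in% viol(list(eps[1], character())))
  # unknown vertex
  expect_true("C1" %in% viol(list(eps[1], "WWWWWWWWW")))
})

test_that("edge-weight budget violations are detected from the tours alone", {
  # three homopolymer epitopes share no overlap: a 3-epitope mosaic tour
  # weighs exactly 27, well beyond a budget of 15
  eps <- vapply(AA20[1:3], function(a) strrep(a, 9), character(1))
  g <- build_design_graph(unname(eps), "mosaic")
  cat <- catalog_of(unname(eps))
  aff <- toy_affinity(unname(eps), c(0.3, 0.2, 0.1))
  all_ <- toy_alleles()
  cfg <- design_config(n_tours = 1, max_epitopes = 3, max_weight = 15)
  v <- validate_solution(list(unname(eps)), g, cfg, aff, all_, cat)
  expect_identical(v$constraint, "C5")
  # within budget: two epitopes weigh 18 <= 27
  cfg27 <- design_config(n_tours = 1, max_epitopes = 3, max_weight = 27)
  expect_no_violations(validate_solution(list(unname(eps)), g, cfg27, aff, all_, cat))
})

test_that("polypeptide assembly matches the design kind", {
  expect_equal(
    assemble_polypeptide(c("ACDEFGHIK", "KLMNPQRST"), "string_of_beads"),
    "ACDEFGHIKKLMNPQRST"
  )
  expect_equal(
    assemble_polypeptide(c("ACDEFGHIK", "EFGHIKLMN"), "mosaic"),
    "ACDEFGHIKLMN"
  )
  expect_equal(assemble_polypeptide(character(), "mosaic"), "")
  expect_equal(
    assemble_polypeptide(c("AAA", "AAA"), "mixture"),
    "AAAAAA"
  )
})

test_that("the brute-force oracle refuses oversized instances", {
  inst <- synth_instance(seed = 41, n_epitopes = 10)
  g <- build_design_graph(inst$epitopes, "mixture")
  cfg <- design_config(n_tours = 1, max_epitopes = 2)
  expect_error(
    brute_force_design(g, cfg, inst$affinity, inst$alleles, inst$catalog),
    class = "ev_error_guard"
  )
  expect_error(
    brute_force_design(g, design_config(n_tours = 3, max_epitopes = 1),
      inst$affinity, inst$alleles, inst$catalog,
      guard = 12
    ),
    class = "ev_error_guard"
  )
})

test_that("solutions tidy into one row per selected epitope", {
  inst <- synth_instance(seed = 43, n_epitopes = 5)
  g <- build_design_graph(inst$epitopes, "mixture")
  cfg <- design_config(n_tours = 2, max_epitopes = 2)
  sol <- design_vaccine(g, cfg, inst$affinity, inst$alleles, inst$catalog)
  td <- tidy(sol)
  expect_equal(nrow(td), sum(sol$tour_sizes))
  expect_setequal(unique(td$tour), 1:2)
  gl <- glance(sol)
  expect_equal(gl$n_epitopes, sum(sol$tour_sizes))
  expect_equal(gl$status, "optimal")
})

test_that("an unknown solver is a configuration error", {
  inst <- synth_instance(seed = 47, n_epitopes = 4)
  g <- build_design_graph(inst$epitopes, "mixture")
  cfg <- design_config(n_tours = 1, max_epitopes = 2, solver = "gurobi")
  expect_error(
    design_vaccine(g, cfg, inst$affinity, inst$alleles, inst$catalog),
    class = "ev_error_config"
  )
})
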