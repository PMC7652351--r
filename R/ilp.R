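#' Configure a vaccine design run
#'
#' Bundles the knobs of the team-orienteering design problem: how many
#' polypeptides (tours) to produce, the per-tour budgets, the coverage and
#' conservation side constraints, the objective, and solver options.
#'
#' @param n_tours Number of polypeptides in the cocktail (\eqn{|T| \ge 1}).
#' @param max_epitopes Vertex budget `k`: maximum epitopes per tour.
#' @param max_weight Edge-weight budget `h` per tour, summed over *all* tour
#'   edges including the terminus edges (for mosaics this is the maximum
#'   polypeptide length). `NULL` inherits the graph's budget; `Inf` disables
#'   the constraint entirely (it is omitted from the program, not modelled
#'   with a large constant).
#' @param min_pathogen_cover Minimum number of pathogen sequences that must
#'   contain at least one selected epitope (\eqn{\Theta_s}).
#' @param min_allele_cover Minimum number of MHC alleles that must bind at
#'   least one selected epitope (\eqn{\Theta_a}).
#' @param min_conservation Minimum *average* epitope conservation
#'   \eqn{\Gamma}, as a fraction of the pathogen panel in \eqn{[0, 1]}.
#' @param objective Objective mode. `"immunogenicity"` maximizes \eqn{I(P)}
#'   alone; `"coverage"` adds the number of covered pathogens;
#'   `"conservation"` maximizes average conservation and pathogen coverage
#'   together with immunogenicity (all unit weights — immunogenicity is
#'   typically orders of magnitude smaller than the other two terms, so it
#'   acts as a tie-breaker); `"weighted"` uses the weights supplied in
#'   `weights`.
#' @param weights Named numeric vector with entries `immunogenicity`,
#'   `coverage`, `conservation`; only used for `objective = "weighted"`.
#' @param solver Solver backend; only `"glpk"` (the `glpsol` executable) is
#'   supported.
#' @param time_limit Solver time limit in seconds (`Inf` = none).
#' @param mip_gap Relative MIP gap at which the solver may stop early
#'   (default 0: solve to proven optimality).
#' @return An object of class `ev_config`.
#' @export
design_config <- function(n_tours = 1, max_epitopes = 10, max_weight = NULL,
                          min_pathogen_cover = 0, min_allele_cover = 0,
                          min_conservation = 0,
                          objective = c(
                            "immunogenicity", "coverage",
                            "conservation", "weighted"
                          ),
                          weights = c(
                            immunogenicity = 1, coverage = 1,
                            conservation = 1
                          ),
                          solver = "glpk", time_limit = Inf, mip_gap = 0) {
  objective <- match.arg(objective)
  if (n_tours < 1 || max_epitopes < 1) {
    abort("`n_tours` and `max_epitopes` must be at least 1.", class = "ev_error")
  }
  if (min_conservation < 0 || min_conservation > 1) {
    abort("`min_conservation` must be a fraction in [0, 1].", class = "ev_error")
  }
  structure(
    list(
      n_tours = as.integer(n_tours),
      max_epitopes = as.integer(max_epitopes),
      max_weight = max_weight,
      min_pathogen_cover = as.integer(min_pathogen_cover),
      min_allele_cover = as.integer(min_allele_cover),
      min_conservation = min_conservation,
      objective = objective,
      weights = weights,
      solver = solver,
      time_limit = time_limit,
      mip_gap = mip_gap
    ),
    class = "ev_config"
  )
}

# Objective weights (immunogenicity, coverage, conservation) implied by the
# configured mode.
objective_weights <- function(config) {
  switch(config$objective,
    immunogenicity = c(immunogenicity = 1, coverage = 0, conservation = 0),
    coverage = c(immunogenicity = 1, coverage = 1, conservation = 0),
    conservation = c(immunogenicity = 1, coverage = 1, conservation = 1),
    weighted = {
      w <- config$weights
      c(
        immunogenicity = unname(w["immunogenicity"]),
        coverage = unname(w["coverage"]),
        conservation = unname(w["conservation"])
      )
    }
  )
}

# Shared preprocessing for the ILP and the brute-force oracle: per-epitope
# rewards, conservation counts, and incidence/binder indicator matrices
# restricted to the graph's epitopes.
prepare_instance <- function(graph, affinity, alleles, catalog) {
  assert_alleles(alleles)
  epitopes <- graph$epitopes
  tau_s <- incidence_matrix(catalog, epitopes)
  rewards <- epitope_rewards(epitopes, affinity, alleles)
  conscount <- rowSums(tau_s)

  aff <- affinity
  if (!"binder" %in% names(aff)) {
    aff <- binder_indicators(aff)
  }
  tau_a <- matrix(FALSE, length(epitopes), nrow(alleles),
    dimnames = list(epitopes, alleles$allele)
  )
  bnd <- aff[aff$binder & aff$epitope %in% epitopes & aff$allele %in% alleles$allele, ]
  if (nrow(bnd)) {
    tau_a[cbind(bnd$epitope, bnd$allele)] <- TRUE
  }
  list(
    epitopes = epitopes,
    rewards = rewards,
    conscount = conscount,
    tau_s = tau_s,
    tau_a = tau_a,
    n_pathogens = n_pathogens(catalog)
  )
}

# Effective per-tour edge-weight budget: config overrides the graph.
effective_h <- function(graph, config) {
  config$max_weight %||% graph$h %||% Inf
}

#' Solve the vaccine design problem
#'
#' Formulates the generalized epitope vaccine design problem — a team
#' orienteering problem on the design graph with coverage and conservation
#' side constraints — as an integer linear program and solves it with GLPK.
#' The program selects `n_tours` vertex-disjoint simple tours through the
#' terminus vertex, each visiting at most `max_epitopes` epitopes and using
#' edge weight at most `max_weight`, such that the selected epitopes
#' maximize the configured objective while jointly covering at least
#' `min_pathogen_cover` pathogens and `min_allele_cover` alleles with
#' average conservation at least `min_conservation`. Subtours are excluded
#' with Miller-Tucker-Zemlin integer node potentials.
#'
#' @param graph Design graph from [build_design_graph()].
#' @param config Design configuration from [design_config()].
#' @param affinity Affinity table (`epitope`, `allele`, `immunogenicity`,
#'   optionally `ic50`/`binder`). Epitopes absent from the table are legal
#'   vertices that contribute no immunogenicity.
#' @param alleles Allele table (`allele`, `frequency`, `locus`).
#' @param catalog Epitope catalog covering all graph epitopes.
#' @return An object of class `ev_solution` with the ordered tours, the
#'   assembled polypeptides, per-tour weights and sizes, the objective
#'   value, the covered pathogens and alleles, and the solver status
#'   (`"optimal"` or `"feasible"` when stopped at a gap/time limit).
#'   Infeasible constraint sets raise an error of class `ev_infeasible`.
#' @examples
#' \dontrun{
#' sol <- design_vaccine(graph, design_config(n_tours = 1, max_epitopes = 5),
#'   affinity, alleles, catalog
#' )
#' tidy(sol)
#' }
#' @export
design_vaccine <- function(graph, config, affinity, alleles, catalog) {
  solve_design(graph, config, affinity, alleles, catalog)
}

# Core solve with extra knobs used by the Pareto sweep:
#   wmax   — upper bound on the total edge weight across all tours
#   imin   — lower bound on total immunogenicity
#   w_cleav — objective penalty per unit of total edge weight
#   override_weights — replace the configured objective weights
solve_design <- function(graph, config, affinity, alleles, catalog,
                         wmax = NULL, imin = NULL, w_cleav = 0,
                         override_weights = NULL) {
  if (!identical(config$solver, "glpk")) {
    abort(sprintf("unknown solver '%s' (only \"glpk\" is available).", config$solver),
      class = "ev_error_config"
    )
  }
  if (Sys.which("glpsol") == "") {
    abort("the GLPK solver executable `glpsol` was not found on the PATH.",
      class = "ev_error_config"
    )
  }
  inst <- prepare_instance(graph, affinity, alleles, catalog)
  h <- effective_h(graph, config)
  obj_w <- override_weights %||% objective_weights(config)

  dir <- tempfile("evdesign-")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  dat <- file.path(dir, "instance.dat")
  write_gmpl_data(
    dat, graph, inst,
    k = config$max_epitopes, n_tours = config$n_tours, h = h,
    theta_s_min = config$min_pathogen_cover,
    theta_a_min = config$min_allele_cover,
    gamma = config$min_conservation * inst$n_pathogens,
    obj_w = obj_w, w_cleav = w_cleav, wmax = wmax, imin = imin
  )

  model <- system.file("glpk", "ev_design.mod", package = "evdesign", mustWork = TRUE)
  args <- c("-m", model, "-d", dat, "-o", "glpsol.out")
  if (is.finite(config$time_limit)) {
    args <- c(args, "--tmlim", as.character(ceiling(config$time_limit)))
  }
  if (config$mip_gap > 0) {
    args <- c(args, "--mipgap", format(config$mip_gap, scientific = FALSE))
  }
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  out <- suppressWarnings(system2("glpsol", args, stdout = TRUE, stderr = TRUE))
  setwd(old)

  status <- glpsol_status(file.path(dir, "glpsol.out"), out)
  if (status == "infeasible") {
    abort("the design problem is infeasible under the given constraints.",
      class = "ev_infeasible"
    )
  }
  if (status == "undefined") {
    abort(
      paste0(
        "glpsol did not produce a solution:\n",
        paste(utils::tail(out, 15), collapse = "\n")
      ),
      class = "ev_error_solver"
    )
  }

  vars <- readr::read_csv(file.path(dir, "ev_solution.csv"),
    col_types = readr::cols(
      var = readr::col_character(),
      i = readr::col_integer(),
      j = readr::col_integer(),
      t = readr::col_integer()
    ),
    progress = FALSE
  )
  build_solution(graph, config, inst, vars,
    status = status, obj_w = obj_w, h = h
  )
}

# Map the glpsol report to a status: optimal / feasible / infeasible / undefined.
glpsol_status <- function(out_file, stdout_lines) {
  status_line <- ""
  if (file.exists(out_file)) {
    lines <- readLines(out_file, n = 20L, warn = FALSE)
    status_line <- paste(grep("^Status:", lines, value = TRUE), collapse = " ")
  }
  all_text <- paste(c(status_line, stdout_lines), collapse = "\n")
  if (grepl("INTEGER OPTIMAL", status_line)) {
    return("optimal")
  }
  if (grepl("INTEGER NON-OPTIMAL", status_line)) {
    return("feasible")
  }
  if (grepl("INTEGER EMPTY", status_line) ||
    grepl("NO.*FEASIBLE SOLUTION", all_text)) {
    return("infeasible")
  }
  "undefined"
}

# Serialize one problem instance as a GMPL data file.
write_gmpl_data <- function(path, graph, inst, k, n_tours, h,
                            theta_s_min, theta_a_min, gamma,
                            obj_w, w_cleav, wmax, imin) {
  nv <- length(inst$epitopes)
  ns <- inst$n_pathogens
  na_ <- ncol(inst$tau_a)
  num <- function(x) sprintf("%.15g", x)

  lines <- c(
    "data;",
    sprintf("param nv := %d;", nv),
    sprintf("param nt := %d;", n_tours),
    sprintf("param ns := %d;", ns),
    sprintf("param na := %d;", max(na_, 1L)),
    sprintf("param k := %d;", k),
    sprintf("param has_h := %d;", as.integer(is.finite(h))),
    sprintf("param h := %s;", num(if (is.finite(h)) h else 0)),
    sprintf("param has_wmax := %d;", as.integer(!is.null(wmax))),
    sprintf("param wmax := %s;", num(wmax %||% 0)),
    sprintf("param has_imin := %d;", as.integer(!is.null(imin))),
    sprintf("param imin := %s;", num(imin %||% 0)),
    sprintf("param theta_s_min := %d;", theta_s_min),
    sprintf("param theta_a_min := %d;", theta_a_min),
    sprintf("param gamma := %s;", num(gamma)),
    sprintf("param w_imm := %s;", num(obj_w[["immunogenicity"]])),
    sprintf("param w_cov := %s;", num(obj_w[["coverage"]])),
    sprintf("param w_cons := %s;", num(obj_w[["conservation"]])),
    sprintf("param w_cleav := %s;", num(w_cleav))
  )

  # weight matrix over terminus (0) and epitopes (1..nv)
  idx <- 0:nv
  header <- paste("param w :", paste(idx, collapse = " "), ":=")
  w <- graph$w
  rows <- vapply(seq_along(idx), function(r) {
    vals <- vapply(seq_along(idx), function(c) {
      if (r == c) "." else num(w[r, c])
    }, character(1))
    paste(idx[r], paste(vals, collapse = " "))
  }, character(1))
  lines <- c(lines, header, rows, ";")

  lines <- c(
    lines,
    paste(
      "param reward :=",
      paste(sprintf("%d %s", seq_len(nv), num(inst$rewards)), collapse = " "), ";"
    ),
    paste(
      "param conscount :=",
      paste(sprintf("%d %s", seq_len(nv), num(inst$conscount)), collapse = " "), ";"
    )
  )

  mat_param <- function(name, m) {
    if (ncol(m) == 0L || !any(m)) {
      return(character())
    }
    header <- paste("param", name, ":", paste(seq_len(ncol(m)), collapse = " "), ":=")
    rows <- vapply(seq_len(nrow(m)), function(r) {
      paste(r, paste(as.integer(m[r, ]), collapse = " "))
    }, character(1))
    c(header, rows, ";")
  }
  lines <- c(
    lines,
    mat_param("tau_s", inst$tau_s),
    mat_param("tau_a", inst$tau_a),
    "end;"
  )
  writeLines(lines, path)
  invisible(path)
}

# Reconstruct ordered tours and solution metadata from the solver variables.
build_solution <- function(graph, config, inst, vars, status, obj_w, h) {
  nv <- length(inst$epitopes)
  tours <- vector("list", config$n_tours)
  xe <- vars[vars$var == "x", ]
  for (t in seq_len(config$n_tours)) {
    et <- xe[xe$t == t, ]
    nxt <- setNames(et$j, as.character(et$i))
    tour <- integer()
    cur <- 0L
    repeat {
      cur <- unname(nxt[as.character(cur)])
      if (is.na(cur) || cur == 0L || length(tour) > nv) break
      tour <- c(tour, cur)
    }
    tours[[t]] <- inst$epitopes[tour]
  }
  finish_solution(graph, config, inst, tours, status, obj_w, h)
}

# Shared between the ILP and brute-force paths: recompute tour weights,
# coverage, objective, and assemble polypeptides from the tours alone.
finish_solution <- function(graph, config, inst, tours, status, obj_w, h) {
  selected <- unlist(tours, use.names = FALSE)
  tour_w <- vapply(tours, function(tr) tour_weight(graph, tr), numeric(1))
  sel_idx <- match(selected, inst$epitopes)
  covered_s <- if (length(sel_idx)) {
    colnames(inst$tau_s)[colSums(inst$tau_s[sel_idx, , drop = FALSE]) > 0]
  } else {
    character()
  }
  covered_a <- if (length(sel_idx)) {
    colnames(inst$tau_a)[colSums(inst$tau_a[sel_idx, , drop = FALSE]) > 0]
  } else {
    character()
  }
  immunogenicity <- sum(inst$rewards[sel_idx])
  mean_cons <- if (length(sel_idx)) {
    mean(inst$conscount[sel_idx]) / inst$n_pathogens
  } else {
    NA_real_
  }
  objective <- obj_w[["immunogenicity"]] * immunogenicity +
    obj_w[["coverage"]] * length(covered_s) +
    obj_w[["conservation"]] * sum(inst$conscount[sel_idx]) / inst$n_pathogens

  structure(
    list(
      tours = tours,
      polypeptides = vapply(
        tours, assemble_polypeptide, character(1),
        kind = graph$kind
      ),
      kind = graph$kind,
      tour_weights = tour_w,
      tour_sizes = lengths(tours),
      objective = unname(objective),
      immunogenicity = unname(immunogenicity),
      cleavage_score = -sum(tour_w),
      mean_conservation = mean_cons,
      covered_pathogens = covered_s,
      covered_alleles = covered_a,
      status = status,
      h = h,
      config = config
    ),
    class = "ev_solution"
  )
}

#' @export
print.ev_solution <- function(x, ...) {
  cat(sprintf(
    "# Vaccine design (%s, %s): %d tour(s), %d epitopes, objective %.6g\n",
    x$kind, x$status, length(x$tours), sum(x$tour_sizes), x$objective
  ))
  for (t in seq_along(x$tours)) {
    cat(sprintf(
      "  tour %d [w = %.4g]: %s\n", t, x$tour_weights[t],
      paste(x$tours[[t]], collapse = " -> ")
    ))
  }
  invisible(x)
}
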