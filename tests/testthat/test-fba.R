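test_that("the FBA program transcribes the toy model", {
  m <- make_toy_loop_model()
  lp <- build_fba_lp(m)
  expect_equal(nrow(lp$eq_matrix$num), 3L)
  expect_equal(length(lp$ids), 5L)
  expect_equal(unname(as.numeric(lp$objective)), c(0, 0, 0, 0, 1))
})

test_that("misparsing the boundary adds the extra equality row", {
  p <- tempfile(fileext = ".xml")
  make_boundary_fixture(p)
  bad <- read_sbml(p, parse_options(respect_boundary = FALSE))$model
  lp <- build_fba_lp(bad)
  expect_equal(nrow(lp$eq_matrix$num), 4L)
  unlink(p)
})

test_that("a model with no internal metabolites optimizes at a bound", {
  m <- gem_model("b",
    list(gem_metabolite("X_b", boundary = TRUE)),
    list(gem_reaction("EX", c(X_b = 1), 0, 7, objective = 1)))
  lp <- build_fba_lp(m)
  expect_equal(nrow(lp$eq_matrix$num), 0L)
  f <- solve_fba(m, "exact")
  expect_equal(rat_format(f$objective_value), "7")
})

test_that("an all-zero objective is an explicit error", {
  m <- gem_model("noobj", list(gem_metabolite("A")),
                 list(gem_reaction("R", c(A = 1), 0, 1)))
  expect_error(build_fba_lp(m), "no objective")
})

test_that("toy FBA: exact objective 10, float within 1e-6", {
  m <- make_toy_loop_model()
  fe <- solve_fba(m, "exact")
  expect_equal(fe$status, "optimal")
  expect_equal(rat_format(fe$objective_value), "10")
  ff <- solve_fba(m, "float")
  expect_equal(ff$status, "optimal")
  expect_lt(abs(ff$objective_value - 10), 1e-6)
})

test_that("closing the import pins the optimum at exactly zero", {
  m <- make_toy_loop_model()
  m$reactions$EX_A$lb <- as_vrat(0)
  m$reactions$EX_A$ub <- as_vrat(0)
  f <- solve_fba(m, "exact")
  expect_equal(f$status, "optimal")
  expect_equal(rat_format(f$objective_value), "0")
})

test_that("exact-mode optima re-verify with zero residual", {
  for (s in 1:5) {
    m <- make_random_model(random_model_spec(seed = s))
    f <- solve_fba(m, "exact")
    expect_equal(f$status, "optimal")
    rep <- verify_flux_state(m, f)
    expect_equal(rep$verdict, "exact_feasible")
    expect_true(isTRUE(rep$objective_value == f$objective_value))
  }
})

test_that("solver comparison agrees on the toy model", {
  ag <- compare_solvers(make_toy_loop_model())
  expect_true(ag$agrees)
  expect_lte(ag$max_abs_difference, 1e-6)
})

test_that("the boundary discrepancy is a parsing artifact, not solver error", {
  p <- tempfile(fileext = ".xml")
  make_boundary_fixture(p)
  good <- read_sbml(p, parse_options(respect_boundary = TRUE))$model
  bad <- read_sbml(p, parse_options(respect_boundary = FALSE))$model
  ag_good <- compare_solvers(good)
  ag_bad <- compare_solvers(bad)
  # within each parse, float and exact agree; across parses the exact
  # objectives differ (10 vs 0) -- the discrepancy lives in the parsing
  expect_true(ag_good$agrees)
  expect_true(ag_bad$agrees)
  expect_equal(rat_format(ag_good$exact_objective), "10")
  expect_equal(rat_format(ag_bad$exact_objective), "0")
  unlink(p)
})

test_that("consistent infeasibility counts as agreement", {
  m <- gem_model("inf",
    list(gem_metabolite("A"), gem_metabolite("A_b", boundary = TRUE)),
    list(gem_reaction("EX", c(A_b = -1, A = 1), 0, 0),
         gem_reaction("FORCE", c(A = -1), 5, 10, objective = 1)))
  ag <- compare_solvers(m)
  expect_equal(ag$exact_status, "infeasible")
  expect_true(all(ag$float_statuses == "infeasible"))
  expect_true(ag$agrees)
})

test_that("relaxing any single bound never decreases the exact optimum", {
  for (s in c(2, 5, 8)) {
    m <- make_random_model(random_model_spec(seed = s))
    base <- solve_fba(m, "exact")$objective_value
    rid <- sample(names(m$reactions), 3)
    for (r in rid) {
      m2 <- m
      m2$reactions[[r]]$ub <- m2$reactions[[r]]$ub + as_vrat(50)
      relaxed <- solve_fba(m2, "exact")$objective_value
      expect_true(isTRUE(relaxed >= base))
      m3 <- m
      m3$reactions[[r]]$lb <- m3$reactions[[r]]$lb - as_vrat(50)
      relaxed3 <- solve_fba(m3, "exact")$objective_value
      expect_true(isTRUE(relaxed3 >= base))
    }
  }
})

test_that("an unknown backend errors with its name", {
  expect_error(solve_fba(make_toy_loop_model(), "float", backend = "nope"),
               "backend unavailable.*nope")
})

test_that("the SciPy/HiGHS backend solves the same program to 1e-6", {
  m <- make_toy_loop_model()
  ag <- compare_solvers(m, backends = c("simplex_float", "scipy_highs"))
  expect_true(ag$agrees)
  for (s in 1:3) {
    mr <- make_random_model(random_model_spec(seed = s))
    agr <- compare_solvers(mr, backends = "scipy_highs")
    expect_true(agr$agrees, label = paste("seed", s))
  }
})
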