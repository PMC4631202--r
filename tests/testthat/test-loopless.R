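test_that("the toy model's circulation space is one-dimensional R2+R3", {
  N <- internal_nullspace(make_toy_loop_model())
  expect_equal(dim(N), c(3L, 1L))
  expect_equal(dimnames(N)[[1]], c("R1", "R2", "R3"))
  v <- gemverify:::ratmat_col(N, 1)
  # proportional to (R1:0, R2:1, R3:1)
  expect_equal(v$num[1], 0)
  expect_true(isTRUE(v[2] == v[3]))
  expect_true(v$num[2] != 0)
})

test_that("a loop-free chain has an empty circulation space", {
  N <- internal_nullspace(make_loop_free_chain())
  expect_equal(ncol(N$num), 0L)
  expect_equal(nrow(N$num), 2L)  # R1, R2 are the internal reactions
})

test_that("two planted disjoint 2-cycles give at least two circulations", {
  m <- make_random_model(random_model_spec(seed = 4, n_planted_loops = 2))
  expect_gte(ncol(internal_nullspace(m)$num), 2L)
})

test_that("every null-space column is an exact circulation", {
  for (s in c(1, 6, 9)) {
    m <- make_random_model(random_model_spec(seed = s))
    N <- internal_nullspace(m)
    int <- gemverify:::internal_reaction_ids(m)
    S <- stoichiometric_matrix(m)
    keep <- match(int, gemverify:::rxn_ids(m))
    Sint <- ratmat(S$num[, keep, drop = FALSE], S$den[, keep, drop = FALSE])
    for (j in seq_len(ncol(N$num))) {
      res <- rat_matvec(Sint, gemverify:::ratmat_col(N, j))
      expect_true(all(res$num == 0))
    }
  }
})

test_that("loop detection finds the R2/R3 cycle and respects its absence", {
  m <- make_toy_loop_model()
  loopy <- rat_parse(c("10", "10", "5", "5", "10"))
  names(loopy) <- c("EX_A", "R1", "R2", "R3", "BIO")
  res <- is_loopless(m, loopy)
  expect_false(res$loopless)
  expect_setequal(names(res$witness$cycle), c("R2", "R3"))
  # witness is itself an exact circulation matching the flux signs
  expect_true(all(res$witness$cycle$num > 0))

  clean <- rat_parse(c("10", "10", "0", "0", "10"))
  names(clean) <- c("EX_A", "R1", "R2", "R3", "BIO")
  expect_true(is_loopless(m, clean)$loopless)
})

test_that("models with no circulations are loopless for any flux", {
  m <- make_loop_free_chain()
  f <- solve_fba(m, "exact")
  expect_true(is_loopless(m, f)$loopless)
})

test_that("loopless FBA matches exhaustive enumeration on the toy model", {
  m <- make_toy_loop_model()
  lf <- loopless_fba(m)
  expect_equal(lf$status, "optimal")
  expect_equal(rat_format(lf$objective_value), "10")
  expect_equal(rat_format(lf$values[c("R2", "R3")]), c(R2 = "0", R3 = "0"))
  # independent check: best value over all 2^3 direction assignments
  oracle <- enumerate_loopless_optimum(m)
  expect_true(isTRUE(lf$objective_value == oracle))
  # branch and bound agrees with the removal-based fast path
  milp <- loopless_fba(m, force_milp = TRUE)
  expect_true(isTRUE(milp$objective_value == lf$objective_value))
  expect_true(is_loopless(m, milp)$loopless)
})

test_that("loop-law constraints are vacuous on a loop-free model", {
  m <- make_loop_free_chain()
  plain <- solve_fba(m, "exact")
  lf <- loopless_fba(m, force_milp = TRUE)
  expect_true(isTRUE(lf$objective_value == plain$objective_value))
})

test_that("a forced thermodynamic cycle makes loopless FBA infeasible", {
  m <- make_forced_cycle_model()
  expect_equal(solve_fba(m, "exact")$status, "optimal")  # plain FBA feasible
  lf <- loopless_fba(m)
  expect_equal(lf$status, "infeasible")
  expect_null(enumerate_loopless_optimum(m))  # exhaustive agreement
})

test_that("an undersized big_M is rejected", {
  expect_error(loopless_fba(make_toy_loop_model(), big_M = 10), "big_M")
})

test_that("loop removal collapses a planted 500-unit cycle exactly", {
  m <- make_toy_loop_model()
  v <- rat_parse(c("10", "10", "500", "500", "10"))
  names(v) <- c("EX_A", "R1", "R2", "R3", "BIO")
  expect_equal(verify_flux_state(m, v)$verdict, "exact_feasible")
  w <- remove_loops(m, v)
  expect_equal(rat_format(w$values),
               c(EX_A = "10", R1 = "10", R2 = "0", R3 = "0", BIO = "10"))
  expect_equal(rat_format(w$objective_value), "10")
})

test_that("an already-loopless flux is its own L1 minimizer", {
  m <- make_toy_loop_model()
  v <- rat_parse(c("10", "10", "0", "0", "10"))
  names(v) <- c("EX_A", "R1", "R2", "R3", "BIO")
  w <- remove_loops(m, v)
  expect_true(all(w$values == v[names(w$values)]))
})

test_that("loop removal refuses models with zero-excluding bounds", {
  m <- make_forced_cycle_model()
  f <- solve_fba(m, "exact")
  expect_error(remove_loops(m, f), "ZERO_EXCLUDED_BOUNDS|allow zero")
})

test_that("loop removal preserves exchanges and objective bit-exactly (property)", {
  for (s in 1:10) {
    m <- make_random_model(random_model_spec(seed = s))
    f <- solve_fba(m, "exact")
    expect_equal(f$status, "optimal")
    w <- remove_loops(m, f)
    exch <- identify_exchanges(m)
    expect_true(all(w$values[exch] == f$values[exch]), label = paste("seed", s))
    expect_true(isTRUE(w$objective_value == f$objective_value),
                label = paste("seed", s))
    expect_true(is_loopless(m, w)$loopless, label = paste("seed", s))
    # sign-preserving shrinkage on every internal reaction
    int <- gemverify:::internal_reaction_ids(m)
    vi <- f$values[int]; wi <- w$values[int]
    sgn <- gemverify:::rat_sign(vi)
    expect_true(all(abs(wi) <= abs(vi)))
    expect_true(all(gemverify:::rat_sign(wi) == sgn | wi$num == 0))
  }
})

test_that("loopless and plain FBA coincide when all bounds allow zero flux", {
  for (s in 11:16) {
    m <- make_random_model(random_model_spec(seed = s))
    plain <- solve_fba(m, "exact")
    lf <- loopless_fba(m)
    expect_true(isTRUE(lf$objective_value == plain$objective_value),
                label = paste("seed", s))
    expect_true(is_loopless(m, lf)$loopless)
  }
})

test_that("branch and bound agrees with the removal fast path on random models", {
  for (s in c(2, 5)) {
    m <- make_random_model(random_model_spec(seed = s, n_metabolites = 5,
                                             n_reactions = 8,
                                             n_planted_loops = 1))
    fast <- loopless_fba(m)
    milp <- loopless_fba(m, force_milp = TRUE)
    expect_equal(milp$status, "optimal")
    expect_true(isTRUE(milp$objective_value == fast$objective_value),
                label = paste("seed", s))
    expect_true(is_loopless(m, milp)$loopless)
  }
})
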