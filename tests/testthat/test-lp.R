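empty_eq <- function(n) ratmat(matrix(0, 0, n), matrix(1, 0, n))

test_that("bound-attained optima are exact", {
  lp <- rational_lp(objective = as_vrat(1), eq_matrix = empty_eq(1),
                    eq_rhs = as_vrat(numeric(0)),
                    lower = as_vrat(0), upper = rat_parse("1/3"), ids = "x")
  sol <- solve_lp_rational(lp)
  expect_equal(sol$status, "optimal")
  expect_equal(rat_format(sol$values), c(x = "1/3"))
  expect_equal(rat_format(sol$objective_value), "1/3")
})

test_that("equality-constrained optimum is exact", {
  lp <- rational_lp(objective = as_vrat(c(1, 1)),
                    eq_matrix = ratmat(matrix(1, 1, 2)),
                    eq_rhs = as_vrat(1),
                    lower = as_vrat(c(0, 0)), upper = as_vrat(c(1, 1)))
  sol <- solve_lp_rational(lp)
  expect_equal(sol$status, "optimal")
  expect_equal(rat_format(sol$objective_value), "1")
})

test_that("infeasible and unbounded programs are reported as statuses", {
  lp_inf <- rational_lp(objective = as_vrat(1),
                        eq_matrix = ratmat(matrix(1, 1, 1)),
                        eq_rhs = as_vrat(5),
                        lower = as_vrat(0), upper = as_vrat(1))
  expect_equal(solve_lp_rational(lp_inf)$status, "infeasible")

  lp_unb <- rational_lp(objective = as_vrat(1), eq_matrix = empty_eq(1),
                        eq_rhs = as_vrat(numeric(0)),
                        lower = as_vrat(0), upper = vrat(1, 0))
  expect_equal(solve_lp_rational(lp_unb)$status, "unbounded")
})

test_that("rational simplex agrees exactly with basic-solution enumeration", {
  for (s in 1:30) {
    lp <- random_small_lp(s)
    oracle <- brute_force_lp(lp)
    sol <- solve_lp_rational(lp)
    if (oracle$status == "infeasible") {
      expect_equal(sol$status, "infeasible", label = paste("seed", s))
    } else {
      expect_equal(sol$status, "optimal", label = paste("seed", s))
      expect_true(isTRUE(sol$objective_value == oracle$objective),
                  label = paste("seed", s, "objective",
                                rat_format(sol$objective_value), "vs oracle",
                                rat_format(oracle$objective)))
    }
  }
})

test_that("optimal solutions satisfy their own constraints exactly", {
  for (s in 31:40) {
    lp <- random_small_lp(s)
    sol <- solve_lp_rational(lp)
    if (sol$status != "optimal") next
    if (nrow(lp$eq_matrix$num) > 0) {
      res <- rat_matvec(lp$eq_matrix, sol$values)
      expect_true(all(res == lp$eq_rhs))
    }
    expect_true(all(sol$values >= lp$lower))
    expect_true(all(sol$values <= lp$upper))
  }
})

test_that("row scaling cannot change the exact optimum", {
  for (s in c(3, 7, 11, 19)) {
    lp <- random_small_lp(s)
    if (nrow(lp$eq_matrix$num) == 0) next
    base <- solve_lp_rational(lp)
    sc <- rat_parse("3/7")
    A2 <- lp$eq_matrix
    A2num <- A2$num; A2den <- A2$den
    row1 <- gemverify:::new_vrat(A2num[1, ], A2den[1, ]) * sc
    A2num[1, ] <- row1$num; A2den[1, ] <- row1$den
    rhs2 <- lp$eq_rhs
    rhs2[1] <- rhs2[1] * sc
    lp2 <- rational_lp(lp$objective, ratmat(A2num, A2den), rhs2,
                       lp$lower, lp$upper, ids = lp$ids)
    scaled <- solve_lp_rational(lp2)
    expect_equal(scaled$status, base$status)
    if (base$status == "optimal")
      expect_true(isTRUE(scaled$objective_value == base$objective_value))
  }
})

test_that("the float simplex solves the same programs to working precision", {
  for (s in 1:15) {
    lp <- random_small_lp(s)
    exact <- solve_lp_rational(lp)
    fl <- solve_lp_float(lp)
    expect_equal(fl$status, exact$status, label = paste("seed", s))
    if (exact$status == "optimal")
      expect_lt(abs(fl$objective_value - as.numeric(exact$objective_value)), 1e-6)
  }
})

test_that("the iteration cap aborts rather than returning unverified answers", {
  lp <- random_small_lp(1)
  expect_error(solve_lp_rational(lp, max_iterations = 0), "abandoned")
})
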