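# Independent oracles used to validate the simplex implementation.
#
# The brute-force LP oracle enumerates every basic solution of a bounded,
# equality-constrained LP: choose m basic columns, pin each nonbasic column to
# one of its (finite) bounds, solve the m x m rational system by Gaussian
# elimination written here in plain R on vrat scalars, keep the feasible ones,
# and take the best objective. For a feasible bounded LP the optimum is
# attained at such a point, so this is exhaustive ground truth for small n.

# Solve A x = b exactly (A: ratmat m x m, b: vrat). NULL if singular.
rat_solve_dense <- function(A, b) {
  m <- length(b)
  if (m == 0) return(as_vrat(numeric(0)))
  rows <- lapply(seq_len(m), function(i) c(ratmat_row_v(A, i), b[i]))
  for (col in seq_len(m)) {
    piv <- NULL
    for (i in col:m) if (rows[[i]][col]$num[1] != 0) { piv <- i; break }
    if (is.null(piv)) return(NULL)
    tmp <- rows[[col]]; rows[[col]] <- rows[[piv]]; rows[[piv]] <- tmp
    rows[[col]] <- rows[[col]] / rows[[col]][col]
    for (i in seq_len(m)) {
      if (i == col) next
      f <- rows[[i]][col]
      if (f$num[1] != 0) rows[[i]] <- rows[[i]] - f * rows[[col]]
    }
  }
  do.call(c, lapply(seq_len(m), function(i) rows[[i]][m + 1]))
}

ratmat_row_v <- function(A, i) {
  gemverify:::new_vrat(A$num[i, ], A$den[i, ])
}

# Exhaustive optimum of a rational_lp with all-finite bounds.
brute_force_lp <- function(lp) {
  n <- length(lp$ids)
  m <- nrow(lp$eq_matrix$num)
  stopifnot(all(lp$lower$den != 0), all(lp$upper$den != 0))
  best <- NULL
  feasible <- FALSE
  consider <- function(x) {
    if (!(all(x >= lp$lower) && all(x <= lp$upper))) return()
    if (m > 0) {
      res <- rat_matvec(lp$eq_matrix, x)
      if (!all(res == lp$eq_rhs)) return()
    }
    feasible <<- TRUE
    obj <- rat_sum(lp$objective * x)
    if (is.null(best) || isTRUE(obj > best)) best <<- obj
  }
  basis_sets <- if (m == 0) list(integer(0)) else
    asplit(utils::combn(n, m), 2)
  for (basic in basis_sets) {
    basic <- as.integer(basic)
    nonbasic <- setdiff(seq_len(n), basic)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nonbasic)))
    if (nrow(grid) == 0) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- gemverify:::rat_zero(n)
      for (t in seq_along(nonbasic)) {
        j <- nonbasic[t]
        x[j] <- if (isTRUE(grid[g, t])) lp$upper[j] else lp$lower[j]
      }
      if (m > 0) {
        rhs <- lp$eq_rhs
        if (length(nonbasic) > 0) {
          Nmat <- ratmat(lp$eq_matrix$num[, nonbasic, drop = FALSE],
                         lp$eq_matrix$den[, nonbasic, drop = FALSE])
          xn <- do.call(c, lapply(nonbasic, function(j) x[j]))
          rhs <- rhs - rat_matvec(Nmat, xn)
        }
        Bmat <- ratmat(lp$eq_matrix$num[, basic, drop = FALSE],
                       lp$eq_matrix$den[, basic, drop = FALSE])
        xb <- rat_solve_dense(Bmat, rhs)
        if (is.null(xb)) next
        for (t in seq_along(basic)) x[basic[t]] <- xb[t]
      }
      consider(x)
    }
  }
  if (!feasible) list(status = "infeasible", objective = NULL)
  else list(status = "optimal", objective = best)
}

# Seeded random LP with small rational data and finite bounds.
random_small_lp <- function(seed, max_n = 6, max_m = 4) {
  set.seed(seed)
  n <- sample(2:max_n, 1)
  m <- sample(0:min(max_m, n - 1), 1)
  rnd_rat <- function(k) vrat(sample(-3:3, k, replace = TRUE),
                              sample(1:3, k, replace = TRUE))
  A <- ratmat(matrix(sample(-3:3, m * n, replace = TRUE), m, n),
              matrix(sample(1:2, m * n, replace = TRUE), m, n))
  b <- rnd_rat(max(m, 0))
  if (m == 0) b <- as_vrat(numeric(0))
  lb_i <- sample(-3:0, n, replace = TRUE)
  ub_i <- lb_i + sample(0:5, n, replace = TRUE)
  rational_lp(objective = rnd_rat(n), eq_matrix = A, eq_rhs = b,
              lower = as_vrat(lb_i), upper = as_vrat(ub_i),
              ids = paste0("x", seq_len(n)))
}

# Exhaustive loopless-FBA oracle: try every 0/1 assignment of the direction
# binaries and take the best exact LP value over the leaves.
enumerate_loopless_optimum <- function(model, big_M = 1000) {
  llp <- gemverify:::loop_law_problem(model, big_M)
  k <- length(llp$internal_ids)
  best <- NULL
  for (mask in 0:(2^k - 1)) {
    a <- as.integer(intToBits(mask))[seq_len(k)]
    rel <- gemverify:::loopless_relaxation(model, llp, a)
    sol <- solve_lp_rational(rel$lp)
    if (sol$status != "optimal") next
    if (is.null(best) || isTRUE(sol$objective_value > best)) best <- sol$objective_value
  }
  best  # NULL when no assignment admits a feasible flux
}
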