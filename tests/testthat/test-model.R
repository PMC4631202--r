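test_that("stoichiometric matrix transcribes the toy model exactly", {
  m <- make_toy_loop_model()
  S <- stoichiometric_matrix(m, include_boundary = FALSE)
  expect_equal(dim(S), c(3L, 5L))
  expect_equal(dimnames(S)[[1]], c("A", "B", "C"))
  expect_equal(rat_format(gemverify:::ratmat_col(S, 2)), c(A = "-1", B = "1", C = "0"))
  Sb <- stoichiometric_matrix(m, include_boundary = TRUE)
  expect_equal(dim(Sb), c(4L, 5L))
  expect_true("A_b" %in% dimnames(Sb)[[1]])
  # the boundary row carries EX_A's -1
  expect_equal(rat_format(gemverify:::ratmat_col(Sb, 1))[["A_b"]], "-1")
})

test_that("empty model yields a 0 x 0 matrix", {
  m <- gem_model("empty", list(), list())
  expect_equal(dim(stoichiometric_matrix(m)), c(0L, 0L))
})

test_that("exchange identification uses the boundary flag, then one-signedness", {
  m <- make_toy_loop_model()
  expect_setequal(identify_exchanges(m), c("EX_A", "BIO"))

  # all mass-balanced, no boundary species: nothing is an exchange
  closed <- gem_model("closed",
    list(gem_metabolite("A"), gem_metabolite("B")),
    list(gem_reaction("R1", c(A = -1, B = 1), -10, 10),
         gem_reaction("R2", c(B = -1, A = 1), -10, 10)))
  expect_length(identify_exchanges(closed), 0)

  # a pure source with no substrate is an exchange by the one-sign rule
  src <- gem_model("src", list(gem_metabolite("A")),
                   list(gem_reaction("SRC", c(A = 1), 0, 5)))
  expect_equal(identify_exchanges(src), "SRC")
})

test_that("case-colliding species ids produce one CASE_COLLISION finding", {
  m <- gem_model("cc",
    list(gem_metabolite("CO2"), gem_metabolite("co2")),
    list(gem_reaction("R1", c(CO2 = 1), 0, 10),
         gem_reaction("R2", c(co2 = 1), 0, 10, objective = 1)))
  rep <- lint_model(m, raw_species_ids = c("CO2", "co2"))
  cc <- rep[rep$code == "CASE_COLLISION", ]
  expect_equal(nrow(cc), 1L)
  expect_match(cc$subject, "CO2")
  expect_match(cc$subject, "co2")
})

test_that("the toy model lints clean and linting is pure", {
  m <- make_toy_loop_model()
  r1 <- lint_model(m)
  expect_equal(nrow(r1[r1$severity == "error", ]), 0L)
  expect_equal(nrow(r1), 0L)
  expect_identical(r1, lint_model(m))
})

test_that("bounds excluding zero flux are flagged", {
  m <- gem_model("z",
    list(gem_metabolite("A"), gem_metabolite("A_b", boundary = TRUE)),
    list(gem_reaction("EX", c(A_b = -1, A = 1), 5, 10),
         gem_reaction("SINK", c(A = -1), 0, 10, objective = 1)))
  rep <- lint_model(m)
  zeb <- rep[rep$code == "ZERO_EXCLUDED_BOUNDS", ]
  expect_equal(zeb$subject, "EX")
})

test_that("missing exchanges and missing objective are reported", {
  m <- gem_model("dead",
    list(gem_metabolite("A"), gem_metabolite("B")),
    list(gem_reaction("R1", c(A = -1, B = 1), -10, 10),
         gem_reaction("R2", c(B = -1, A = 1), -10, 10)))
  rep <- lint_model(m)
  expect_true("NO_EXCHANGES" %in% rep$code)
  expect_true("NO_OBJECTIVE" %in% rep$code)
})

test_that("construction enforces the model invariants", {
  expect_error(gem_reaction("bad", c(A = 1), 5, 1), "lower bound exceeds")
  expect_error(gem_model("dup",
    list(gem_metabolite("A"), gem_metabolite("A")),
    list()), "duplicate metabolite")
  expect_error(gem_model("orphan", list(gem_metabolite("A")),
    list(gem_reaction("R", c(B = 1), 0, 1))), "unknown metabolite")
  # zero coefficients are dropped at construction
  r <- gem_reaction("r", c(A = 1, B = 0), 0, 1)
  expect_equal(r$met_ids, "A")
})

test_that("internal row count equals internal metabolite count for any model", {
  for (s in 1:5) {
    m <- make_random_model(random_model_spec(seed = s))
    S <- stoichiometric_matrix(m, include_boundary = FALSE)
    expect_equal(nrow(S$num), length(gemverify:::internal_met_ids(m)))
  }
})
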