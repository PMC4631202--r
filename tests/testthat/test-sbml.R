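models_equal <- function(a, b) {
  expect_equal(gemverify:::met_ids(a), gemverify:::met_ids(b))
  expect_equal(gemverify:::rxn_ids(a), gemverify:::rxn_ids(b))
  expect_equal(gemverify:::boundary_ids(a), gemverify:::boundary_ids(b))
  ba <- gemverify:::bounds_vectors(a); bb <- gemverify:::bounds_vectors(b)
  expect_true(all(ba$lb == bb$lb))
  expect_true(all(ba$ub == bb$ub))
  expect_true(all(gemverify:::objective_vector(a) == gemverify:::objective_vector(b)))
  for (rid in gemverify:::rxn_ids(a)) {
    ra <- a$reactions[[rid]]; rb <- b$reactions[[rid]]
    expect_equal(ra$met_ids[order(ra$met_ids)], rb$met_ids[order(rb$met_ids)])
    oa <- order(ra$met_ids); ob <- order(rb$met_ids)
    expect_true(all(ra$coef[oa] == rb$coef[ob]))
  }
}

test_that("fbc v2 round trip is exact field-for-field", {
  for (m in list(make_toy_loop_model(), make_loop_free_chain(),
                 make_forced_cycle_model(),
                 make_random_model(random_model_spec(seed = 11)))) {
    p <- tempfile(fileext = ".xml")
    write_sbml_fbc2(m, p)
    expect_equal(detect_dialect(p), "fbc2")
    back <- read_sbml(p, parse_options(dialect = "fbc2"))$model
    models_equal(m, back)
    unlink(p)
  }
})

test_that("legacy dialect round trip is exact field-for-field", {
  m <- make_toy_loop_model()
  p <- tempfile(fileext = ".xml")
  make_boundary_fixture(p)
  expect_equal(detect_dialect(p), "legacy_cobra")
  back <- read_sbml(p)$model
  models_equal(m, back)
  unlink(p)
})

test_that("boundary semantics flip reproduces the misparse mechanism", {
  p <- tempfile(fileext = ".xml")
  make_boundary_fixture(p)

  good <- read_sbml(p, parse_options(respect_boundary = TRUE))$model
  bad <- read_sbml(p, parse_options(respect_boundary = FALSE))$model

  f_good <- solve_fba(good, "exact")
  f_bad <- solve_fba(bad, "exact")
  expect_equal(rat_format(f_good$objective_value), "10")
  expect_equal(rat_format(f_bad$objective_value), "0")

  # the misparse adds exactly one mass-balance row per boundary species
  n_good <- nrow(stoichiometric_matrix(good)$num)
  n_bad <- nrow(stoichiometric_matrix(bad)$num)
  expect_equal(n_bad - n_good, length(gemverify:::boundary_ids(good)))
  unlink(p)
})

test_that("species without a boundary-condition attribute default to internal", {
  p <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="mini"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="SINK" reversible="false">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="10"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '</listOfParameters></kineticLaw></reaction></listOfReactions>',
    '</model></sbml>'), p)
  m <- read_sbml(p)$model
  expect_false(m$metabolites$A$boundary)
  unlink(p)
})

test_that("inverted bounds are repaired and linted, not silently accepted", {
  p <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="inv"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="c" boundaryCondition="true"/>',
    '<species id="B" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="EX" reversible="false">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="10"/><parameter id="UPPER_BOUND" value="0"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="0"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="BIO" reversible="false">',
    '<listOfReactants><speciesReference species="B"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="10"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '</listOfParameters></kineticLaw></reaction></listOfReactions>',
    '</model></sbml>'), p)
  out <- read_sbml(p)
  expect_true("INVERTED_BOUNDS" %in% out$lint$code)
  r <- out$model$reactions$EX
  expect_true(isTRUE(r$lb <= r$ub))
  unlink(p)
})

test_that("non-decimal rationals survive the round trip via annotation", {
  m <- gem_model("rt",
    list(gem_metabolite("A"), gem_metabolite("A_b", boundary = TRUE)),
    list(gem_reaction("EX", c(A_b = -1, A = 1), 0, rat_parse("1/3")),
         gem_reaction("SINK", c(A = "-2/7"), 0, 1000, objective = 1)))
  p <- tempfile(fileext = ".xml")
  write_sbml_fbc2(m, p)
  txt <- readLines(p)
  expect_true(any(grepl("0.3333333333", txt, fixed = TRUE)))
  expect_true(any(grepl('value="1/3"', txt, fixed = TRUE)))
  back <- read_sbml(p)$model
  expect_true(isTRUE(back$reactions$EX$ub == rat_parse("1/3")))
  expect_true(isTRUE(back$reactions$SINK$coef[1] == rat_parse("-2/7")))
  unlink(p)
})

test_that("dialect detection never silently guesses", {
  p <- tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
               '<model id="empty"/></sbml>'), p)
  expect_error(detect_dialect(p), "dialect undetermined")
  expect_error(read_sbml(p), "dialect undetermined|no reactions")
  unlink(p)
})

test_that("the case-collision file parses to two species and one lint finding", {
  p <- tempfile(fileext = ".xml")
  make_case_collision_sbml(p)
  out <- read_sbml(p)
  expect_equal(sum(out$lint$code == "CASE_COLLISION"), 1L)
  expect_true(all(c("CO2", "co2") %in% gemverify:::met_ids(out$model)))
  # merging the two species would remove one internal mass-balance row
  expect_equal(nrow(stoichiometric_matrix(out$model)$num), 3L)
  f <- solve_fba(out$model, "exact")
  expect_equal(f$status, "optimal")
  expect_equal(rat_format(f$objective_value), "10")
  unlink(p)
})
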