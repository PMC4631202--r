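corpus_dir <- local({
  d <- NULL
  function() {
    if (is.null(d)) {
      d <<- tempfile("corpus")
      write_fixture_corpus(d)
    }
    d
  }
})

test_that("the boundary fixture verifies feasible with exact objective 10", {
  rep <- gem_check(file.path(corpus_dir(), "boundary_fixture.xml"))
  expect_equal(rep$verdict, "verified_feasible")
  expect_equal(rep$fba$objective_exact, "10")
  # the exact rational flux certificate is embedded in the report
  expect_false(is.null(rep$exact_flux))
  expect_equal(rep$exact_flux$BIO, "10")
})

test_that("deliberately misparsing the boundary reproduces the blocked verdict", {
  rep <- gem_check(file.path(corpus_dir(), "boundary_fixture.xml"),
                   misparse_boundary = TRUE)
  expect_equal(rep$verdict, "verified_infeasible")
  expect_equal(rep$fba$objective_exact, "0")
  expect_match(paste(rep$notes, collapse = " "), "blocked")
})

test_that("the case-collision fixture is feasible but carries the warning", {
  rep <- gem_check(file.path(corpus_dir(), "case_collision.xml"))
  expect_equal(rep$verdict, "verified_feasible")
  expect_equal(sum(rep$lint$code == "CASE_COLLISION"), 1L)
})

test_that("a forced cycle downgrades to verified_infeasible with a reason", {
  rep <- gem_check(file.path(corpus_dir(), "forced_cycle.xml"))
  expect_equal(rep$verdict, "verified_infeasible")
  expect_match(paste(rep$notes, collapse = " "), "cycle")
})

test_that("batch aggregates all fixtures with deterministic counts", {
  b <- gem_batch(corpus_dir())
  expect_equal(length(b$reports), 12L)
  expect_equal(unname(b$counts[["verified_infeasible"]]), 1L)  # forced cycle
  expect_equal(unname(b$counts[["verified_feasible"]]), 11L)
  expect_equal(unname(b$counts[["parse_error"]]), 0L)
  # rerun is identical
  b2 <- gem_batch(corpus_dir())
  expect_identical(b$counts, b2$counts)
  expect_identical(lapply(b$reports, check_report_as_list),
                   lapply(b2$reports, check_report_as_list))
})

test_that("one broken file is isolated as parse_error", {
  d <- tempfile("broken")
  dir.create(d)
  file.copy(file.path(corpus_dir(), "toy_loop.xml"), file.path(d, "ok.xml"))
  writeLines("<sbml this is not xml", file.path(d, "broken.xml"))
  b <- gem_batch(d)
  expect_equal(unname(b$counts[["parse_error"]]), 1L)
  expect_equal(unname(b$counts[["verified_feasible"]]), 1L)
  verdicts <- vapply(b$reports, function(r) r$verdict, character(1))
  expect_equal(verdicts[basename(b$files) == "broken.xml"], "parse_error")
  unlink(d, recursive = TRUE)
})

test_that("verified_feasible always carries an exact certificate that re-verifies", {
  for (f in c("toy_loop.xml", "random_01.xml", "random_02.xml")) {
    rep <- gem_check(file.path(corpus_dir(), f))
    expect_equal(rep$verdict, "verified_feasible")
    model <- read_sbml(file.path(corpus_dir(), f))$model
    flux <- rat_parse(unlist(rep$exact_flux))
    names(flux) <- names(rep$exact_flux)
    ver <- verify_flux_state(model, flux)
    expect_equal(ver$verdict, "exact_feasible", label = f)
  }
})
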