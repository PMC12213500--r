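test_that("geometric-mean aggregation obeys its closed-form identities", {
  expect_identical(aggregate_qea(rep(1, 6)), 1)
  expect_equal(aggregate_qea(0.37), 0.37)               # single component
  expect_equal(aggregate_qea(c(0.25, 1, 1, 1, 1, 1)), 0.25^(1 / 6),
               tolerance = 1e-12)
  expect_error(aggregate_qea(numeric(0)), "empty")
  expect_error(aggregate_qea(c(0.5, NA)), "finite")
})

test_that("any non-positive desirability forces a hard zero", {
  expect_identical(aggregate_qea(c(0.5, -0.01, 0.9, 0.9, 0.9, 0.9)), 0)
  expect_identical(aggregate_qea(c(1, 1, 0, 1, 1, 1)), 0)
  expect_identical(aggregate_qea(rep(-1, 6)), 0)
})

test_that("aggregation is permutation-invariant and penalises each drop", {
  set.seed(1)
  for (i in 1:20) {
    d <- runif(6, 0.05, 1)
    expect_equal(aggregate_qea(d), aggregate_qea(sample(d)))
    j <- sample(6, 1)
    worse <- d
    worse[j] <- d[j] * 0.5
    expect_lt(aggregate_qea(worse), aggregate_qea(d))
  }
})

test_that("profile fitting recovers the generating peak locations", {
  prof <- fit_qea_profile(simulate_descriptors(500, seed = 101),
                          provenance = "synthetic positives")
  params <- simulation_params("positive")
  # continuous laws: fitted b within one bin width of the generating mode
  # (lognormal mode = median * exp(-sdlog^2))
  for (d in c("mw", "logp")) {
    law <- params[[d]]
    gen_mode <- law$median * exp(-law$sdlog^2)
    m <- prof$models[[d]]
    expect_lt(abs(m$b - gen_mode), m$bin_width, label = d)
  }
  # discrete laws: fitted b within 1 unit of the generating mode
  for (d in c("hba", "hbd", "nrotb", "narr")) {
    law <- params[[d]]
    gen_mode <- floor(law$mean) + law$shift
    expect_lt(abs(prof$models[[d]]$b - gen_mode), 1, label = d)
  }
})

test_that("profile fitting enforces the reference-set floor", {
  expect_error(fit_qea_profile(simulate_descriptors(10, seed = 1)),
               "insufficient")
  expect_error(fit_qea_profile(simulate_descriptors(40, seed = 1), min_n = 50),
               "insufficient")
})

test_that("scores live in [0, 1] and peak compounds score the peak value", {
  prof <- fit_qea_profile(simulate_descriptors(300, seed = 7))
  batch <- simulate_descriptors(500, seed = 8, mode = "decoy")
  scored <- qea_score(batch, prof)
  expect_true(all(scored$qea >= 0 & scored$qea <= 1))
  expect_equal(nrow(scored), 500)
  expect_equal(scored$id, batch$id)        # input order preserved

  # a compound sitting exactly at every b scores the geometric mean of the
  # (clamped) peak heights
  at_peak <- tibble::as_tibble(
    as.list(stats::setNames(vapply(prof$models[qealike:::qea_descriptors],
                                   function(m) m$b, numeric(1)),
                            qealike:::qea_descriptors)))
  peak_score <- qea_score(at_peak, prof)$qea
  expected <- aggregate_qea(vapply(prof$models[qealike:::qea_descriptors],
                                   function(m) min(m$o + m$a, 1), numeric(1)))
  expect_equal(peak_score, expected, tolerance = 1e-12)
})

test_that("invalid compounds carry a null score with the reason kept", {
  prof <- fit_qea_profile(simulate_descriptors(300, seed = 7))
  rec <- compound_tbl(c("CCO", "zzz9"), c("ok", "bad"))
  scored <- qea_score(rec, prof)
  expect_equal(nrow(scored), 2)
  expect_true(is.na(scored$qea[scored$id == "bad"]))
  expect_false(is.na(scored$failure_reason[scored$id == "bad"]))
  expect_true(scored$qea[scored$id == "ok"] >= 0 &&
              scored$qea[scored$id == "ok"] <= 1)
})

test_that("profiles round-trip through JSON byte-identically", {
  prof <- fit_qea_profile(simulate_descriptors(200, seed = 3),
                          provenance = "fixed provenance")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_qea_profile(prof, p1)
  back <- read_qea_profile(p1)
  write_qea_profile(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$models$mw$b, prof$models$mw$b, tolerance = 1e-12)

  # refit on identical input -> byte-identical profile JSON
  prof2 <- fit_qea_profile(simulate_descriptors(200, seed = 3),
                           provenance = "fixed provenance")
  p3 <- withr::local_tempfile(fileext = ".json")
  write_qea_profile(prof2, p3)
  expect_identical(readLines(p1), readLines(p3))
})

test_that("scoring refuses profiles with mismatched descriptor conventions", {
  prof <- fit_qea_profile(simulate_descriptors(200, seed = 3))
  prof$descriptor_conventions[["logp"]] <- "some other logP method"
  expect_error(qea_score(simulate_descriptors(5, seed = 1), prof),
               "conventions")
  expect_error(write_qea_profile(prof, tempfile()), "conventions")
})

test_that("profile accessors tidy, glance and autoplot work", {
  prof <- fit_qea_profile(simulate_descriptors(200, seed = 3))
  td <- tidy(prof)
  expect_equal(nrow(td), 24)
  expect_setequal(unique(td$descriptor),
                  c("mw", "logp", "hba", "hbd", "nrotb", "narr"))
  gl <- glance(prof)
  expect_equal(nrow(gl), 6)
  expect_true(all(gl$fit_rmse >= 0))
  p <- autoplot(prof)
  expect_s3_class(p, "ggplot")
})
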