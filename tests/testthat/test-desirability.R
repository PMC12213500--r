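test_that("closed-form evaluation matches direct arithmetic", {
  # peak value is o + a at x = b
  expect_equal(desirability(5, o = 0.1, a = 0.8, b = 5, c = 2), 0.9)
  # o=0, a=1, b=0, c=1 at x=1: exp(-exp(-1) - 1 + 1) = exp(-exp(-1))
  expect_equal(desirability(1, 0, 1, 0, 1), exp(-exp(-1)))
  expect_equal(desirability(1, 0, 1, 0, 1), 0.6922006276, tolerance = 1e-9)
  # both tails approach the baseline o
  expect_equal(desirability(300 + 20 * 50, 0.05, 0.9, 300, 50), 0.05,
               tolerance = 1e-6)
  expect_equal(desirability(300 - 20 * 50, 0.05, 0.9, 300, 50), 0.05,
               tolerance = 1e-6)
  expect_error(desirability(1, 0, 1, 0, 0), "nonzero")
})

test_that("the curve is strictly unimodal around b", {
  for (cc in c(0.5, 2, -1.3)) {
    b <- 3
    # steep (double-exponential) side hits the baseline to machine precision
    # within ~4 scale lengths; keep the strictness window inside that
    left_ext <- if (cc > 0) 3 else 6
    right_ext <- if (cc > 0) 6 else 3
    grid <- seq(b - left_ext * abs(cc), b + right_ext * abs(cc),
                length.out = 2001)
    y <- desirability(grid, o = 0.05, a = 0.9, b = b, c = cc)
    left <- y[grid < b]
    right <- y[grid > b]
    expect_true(all(diff(left) > 0), info = paste("c =", cc))
    expect_true(all(diff(right) < 0), info = paste("c =", cc))
    expect_equal(max(y), desirability(b, 0.05, 0.9, b, cc),
                 tolerance = 1e-4)   # b need not be a grid point
  }
})

test_that("noise-free self-samples recover the generating parameters", {
  truth <- list(o = 0.05, a = 0.9, b = 3.0, c = 0.8)
  xs <- seq(0, 8, length.out = 25)
  freq <- tibble::tibble(x = xs,
                         count = desirability(xs, truth$o, truth$a,
                                              truth$b, truth$c))
  fit <- fit_desirability(freq, "logp")
  # normalisation rescales counts so the peak maps to 1; undo it for o and a
  scale <- 1 / max(freq$count)
  expect_equal(fit$b, truth$b, tolerance = 0.01)
  expect_equal(fit$c, truth$c, tolerance = 0.01)
  expect_equal(fit$o, truth$o * scale, tolerance = 0.01)
  expect_equal(fit$a, truth$a * scale, tolerance = 0.01)
  expect_lt(fit$fit_rmse, 1e-6)
})

test_that("left-skewed shapes are captured with negative c", {
  xs <- seq(0, 10, length.out = 40)
  y <- desirability(xs, 0.02, 0.95, 6, -1.2)
  fit <- fit_desirability(tibble::tibble(x = xs, count = y), "mw")
  expect_lt(fit$c, 0)
  expect_equal(fit$b, 6, tolerance = 0.01)
})

test_that("median relative error of b stays under 5% across noisy refits", {
  set.seed(2024)
  rel_err <- replicate(50, {
    o <- runif(1, 0, 0.15)
    b <- runif(1, 2, 8)
    cc <- runif(1, 0.5, 2) * sample(c(1, -1), 1)
    xs <- seq(b - 6 * abs(cc), b + 6 * abs(cc), length.out = 30)
    y <- desirability(xs, o, 1 - o, b, cc) + rnorm(30, 0, 0.05)
    fit <- fit_desirability(tibble::tibble(x = xs, count = pmax(y, 0)), "x")
    abs(fit$b - b) / abs(b)
  })
  expect_lt(median(rel_err), 0.05)
})

test_that("fitted b lands within one bin of the empirical mode", {
  set.seed(5)
  x <- rlnorm(2000, log(300), 0.35)
  freq <- bin_frequencies(x)
  fit <- fit_desirability(freq, "mw")
  mode_x <- freq$x[which.max(freq$count)]
  expect_lt(abs(fit$b - mode_x), attr(freq, "bin_width"))
})

test_that("multi-start refits never regress past their best start", {
  set.seed(8)
  x <- rpois(300, 3)
  freq <- integer_frequencies(x)
  fit <- fit_desirability(freq, "hba")
  y <- freq$count / max(freq$count)
  # residual of the naive single start the grid begins from
  naive <- sum((desirability(freq$x, 0, 1, freq$x[which.max(freq$count)],
                             sd(x) / 2) - y)^2)
  expect_lte(fit$fit_rmse^2 * nrow(freq), naive + 1e-12)
})

test_that("undersized or degenerate tables are rejected", {
  expect_error(fit_desirability(tibble::tibble(x = 1:4, count = c(1, 2, 2, 1))),
               "insufficient")
  expect_error(fit_desirability(tibble::tibble(x = 1:5, count = rep(0, 5))),
               "positive")
  expect_error(fit_desirability(data.frame(bad = 1)), "frequency table")
})

test_that("tidy and glance expose the coefficients", {
  xs <- seq(0, 8, length.out = 25)
  fit <- fit_desirability(
    tibble::tibble(x = xs, count = desirability(xs, 0, 1, 3, 1)), "logp")
  td <- tidy(fit)
  expect_equal(td$term, c("o", "a", "b", "c"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$descriptor, "logp")
  expect_equal(gl$peak, fit$o + fit$a)
})
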