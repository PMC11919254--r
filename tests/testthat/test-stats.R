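exp1_profile <- function(n_part = 4, seed = 50, fun = NULL) {
  x <- seq(30, by = -1.6, length.out = 21)
  set.seed(seed)
  if (is.null(fun)) fun <- function(xx) 0 * xx
  y <- matrix(rep(fun(x), each = n_part) + rnorm(n_part * 21, 0, 0.1),
              nrow = n_part)
  snr_profile(x, y, "p1n1")
}

test_that("sliding averages reproduce the printed condition ranges", {
  prof <- exp1_profile()
  sm <- sliding_average(prof, 3)
  expect_length(sm$x, 19)
  expect_equal(max(sm$x), 28.4, tolerance = 1e-9)
  expect_equal(min(sm$x), -0.4, tolerance = 1e-9)
  # values are means of consecutive triples
  expect_equal(sm$y[, 1], rowMeans(prof$y[, 1:3]), tolerance = 1e-12)
  # even window: x is the mean of the window levels
  sm4 <- sliding_average(prof, 4)
  expect_equal(sm4$x[1], mean(prof$x[1:4]), tolerance = 1e-12)
  # constant data are unchanged; window 1 is the identity
  const <- snr_profile(prof$x, matrix(2, 3, 21), "c")
  expect_true(all(sliding_average(const, 3)$y == 2))
  expect_equal(sliding_average(prof, 1)$y, prof$y)
  expect_error(sliding_average(prof, 22), "exceeds")
})

test_that("paired tests against clear speech use BH FDR", {
  # textbook BH: p = (.01,.02,.03,.04), m = 4, q = .05 -> all significant
  expect_identical(bh_oracle(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  set.seed(51)
  x <- seq(20, by = -4, length.out = 5)
  clear <- rnorm(10)
  y <- matrix(rnorm(50), 10) + rep(c(2, 1.5, 0, 0, 0), each = 10)
  res <- paired_tests_vs_clear(clear, snr_profile(x, y, "m"), q = 0.05)
  expect_identical(res$significant, stats::p.adjust(res$p, "BH") <= 0.05)
  expect_identical(res$significant, bh_oracle(res$p, 0.05))
  # t, dof and d match the textbook formulas
  k <- 2
  diffs <- y[, k] - clear
  expect_equal(res$t[k], mean(diffs) / (sd(diffs) / sqrt(10)), tolerance = 1e-12)
  expect_equal(res$dof[k], 9)
  expect_equal(res$d[k], mean(diffs) / sd(diffs), tolerance = 1e-12)
  # all p = 1 -> nothing significant
  same <- matrix(rep(clear, 5), 10) + rnorm(50, sd = 1e-6)
  res1 <- paired_tests_vs_clear(clear, snr_profile(x, same, "m"))
  expect_false(any(res1$p < 0.9 & res1$significant))
  # identical values -> zero-variance error
  expect_error(
    paired_tests_vs_clear(clear, snr_profile(x, matrix(rep(clear, 5), 10), "m")),
    "zero-variance")
})

test_that("BH flags equal the brute-force step-up enumeration", {
  set.seed(52)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    flags <- stats::p.adjust(p, "BH") <= 0.05
    expect_identical(flags, bh_oracle(p, 0.05))
  }
})

test_that("broken-stick regression finds exact breakpoints and documents ties", {
  x <- seq(30, by = -2, length.out = 15)
  truth <- ifelse(x >= 10, 1 * (30 - x), 20)      # rises until +10, then flat
  tilt <- 0.01 * (30 - x)                         # opposite per-participant tilts
  y <- rbind(truth + tilt, truth - tilt)          # group mean stays exact
  fit <- piecewise_fit(snr_profile(x, y, "m"))
  expect_equal(fit$breakpoint, 10, tolerance = 1e-9)
  expect_equal(unname(fit$slopes_group["piece1"]), -1, tolerance = 1e-9)
  expect_equal(unname(fit$slopes_group["piece2"]), 0, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)
  # perfectly linear data: all candidates tie; the highest-SNR one is chosen
  ylin <- rbind(2 * x, 2.1 * x)
  fit_lin <- piecewise_fit(snr_profile(x, ylin, "m"))
  expect_equal(fit_lin$breakpoint, x[2], tolerance = 1e-12)
  expect_error(piecewise_fit(snr_profile(x[1:4], ylin[, 1:4], "m")),
               "at least 5")
  # per-participant slopes feed the t-tests with dof = n - 1
  expect_equal(unique(fit$tests$dof), 1)
})

test_that("slope t-test matches hand computation and its symmetries", {
  res <- slope_ttest(c(1, 2, 3))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$dof, 2)
  expect_equal(res$d, 2, tolerance = 1e-12)
  neg <- slope_ttest(-c(1, 2, 3))
  expect_equal(neg$t, -res$t, tolerance = 1e-12)
  expect_equal(neg$p, res$p, tolerance = 1e-12)
  zero <- slope_ttest(numeric(5))
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  expect_error(slope_ttest(rep(2, 5)), "zero-variance")
  expect_error(slope_ttest(1), "at least 2")
})

test_that("sliding average plus broken stick keeps breakpoints on the center grid", {
  centers <- seq(28.4, by = -1.6, length.out = 19)
  for (s in 1:5) {
    prof <- exp1_profile(n_part = 8, seed = 60 + s,
                         fun = function(xx) pmin(0.1 * (30 - xx), 1.5))
    fit <- piecewise_fit(sliding_average(prof, 3))
    expect_true(any(abs(fit$breakpoint - centers) < 1e-9))
  }
  # the printed experiment breakpoints all lie on that grid
  for (bp in c(15.6, 9.2, 4.4)) {
    expect_true(any(abs(bp - centers) < 1e-9))
  }
})

test_that("piecewise tidiers and plots summarize the fit", {
  x <- seq(30, by = -2, length.out = 11)
  set.seed(54)
  y <- matrix(rep(ifelse(x >= 10, 30 - x, 20), each = 6), 6) + rnorm(66, 0, 0.3)
  fit <- piecewise_fit(snr_profile(x, y, "p1n1"))
  td <- tidy(fit)
  expect_identical(td$piece, c("piece1", "piece2"))
  expect_identical(names(td), c("piece", "slope", "t", "dof", "p", "d"))
  gl <- glance(fit)
  expect_equal(gl$n_participants, 6)
  expect_s3_class(autoplot(fit), "ggplot")
})
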