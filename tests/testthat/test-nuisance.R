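test_that("framewise displacement follows the radius-weighted sum of differences", {
  zero <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(zero), rep(0, 10))
  # single 0.1 mm x-translation step
  m <- zero; m[5:10, 1] <- 0.1
  expect_equal(framewise_displacement(m), c(rep(0, 4), 0.1, rep(0, 5)))
  # 0.002 rad pitch step -> 50 * 0.002 = 0.1 mm
  m2 <- zero; m2[3:10, 4] <- 0.002
  expect_equal(framewise_displacement(m2)[3], 0.1)
  # invariant under a constant offset on all parameters
  off <- matrix(rnorm(60), 10, 6)
  expect_equal(framewise_displacement(off), framewise_displacement(off + 5))
  expect_error(framewise_displacement(matrix(0, 10, 5)), "frames x 6")
})

test_that("Friston-24 expansion matches a brute-force construction", {
  set.seed(1)
  m <- matrix(rnorm(60), 10, 6)
  f <- friston24(m)
  expect_equal(ncol(f), 24)
  # independent column-by-column construction
  for (k in 1:6) {
    lag <- c(0, m[1:9, k])
    expect_equal(unname(f[, k]), m[, k])
    expect_equal(unname(f[, k + 6]), m[, k]^2)
    expect_equal(unname(f[, k + 12]), lag)
    expect_equal(unname(f[, k + 18]), lag^2)
  }
  # constant motion: lagged columns equal unlagged except the first frame
  mc <- matrix(rep(0.3, 60), 10, 6)
  fc <- friston24(mc)
  expect_equal(unname(fc[-1, 13:18]), unname(fc[-1, 1:6]))
  expect_true(all(fc[1, 13:24] == 0))
})

test_that("spike regressors flag only frames strictly above 500 microns", {
  expect_equal(ncol(spike_regressors(c(0, 0.4, 0.2))), 0)
  expect_equal(ncol(spike_regressors(c(0, 0.5, 0.2))), 0)   # strict inequality
  s <- spike_regressors(c(0, 0.6, 0.2, 0.1))
  expect_equal(dim(s), c(4L, 1L))
  expect_equal(unname(s[, 1]), c(0, 1, 0, 0))
})

test_that("clean_timeseries residualizes against the design (normal-equations oracle)", {
  set.seed(2)
  nf <- 80
  ts <- matrix(rnorm(5 * nf, mean = 1000, sd = 20), 5, nf)
  design <- cbind(sin(1:nf / 5), rnorm(nf))
  out <- clean_timeseries(ts, design)
  # oracle: explicit normal equations on the scaled data
  scaled <- ts * 1000 / median(ts)
  X <- cbind(1, seq_len(nf), design)
  beta <- solve(crossprod(X), crossprod(X, t(scaled)))
  oracle <- t(t(scaled) - X %*% beta) + 1000
  expect_equal(unclass(out), oracle, tolerance = 1e-9, ignore_attr = TRUE)
  # residual component orthogonal to every design column
  resid_part <- out - 1000
  for (k in seq_len(ncol(X)))
    expect_lt(abs(sum(resid_part[1, ] * X[, k])),
              1e-8 * sqrt(sum(resid_part[1, ]^2)) * sqrt(sum(X[, k]^2)) + 1e-8)
})

test_that("a timeseries equal to a design column is annihilated", {
  nf <- 60
  design <- matrix(sin(1:nf / 3), ncol = 1)
  ts <- matrix(rep(design[, 1], 2), 2, nf, byrow = TRUE)
  out <- clean_timeseries(ts, design, scale_median = NULL)
  expect_lt(max(abs(out)), 1e-10)
})

test_that("cleaning is idempotent and empty designs reduce to scale + detrend", {
  set.seed(3)
  nf <- 100
  ts <- matrix(rnorm(3 * nf, 1000, 10), 3, nf)
  design <- matrix(rnorm(nf), ncol = 1)
  # exact idempotence without rescaling
  p1 <- clean_timeseries(ts, design, scale_median = NULL)
  p2 <- clean_timeseries(p1, design, scale_median = NULL)
  expect_equal(p2, p1, tolerance = 1e-12)
  # near-idempotence with the median-1000 rescale
  q1 <- clean_timeseries(ts, design)
  q2 <- clean_timeseries(q1, design)
  expect_lt(max(abs(q2 - q1)) / stats::sd(q1), 0.05)
  # empty design: scaled, detrended input (plus restored baseline)
  e <- clean_timeseries(ts, NULL)
  scaled <- ts * 1000 / median(ts)
  X <- cbind(1, seq_len(nf))
  beta <- solve(crossprod(X), crossprod(X, t(scaled)))
  expect_equal(unclass(e), t(t(scaled) - X %*% beta) + 1000,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rank-deficient designs are handled by dropping columns", {
  nf <- 50
  ts <- matrix(rnorm(2 * nf, 1000, 5), 2, nf)
  design <- cbind(a = rnorm(nf))
  design <- cbind(design, b = 2 * design[, 1])
  expect_warning(out <- clean_timeseries(ts, design), "rank-deficient")
  expect_equal(dim(out), dim(ts))
})

test_that("nuisance_design detrends continuous columns and drops all-zero ones", {
  set.seed(4)
  motion <- matrix(rnorm(120, sd = 0.01), 20, 6)
  X <- nuisance_design(motion = motion,
                       spikes = spike_regressors(rep(0.1, 20)))
  expect_equal(ncol(X), 24)       # no spikes flagged, 24 motion columns
  tt <- seq_len(20)
  for (k in seq_len(ncol(X)))
    expect_lt(abs(sum(X[, k] * (tt - mean(tt)))), 1e-8)
  expect_equal(ncol(nuisance_design(motion = matrix(0, 20, 6),
                                    spikes = spike_regressors(c(rep(0, 19), 0.7)))),
               1)                 # zero motion columns dropped, spike kept
})
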