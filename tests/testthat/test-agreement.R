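# Independent oracle for Lin's CCC: the moment formula written out as raw
# sums, deliberately not reusing any package code.
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

test_that("lin_ccc matches the moment-formula oracle", {
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(2, 3, 4, 5)), 2 * 1.25 / 3.5,
               tolerance = 1e-12)
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.714286,
               tolerance = 1e-6)
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(50, 60, 30)
    y <- 0.8 * x + rnorm(50, 5, 20)
    expect_equal(lin_ccc(x, y), ccc_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("lin_ccc is 1 on self-agreement and near 0 under independence", {
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(20)
    expect_equal(lin_ccc(x, x), 1, tolerance = 1e-12)
  }
  x <- rnorm(1e5)
  y <- rnorm(1e5)
  expect_lt(abs(lin_ccc(x, y)), 0.02)
})

test_that("lin_ccc is symmetric, bounded by |Pearson r|, and rejects degenerate input", {
  set.seed(31)
  for (i in 1:200) {
    x <- rnorm(15, sd = runif(1, 0.5, 3))
    y <- rnorm(15, mean = runif(1, -2, 2))
    ccc <- lin_ccc(x, y)
    expect_equal(ccc, lin_ccc(y, x), tolerance = 1e-12)
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
    expect_lte(abs(ccc), 1)
  }
  expect_error(lin_ccc(rep(1, 5), rep(1, 5)), "constant")
  expect_error(lin_ccc(1:3, 1:4), "equal length")
})

test_that("Fisher z interval matches the closed form and is symmetric at 0", {
  ci <- ccc_ci(0, 100)
  expect_equal(ci[1], -ci[2], tolerance = 1e-12)

  ci9 <- ccc_ci(0.9, 10)
  expect_equal(ci9, tanh(atanh(0.9) + c(-1, 1) * qnorm(0.975) / sqrt(8)),
               tolerance = 1e-12)

  expect_warning(cip <- ccc_ci(1, 10), "degenerate")
  expect_equal(cip, c(1, 1))
})

test_that("Fisher z interval has near-nominal coverage for bivariate normal pairs", {
  # shared-signal model: x = s + e1, y = s + e2 with var(s) = var(e) = 1
  # gives population CCC = 0.5
  set.seed(41)
  hits <- vapply(1:500, function(i) {
    s <- rnorm(50)
    x <- s + rnorm(50)
    y <- s + rnorm(50)
    ci <- ccc_ci(lin_ccc(x, y), 50)
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.91)
  expect_lte(mean(hits), 0.99)
})

test_that("Bland-Altman LoA match hand arithmetic", {
  expect_equal(bland_altman_loa(rep(12, 5)),
               c(bias = 12, lower = 12, upper = 12))
  loa <- bland_altman_loa(c(-10, 0, 10))
  expect_equal(unname(loa), c(0, -19.6, 19.6))
  expect_error(bland_altman_loa(5), "at least 2")
})

test_that("cluster bootstrap handles degenerate and invalid panels", {
  panel <- tibble::tibble(
    participant_id = rep(c("A", "B", "C"), each = 5),
    sensor = rnorm(15, 60, 20)
  )
  panel$selfreport <- panel$sensor
  ci <- cluster_bootstrap_ci(panel, n_boot = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))

  single <- panel[panel$participant_id == "A", ]
  expect_error(cluster_bootstrap_ci(single, n_boot = 200), "2 participants")
})

test_that("CCC banding uses the inclusive moderate boundaries", {
  expect_equal(ccc_band(0.70), "moderate")
  expect_equal(ccc_band(0.92), "excellent")
  expect_equal(ccc_band(0.5), "moderate")
  expect_equal(ccc_band(0.75), "moderate")
  expect_equal(ccc_band(0.9), "strong")
  expect_equal(ccc_band(0.49), "poor")
  expect_error(ccc_band(1.2), "\\[-1, 1\\]")
})

test_that("aggregated-level CCC equals lin_ccc on the per-participant summaries", {
  set.seed(51)
  vals <- lapply(1:6, function(i) pmax(0, rnorm(14, 60, 30)))
  names(vals) <- sprintf("P%02d", 1:6)
  sensor <- daily_tbl(vals)
  noisy <- lapply(vals, function(v) pmax(0, v + rnorm(14, 8, 25)))
  selfrep <- daily_tbl(noisy)

  est <- agreement_at_level(sensor, selfrep, "avg_daily")
  s <- summarize_wear(sensor)
  r <- summarize_wear(selfrep)
  expect_equal(est$ccc, lin_ccc(s$avg_daily_minutes, r$avg_daily_minutes),
               tolerance = 1e-12)
  expect_equal(est$n_pairs, 6)
  expect_equal(est$ci_method, "fisher_z")

  # bias is antisymmetric under swapping the two methods
  est_sw <- agreement_at_level(selfrep, sensor, "avg_daily")
  expect_equal(est$bias, -est_sw$bias, tolerance = 1e-12)
})

test_that("perfect agreement yields CCC 1, zero bias and degenerate LoA at every level", {
  set.seed(61)
  vals <- lapply(1:4, function(i) round(pmax(0, rnorm(20, 60, 40))))
  names(vals) <- sprintf("P%02d", 1:4)
  sensor <- daily_tbl(vals)
  tab <- suppressWarnings(
    agreement_table(sensor, sensor, n_boot = 200, seed = 2)
  )
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$ccc == 1))
  expect_true(all(tab$bias == 0))
  expect_true(all(tab$loa_lo == 0 & tab$loa_hi == 0))
  expect_true(all(tab$band == "excellent"))
})

test_that("daily panels drop missing-log days and order LoA around the bias", {
  set.seed(71)
  vals <- lapply(1:5, function(i) pmax(0, rnorm(21, 60, 30)))
  names(vals) <- sprintf("P%02d", 1:5)
  sensor <- daily_tbl(vals)
  selfrep <- daily_tbl(lapply(vals, function(v) v + rnorm(21, 10, 30)))
  selfrep$minutes[c(3, 40, 41)] <- NA

  panel <- align_panel(sensor, selfrep, "daily")
  expect_equal(nrow(panel), 5 * 21 - 3)

  est <- agreement_at_level(sensor, selfrep, "daily", n_boot = 200, seed = 3)
  expect_lte(est$loa_lo, est$bias)
  expect_lte(est$bias, est$loa_hi)
  expect_lte(est$ccc_lo, est$ccc)
  expect_gte(est$ccc_hi, est$ccc)
  expect_equal(est$ci_method, "cluster_bootstrap")
})

test_that("the repeated-measures LoA correction and VC estimator agree on balanced data", {
  # balanced subject random-effect data: both estimators should land close
  # to the pooled ones
  set.seed(81)
  a <- rnorm(8, 0, 15)
  vals <- lapply(seq_len(8), function(i) pmax(0, 60 + a[i] + rnorm(30, 0, 35)))
  names(vals) <- sprintf("P%02d", 1:8)
  sensor <- daily_tbl(vals)
  selfrep <- daily_tbl(lapply(vals, function(v) v + rnorm(30, 0, 25)))

  pooled <- agreement_at_level(sensor, selfrep, "daily", ci = FALSE)
  rm_loa <- agreement_at_level(sensor, selfrep, "daily", ci = FALSE,
                               loa_rm_correction = TRUE)
  expect_equal(rm_loa$loa_hi - rm_loa$loa_lo,
               pooled$loa_hi - pooled$loa_lo, tolerance = 0.1)
  expect_equal(rm_loa$loa_method, "rm_corrected")

  vc <- agreement_at_level(sensor, selfrep, "daily", ci = FALSE,
                           estimator = "vc")
  expect_equal(vc$estimator, "vc")
  expect_equal(vc$ccc, pooled$ccc, tolerance = 0.12)
})

test_that("rolling LoA shrink roughly with the square root of the window", {
  set.seed(91)
  vals <- lapply(1:10, function(i) pmax(0, rnorm(42, 60, 35)))
  names(vals) <- sprintf("P%02d", 1:10)
  sensor <- daily_tbl(vals)
  selfrep <- daily_tbl(lapply(vals, function(v) v + rnorm(42, 0, 100)))

  daily <- agreement_at_level(sensor, selfrep, "daily", ci = FALSE)
  r7 <- agreement_at_level(sensor, selfrep, "rolling7", ci = FALSE)
  half_daily <- (daily$loa_hi - daily$loa_lo) / 2
  half_r7 <- (r7$loa_hi - r7$loa_lo) / 2
  expect_lt(abs(half_r7 / (half_daily / sqrt(7)) - 1), 0.3)
})
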