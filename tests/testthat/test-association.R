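test_that("Spearman correlation handles monotone and tied data", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_r(x, sort(x)[rank(x)]), 1) # y increasing in x
  expect_equal(spearman_r(x, 2 * x + 1), 1)
  expect_equal(spearman_r(x, -x), -1)
  # ties: Pearson correlation of average ranks, computed by hand
  a <- c(1, 2, 2, 3)
  b <- c(10, 20, 30, 40)
  ra <- c(1, 2.5, 2.5, 4)
  rb <- c(1, 2, 3, 4)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearman_r(a, b), oracle)
  expect_error(spearman_r(c(1, 1, 1), b[1:3]), "constant")
  expect_error(spearman_r(1:4, 1:5), "length")
})

test_that("HDI is the shortest interval with the requested mass", {
  set.seed(41)
  x <- rnorm(1e6)
  h <- hdi(x, 0.95)
  expect_equal(h[["lower"]], -1.96, tolerance = 0.02)
  expect_equal(h[["upper"]], 1.96, tolerance = 0.02)
  # uniform draws: width approximately the mass
  u <- runif(2e5)
  hu <- hdi(u, 0.95)
  expect_equal(hu[["upper"]] - hu[["lower"]], 0.95, tolerance = 0.01)
  # degenerate sample
  expect_equal(hdi(rep(3, 50)), c(lower = 3, upper = 3))
  expect_error(hdi(numeric(0)), "empty")
  expect_error(hdi(x, 1), "mass")
  # skewed sample: HDI is shorter than the equal-tailed interval
  y <- rexp(2e5)
  hy <- hdi(y, 0.9)
  et <- quantile(y, c(0.05, 0.95))
  expect_lt(hy[["upper"]] - hy[["lower"]], et[[2]] - et[[1]])
  expect_equal(hy[["lower"]], 0, tolerance = 0.005)
})

test_that("HDI is equivariant under shifts", {
  set.seed(42)
  x <- rgamma(5000, 2, 3)
  h0 <- hdi(x)
  for (c0 in c(-2, 0.5, 10)) {
    expect_equal(unname(hdi(x + c0)), unname(h0 + c0), tolerance = 1e-12)
  }
})

test_that("ROPE verdicts follow the interval geometry", {
  expect_equal(rope_decision(c(-0.56, -0.38)), "reject_null")
  expect_equal(rope_decision(c(-0.05, 0.05)), "within_rope")
  expect_equal(rope_decision(c(-0.2, 0.05)), "undecided")
  expect_equal(rope_decision(c(0.12, 0.5)), "reject_null")
  expect_equal(rope_decision(c(-0.1, 0.1)), "within_rope") # touching bounds
  expect_error(rope_decision(c(0.5, -0.5)), "interval")
  expect_error(rope_decision(c(NA, 1)), "interval")
})

make_draws <- function(theta, n_draws, noise_sd, seed = 1) {
  set.seed(seed)
  n <- length(theta)
  tibble::tibble(
    chain = 1L,
    iteration = rep(seq_len(n_draws), each = n),
    participant_id = rep(sprintf("P%02d", seq_len(n)), n_draws),
    ssrt = rep(theta, n_draws) + rnorm(n * n_draws, 0, noise_sd))
}

test_that("degenerate posteriors give the point Spearman for every draw", {
  theta <- seq(0.2, 0.5, length.out = 12)
  draws <- make_draws(theta, 150, 0)
  vals <- tibble::tibble(participant_id = sprintf("P%02d", 1:12),
                         residual = -(1:12) + rnorm(12, 0, 3))
  cp <- posterior_correlation(draws, vals)
  expect_equal(unname(cp$hdi["lower"]), unname(cp$hdi["upper"]))
  expect_equal(cp$r_mean, spearman_r(theta, vals$residual))
  expect_equal(cp$r_point, cp$r_mean)
})

test_that("strong negative coupling concentrates the posterior below zero", {
  set.seed(43)
  theta <- rnorm(33, 0.4, 0.1)
  resid <- -0.5 * scale(theta)[, 1] + rnorm(33, 0, 0.25)
  draws <- make_draws(theta, 300, 0.03)
  vals <- tibble::tibble(participant_id = sprintf("P%02d", 1:33),
                         residual = resid)
  cp <- posterior_correlation(draws, vals)
  expect_lt(cp$hdi[["upper"]], 0)
  expect_equal(cp$verdict, "reject_null")
  # shuffling the residual labels breaks the association
  set.seed(44)
  centred <- vapply(1:40, function(i) {
    v2 <- vals
    v2$residual <- sample(v2$residual)
    posterior_correlation(draws, v2)$r_mean
  }, numeric(1))
  expect_lt(abs(mean(centred)), 0.1)
})

test_that("participant mismatches and short draws are rejected", {
  draws <- make_draws(1:5 / 10, 200, 0.01)
  vals <- tibble::tibble(participant_id = sprintf("P%02d", 1:4),
                         residual = rnorm(4))
  expect_error(posterior_correlation(draws, vals), "mismatch")
  draws2 <- make_draws(1:5 / 10, 50, 0.01)
  vals2 <- tibble::tibble(participant_id = sprintf("P%02d", 1:5),
                          residual = rnorm(5))
  expect_error(posterior_correlation(draws2, vals2), "100")
})

test_that("tidy and autoplot summarise a correlation posterior", {
  draws <- make_draws(seq(0.2, 0.6, length.out = 10), 200, 0.05)
  vals <- tibble::tibble(participant_id = sprintf("P%02d", 1:10),
                         residual = rnorm(10))
  cp <- posterior_correlation(draws, vals)
  td <- tidy(cp)
  expect_true(all(c("r_mean", "hdi_low", "hdi_high", "verdict") %in%
                    names(td)))
  expect_true(td$hdi_low <= td$hdi_high)
  expect_s3_class(autoplot(cp), "ggplot")
})

test_that("generator-strength coupling is detected in most replicates", {
  # power property at the study size: coupling tuned so the point Spearman
  # is near -0.5 across 33 patients, with realistic posterior widths
  verdicts <- vapply(1:20, function(k) {
    withr::with_seed(600 + k, {
      theta <- rnorm(33, 0.4, 0.07)
      resid <- -0.5 * scale(theta)[, 1] + rnorm(33, 0, sqrt(1 - 0.5^2))
      draws <- make_draws(theta, 300, 0.02, seed = 700 + k)
      vals <- tibble::tibble(participant_id = sprintf("P%02d", 1:33),
                             residual = as.numeric(resid))
      posterior_correlation(draws, vals)$verdict
    })
  }, character(1))
  expect_gte(mean(verdicts == "reject_null"), 0.8)
})

test_that("under a true null the correlation posterior is centred at zero", {
  # The HDI/ROPE rule is not a calibrated frequentist test: with tight SSRT
  # posteriors its null rejection rate at n = 33 substantially exceeds 5%
  # (see the methods vignette). What holds is that the r distribution is
  # centred at zero, and that rejections become rare once the posterior
  # uncertainty is comparable to the between-participant spread.
  res <- vapply(1:30, function(k) {
    withr::with_seed(800 + k, {
      theta <- rnorm(33, 0.4, 0.07)
      vals <- tibble::tibble(participant_id = sprintf("P%02d", 1:33),
                             residual = rnorm(33))
      wide <- posterior_correlation(make_draws(theta, 300, 0.05,
                                               seed = 900 + k), vals)
      c(r = wide$r_mean, reject = wide$verdict == "reject_null")
    })
  }, c(r = 0, reject = 0))
  expect_lt(abs(mean(res["r", ])), 0.08)
  expect_lte(mean(res["reject", ]), 0.1)
})
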