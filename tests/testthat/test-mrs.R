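# synthetic metabolite table with known coefficients
make_metab <- function(n = 40, seed = 1, beta_gm = 1.2, deficit = 0,
                       noise = 0.1, regions = "right_IFG",
                       metabolite = "GABA") {
  withr::with_seed(seed, {
    purrr::map_dfr(regions, function(rg) {
      grp <- rep(c("control", "patient"), length.out = n)
      age <- rnorm(n, 66, 7)
      sex <- sample(c("F", "M"), n, replace = TRUE)
      f_gm <- runif(n, 0.3, 0.5)
      f_wm <- runif(n, 0.25, 0.45)
      crlb <- runif(n, 5, 15)
      dep <- if (rg == "right_IFG") deficit else 0
      conc <- 2 + 0.01 * (age - 65) + 0.05 * (sex == "M") + beta_gm * f_gm -
        dep * (grp == "patient") + rnorm(n, 0, noise)
      tibble::tibble(participant_id = sprintf("S%02d", seq_len(n)),
                     group = grp, region = rg, metabolite = metabolite,
                     concentration = conc, crlb = crlb, f_gm = f_gm,
                     f_wm = f_wm, f_csf = pmax(1 - f_gm - f_wm, 0),
                     age = age, sex = sex)
    })
  })
}

test_that("weighted residuals are orthogonal to every covariate", {
  recs <- make_metab(n = 50, seed = 2, deficit = 0.3)
  out <- correct_concentrations(recs)
  w <- 1 / recs$crlb^2
  for (v in list(recs$age, as.numeric(factor(recs$sex)), recs$f_gm)) {
    wc <- sum(w * (v - weighted.mean(v, w)) * out$residual)
    expect_lt(abs(wc / sum(w)), 1e-10)
  }
  expect_lt(abs(weighted.mean(out$residual, w)), 1e-12)
  # known grey-matter slope recovered
  cf <- attr(out, "coefficients")
  expect_equal(cf$estimate[cf$term == "f_gm"], 1.2, tolerance = 0.35)
  # the injected group deficit survives correction
  expect_gt(mean(out$residual[out$group == "control"]) -
              mean(out$residual[out$group == "patient"]), 0.15)
})

test_that("correction reduces to a weighted mean when covariates are constant", {
  recs <- make_metab(n = 20, seed = 3)
  recs$age <- 66
  recs$sex <- "F"
  recs$f_gm <- 0.4
  recs$f_wm <- 0.35
  recs$f_csf <- 0.25
  out <- correct_concentrations(recs)
  w <- 1 / recs$crlb^2
  expect_equal(out$residual,
               recs$concentration - weighted.mean(recs$concentration, w),
               tolerance = 1e-10)
})

test_that("residualisation is idempotent and weighting converges", {
  recs <- make_metab(n = 40, seed = 4)
  out1 <- correct_concentrations(recs)
  recs2 <- recs
  recs2$concentration <- out1$residual
  out2 <- correct_concentrations(recs2)
  expect_equal(out2$residual, out1$residual, tolerance = 1e-10)
  # equal-weight limit: as CRLB variation vanishes the two weightings agree
  recs3 <- recs
  recs3$crlb <- 10
  a <- correct_concentrations(recs3, weighting = "inv_crlb2")
  b <- correct_concentrations(recs3, weighting = "inv_crlb")
  expect_equal(a$residual, b$residual, tolerance = 1e-12)
})

test_that("degenerate designs and bad inputs error informatively", {
  recs <- make_metab(n = 30, seed = 5)
  recs$f_wm <- recs$f_gm # collinear with f_gm under the glutamate set
  recs$f_csf <- pmax(1 - recs$f_gm - recs$f_wm, 0)
  recs$metabolite <- "glutamate"
  expect_error(correct_concentrations(recs), "collinear")
  recs2 <- make_metab(n = 30, seed = 6)
  recs2$crlb[3] <- 0
  expect_error(correct_concentrations(recs2), "crlb")
  expect_error(correct_concentrations(make_metab(4)[, -5]), "missing columns")
})

test_that("Grubbs test flags a single gross outlier and only then", {
  # closed-form oracle computed here, independently of the implementation
  g_crit <- function(n, alpha = 0.05) {
    t2 <- qt(1 - alpha / (2 * n), n - 2)^2
    (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
  }
  x <- c(1, 1.1, 0.9, 8)
  expect_gt(max(abs(x - mean(x))) / sd(x), g_crit(4)) # oracle says outlier
  expect_equal(grubbs_outlier(x), 4L)
  y <- c(1, 1.1, 0.9, 1.05)
  expect_lt(max(abs(y - mean(y))) / sd(y), g_crit(4))
  expect_true(is.na(grubbs_outlier(y)))
  expect_true(is.na(grubbs_outlier(rep(2, 5))))
  expect_error(grubbs_outlier(c(1, 2)), "at least 3")
  # symmetric under sign flip of centred data
  z <- c(rnorm(20), 6)
  expect_equal(grubbs_outlier(z), grubbs_outlier(-z + 2 * mean(z)))
})

test_that("mixed ANOVA matches the textbook decomposition on a balanced toy", {
  # 2 groups x 2 regions, 4 subjects per group, hand-decomposable values
  df <- tidyr::expand_grid(group = c("a", "b"), subj = 1:4,
                           region = c("r1", "r2"))
  df$participant_id <- paste0(df$group, df$subj)
  set.seed(7)
  eff <- c(a = 0, b = 1.5)
  reg <- c(r1 = 0, r2 = 0.5)
  df$residual <- eff[df$group] + reg[df$region] +
    rep(rnorm(8, 0, 0.3), each = 2) + rnorm(16, 0, 0.2)
  df$metabolite <- "GABA"
  out <- group_region_anova(df, "GABA")
  # between-subject F for group, computed by hand from subject means
  sm <- tapply(df$residual, df$participant_id, mean)
  gm <- substr(names(sm), 1, 1)
  ssb <- 2 * sum(tapply(sm, gm, function(v) length(v) * (mean(v) - mean(sm))^2))
  ssw <- 2 * sum((sm - ave(sm, gm))^2)
  f_hand <- (ssb / 1) / (ssw / 6)
  f_pkg <- out$anova$statistic[out$anova$term == "group" &
                                 !is.na(out$anova$statistic)]
  expect_equal(f_pkg, f_hand, tolerance = 1e-8)
  # simple effects: one-way F per region equals aov run by hand
  for (r in c("r1", "r2")) {
    sub <- df[df$region == r, ]
    f_r <- summary(aov(residual ~ group, sub))[[1]]$`F value`[1]
    expect_equal(out$simple_effects$statistic[out$simple_effects$region == r],
                 f_r)
  }
})

test_that("a frontal-only deficit yields the region-specific pattern", {
  recs <- dplyr::bind_rows(
    make_metab(n = 53, seed = 8, deficit = 0.25, noise = 0.18,
               regions = "right_IFG"),
    make_metab(n = 53, seed = 9, deficit = 0, noise = 0.18,
               regions = "right_occipital"))
  out <- correct_concentrations(recs)
  an <- group_region_anova(out, "GABA")
  se <- an$simple_effects
  expect_lt(se$p.value[se$region == "right_IFG"], 0.05)
  expect_gt(se$p.value[se$region == "right_occipital"], 0.05)
  expect_s3_class(tidy(an), "tbl_df")
  expect_true(is.finite(glance(an)$group_F))
})

test_that("participants missing a region are dropped listwise", {
  recs <- dplyr::bind_rows(
    make_metab(n = 20, seed = 10, regions = "right_IFG"),
    make_metab(n = 20, seed = 11, regions = "right_occipital"))
  out <- correct_concentrations(recs)
  out <- out[-3, ] # S03 loses one region
  expect_message(an <- group_region_anova(out, "GABA"), "dropping 1")
  expect_equal(an$dropped, "S03")
})
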