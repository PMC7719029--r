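#' Default covariate sets for metabolite correction
#'
#' Glutamate is corrected for age, sex and both grey- and white-matter
#' fractions; GABA for age, sex and the grey-matter fraction. Any
#' metabolite not listed falls back to the glutamate set.
#'
#' @return Named list of character vectors of covariate column names.
#' @export
default_covariate_sets <- function() {
  list(glutamate = c("age", "sex", "f_gm", "f_wm"),
       GABA = c("age", "sex", "f_gm"))
}

check_metabolite_records <- function(records) {
  need <- c("participant_id", "group", "region", "metabolite",
            "concentration", "crlb", "f_gm", "f_wm", "f_csf", "age", "sex")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    rlang::abort(paste0("metabolite table is missing columns: ",
                        paste(miss, collapse = ", ")))
  }
  if (any(records$crlb <= 0 | !is.finite(records$crlb))) {
    rlang::abort("crlb must be positive")
  }
  fr <- records$f_gm + records$f_wm + records$f_csf
  if (any(records$f_gm < 0 | records$f_wm < 0 | records$f_csf < 0 |
          fr > 1 + 1e-6)) {
    rlang::abort("tissue fractions must be in [0,1] and sum to at most 1")
  }
  invisible(records)
}

#' CRLB-weighted covariate correction of metabolite concentrations
#'
#' Removes the effect of age, sex and partial volume from water-scaled
#' metabolite concentrations with a weighted linear model fitted per
#' (region, metabolite) cell; the residuals are used for all further
#' analysis. Weights default to `1 / crlb^2`, reading the Cramer-Rao lower
#' bound as a percent standard deviation of the measurement (switchable to
#' `1 / crlb`). Age is centred and sex enters as a single indicator
#' contrast. Diagnostic group is deliberately excluded from the design so
#' that group differences survive in the residuals.
#'
#' @param records Metabolite table: one row per participant x region x
#'   metabolite with columns `participant_id`, `group`, `region`,
#'   `metabolite`, `concentration`, `crlb` (percent, > 0), `f_gm`, `f_wm`,
#'   `f_csf`, `age`, `sex`.
#' @param covariate_sets Named list mapping metabolite names to covariate
#'   column vectors; see [default_covariate_sets()].
#' @param weighting `"inv_crlb2"` (default) or `"inv_crlb"`.
#' @return The input tibble with a `residual` column, plus attribute
#'   `coefficients`: a tibble of fitted coefficients per (region,
#'   metabolite).
#' @export
correct_concentrations <- function(records,
                                   covariate_sets = default_covariate_sets(),
                                   weighting = c("inv_crlb2", "inv_crlb")) {
  weighting <- match.arg(weighting)
  check_metabolite_records(records)
  records <- tibble::as_tibble(records)
  cells <- dplyr::group_split(dplyr::group_by(records, .data$region,
                                              .data$metabolite))
  fitted <- lapply(cells, function(cell) {
    met <- as.character(cell$metabolite[1])
    covs <- covariate_sets[[met]] %||% covariate_sets[["glutamate"]] %||%
      c("age", "sex", "f_gm", "f_wm")
    if (anyNA(cell[covs])) {
      rlang::abort(sprintf("missing covariate values in %s / %s",
                           cell$region[1], met))
    }
    if (nrow(cell) < length(covs) + 2) {
      rlang::abort(sprintf("too few records in %s / %s to fit %d covariates",
                           cell$region[1], met, length(covs)))
    }
    df <- cell
    if ("age" %in% covs) df$age <- df$age - mean(df$age)
    if ("sex" %in% covs) df$sex <- as.numeric(factor(df$sex)) - 1
    # constant covariates carry no information and would only break the
    # design; the fit then degrades gracefully to the weighted mean
    covs <- covs[vapply(covs, function(v) var(df[[v]]) > 0, logical(1))]
    if (length(covs) == 0) covs <- "1"
    w <- if (weighting == "inv_crlb2") 1 / df$crlb^2 else 1 / df$crlb
    form <- stats::as.formula(paste("concentration ~",
                                    paste(covs, collapse = " + ")))
    X <- stats::model.matrix(form, data = df)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      rlang::abort(paste0("rank-deficient design; collinear columns: ",
                          paste(bad, collapse = ", ")))
    }
    fit <- lm(form, data = df, weights = w)
    cell$residual <- as.numeric(residuals(fit))
    coefs <- tibble::tibble(region = cell$region[1], metabolite = met,
                            term = names(stats::coef(fit)),
                            estimate = as.numeric(stats::coef(fit)))
    list(cell = cell, coefs = coefs)
  })
  out <- dplyr::bind_rows(lapply(fitted, `[[`, "cell"))
  attr(out, "coefficients") <- dplyr::bind_rows(lapply(fitted, `[[`, "coefs"))
  out
}

#' Two-sided single-outlier Grubbs test
#'
#' Flags at most one observation: the point furthest from the mean in
#' standard-deviation units, if its statistic
#' `G = max |x - mean| / sd` exceeds the t-based critical value
#' `((n-1)/sqrt(n)) sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha / (2n), n - 2)`.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return Index of the flagged outlier, or `NA_integer_` if none (also
#'   when the values have zero variance).
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) rlang::abort("Grubbs test needs at least 3 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(NA_integer_)
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  tcrit <- qt(1 - alpha / (2 * n), n - 2)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  if (g > gcrit) which.max(dev) else NA_integer_
}

#' Region-by-diagnosis ANOVA on corrected metabolite levels
#'
#' Mixed two-way analysis of variance with region of interest as a
#' within-subject factor and diagnostic group as a between-subject factor,
#' followed by simple main effects of diagnosis within each region
#' (one-way F tests) and Tukey-adjusted pairwise group contrasts per
#' region. Participants lacking either region are dropped listwise (with a
#' message).
#'
#' @param corrected Output of [correct_concentrations()] (or any tibble
#'   with `participant_id`, `group`, `region`, `metabolite`, `residual`).
#' @param metabolite Which metabolite to analyse.
#' @return An object of class `mrs_anova`: list with `anova` (the
#'   within/between table), `simple_effects` (per-region F tests) and
#'   `tukey` (adjusted pairwise contrasts). `tidy()` returns the simple
#'   effects.
#' @export
group_region_anova <- function(corrected, metabolite) {
  dat <- dplyr::filter(corrected, .data$metabolite == !!metabolite)
  if (nrow(dat) == 0) rlang::abort("no rows for that metabolite")
  n_regions <- length(unique(dat$region))
  complete <- dat |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == n_regions)
  dropped <- setdiff(unique(dat$participant_id), complete$participant_id)
  if (length(dropped)) {
    rlang::inform(sprintf("dropping %d participant(s) without both regions",
                          length(dropped)))
    dat <- dplyr::filter(dat, !.data$participant_id %in% dropped)
  }
  tab <- table(dat$group, dat$region)
  if (any(tab == 0)) rlang::abort("a group is empty in at least one cell")
  dat <- dplyr::mutate(dat,
                       participant_id = factor(.data$participant_id),
                       group = factor(.data$group),
                       region = factor(.data$region))
  # do.call embeds the data in the call so that emmeans can recover it
  fit <- do.call(stats::aov, list(
    residual ~ group * region + Error(participant_id / region),
    data = as.data.frame(dat)))
  anova_tbl <- purrr::map_dfr(names(summary(fit)), function(stratum) {
    s <- summary(fit)[[stratum]][[1]]
    tibble::tibble(stratum = stratum, term = trimws(rownames(s)),
                   df = s$Df, sumsq = s$`Sum Sq`,
                   statistic = s$`F value`, p.value = s$`Pr(>F)`)
  })
  simple <- purrr::map_dfr(levels(dat$region), function(r) {
    sub <- dat[dat$region == r, ]
    a <- summary(aov(residual ~ group, data = sub))[[1]]
    tibble::tibble(region = r, metabolite = metabolite,
                   df1 = a$Df[1], df2 = a$Df[2],
                   statistic = a$`F value`[1], p.value = a$`Pr(>F)`[1])
  })
  tukey <- NULL
  if (requireNamespace("emmeans", quietly = TRUE)) {
    em <- emmeans::emmeans(fit, ~ group | region, data = as.data.frame(dat))
    tukey <- tibble::as_tibble(summary(emmeans::contrast(
      em, method = "pairwise", adjust = "tukey")))
  }
  structure(list(metabolite = metabolite, anova = anova_tbl,
                 simple_effects = simple, tukey = tukey,
                 dropped = dropped),
            class = "mrs_anova")
}

#' @export
tidy.mrs_anova <- function(x, ...) x$simple_effects

#' @export
glance.mrs_anova <- function(x, ...) {
  ge <- x$anova[x$anova$term == "group" & !is.na(x$anova$statistic), ]
  tibble::tibble(metabolite = x$metabolite,
                 group_F = ge$statistic[1], group_p = ge$p.value[1],
                 n_dropped = length(x$dropped))
}

#' @export
print.mrs_anova <- function(x, ...) {
  cat("Region-by-diagnosis ANOVA:", x$metabolite, "\n\nSimple main effects of group:\n")
  print(as.data.frame(x$simple_effects), row.names = FALSE)
  invisible(x)
}
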