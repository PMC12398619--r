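#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

stat_row <- function(test, statistic, df, p_value, effect_direction = NA,
                     ci_low = NA_real_, ci_high = NA_real_,
                     df2 = NA_real_) {
  tibble::tibble(test = test, statistic = statistic, df = df, df2 = df2,
                 p_value = p_value,
                 effect_direction = effect_direction,
                 ci_low = ci_low, ci_high = ci_high)
}

pull_groups <- function(data, value, group, n_levels = NULL) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (!is.null(n_levels) && nlevels(g) != n_levels)
    stop("expected ", n_levels, " groups, found ", nlevels(g))
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  list(v = v, g = g)
}

#' Independent-samples t test
#'
#' @param data data frame with one row per subject.
#' @param value unquoted column of the continuous outcome.
#' @param group unquoted column with exactly two levels.
#' @param variant `"pooled"` (classical) or `"welch"`.
#' @param alternative passed to [stats::t.test()].
#' @return one-row tibble (`test`, `statistic`, `df`, `p_value`,
#'   `effect_direction`, confidence bounds).
#' @export
two_sample_t <- function(data, value, group, variant = c("pooled", "welch"),
                         alternative = "two.sided") {
  variant <- match.arg(variant)
  gv <- pull_groups(data, {{ value }}, {{ group }}, n_levels = 2)
  sds <- tapply(gv$v, gv$g, stats::sd)
  if (all(sds == 0) && diff(tapply(gv$v, gv$g, mean)) == 0) {
    # identical constant samples: no evidence of any difference
    return(stat_row("t", 0, length(gv$v) - 2, 1, "none"))
  }
  if (all(sds == 0)) stop("degenerate (zero-variance) samples")
  tt <- stats::t.test(gv$v ~ gv$g, var.equal = variant == "pooled",
                      alternative = alternative)
  means <- tapply(gv$v, gv$g, mean)
  dir <- paste(levels(gv$g)[order(means, decreasing = TRUE)],
               collapse = " > ")
  if (means[1] == means[2]) dir <- "none"
  stat_row("t", unname(tt$statistic), unname(tt$parameter), tt$p.value,
           dir, tt$conf.int[1], tt$conf.int[2])
}

#' One-way ANOVA with Tukey HSD post hoc tests
#'
#' Classical fixed-effects ANOVA; pairwise comparisons are reported both
#' Tukey-corrected (studentized-range distribution) and uncorrected
#' (pooled-SD t tests), mirroring the convention of reporting both.
#'
#' @inheritParams two_sample_t
#' @return list with `omnibus` (one-row tibble: F, df pair, p) and
#'   `pairwise` (tibble: contrast, difference, Tukey-adjusted and
#'   unadjusted p).
#' @export
oneway_anova_tukey <- function(data, value, group) {
  gv <- pull_groups(data, {{ value }}, {{ group }})
  if (nlevels(gv$g) < 2) stop("need at least 2 groups")
  fit <- stats::aov(v ~ g, data = data.frame(v = gv$v, g = gv$g))
  s <- summary(fit)[[1]]
  om <- stat_row("F", s[1, "F value"], s[1, "Df"], s[1, "Pr(>F)"],
                 df2 = s[2, "Df"])
  if (all(tapply(gv$v, gv$g, stats::sd) == 0) &&
      length(unique(tapply(gv$v, gv$g, mean))) == 1)
    om <- stat_row("F", 0, s[1, "Df"], 1, df2 = s[2, "Df"])
  tk <- stats::TukeyHSD(fit)$g
  un <- stats::pairwise.t.test(gv$v, gv$g, p.adjust.method = "none",
                               pool.sd = TRUE)$p.value
  pw <- tibble::tibble(
    contrast = rownames(tk),
    difference = tk[, "diff"],
    ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
    p_tukey = tk[, "p adj"],
    p_unadjusted = vapply(rownames(tk), function(cn) {
      ab <- strsplit(cn, "-", fixed = TRUE)[[1]]
      p <- tryCatch(un[ab[1], ab[2]], error = function(e) NA_real_)
      if (is.na(p)) p <- tryCatch(un[ab[2], ab[1]],
                                  error = function(e) NA_real_)
      p
    }, 0))
  list(omnibus = om, pairwise = pw)
}

#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' @inheritParams two_sample_t
#' @return one-row tibble with the Welch F statistic and
#'   Welch–Satterthwaite degrees of freedom.
#' @export
welch_anova <- function(data, value, group) {
  gv <- pull_groups(data, {{ value }}, {{ group }})
  if (all(tapply(gv$v, gv$g, stats::sd) == 0) &&
      length(unique(tapply(gv$v, gv$g, mean))) == 1)
    return(stat_row("F_welch", 0, nlevels(gv$g) - 1, 1, df2 = Inf))
  wt <- stats::oneway.test(v ~ g, data = data.frame(v = gv$v, g = gv$g),
                           var.equal = FALSE)
  stat_row("F_welch", unname(wt$statistic), unname(wt$parameter[1]),
           wt$p.value, df2 = unname(wt$parameter[2]))
}

#' Brown–Forsythe/Levene test of homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group medians; used as the
#' trigger for falling back from classical to Welch's ANOVA.
#'
#' @inheritParams two_sample_t
#' @return one-row tibble.
#' @export
levene_test <- function(data, value, group) {
  gv <- pull_groups(data, {{ value }}, {{ group }})
  med <- tapply(gv$v, gv$g, stats::median)
  z <- abs(gv$v - med[gv$g])
  if (stats::sd(z) == 0)
    return(stat_row("levene", 0, nlevels(gv$g) - 1, 1,
                    df2 = length(z) - nlevels(gv$g)))
  fit <- summary(stats::aov(z ~ g, data = data.frame(z = z, g = gv$g)))[[1]]
  stat_row("levene", fit[1, "F value"], fit[1, "Df"], fit[1, "Pr(>F)"],
           df2 = fit[2, "Df"])
}

#' One-way comparison with automatic Welch fallback
#'
#' Runs [levene_test()]; when its p-value falls below `trigger` the Welch
#' ANOVA is reported, otherwise the classical ANOVA (with Tukey HSD).
#'
#' @inheritParams two_sample_t
#' @param trigger Levene p-value below which Welch's ANOVA is used.
#' @param force_welch always use Welch's ANOVA.
#' @return as [oneway_anova_tukey()], with an extra `variant` element.
#' @export
oneway_anova_auto <- function(data, value, group, trigger = 0.05,
                              force_welch = FALSE) {
  lev <- levene_test(data, {{ value }}, {{ group }})
  if (force_welch || (!is.na(lev$p_value) && lev$p_value < trigger)) {
    res <- oneway_anova_tukey(data, {{ value }}, {{ group }})
    res$omnibus <- welch_anova(data, {{ value }}, {{ group }})
    res$variant <- "welch"
  } else {
    res <- oneway_anova_tukey(data, {{ value }}, {{ group }})
    res$variant <- "classical"
  }
  res$levene <- lev
  res
}

#' Pearson chi-square test on a contingency table
#'
#' `chi2 = sum (O - E)^2 / E` with expectations from the margins and no
#' continuity correction, as used for the cohort's demographic tables.
#'
#' @param table matrix of nonnegative integer counts.
#' @return one-row tibble with the chi-square statistic and
#'   `(r - 1)(c - 1)` degrees of freedom.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stat_row("chi_square", unname(ct$statistic), unname(ct$parameter),
           ct$p.value)
}

#' Wilcoxon rank test
#'
#' Rank-sum (Mann–Whitney) for independent groups; the signed-rank variant
#' is available for genuinely paired designs via `paired = TRUE`.
#'
#' @inheritParams two_sample_t
#' @param paired use the signed-rank test on paired observations.
#' @return one-row tibble.
#' @export
wilcoxon_rank <- function(data, value, group, paired = FALSE) {
  gv <- pull_groups(data, {{ value }}, {{ group }}, n_levels = 2)
  if (length(unique(gv$v)) == 1) stop("all observations are tied")
  wt <- suppressWarnings(
    stats::wilcox.test(gv$v ~ gv$g, paired = paired))
  med <- tapply(gv$v, gv$g, stats::median)
  dir <- if (med[1] == med[2]) "none" else
    paste(levels(gv$g)[order(med, decreasing = TRUE)], collapse = " > ")
  stat_row(if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum",
           unname(wt$statistic), NA_real_, wt$p.value, dir)
}

# model matrix rank check shared by the model fitters
check_full_rank <- function(mm) {
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
}

#' Linear mixed-effects model with random subject intercept
#'
#' Fits `outcome ~ fixed effects + (1 | subject)` by REML and reports
#' Wald-z coefficient tables (estimate, SE, z, p, 95% CI) plus the
#' random-intercept variance. With exactly one observation per subject the
#' random intercept is not identifiable; the fit is flagged and an ordinary
#' least-squares fit of the same fixed effects is reported alongside.
#'
#' @param data data frame (e.g. an SCS table joined with covariates).
#' @param outcome outcome column name (string).
#' @param fixed character vector of fixed-effect column names.
#' @param group subject-identifier column name.
#' @return object of class `tep_mixed_fit`; see [tidy.tep_mixed_fit()].
#' @export
mixed_model <- function(data, outcome, fixed, group = "subject_id") {
  stopifnot(is.character(outcome), is.character(fixed), length(fixed) >= 1)
  data <- as.data.frame(data)
  if (nrow(data) < 10) stop("need at least 10 observations")
  for (f in fixed) {
    if (!f %in% names(data)) stop("missing fixed-effect column: ", f)
    if (!is.numeric(data[[f]]) && length(unique(data[[f]])) < 2)
      stop("constant fixed term: ", f)
  }
  ff <- stats::as.formula(paste(outcome, "~",
                                paste(fixed, collapse = " + ")))
  mm <- stats::model.matrix(ff, data)
  check_full_rank(mm)
  one_per_subject <- !anyDuplicated(data[[group]])
  fml <- stats::as.formula(paste(outcome, "~", paste(fixed, collapse = " + "),
                                 "+ (1 |", group, ")"))
  # with one observation per subject the residual/intercept split is not
  # identifiable; the nobs-vs-levels check is relaxed so the REML fit is
  # still reported (flagged), alongside an OLS fit of the fixed effects
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.conv.singular = lme4::.makeCC(
                              action = "ignore", tol = 1e-4))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(fml, data = data, REML = TRUE, control = ctrl))),
    error = function(e) NULL)
  mk_tab <- function(co) {
    z <- co[, "Estimate"] / co[, "Std. Error"]
    tibble::tibble(
      term = rownames(co),
      estimate = co[, "Estimate"], std_error = co[, "Std. Error"],
      z = z, p_value = 2 * stats::pnorm(-abs(z)),
      ci_low = co[, "Estimate"] - stats::qnorm(0.975) * co[, "Std. Error"],
      ci_high = co[, "Estimate"] + stats::qnorm(0.975) * co[, "Std. Error"])
  }
  lfit <- stats::lm(ff, data = data)
  # summary.lm warns on an essentially perfect (noiseless) fit
  ols <- mk_tab(suppressWarnings(stats::coef(summary(lfit))))
  if (!is.null(fit)) {
    terms <- mk_tab(stats::coef(summary(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_var <- vc$vcov[vc$grp == group][1]
  } else {
    terms <- ols
    re_var <- NA_real_
  }
  structure(list(terms = terms, random_effect_variance = re_var,
                 random_effect_identifiable = !one_per_subject,
                 ols_fallback = if (one_per_subject) ols else NULL,
                 n_obs = nrow(data),
                 outcome = outcome, fit = if (is.null(fit)) lfit else fit),
            class = "tep_mixed_fit")
}

#' @export
print.tep_mixed_fit <- function(x, ...) {
  cat("<tep_mixed_fit>", x$outcome, "~ ...,", x$n_obs, "obs; group var =",
      signif(x$random_effect_variance, 4),
      if (!x$random_effect_identifiable)
        "(one obs/subject: not identifiable, OLS fallback reported)", "\n")
  print(x$terms)
  invisible(x)
}

#' @rdname mixed_model
#' @param x,object a `tep_mixed_fit`.
#' @param ... unused.
#' @export
tidy.tep_mixed_fit <- function(x, ...) x$terms

#' @rdname mixed_model
#' @export
glance.tep_mixed_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs,
                 random_effect_variance = x$random_effect_variance,
                 random_effect_identifiable = x$random_effect_identifiable)
}

#' Logistic regression for the presence of suicidal ideation
#'
#' Maximum-likelihood logistic fit of SI-vs-NSI group membership on the
#' given predictors (e.g. SCS values, controlling for age). Complete or
#' quasi-complete separation is detected and flagged in the result rather
#' than raising an error.
#'
#' @param data data frame containing an SI/NSI `group` column and the
#'   predictors.
#' @param predictors character vector of predictor column names.
#' @param outcome name of the group column (levels must include `"SI"`;
#'   `SI` is coded 1).
#' @return object of class `tep_logistic_fit` with a `terms` tibble
#'   (coefficients, odds ratios, Wald CIs), `separation` flag; has
#'   [tidy()]/[glance()] methods.
#' @export
si_logistic <- function(data, predictors, outcome = "group") {
  data <- as.data.frame(data)
  y <- data[[outcome]]
  keep <- y %in% c("SI", "NSI")
  data <- data[keep, , drop = FALSE]
  data$.si <- as.integer(data[[outcome]] == "SI")
  if (length(unique(data$.si)) < 2)
    stop("need both SI and NSI rows")
  ff <- stats::as.formula(paste(".si ~", paste(predictors, collapse = " + ")))
  mm <- stats::model.matrix(ff, data)
  check_full_rank(mm)
  sep <- FALSE
  withCallingHandlers(
    fit <- stats::glm(ff, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || any(abs(stats::coef(fit)) > 15)) sep <- TRUE
  co <- stats::coef(summary(fit))
  terms <- tibble::tibble(
    term = rownames(co), estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"], z = co[, "z value"],
    p_value = co[, "Pr(>|z|)"],
    odds_ratio = exp(co[, "Estimate"]),
    ci_low = co[, "Estimate"] - stats::qnorm(0.975) * co[, "Std. Error"],
    ci_high = co[, "Estimate"] + stats::qnorm(0.975) * co[, "Std. Error"])
  structure(list(terms = terms, separation = sep, n_obs = nrow(data),
                 fit = fit),
            class = "tep_logistic_fit")
}

#' @export
print.tep_logistic_fit <- function(x, ...) {
  cat("<tep_logistic_fit>", x$n_obs, "obs",
      if (x$separation) "(separation detected: estimates unreliable)", "\n")
  print(x$terms)
  invisible(x)
}

#' @rdname si_logistic
#' @param x,object a `tep_logistic_fit`.
#' @param ... unused.
#' @export
tidy.tep_logistic_fit <- function(x, ...) x$terms

#' @rdname si_logistic
#' @export
glance.tep_logistic_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, separation = x$separation,
                 deviance = x$fit$deviance, aic = stats::AIC(x$fit))
}
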