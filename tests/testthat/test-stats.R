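test_that("t test matches the textbook formula and handles edge cases", {
  x <- c(1, 2, 3, 4); y <- c(3, 5, 7)
  d <- data.frame(v = c(x, y), g = rep(c("a", "b"), c(4, 3)))
  res <- two_sample_t(d, v, g, variant = "pooled")
  # brute-force pooled statistic
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_brute <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res$statistic, t_brute, tolerance = 1e-12)
  expect_equal(res$df, length(x) + length(y) - 2)
  expect_equal(res$effect_direction, "b > a")

  ident <- data.frame(v = rep(c(1, 1, 1), 2), g = rep(c("a", "b"), 3))
  r2 <- two_sample_t(ident, v, g)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  # clearly separated normal samples at large n
  set.seed(1)
  big <- data.frame(v = c(rnorm(200), rnorm(200, 1)),
                    g = rep(c("a", "b"), each = 200))
  expect_lt(two_sample_t(big, v, g)$p_value, 1e-3)
})

test_that("ANOVA matches brute-force sums of squares; F equals t^2", {
  g1 <- c(6, 8, 4, 5, 3, 4); g2 <- c(8, 12, 9, 11, 6, 8)
  g3 <- c(13, 9, 11, 8, 7, 12)
  d <- data.frame(v = c(g1, g2, g3),
                  g = rep(c("a", "b", "c"), each = 6))
  res <- oneway_anova_tukey(d, v, g)
  # brute force
  gm <- mean(d$v)
  ssb <- 6 * sum((tapply(d$v, d$g, mean) - gm)^2)
  ssw <- sum((d$v - ave(d$v, d$g))^2)
  f_brute <- (ssb / 2) / (ssw / 15)
  expect_equal(res$omnibus$statistic, f_brute, tolerance = 1e-12)
  expect_equal(res$omnibus$df, 2)
  expect_equal(res$omnibus$df2, 15)

  # Tukey-adjusted p never below the unadjusted pairwise p
  expect_true(all(res$pairwise$p_tukey >= res$pairwise$p_unadjusted - 1e-12))

  # two groups: F = pooled t^2
  d2 <- d[d$g != "c", ]
  f2 <- oneway_anova_tukey(d2, v, g)$omnibus
  t2 <- two_sample_t(d2, v, g, variant = "pooled")
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p_value, t2$p_value, tolerance = 1e-10)

  # degenerate identical groups
  same <- data.frame(v = rep(2, 9), g = rep(c("a", "b", "c"), 3))
  r0 <- oneway_anova_tukey(same, v, g)$omnibus
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("Welch ANOVA agrees with the classical test under homoscedasticity
           and with its defining formula under heteroscedasticity", {
  set.seed(2)
  # groups standardized to exactly equal sample variance: the Welch and
  # classical statistics then agree to two decimals
  gvals <- lapply(c(0, 0.15, 0.3), function(m) m + scale(rnorm(100))[, 1])
  d <- data.frame(v = unlist(gvals), g = rep(c("a", "b", "c"), each = 100))
  w <- welch_anova(d, v, g)
  cl <- oneway_anova_tukey(d, v, g)$omnibus
  expect_lt(abs(w$statistic - cl$statistic), 0.01)

  # independent implementation of the Welch statistic
  het <- data.frame(v = c(rnorm(10, 0, 1), rnorm(15, 1, 4), rnorm(12, 2, 8)),
                    g = rep(c("a", "b", "c"), c(10, 15, 12)))
  ni <- tapply(het$v, het$g, length)
  mi <- tapply(het$v, het$g, mean)
  vi <- tapply(het$v, het$g, var)
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  k <- 3
  num <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - wi / sum(wi))^2 / (ni - 1)) / (k^2 - 1)
  f_welch <- num / (1 + 2 * lam * (k - 2))
  df2 <- 1 / (3 * lam)
  res <- welch_anova(het, v, g)
  expect_equal(res$statistic, f_welch, tolerance = 1e-10)
  expect_equal(res$df2, df2, tolerance = 1e-10)

  same <- data.frame(v = rep(1, 9), g = rep(c("a", "b", "c"), 3))
  expect_equal(welch_anova(same, v, g)$p_value, 1)
})

test_that("the Welch fallback triggers on heteroscedasticity", {
  set.seed(3)
  het <- data.frame(v = c(rnorm(40, 0, 1), rnorm(40, 0, 6)),
                    g = rep(c("a", "b"), each = 40))
  res <- oneway_anova_auto(het, v, g)
  expect_equal(res$variant, "welch")
  set.seed(8)
  hom <- data.frame(v = rnorm(160), g = rep(c("a", "b"), each = 80))
  expect_equal(oneway_anova_auto(hom, v, g)$variant, "classical")
})

test_that("chi-square reproduces the cohort's demographic statistics", {
  # gender split of the two clinical groups
  gender <- matrix(c(31, 61, 27, 47), 2,
                   dimnames = list(c("male", "female"), c("NSI", "SI")))
  res <- pearson_chi_square(gender)
  expect_lt(abs(res$statistic - 0.14), 0.005)
  expect_equal(res$df, 1)
  expect_gt(res$p_value, 0.7)

  # antidepressant type (4 x 2)
  ad <- matrix(c(60, 7, 16, 9, 48, 7, 12, 7), 4)
  res2 <- pearson_chi_square(ad)
  expect_lt(abs(res2$statistic - 0.21), 0.005)
  expect_equal(res2$df, 3)

  # proportional rows are exactly independent
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(pearson_chi_square(prop)$statistic, 0, tolerance = 1e-12)

  expect_error(pearson_chi_square(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(pearson_chi_square(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("2x2 chi-square equals the squared two-proportion z statistic", {
  for (s in 1:5) {
    set.seed(s)
    tab <- matrix(rpois(4, 30) + 1, 2)
    chi <- pearson_chi_square(tab)$statistic
    n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
    p1 <- tab[1, 1] / n1; p2 <- tab[1, 2] / n2
    pp <- (tab[1, 1] + tab[1, 2]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(chi, z^2, tolerance = 1e-10)
  }
})

test_that("rank-sum test matches exhaustive enumeration on a small sample", {
  x <- c(1.2, 3.1, 4.5, 6.2); y <- c(2.0, 5.1, 7.3)
  d <- data.frame(v = c(x, y), g = rep(c("a", "b"), c(4, 3)))
  res <- wilcoxon_rank(d, v, g)
  # enumerate all assignments of ranks to group a
  ranks <- rank(d$v)
  w_obs <- sum(ranks[d$g == "a"]) - 4 * 5 / 2   # Mann-Whitney U of group a
  combs <- utils::combn(7, 4)
  w_all <- apply(combs, 2, function(i) sum(ranks[i])) - 10
  p_exact <- mean(abs(w_all - 6) >= abs(w_obs - 6))  # center = n1*n2/2 = 6
  expect_equal(res$p_value, p_exact, tolerance = 1e-10)

  # fully separated samples reach the minimal attainable p
  sep <- data.frame(v = c(1, 2, 3, 4, 11, 12, 13), g = rep(c("a", "b"),
                                                           c(4, 3)))
  expect_equal(wilcoxon_rank(sep, v, g)$p_value, 2 / choose(7, 4),
               tolerance = 1e-10)

  tied <- data.frame(v = rep(1, 8), g = rep(c("a", "b"), 4))
  expect_error(wilcoxon_rank(tied, v, g), "tied")
})

test_that("mixed model recovers noiseless and simulated coefficients", {
  # noiseless linear outcome: exact interpolation
  set.seed(4)
  n <- 40
  d <- data.frame(subject_id = sprintf("s%02d", 1:n),
                  x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 2 + 1.5 * d$x1 - 0.7 * d$x2
  fit <- mixed_model(d, "y", c("x1", "x2"))
  expect_false(fit$random_effect_identifiable)
  expect_false(is.null(fit$ols_fallback))
  est <- fit$ols_fallback$estimate
  expect_equal(unname(est), c(2, 1.5, -0.7), tolerance = 1e-8)

  # simulated cohort-sized fit: estimates within 2 SE of truth
  set.seed(5)
  n <- 166
  d2 <- data.frame(subject_id = sprintf("s%03d", 1:n),
                   group_si = rbinom(n, 1, 0.45),
                   age = rnorm(n, 30, 10), hamd = rnorm(n, 25, 5))
  d2$y <- -0.8 - 1.4 * d2$group_si - 0.02 * d2$age + 0.004 * d2$hamd +
    rnorm(n, 0, 2)
  fit2 <- mixed_model(d2, "y", c("group_si", "age", "hamd"))
  tab <- fit2$ols_fallback
  truth <- c(-0.8, -1.4, -0.02, 0.004)
  expect_true(all(abs(tab$estimate - truth) <= 2 * tab$std_error))

  # repeated observations identify the random intercept
  d3 <- do.call(rbind, replicate(4, d2[1:40, ], simplify = FALSE))
  d3$y <- d3$y + rnorm(nrow(d3), rep(rnorm(40, 0, 3), 4), 0.5)
  fit3 <- mixed_model(d3, "y", c("group_si", "age"))
  expect_true(fit3$random_effect_identifiable)
  expect_gt(fit3$random_effect_variance, 0.5)
  expect_s3_class(tidy(fit3), "tbl_df")
  expect_equal(glance(fit3)$n_obs, 160)

  # collinear designs are rejected with the offending term
  d2$age2 <- d2$age
  expect_error(mixed_model(d2, "y", c("age", "age2")), "age2")
  expect_error(mixed_model(d2[1:5, ], "y", "age"), "10 observations")
})

test_that("logistic regression recovers a known slope and flags separation", {
  set.seed(6)
  n <- 300
  scs <- rnorm(n, 100, 30)
  age <- rnorm(n, 30, 10)
  lp <- -2 + 0.02 * scs - 0.01 * age
  si <- rbinom(n, 1, plogis(lp))
  d <- data.frame(group = ifelse(si == 1, "SI", "NSI"), scs = scs,
                  age = age)
  fit <- si_logistic(d, c("scs", "age"))
  expect_false(fit$separation)
  row <- fit$terms[fit$terms$term == "scs", ]
  expect_lt(abs(row$estimate - 0.02), 2 * row$std_error)
  expect_equal(row$odds_ratio, exp(row$estimate))

  # perfect separation is flagged, not an error
  d2 <- data.frame(group = rep(c("SI", "NSI"), each = 20),
                   x = c(rnorm(20, 10), rnorm(20, -10)))
  fit2 <- si_logistic(d2, "x")
  expect_true(fit2$separation)

  d3 <- data.frame(group = rep(c("SI", "NSI"), each = 10), x = 1)
  expect_error(si_logistic(d3, "x"), "rank|collinear")
})

test_that("coefficient CIs achieve nominal coverage for a null predictor", {
  set.seed(7)
  cover <- replicate(200, {
    n <- 120
    d <- data.frame(group = sample(rep(c("SI", "NSI"), each = n / 2)),
                    x = rnorm(n))
    fit <- si_logistic(d, "x")
    row <- fit$terms[fit$terms$term == "x", ]
    row$ci_low <= 0 && 0 <= row$ci_high
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})
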