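test_that("repeatability hits the degenerate and boundary cases", {
  # identical values within individuals, individuals differ -> R = 1
  d <- data.frame(id = rep(letters[1:5], each = 2), y = rep(c(3, 9, 1, 5, 7), each = 2))
  r1 <- repeatability(d$y, d$id, n_boot = 50, seed = 1)
  expect_equal(r1$R, 1, tolerance = 1e-6)
  expect_lt(r1$p_value, 0.01)
  # i.i.d. values -> R near 0 (boundary allowed)
  set.seed(2)
  d2 <- data.frame(id = rep(letters[1:20], each = 2), y = rnorm(40))
  r2 <- repeatability(d2$y, d2$id, n_boot = 50, seed = 1)
  expect_lt(r2$R, 0.25)
  expect_error(repeatability(1:5, rep("a", 5)), "2 individuals")
  expect_error(repeatability(rep(1, 6), rep(letters[1:3], 2)), "zero total variance")
  # deterministic given seed
  r3 <- repeatability(d2$y, d2$id, n_boot = 100, seed = 7)
  r4 <- repeatability(d2$y, d2$id, n_boot = 100, seed = 7)
  expect_identical(r3$ci_low, r4$ci_low)
})

test_that("REML estimate equals the balanced ANOVA ICC and the lme4 fit", {
  d <- sim_icc_data(76, 2, 100, 2, 1, seed = 11)
  r <- repeatability(d$y, d$id, n_boot = 20, seed = 1)
  expect_equal(r$R, oracle_anova_icc(d$y, d$id), tolerance = 1e-6)
  expect_equal(r$R, r$var_among / (r$var_among + r$var_residual), tolerance = 1e-9)
  # independent mixed-model route (lme4, REML) on balanced and unbalanced data
  fit <- lme4::lmer(y ~ 1 + (1 | id), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(r$var_among, vc$vcov[1], tolerance = 1e-5)
  expect_equal(r$var_residual, vc$vcov[2], tolerance = 1e-5)
  d2 <- sim_icc_data(40, 3, 50, 3, 2, seed = 12)[-c(1, 5, 20), ]
  r2 <- repeatability(d2$y, d2$id, n_boot = 20, seed = 1)
  fit2 <- lme4::lmer(y ~ 1 + (1 | id), data = d2, REML = TRUE)
  vc2 <- as.data.frame(lme4::VarCorr(fit2))
  expect_equal(r2$var_among / (r2$var_among + r2$var_residual),
               vc2$vcov[1] / sum(vc2$vcov), tolerance = 1e-5)
})

test_that("GLM fits match a direct maximum-likelihood oracle", {
  set.seed(21)
  n <- 300
  d <- data.frame(same = rbinom(n, 1, 0.3), diff = runif(n, 0, 150))
  mu <- 1800 - 1200 * d$same + 2 * d$diff
  d$emd <- rgamma(n, shape = 5, rate = 5 / mu)
  f1 <- fit_glm(d, emd ~ same + diff, "gamma", "identity")
  b1 <- oracle_glm_ml(emd ~ same + diff, d, "gamma", "identity")
  expect_equal(unname(f1$coefficients$estimate), unname(b1), tolerance = 1e-6)
  d$rng <- rgamma(n, shape = 4, rate = 4 / exp(2 + 0.8 * d$same))
  f2 <- fit_glm(d, rng ~ same, "gamma", "log")
  b2 <- oracle_glm_ml(rng ~ same, d, "gamma", "log")
  expect_equal(unname(f2$coefficients$estimate), unname(b2), tolerance = 1e-6)
  d$ba <- plogis(rnorm(n, -1 + 0.8 * d$same, 0.5))
  f3 <- fit_glm(d, ba ~ same + diff, "binomial", "log")
  b3 <- oracle_glm_ml(ba ~ same + diff, d, "binomial", "log")
  expect_equal(unname(f3$coefficients$estimate), unname(b3), tolerance = 1e-4)
  # gaussian identity on exact linear data -> zero residual deviance
  d$lin <- 1 + 2 * d$diff
  f4 <- fit_glm(d, lin ~ diff, "gaussian", "identity")
  expect_equal(f4$deviance, 0, tolerance = 1e-16)
  expect_error(fit_glm(within(d, emd <- emd - 3000), emd ~ diff, "gamma", "identity"),
               "positive")
})

test_that("simulated whole-migration comparisons recover their coefficients", {
  set.seed(22)
  n <- 600
  d <- data.frame(same = rbinom(n, 1, 0.2), diff = runif(n, 0, 160))
  mu <- 1862.17 - 1287.08 * d$same + 2.15 * d$diff
  d$emd <- rgamma(n, shape = 8, rate = 8 / mu)
  f <- fit_glm(d, emd ~ same + diff, "gamma", "identity")
  ct <- f$coefficients
  expect_lt(abs(ct["same", "estimate"] - (-1287.08)) / ct["same", "se"], 3)
  expect_lt(abs(ct["diff", "estimate"] - 2.15) / ct["diff", "se"], 3)
  expect_lt(abs(ct["(Intercept)", "estimate"] - 1862.17) / ct["(Intercept)", "se"], 3)
})

test_that("backwards stepwise respects marginality and drops null interactions", {
  set.seed(23)
  n <- 500
  d <- data.frame(same = rbinom(n, 1, 0.3), diff = runif(n, 0, 150))
  mu <- 1800 - 1000 * d$same + 2 * d$diff   # no interaction in truth
  d$emd <- rgamma(n, shape = 6, rate = 6 / mu)
  full <- fit_glm(d, emd ~ same * diff, "gamma", "identity")
  mam <- stepwise_backward(full)
  trms <- attr(terms(mam$formula), "term.labels")
  expect_false("same:diff" %in% trms)
  expect_true(all(c("same", "diff") %in% trms))   # mains kept (strong effects)
  log_ <- attr(mam, "deletion_log")
  expect_equal(log_$term, "same:diff")
  # all-significant model is unchanged
  mam2 <- stepwise_backward(fit_glm(d, emd ~ same + diff, "gamma", "identity"))
  expect_equal(attr(terms(mam2$formula), "term.labels"), c("same", "diff"))
  # marginality: a main effect is never a candidate while its interaction remains
  d$noise <- rnorm(n)
  f3 <- fit_glm(d, emd ~ same * diff + noise, "gamma", "identity")
  d1 <- gadfly:::.drop_table(f3)
  expect_false("same" %in% d1$term)
  expect_true(all(c("same:diff", "noise") %in% d1$term))
})

test_that("Tukey-adjusted marginal-mean contrasts behave as advertised", {
  set.seed(24)
  n <- 420
  d <- data.frame(stage = factor(rep(c("whole", paste0("s", 1:6)), each = 60)),
                  diff = runif(n, 0, 120))
  mu <- 500 + 300 * (d$stage != "whole") + 30 * as.integer(d$stage) + 2 * d$diff
  d$emd <- rgamma(n, shape = 6, rate = 6 / mu)
  f <- fit_glm(d, emd ~ stage + diff, "gamma", "identity")
  em <- emmeans_tukey(f, "stage", at = list(diff = 50))
  expect_equal(nrow(em$contrasts), choose(7, 2))  # 21 pairwise contrasts
  expect_true(all(em$contrasts$p_tukey >= em$contrasts$p_raw - 1e-12))
  # two-level factor: adjusted p equals the raw p
  d$grp <- factor(rep(c("a", "b"), n / 2))
  f2 <- fit_glm(d, emd ~ grp + diff, "gamma", "identity")
  em2 <- emmeans_tukey(f2, "grp")
  expect_equal(em2$contrasts$p_tukey, em2$contrasts$p_raw, tolerance = 1e-7)
  expect_error(emmeans_tukey(f2, "nope"), "not in model")
})

test_that("seasonal variability contrasts winter against summer departures", {
  set.seed(25)
  mk_phen <- function(n, season_sd, months) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      m <- sample(months, 1)
      base <- as.Date(sprintf("2016-%02d-15", m))
      data.frame(individual = sprintf("%s%03d", months[1], i),
                 departure_date = base + round(rnorm(2, 0, season_sd)),
                 arrival_date = base + 175 + round(rnorm(2, 0, 5)))
    }))
  }
  phen <- rbind(mk_phen(17, 25, c(6, 7, 8)),    # winter departers, high spread
                mk_phen(39, 8, c(11, 12, 1)))   # summer departers, low spread
  sv <- seasonal_variability(phen)
  expect_s3_class(sv$departure, "gadfly_glm")
  ct <- sv$departure$coefficients
  wrow <- grep("winter", rownames(ct))
  expect_gt(ct$estimate[wrow], 0)              # winter more variable
  expect_lt(ct$p[wrow], 0.05)
  # zero ranges are replaced by half a day (gamma support)
  phen0 <- data.frame(individual = rep(c("a", "b", "c", "d"), each = 2),
                      departure_date = rep(as.Date(c("2016-07-01", "2016-07-10",
                                                     "2016-12-01", "2016-12-20")), each = 2),
                      arrival_date = rep(as.Date("2017-01-05"), 8))
  sv0 <- seasonal_variability(phen0)
  expect_true(all(sv0$ranges$departure$range_days == 0.5))
})

test_that("the range correlation reproduces the published r/t relationship", {
  expect_equal(pearson_range_correlation(1:10, 2 * (1:10))$r, 1)
  # t = 6.38 on df = 60 corresponds to r that prints as 0.64
  r_implied <- 6.38 / sqrt(60 + 6.38^2)
  expect_equal(round(r_implied, 2), 0.64)
  set.seed(26)
  x <- rnorm(62); y <- r_implied * x + sqrt(1 - r_implied^2) * rnorm(62)
  out <- pearson_range_correlation(x, y)
  expect_equal(out$df, 60)
  expect_equal(out$t, out$r * sqrt(60 / (1 - out$r^2)), tolerance = 1e-12)
  # null simulation: p roughly uniform
  set.seed(27)
  ps <- replicate(200, pearson_range_correlation(rnorm(20), rnorm(20))$p)
  expect_gt(mean(ps > 0.5), 0.35); expect_lt(mean(ps > 0.5), 0.65)
  expect_error(pearson_range_correlation(1:2, 1:2), "at least 3")
})
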