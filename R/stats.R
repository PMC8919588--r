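## Statistical layer: repeatability (one-way random-intercept mixed model,
## REML, parametric bootstrap CI, LRT p), the GLM suite (gamma/identity,
## gamma/log, binomial/log) with backwards stepwise deletion and
## Tukey-adjusted marginal-mean contrasts, seasonal-variability models and
## the date-range correlation.

## Profiled REML / ML criteria for y_ij = mu + a_i + e_ij, a_i ~ N(0, la*s2),
## returning -2 log-likelihood up to a constant. Direct 1-D optimisation is
## exact for this model and ~1000x faster than a generic mixed-model fit,
## which is what makes 1000-iteration bootstraps and coverage simulations
## cheap; lme4 serves as the independent cross-check in the tests.
.icc_crit <- function(loglambda, y, gid, reml = TRUE) {
  la <- exp(loglambda)
  S <- rowsum(y, gid); n_i <- as.numeric(table(gid)[rownames(S)])
  h <- 1 / (1 + n_i * la)
  mu <- sum(S * h) / sum(n_i * h)
  ss <- rowsum((y - mu)^2, gid)
  q <- sum(ss) - la * sum(h * (S - n_i * mu)^2)
  N <- length(y)
  if (reml) {
    s2 <- q / (N - 1)
    (N - 1) * log(s2) + sum(log(1 + n_i * la)) + log(sum(n_i * h)) + (N - 1)
  } else {
    s2 <- q / N
    N * log(s2) + sum(log(1 + n_i * la)) + N
  }
}

.icc_fit <- function(y, gid, reml = TRUE) {
  f <- function(ll) .icc_crit(ll, y, gid, reml)
  opt <- stats::optimize(f, c(-14, 14), tol = 1e-10)
  # compare against the boundary lambda -> 0
  at0 <- .icc_crit(-30, y, gid, reml)
  if (at0 <= opt$objective) { la <- 0; obj <- at0 } else { la <- exp(opt$minimum); obj <- opt$objective }
  S <- rowsum(y, gid); n_i <- as.numeric(table(gid)[rownames(S)])
  h <- 1 / (1 + n_i * la)
  mu <- sum(S * h) / sum(n_i * h)
  ss <- rowsum((y - mu)^2, gid)
  q <- sum(ss) - la * sum(h * (S - n_i * mu)^2)
  N <- length(y)
  s2e <- q / (if (reml) N - 1 else N)
  list(lambda = la, mu = mu, var_residual = s2e, var_among = la * s2e,
       R = la / (1 + la), m2ll = obj)
}

#' Repeatability (intraclass correlation) of a migratory timing
#'
#' Gaussian random-intercept model `value ~ 1 + (1 | individual)` fitted
#' by REML; `R = var_among / (var_among + var_residual)`. The 95% CI comes
#' from a parametric bootstrap (`n_boot` refits of data simulated from the
#' fitted model), and the p value from a likelihood-ratio test of the
#' random effect against the 0.5*chi2(0) + 0.5*chi2(1) boundary mixture.
#'
#' @param values numeric response (signed arrival/departure days, or
#'   durations).
#' @param individual_ids grouping factor.
#' @param n_boot parametric bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return list of class `repeatability_estimate`: `R`, `ci_low`,
#'   `ci_high`, `p_value`, `var_among`, `var_residual`,
#'   `n_individuals`, `n_observations`.
#' @export
repeatability <- function(values, individual_ids, n_boot = 1000, seed = 1) {
  gid <- as.character(individual_ids)
  ok <- !is.na(values) & !is.na(gid)
  y <- as.numeric(values[ok]); gid <- gid[ok]
  if (length(unique(gid)) < 2) stop("repeatability: need at least 2 individuals")
  if (stats::var(y) <= 0) stop("repeatability: zero total variance, R undefined")
  fit <- .icc_fit(y, gid, reml = TRUE)
  # LRT on the ML scale against the null (no among-individual variance)
  ml <- .icc_fit(y, gid, reml = FALSE)
  null_m2ll <- length(y) * log(mean((y - mean(y))^2)) + length(y)
  lrt <- max(0, null_m2ll - ml$m2ll)
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  set.seed(seed)
  n_i <- table(gid)
  g_index <- match(gid, names(n_i))
  bootR <- numeric(n_boot)
  sa <- sqrt(fit$var_among); se <- sqrt(fit$var_residual)
  for (b in seq_len(n_boot)) {
    a <- stats::rnorm(length(n_i), 0, sa)
    yb <- fit$mu + a[g_index] + stats::rnorm(length(y), 0, se)
    bootR[b] <- .icc_fit(yb, gid, reml = TRUE)$R
  }
  ci <- stats::quantile(bootR, c(0.025, 0.975), names = FALSE)
  structure(list(R = fit$R, ci_low = ci[1], ci_high = ci[2], p_value = p,
                 var_among = fit$var_among, var_residual = fit$var_residual,
                 n_individuals = length(n_i), n_observations = length(y),
                 boot = bootR, mu = fit$mu),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f [%.3f, %.3f], p = %.3g (N_ind = %d, N_obs = %d)\n",
              x$R, x$ci_low, x$ci_high, x$p_value, x$n_individuals, x$n_observations))
  invisible(x)
}

#' Fit a generalised linear model of the similarity / variability suite
#'
#' Thin, validated wrapper around IRLS GLM fitting for the family/link
#' combinations the analysis uses: gamma with identity link (EMD models;
#' step-halving keeps fitted means positive, and a linear-model start is
#' supplied), gamma with log link (seasonal variability), binomial with
#' log link (BA overlap), and gaussian. Dispersion is the Pearson
#' estimator.
#'
#' @param data model frame.
#' @param formula model formula.
#' @param family `"gamma"`, `"binomial"` or `"gaussian"`.
#' @param link link function name.
#' @return object of class `gadfly_glm` wrapping the fit with a
#'   coefficient table (`estimate, se, t, p`), `dispersion`, `deviance`,
#'   `df_residual`.
#' @export
fit_glm <- function(data, formula, family = c("gamma", "binomial", "gaussian"),
                    link = "identity") {
  family <- match.arg(family)
  fam <- switch(family,
                gamma = stats::Gamma(link = link),
                binomial = stats::binomial(link = link),
                gaussian = stats::gaussian(link = link))
  resp <- stats::model.response(stats::model.frame(formula, data))
  if (family == "gamma" && any(resp <= 0)) {
    stop("fit_glm: gamma family needs a strictly positive response")
  }
  if (family == "binomial" && any(resp < 0 | resp > 1)) {
    stop("fit_glm: binomial family needs a response in [0, 1]")
  }
  start <- NULL
  if (family == "gamma" && link == "identity") {
    start <- stats::coef(stats::lm(formula, data))
    X <- stats::model.matrix(formula, data)
    if (anyNA(start) || any(X %*% start <= 0)) {
      # linear-model start leaves the gamma mean space; fall back to a flat
      # start at the response mean
      start <- c(mean(resp), rep(0, ncol(X) - 1))
    }
  }
  if (family == "binomial" && link == "log") {
    # start strictly inside the parameter space (mu < 1)
    x <- stats::model.matrix(formula, data)
    start <- c(log(max(min(mean(resp), 0.99), 1e-3)), rep(0, ncol(x) - 1))
  }
  fit <- suppressWarnings(stats::glm(formula, family = fam, data = data,
                                     start = start,
                                     control = stats::glm.control(epsilon = 1e-10,
                                                                  maxit = 100)))
  if (!fit$converged) stop("fit_glm: IRLS failed to converge in 100 iterations")
  mu <- stats::fitted(fit)
  if (family == "gamma" && any(mu <= 0)) {
    stop("fit_glm: negative fitted mean under identity link; consider the log link")
  }
  disp <- if (family == "binomial") 1 else
    sum(stats::residuals(fit, "pearson")^2) / fit$df.residual
  sm <- summary(fit, dispersion = disp)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "stat", "p")
  structure(list(fit = fit, family = family, link = link, formula = formula,
                 data = data, coefficients = ct, dispersion = disp,
                 deviance = stats::deviance(fit), df_residual = fit$df.residual),
            class = "gadfly_glm")
}

#' @export
print.gadfly_glm <- function(x, ...) {
  cat(sprintf("GLM (%s, %s link): %s\n", x$family, x$link,
              deparse(x$formula)))
  print(round(x$coefficients, 4))
  cat(sprintf("dispersion %.4f, residual deviance %.2f on %d df\n",
              x$dispersion, x$deviance, x$df_residual))
  invisible(x)
}

#' Backwards stepwise deletion by ANOVA
#'
#' Repeatedly removes the least significant removable term with
#' p >= alpha, respecting marginality (an interaction is removable before
#' its main effects; a main effect is never dropped while one of its
#' interactions remains). Significance is an F test for families with
#' estimated dispersion (gamma, gaussian) and a chi-squared test for
#' binomial.
#'
#' @param fit a [fit_glm()] object.
#' @param alpha retention threshold (default 0.05).
#' @return the minimum adequate `gadfly_glm`, with a `deletion_log`
#'   attribute (term, p at removal).
#' @export
stepwise_backward <- function(fit, alpha = 0.05) {
  log_ <- data.frame(term = character(), p = numeric())
  repeat {
    d1 <- .drop_table(fit)
    if (!nrow(d1) || all(is.na(d1$p))) break
    worst <- which.max(d1$p)
    if (is.na(d1$p[worst]) || d1$p[worst] < alpha) break
    log_ <- rbind(log_, data.frame(term = d1$term[worst], p = d1$p[worst]))
    new_formula <- stats::update(fit$formula,
                                 paste(". ~ . -", d1$term[worst]))
    fit <- fit_glm(fit$data, new_formula, fit$family, fit$link)
  }
  attr(fit, "deletion_log") <- log_
  fit
}

## single-deletion ANOVA table: terms removable under marginality, with an
## F test (estimated dispersion) or chi-squared test (binomial); submodels
## are refitted through fit_glm so gamma/identity keeps its guarded start
.drop_table <- function(fit) {
  terms_ <- stats::drop.scope(fit$formula)
  if (!length(terms_)) {
    return(data.frame(term = character(), p = numeric()))
  }
  out <- data.frame(term = terms_, df = NA_real_, stat = NA_real_, p = NA_real_)
  for (i in seq_along(terms_)) {
    sub <- try(fit_glm(fit$data,
                       stats::update(fit$formula, paste(". ~ . -", terms_[i])),
                       fit$family, fit$link), silent = TRUE)
    if (inherits(sub, "try-error")) next  # untestable term: p stays NA (kept)
    ddf <- sub$df_residual - fit$df_residual
    ddev <- sub$deviance - fit$deviance
    if (fit$family == "binomial") {
      out$stat[i] <- ddev
      out$p[i] <- stats::pchisq(ddev, ddf, lower.tail = FALSE)
    } else {
      out$stat[i] <- (ddev / ddf) / fit$dispersion
      out$p[i] <- stats::pf(out$stat[i], ddf, fit$df_residual, lower.tail = FALSE)
    }
    out$df[i] <- ddf
  }
  out
}

#' Estimated marginal means with Tukey-adjusted pairwise contrasts
#'
#' Marginal (link-scale) means of a factor at a reference grid holding
#' numeric covariates at their means (or supplied values), with all
#' pairwise contrasts and familywise adjustment via the studentized-range
#' distribution on the contrast t statistics.
#'
#' @param fit a [fit_glm()] object.
#' @param factor_name name of a factor term in the model.
#' @param at named list fixing covariate values (e.g.
#'   `list(dep_diff_days = 50)`); unspecified numeric covariates are set
#'   to their data means.
#' @return list with `emmeans` (level, link-scale estimate, se) and
#'   `contrasts` (`estimate, se, t, p_raw, p_tukey`).
#' @export
emmeans_tukey <- function(fit, factor_name, at = list()) {
  data <- fit$data
  if (!factor_name %in% names(data)) stop("emmeans_tukey: factor not in model data")
  f <- data[[factor_name]]
  if (!is.factor(f)) f <- factor(f)
  levs <- levels(f)
  vars <- all.vars(fit$formula)[-1]
  grid <- data.frame(row.names = seq_along(levs))
  for (v in vars) {
    if (v == factor_name) {
      grid[[v]] <- factor(levs, levels = levs)
    } else if (v %in% names(at)) {
      grid[[v]] <- at[[v]]
    } else if (is.numeric(data[[v]])) {
      grid[[v]] <- mean(data[[v]], na.rm = TRUE)
    } else {
      # non-focal factors: proportional average over observed levels
      grid[[v]] <- factor(names(which.max(table(data[[v]]))),
                          levels = levels(factor(data[[v]])))
    }
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)), grid,
                           xlev = fit$fit$xlevels)
  beta <- stats::coef(fit$fit)
  V <- stats::vcov(fit$fit) * fit$dispersion / summary(fit$fit)$dispersion
  est <- drop(X %*% beta)
  se <- sqrt(diag(X %*% V %*% t(X)))
  k <- length(levs)
  pairs_ <- utils::combn(k, 2)
  cst <- data.frame(contrast = character(0))
  df <- fit$df_residual
  rows <- list()
  for (c_ in seq_len(ncol(pairs_))) {
    i <- pairs_[1, c_]; j <- pairs_[2, c_]
    L <- X[i, ] - X[j, ]
    e <- sum(L * beta)
    s <- sqrt(drop(t(L) %*% V %*% L))
    tval <- e / s
    p_raw <- if (fit$family == "binomial") {
      2 * stats::pnorm(-abs(tval))
    } else 2 * stats::pt(-abs(tval), df)
    dfe <- if (fit$family == "binomial") 1e6 else df
    p_tuk <- stats::ptukey(abs(tval) * sqrt(2), k, dfe, lower.tail = FALSE)
    rows[[c_]] <- data.frame(contrast = paste(levs[i], "-", levs[j]),
                             estimate = e, se = s, t = tval,
                             p_raw = p_raw, p_tukey = min(1, p_tuk))
  }
  list(emmeans = data.frame(level = levs, estimate = est, se = se),
       contrasts = do.call(rbind, rows))
}

#' Seasonal variability in migratory timings
#'
#' For each individual that consistently departed (or arrived) in a single
#' season, the within-individual range (days between earliest and latest
#' date, on the signed-day scale) is modelled with a gamma/log GLM with
#' season as a fixed effect. Zero ranges are replaced by 0.5 day (gamma
#' support) and logged.
#'
#' @param phenology data.frame with `individual`, `departure_date`,
#'   `arrival_date`.
#' @return list with `departure` and `arrival` `gadfly_glm` fits (NULL if
#'   a model is not estimable) and the `ranges` table.
#' @export
seasonal_variability <- function(phenology) {
  range_table <- function(datecol) {
    out <- list()
    for (ind in unique(phenology$individual)) {
      d <- phenology[[datecol]][phenology$individual == ind]
      d <- d[!is.na(d)]
      if (length(d) < 2) next
      seas <- season_of(d)
      if (length(unique(seas)) != 1) next  # only consistent-season individuals
      sd_ <- to_signed_days(d)
      rng <- diff(range(sd_))
      if (rng == 0) rng <- 0.5
      out[[length(out) + 1L]] <- data.frame(individual = ind,
                                            season = seas[1], range_days = rng)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  fit_season <- function(tab) {
    if (is.null(tab) || length(unique(tab$season)) < 2) return(NULL)
    fit_glm(tab, range_days ~ season, family = "gamma", link = "log")
  }
  dep <- range_table("departure_date"); arr <- range_table("arrival_date")
  list(departure = fit_season(dep), arrival = fit_season(arr),
       ranges = list(departure = dep, arrival = arr))
}

#' Pearson correlation between per-individual departure and arrival ranges
#'
#' @param departure_ranges,arrival_ranges paired per-individual ranges
#'   (days).
#' @return list `r`, `t`, `df`, `p`.
#' @export
pearson_range_correlation <- function(departure_ranges, arrival_ranges) {
  ok <- !is.na(departure_ranges) & !is.na(arrival_ranges)
  x <- departure_ranges[ok]; y <- arrival_ranges[ok]
  n <- length(x)
  if (n < 3) stop("pearson_range_correlation: need at least 3 pairs")
  r <- stats::cor(x, y)
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
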