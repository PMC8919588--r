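# Independent oracles used by the tests. Each is implemented from first
# principles by a different route than the package code it checks.

# --- exact min-cost flow by successive shortest paths (Bellman-Ford) -----
# Integer supplies/demands; independent check on the transportation-simplex
# EMD solver. Nodes: 1 = source, 2..(m+1) rows, (m+2)..(m+n+1) cols, last = sink.
oracle_mincost_flow <- function(cost, supply, demand) {
  m <- nrow(cost); n <- ncol(cost)
  f <- matrix(0, m, n)
  rem_s <- supply; rem_d <- demand
  total <- 0
  repeat {
    if (sum(rem_s) == 0) break
    nn <- m + n + 2
    dist <- rep(Inf, nn); dist[1] <- 0
    prev <- rep(NA_integer_, nn)
    # Bellman-Ford over residual arcs
    for (iter in seq_len(nn)) {
      changed <- FALSE
      for (i in seq_len(m)) {
        if (rem_s[i] > 0 && dist[1] < dist[1 + i]) {
          dist[1 + i] <- dist[1]; prev[1 + i] <- 1; changed <- TRUE
        }
      }
      for (i in seq_len(m)) for (j in seq_len(n)) {
        u <- 1 + i; v <- 1 + m + j
        if (is.finite(dist[u]) && dist[u] + cost[i, j] < dist[v] - 1e-12) {
          dist[v] <- dist[u] + cost[i, j]; prev[v] <- u; changed <- TRUE
        }
        if (f[i, j] > 0 && is.finite(dist[v]) && dist[v] - cost[i, j] < dist[u] - 1e-12) {
          dist[u] <- dist[v] - cost[i, j]; prev[u] <- v; changed <- TRUE
        }
      }
      for (j in seq_len(n)) {
        v <- 1 + m + j
        if (rem_d[j] > 0 && is.finite(dist[v]) && dist[v] < dist[nn]) {
          dist[nn] <- dist[v]; prev[nn] <- v; changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[nn])) stop("oracle flow: infeasible")
    # trace path, find bottleneck
    path <- integer(0); v <- nn
    while (!is.na(prev[v])) { path <- c(v, path); v <- prev[v] }
    path <- c(1, path[path != 1])
    cap <- Inf
    for (k in seq_len(length(path) - 1)) {
      u <- path[k]; v <- path[k + 1]
      if (u == 1) cap <- min(cap, rem_s[v - 1])
      else if (v == nn) cap <- min(cap, rem_d[u - 1 - m])
      else if (u <= 1 + m) cap <- min(cap, Inf)
      else cap <- min(cap, f[path[k + 1] - 1, u - 1 - m])
    }
    for (k in seq_len(length(path) - 1)) {
      u <- path[k]; v <- path[k + 1]
      if (u == 1) rem_s[v - 1] <- rem_s[v - 1] - cap
      else if (v == nn) rem_d[u - 1 - m] <- rem_d[u - 1 - m] - cap
      else if (u <= 1 + m) f[u - 1, v - 1 - m] <- f[u - 1, v - 1 - m] + cap
      else f[v - 1, u - 1 - m] <- f[v - 1, u - 1 - m] - cap
    }
    total <- sum(f * cost)
  }
  list(cost = sum(f * cost), flow = f)
}

# EMD between uniform point sets via the flow oracle (weights 1/m, 1/n).
oracle_emd_uniform <- function(a, b) {
  m <- nrow(a); n <- nrow(b)
  cost <- outer(seq_len(m), seq_len(n), function(i, j)
    haversine_km(a$lon[i], a$lat[i], b$lon[j], b$lat[j]))
  r <- oracle_mincost_flow(cost, rep(n, m), rep(m, n))
  r$cost / (m * n)
}

# --- exhaustive HMM path enumeration (<= ~10 days) -----------------------
# logpi: 2; logA: 2x2; le: T x 2 log-emissions.
oracle_hmm_enumerate <- function(logpi, logA, le) {
  T_ <- nrow(le)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  lp <- apply(paths, 1, function(s) {
    v <- logpi[s[1]] + le[1, s[1]]
    if (T_ > 1) for (t in 2:T_) v <- v + logA[s[t - 1], s[t]] + le[t, s[t]]
    v
  })
  mx <- max(lp)
  ll <- mx + log(sum(exp(lp - mx)))
  w <- exp(lp - ll)
  gamma <- matrix(0, T_, 2)
  for (t in seq_len(T_)) for (s in 1:2) gamma[t, s] <- sum(w[paths[, t] == s])
  list(loglik = ll, gamma = gamma, viterbi = paths[which.max(lp), ])
}

# --- balanced one-way ANOVA ICC (closed form) ----------------------------
oracle_anova_icc <- function(y, gid) {
  gm <- tapply(y, gid, mean)
  n0 <- unique(table(gid))
  stopifnot(length(n0) == 1)  # balanced designs only
  k <- length(gm)
  msb <- n0 * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[gid])^2) / (length(y) - k)
  sa <- max(0, (msb - msw) / n0)
  sa / (sa + msw)
}

# --- direct maximum-likelihood GLM oracle (generic optimiser) ------------
# The beta MLE for these families does not depend on the dispersion, so the
# kernel of the log-likelihood is optimised directly with optim/BFGS.
oracle_glm_ml <- function(formula, data, family, link) {
  X <- model.matrix(formula, data)
  y <- model.response(model.frame(formula, data))
  linkinv <- switch(link, identity = function(e) e, log = exp,
                    logit = function(e) 1 / (1 + exp(-e)))
  nll <- function(beta) {
    mu <- linkinv(drop(X %*% beta))
    if (family == "gamma") {
      if (any(mu <= 0)) return(1e12)
      sum(y / mu + log(mu))
    } else if (family == "binomial") {
      if (any(mu <= 0 | mu >= 1)) return(1e12)
      -sum(y * log(mu) + (1 - y) * log(1 - mu))
    } else {
      sum((y - mu)^2)
    }
  }
  b0 <- rep(0, ncol(X))
  b0[1] <- switch(link, identity = mean(y), log = log(max(mean(y), 1e-3)),
                  logit = qlogis(min(max(mean(y), 0.01), 0.99)))
  grad <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- linkinv(eta)
    dmu <- switch(link, identity = rep(1, length(eta)), log = mu,
                  logit = mu * (1 - mu))
    dldmu <- if (family == "gamma") 1 / mu - y / mu^2
      else if (family == "binomial") -(y / mu - (1 - y) / (1 - mu))
      else -2 * (y - mu)
    drop(crossprod(X, dldmu * dmu))
  }
  o <- optim(b0, nll, grad, method = "BFGS",
             control = list(maxit = 20000, reltol = 1e-15))
  for (pass in 1:3) {
    o <- optim(o$par, nll, grad, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-15,
                              parscale = pmax(abs(o$par), 1e-3)))
  }
  o$par
}

# --- spherical law of cosines distance (alternative great-circle route) --
oracle_sloc_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  6371 * acos(pmin(1, pmax(-1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))))
}

# small helper: random ocean-ish point sets for EMD property tests
rand_points <- function(n, lon0 = 70, lat0 = -10, spread = 15) {
  data.frame(lon = runif(n, lon0 - spread, lon0 + spread),
             lat = runif(n, lat0 - spread, lat0 + spread))
}

# balanced/unbalanced random-intercept data generator shared across files
sim_icc_data <- function(k, n_per, mu, sa, se, seed) {
  set.seed(seed)
  a <- rnorm(k, 0, sa)
  data.frame(id = rep(sprintf("i%03d", 1:k), each = n_per),
             y = mu + rep(a, each = n_per) + rnorm(k * n_per, 0, se))
}

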