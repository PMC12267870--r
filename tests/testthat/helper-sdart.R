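# shared fixtures and wrappers for the test suite

# short-chain fits warn about R-hat by design; tests assert on substance
quiet_fit <- function(...) suppressWarnings(sda_fit(...))

# tiny stratified dataset built directly (2 participants x 2 bands x 1 length)
toy_strat <- function(seed = 1, n_per_cell = 8) {
  set.seed(seed)
  g <- expand.grid(participant = c("a", "b"), band = 1:2)
  trials <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(participant = g$participant[i], band = g$band[i], length = 4L,
               rt = rshifted(n_per_cell, "gamma", 250, 4, 0.02),
               occurrence = g$band[i] * 10)
  }))
  stratify(trials)
}

# single-participant two-cell instance with fixed hyperparameters,
# used for quadrature cross-checks
toy_fixed_psi <- function(family, seed = 42, n_per_cell = 10) {
  set.seed(seed)
  theta_t <- 250
  pars <- switch(family,
    gamma = list(r1 = c(4, 5), r2 = c(0.02, 0.025),
                 fixed = list(alpha1 = 16, beta1 = 4, alpha2 = 4, beta2 = 200,
                              alpha_theta = 50, beta_theta = 0.2)),
    lognormal = list(r1 = c(5.2, 5.4), r2 = c(0.09, 0.12),
                     fixed = list(alpha1 = 400, beta1 = 75, alpha2 = 9,
                                  beta2 = 100, alpha_theta = 50,
                                  beta_theta = 0.2)),
    wald = list(r1 = c(220, 260), r2 = c(1800, 2200),
                fixed = list(alpha1 = 25, beta1 = 0.1, alpha2 = 16,
                             beta2 = 0.008, alpha_theta = 50,
                             beta_theta = 0.2)))
  y <- c(rshifted(n_per_cell, family, theta_t, pars$r1[1], pars$r2[1]),
         rshifted(n_per_cell, family, theta_t, pars$r1[2], pars$r2[2]))
  trials <- data.frame(participant = "p1", rt = y, length = 4L,
                       band = rep(1:2, each = n_per_cell),
                       occurrence = rep(c(1, 10), each = n_per_cell))
  strat <- stratify(trials)
  list(strat = strat, fixed = pars$fixed, family = family,
       prior = sda_prior(4L, psi_fixed = pars$fixed),
       truth = list(theta = theta_t, r1 = pars$r1, r2 = pars$r2))
}

# dense-grid quadrature oracle for the toy_fixed_psi posterior, via the
# families' sufficient statistics (independent of the package likelihood code)
quad_oracle <- function(toy, n_th = 300, n_r = 140) {
  st <- toy$strat; fx <- toy$fixed; fam <- toy$family
  y <- st$y; cellv <- st$cell_id
  m <- min(y)
  thg <- seq(1e-3, m * (1 - 1e-6), length.out = n_th)
  gr <- switch(fam,
    gamma = list(r1 = exp(seq(log(0.3), log(60), length.out = n_r)),
                 r2 = exp(seq(log(5e-4), log(0.8), length.out = n_r))),
    lognormal = list(r1 = seq(3.5, 7, length.out = n_r),
                     r2 = exp(seq(log(0.005), log(1.5), length.out = n_r))),
    wald = list(r1 = exp(seq(log(30), log(1500), length.out = n_r)),
                r2 = exp(seq(log(100), log(30000), length.out = n_r))))
  wts <- function(g) { d <- diff(g)
    c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2) }
  lw1 <- log(wts(gr$r1)); lw2 <- log(wts(gr$r2))
  lp1 <- dgamma(gr$r1, fx$alpha1, rate = fx$beta1, log = TRUE)
  lp2 <- dgamma(gr$r2, fx$alpha2, rate = fx$beta2, log = TRUE)
  cellZ <- function(idx, th) {
    x <- y[idx] - th
    n <- length(x)
    ll <- switch(fam,
      gamma = { sl <- sum(log(x)); sx <- sum(x)
        outer(gr$r1, gr$r2, function(a, b)
          n * (a * log(b) - lgamma(a)) + (a - 1) * sl - b * sx) },
      lognormal = { sl <- sum(log(x)); s2 <- sum(log(x)^2)
        outer(gr$r1, gr$r2, function(mu, v)
          -n / 2 * log(2 * pi * v) - sl -
            (s2 - 2 * mu * sl + n * mu^2) / (2 * v)) },
      wald = { sx <- sum(x); si <- sum(1 / x); sl3 <- 1.5 * sum(log(x))
        outer(gr$r1, gr$r2, function(mu, l)
          n / 2 * log(l) - n / 2 * log(2 * pi) - sl3 -
            (l / (2 * mu^2)) * (sx - 2 * n * mu + mu^2 * si)) })
    lg <- ll + outer(lp1 + lw1, lp2 + lw2, `+`)
    mx <- max(lg)
    W <- exp(lg - mx)
    Z <- sum(W)
    list(logZ = mx + log(Z), e1 = sum(W * gr$r1) / Z,
         e2 = sum(W %*% gr$r2) / Z)
  }
  c1 <- which(cellv == 1); c2 <- which(cellv == 2)
  res <- do.call(rbind, lapply(thg, function(th) {
    a <- cellZ(c1, th); b <- cellZ(c2, th)
    c(lz = a$logZ + b$logZ +
        dgamma(th, fx$alpha_theta, rate = fx$beta_theta, log = TRUE),
      e11 = a$e1, e12 = a$e2, e21 = b$e1, e22 = b$e2)
  }))
  lpost <- res[, "lz"] + log(wts(thg))
  w <- exp(lpost - max(lpost)); w <- w / sum(w)
  list(means = c(theta = sum(w * thg),
                 rho1_1 = sum(w * res[, "e11"]), rho2_1 = sum(w * res[, "e12"]),
                 rho1_2 = sum(w * res[, "e21"]), rho2_2 = sum(w * res[, "e22"])),
       log_norm_const = max(lpost) + log(sum(exp(lpost - max(lpost)))))
}

# Monte-Carlo standard error of a posterior-mean estimate
mcse_mean <- function(draws, chain) {
  mat <- do.call(cbind, split(draws, chain))
  sd(draws) / sqrt(ess_mean(mat))
}
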