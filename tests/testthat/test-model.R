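test_that("prior configuration enumerates the hyperparameter set", {
  pr <- sda_prior(4:10)
  expect_length(pr$a, 30)  # 4 per length x 7 lengths + the shift pair
  expect_length(pr$b, 30)
  pr3 <- sda_prior(c(4, 7, 10))
  expect_length(pr3$a, 14)
  expect_error(sda_prior(4:10, a = -1), "positive")
  expect_error(sda_prior(4, psi_fixed = list(alpha1 = 1)), "must supply")
})

test_that("log_joint composes likelihood and priors", {
  toy <- toy_fixed_psi("gamma")
  st <- toy$strat
  psi <- list(alpha1 = 16, beta1 = 4, alpha2 = 4, beta2 = 200,
              alpha_theta = 50, beta_theta = 0.2)
  prior <- sda_prior(4L)

  # single trial: likelihood term equals the shifted log density
  one <- stratify(data.frame(participant = "p1", rt = 400, length = 4L,
                             band = 1L, occurrence = 1))
  lj <- log_joint(one, "gamma", theta = 250, rho1 = 4, rho2 = 0.02,
                  psi = psi, prior = prior)
  prior_part <- log_joint(structure(list(y = numeric(0), cell_id = integer(0),
                                         part_id = integer(0),
                                         cells = one$cells,
                                         participants = one$participants,
                                         lengths = one$lengths,
                                         band_spec = NULL),
                                    class = "sda_data"),
                          "gamma", 250, 4, 0.02, psi, prior)
  expect_equal(lj - prior_part,
               dshifted(400, "gamma", 250, 4, 0.02, log = TRUE))

  # empty dataset: exactly the sum of prior log densities, computed directly
  direct <- dgamma(4, 16, rate = 4, log = TRUE) +
    dgamma(0.02, 4, rate = 200, log = TRUE) +
    dgamma(250, 50, rate = 0.2, log = TRUE) +
    sum(dgamma(c(16, 4, 4, 200, 50, 0.2), prior$a, rate = prior$b, log = TRUE))
  expect_equal(prior_part, direct)

  # support: shift at or above the participant's minimum RT kills the joint
  expect_identical(log_joint(one, "gamma", 400, 4, 0.02, psi, prior), -Inf)
  expect_identical(log_joint(one, "gamma", 500, 4, 0.02, psi, prior), -Inf)

  # structural errors
  expect_error(log_joint(st, "gamma", 250, 4, 0.02, psi, prior), "cells")
  expect_error(log_joint(one, "gamma", c(250, 260), 4, 0.02, psi, prior),
               "participant")
})

test_that("log_joint normalising constant matches grid quadrature", {
  # exp(log_joint) integrated over (theta, rho) must equal the quadrature
  # oracle's normalising constant (both with fixed hyperparameters)
  toy <- toy_fixed_psi("gamma")
  or <- quad_oracle(toy, n_th = 250, n_r = 120)
  psi <- toy$fixed
  # direct integration of exp(log_joint) on the oracle's own grids
  st <- toy$strat
  m <- min(st$y)
  thg <- seq(1e-3, m * (1 - 1e-6), length.out = 250)
  r1g <- exp(seq(log(0.3), log(60), length.out = 60))
  r2g <- exp(seq(log(5e-4), log(0.8), length.out = 60))
  wts <- function(g) { d <- diff(g)
    c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2) }
  gr <- expand.grid(r11 = r1g, r21 = r2g)
  # factorised cells: integrate each cell given theta, then over theta
  lZ <- vapply(thg, function(th) {
    za <- vapply(seq_len(nrow(gr)), function(i) {
      sum(dshifted(st$y[st$cell_id == 1], "gamma", th, gr$r11[i], gr$r21[i],
                   log = TRUE)) +
        dgamma(gr$r11[i], psi$alpha1, rate = psi$beta1, log = TRUE) +
        dgamma(gr$r21[i], psi$alpha2, rate = psi$beta2, log = TRUE)
    }, numeric(1))
    zb <- vapply(seq_len(nrow(gr)), function(i) {
      sum(dshifted(st$y[st$cell_id == 2], "gamma", th, gr$r11[i], gr$r21[i],
                   log = TRUE)) +
        dgamma(gr$r11[i], psi$alpha1, rate = psi$beta1, log = TRUE) +
        dgamma(gr$r21[i], psi$alpha2, rate = psi$beta2, log = TRUE)
    }, numeric(1))
    lw <- log(wts(r1g)[match(gr$r11, r1g)]) + log(wts(r2g)[match(gr$r21, r2g)])
    f <- function(v) { mx <- max(v); mx + log(sum(exp(v - mx))) }
    f(za + lw) + f(zb + lw) +
      dgamma(th, psi$alpha_theta, rate = psi$beta_theta, log = TRUE)
  }, numeric(1))
  lw_th <- log(wts(thg))
  mx <- max(lZ + lw_th)
  direct <- mx + log(sum(exp(lZ + lw_th - mx)))
  expect_equal(direct, or$log_norm_const, tolerance = 1e-3)
})

test_that("with no data the posterior reproduces the prior", {
  # prior-only fit: marginal draws of theta must match ancestral simulation
  # from the hierarchical prior (hyperdraws then gamma draws)
  st0 <- toy_strat(n_per_cell = 2)
  st0$y <- numeric(0); st0$cell_id <- integer(0); st0$part_id <- integer(0)
  pr <- sda_prior(4L, a = 2, b = 2)  # proper enough for a stable check
  fit <- quiet_fit(st0, "gamma", prior = pr, draws = 3000, warmup = 1000,
                   chains = 2, seed = 31)
  set.seed(99)
  S <- 6000
  anc_psi_a <- rgamma(S, 2, rate = 2)
  anc_psi_b <- rgamma(S, 2, rate = 2)
  anc_theta <- rgamma(S, shape = anc_psi_a, rate = anc_psi_b)
  got <- as.numeric(fit$theta)
  qs <- c(0.25, 0.5, 0.75)
  expect_equal(quantile(log(got), qs, names = FALSE),
               quantile(log(anc_theta), qs, names = FALSE),
               tolerance = 0.1)
  # rho marginals likewise
  anc_rho <- rgamma(S, shape = rgamma(S, 2, 2), rate = rgamma(S, 2, 2))
  expect_equal(quantile(log(as.numeric(fit$rho1)), qs, names = FALSE),
               quantile(log(anc_rho), qs, names = FALSE),
               tolerance = 0.12)
})

test_that("fits are seed-reproducible and respect support constraints", {
  st <- toy_strat()
  f1 <- quiet_fit(st, "gamma", draws = 100, warmup = 150, chains = 2, seed = 4)
  f2 <- quiet_fit(st, "gamma", draws = 100, warmup = 150, chains = 2, seed = 4)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$rho2, f2$rho2)
  f3 <- quiet_fit(st, "gamma", draws = 100, warmup = 150, chains = 2, seed = 5)
  expect_false(identical(f1$theta, f3$theta))

  # support: every draw below the participant's minimum RT, all rho positive
  m <- tapply(st$y, st$part_id, min)
  for (j in seq_along(m))
    expect_true(all(f1$theta[, j] > 0 & f1$theta[, j] < m[j]))
  expect_true(all(f1$rho1 > 0) && all(f1$rho2 > 0))
  expect_true(all(is.finite(f1$psi)) && all(f1$psi > 0))
})

test_that("posterior medians follow the documented conventions", {
  st <- toy_strat()
  fit <- quiet_fit(st, "gamma", draws = 50, warmup = 100, chains = 1, seed = 2)
  # constant draws -> the constant
  fit2 <- fit
  fit2$theta[] <- 123
  expect_true(all(posterior_medians(fit2, "theta") == 123))
  # even draw count -> midpoint of the two central order statistics
  fit3 <- fit
  fit3$theta[, 1] <- rep(c(10, 20), length.out = nrow(fit3$theta))
  expect_equal(unname(posterior_medians(fit3, "theta")[1]), 15)
  # named per-unit output and derived cell means
  expect_named(posterior_medians(fit, "theta"), as.character(st$participants))
  cm <- posterior_medians(fit, "cell_mean")
  expect_length(cm, nrow(st$cells))
  expect_true(all(cm > posterior_medians(fit, "theta")[st$cells$j]))
  expect_error(posterior_medians(fit, "nonsense"))
})

test_that("theta posterior is stable across frequency measures and shifts only boundedly across families", {
  # the deterministic shift is a property of the participant: re-banding
  # the same RTs under a different occurrence measure must leave the theta
  # posterior essentially unchanged, and swapping the stochastic family
  # shifts the medians only by a bounded, nearly uniform amount
  des <- sda_design(n_participants = 8, lengths = c(4, 7), n_words = 8,
                    n_bands = 2, trials_per_word = 2, family = "lognormal")
  sim <- gen_trials(des, seed = 77)
  lex <- sim$truth$lexicon

  strat_for <- function(measure) {
    tr <- sim$trials
    tr$occurrence <- lex[[measure]][match(tr$item, lex$word)]
    tr$band <- NULL
    bs <- frequency_bands(tr$occurrence, min_count = nrow(tr) %/% 2,
                          measure = measure)
    stratify(tr, bs)
  }

  # (a) same family, three measures: 50% intervals overlap per participant
  cis <- lapply(c("WF", "DCD", "UCD"), function(mm) {
    fit <- quiet_fit(strat_for(mm), "lognormal", draws = 1200, warmup = 1000,
                     chains = 2, seed = 13)
    credible_interval(fit, "theta", level = 0.5)
  })
  overlap <- vapply(seq_len(8), function(j) {
    max(vapply(cis, function(ci) ci[j, "lower"], numeric(1))) <=
      min(vapply(cis, function(ci) ci[j, "upper"], numeric(1)))
  }, logical(1))
  expect_gte(mean(overlap), 0.8)

  # (b) three families on one stratification: medians track each other
  # (same shape, small horizontal shift between families -- small relative
  # to the shift scale itself)
  st <- strat_for("WF")
  med <- sapply(sda_families(), function(f) {
    posterior_medians(quiet_fit(st, f, draws = 1200, warmup = 1000,
                                chains = 2, seed = 13), "theta")
  })
  expect_gt(min(cor(med)), 0.8)
  shifts <- abs(outer(colMeans(med), colMeans(med), `-`))
  expect_lt(max(shifts), 0.5 * mean(med))
})

test_that("sparse cells are flagged but still modelled", {
  trials <- rbind(
    data.frame(participant = "a", rt = rshifted(30, "gamma", 250, 4, 0.02,
                                                seed = 1),
               length = 4L, band = 1L, occurrence = 1),
    data.frame(participant = "a", rt = c(500, 600), length = 4L, band = 2L,
               occurrence = 9))
  st <- stratify(trials)
  fit <- quiet_fit(st, "gamma", draws = 100, warmup = 150, chains = 1,
                   seed = 3)
  expect_equal(fit$sparse_cells, st$cells$cell[st$cells$n < 5])
  expect_length(fit$sparse_cells, 1)
  expect_true(all(is.finite(fit$rho1[, 2])))
})
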