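# a tiny fitted model shared across blocks, plus a degenerate copy whose
# draws are frozen at known parameter values
base_fit <- local({
  st <- toy_strat(seed = 3, n_per_cell = 12)
  quiet_fit(st, "gamma", draws = 200, warmup = 300, chains = 2, seed = 8)
})

frozen_fit <- local({
  f <- base_fit
  f$theta[] <- 250
  f$rho1[] <- 4
  f$rho2[] <- 0.02
  f
})

test_that("posterior predictive replicates are cell-aligned and reproducible", {
  pp <- posterior_predict(base_fit, R = 7, seed = 42)
  expect_equal(dim(pp$yrep), c(length(base_fit$data$y), 7))
  expect_identical(pp$cell_id, base_fit$data$cell_id)
  pp2 <- posterior_predict(base_fit, R = 7, seed = 42)
  expect_identical(pp$yrep, pp2$yrep)   # bitwise under a fixed seed
  expect_false(identical(pp$yrep,
                         posterior_predict(base_fit, R = 7, seed = 43)$yrep))
  # simulate() S3 route is the same operation
  s <- simulate(base_fit, nsim = 3, seed = 1)
  expect_s3_class(s, "sda_ppred")
  expect_equal(ncol(s$yrep), 3)
})

test_that("degenerate draws collapse the predictive to the fixed family", {
  # with all draws frozen the posterior predictive integral collapses;
  # pooled replicates must pass a KS test against the analytic CDF
  pp <- posterior_predict(frozen_fit, R = 30, seed = 5)
  z <- as.numeric(pp$yrep)
  ks <- suppressWarnings(ks.test(z, function(q)
    pshifted(q, "gamma", 250, 4, 0.02)))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(z > 250))
})

test_that("ppp values count replicates at or above the observed statistic", {
  st <- base_fit$data
  pp <- posterior_predict(base_fit, R = 40, seed = 2)
  # all-greater and all-smaller manipulations pin ppp to the extremes
  hi <- pp; hi$yrep <- pp$yrep + 1e6
  expect_true(all(ppp_values(base_fit, hi)$ppp == 1))
  lo <- pp; lo$yrep <- pp$yrep * 0
  expect_true(all(ppp_values(base_fit, lo)$ppp == 0))
  # ties count toward the numerator (>= convention)
  tie <- pp
  obs_means <- vapply(split(st$y, st$cell_id), mean, numeric(1))
  tie$yrep <- matrix(rep(st$y, 40), ncol = 40)  # every replicate == observed
  expect_true(all(ppp_values(base_fit, tie)$ppp == 1))
  # replicate means symmetric about the observed mean give ~0.5
  sym <- pp
  delta <- matrix(rep(c(-25, 25), each = nrow(pp$yrep) * 20), ncol = 40)
  sym$yrep <- matrix(rep(st$y, 40), ncol = 40) + delta
  expect_true(all(abs(ppp_values(base_fit, sym)$ppp - 0.5) <= 0.5 / 40 + 1e-9))
  # output shape and range
  tab <- ppp_values(base_fit, pp)
  expect_equal(nrow(tab), nrow(st$cells))
  expect_true(all(tab$ppp >= 0 & tab$ppp <= 1))
  expect_equal(attr(tab, "R"), 40)
  # participant-level aggregation
  tabp <- ppp_values(base_fit, pp, by = "participant")
  expect_equal(nrow(tabp), length(st$participants))
})

test_that("pointwise log predictive density matches brute force", {
  lpd <- pointwise_log_predictive(base_fit)
  expect_length(lpd, length(base_fit$data$y))
  expect_true(all(is.finite(lpd)))
  # brute force at extended care: explicit mean of densities per trial
  d <- base_fit$data
  for (i in c(1, 17, length(d$y))) {
    dens <- vapply(seq_len(nrow(base_fit$theta)), function(s) {
      th <- base_fit$theta[s, d$cells$j[d$cell_id[i]]]
      dshifted(d$y[i], "gamma", th, base_fit$rho1[s, d$cell_id[i]],
               base_fit$rho2[s, d$cell_id[i]])
    }, numeric(1))
    expect_equal(lpd[i], log(mean(dens)), tolerance = 1e-10)
  }
  # single frozen draw: reduces to the shifted log density
  one <- frozen_fit
  one$theta <- one$theta[1, , drop = FALSE]
  one$rho1 <- one$rho1[1, , drop = FALSE]
  one$rho2 <- one$rho2[1, , drop = FALSE]
  one$chain <- 1L
  lpd1 <- pointwise_log_predictive(one)
  expect_equal(as.numeric(lpd1),
               dshifted(d$y, "gamma", 250, 4, 0.02, log = TRUE))
  # two identical draws average to the same density
  two <- frozen_fit
  two$theta <- two$theta[1:2, , drop = FALSE]
  two$rho1 <- two$rho1[1:2, , drop = FALSE]
  two$rho2 <- two$rho2[1:2, , drop = FALSE]
  two$chain <- c(1L, 1L)
  expect_equal(as.numeric(pointwise_log_predictive(two)),
               as.numeric(lpd1))
})

test_that("elpd methods agree on their definitions", {
  # lpd on a single draw equals the summed pointwise log density
  one <- frozen_fit
  one$theta <- one$theta[1, , drop = FALSE]
  one$rho1 <- one$rho1[1, , drop = FALSE]
  one$rho2 <- one$rho2[1, , drop = FALSE]
  one$chain <- 1L
  e1 <- elpd(one, method = "lpd")
  expect_equal(e1$elpd, sum(pointwise_log_predictive(one)))
  expect_equal(e1$elpd, sum(e1$pointwise))
  # identical models yield identical elpd under every method
  for (meth in c("lpd", "waic", "loo-is")) {
    ea <- elpd(base_fit, method = meth)
    eb <- elpd(base_fit, method = meth)
    expect_identical(ea$elpd, eb$elpd)
    expect_equal(ea$elpd, sum(ea$pointwise))
  }
  # loo-is never exceeds the in-sample lpd (leave-one-out penalisation)
  expect_lte(elpd(base_fit, "loo-is")$elpd, elpd(base_fit, "lpd")$elpd)
  # elpd is invariant to trial order
  st <- toy_strat(seed = 3, n_per_cell = 12)
  perm <- sample(length(st$y))
  st2 <- stratify(data.frame(participant = st$cells$participant[st$cells$j][
                               st$part_id][perm],
                             rt = st$y[perm],
                             length = st$cells$length[st$cell_id][perm],
                             band = st$cells$band[st$cell_id][perm],
                             occurrence = st$cells$band[st$cell_id][perm]))
  f2 <- quiet_fit(st2, "gamma", draws = 200, warmup = 300, chains = 2,
                  seed = 8)
  expect_equal(elpd(f2, "lpd")$elpd, elpd(base_fit, "lpd")$elpd,
               tolerance = 0.05)  # same data, same seed, same chains
})

test_that("model comparison reports paired differences against the best model", {
  ea <- elpd(base_fit, method = "lpd", label = "A")
  # self-comparison: zero difference, zero se
  cmp1 <- compare_elpd(ea, ea)
  expect_equal(cmp1$delta_elpd, c(0, 0))
  expect_equal(cmp1$se, c(0, 0))
  # constant pointwise offset: delta = -n * c, se = 0
  eb <- ea
  eb$label <- "B"
  eb$pointwise <- ea$pointwise - 0.3
  eb$elpd <- sum(eb$pointwise)
  cmp2 <- compare_elpd(ea, eb)
  expect_equal(cmp2$model, c("A", "B"))
  expect_equal(cmp2$delta_elpd[2], -0.3 * ea$n, tolerance = 1e-8)
  expect_equal(cmp2$se[2], 0, tolerance = 1e-8)
  # random pointwise perturbation: se matches the paired-difference formula
  set.seed(5)
  ec <- ea
  ec$label <- "C"
  ec$pointwise <- ea$pointwise + rnorm(ea$n, -0.1, 0.2)
  ec$elpd <- sum(ec$pointwise)
  cmp3 <- compare_elpd(ea, ec)
  dif <- ec$pointwise - ea$pointwise
  expect_equal(cmp3$se[cmp3$model == "C"], sqrt(ea$n) * sd(dif))
  # antisymmetry of the pairwise difference
  expect_equal(cmp3$delta_elpd[cmp3$model == "C"], sum(dif))
  # k identical models give k zeros
  cmpk <- compare_elpd(ea, ea, ea, ea)
  expect_equal(cmpk$delta_elpd, rep(0, 4))
  # mismatched trial sets are structural errors
  ed <- ea
  ed$n <- ea$n - 1L
  ed$pointwise <- ea$pointwise[-1]
  expect_error(compare_elpd(ea, ed), "different trial sets")
})

test_that("the Pareto tail fit recovers known generalised Pareto shapes", {
  set.seed(12)
  for (k in c(-0.2, 0.3, 0.7)) {
    u <- runif(4000)
    x <- if (abs(k) < 1e-12) -log1p(-u) else (1 / k) * ((1 - u)^(-k) - 1)
    f <- sdart:::gpd_fit(x)
    expect_lt(abs(f["k"] - k), 0.1)
    expect_lt(abs(f["sigma"] - 1), 0.15)
  }
})

test_that("PSIS smoothing preserves weight order and caps at the raw maximum", {
  set.seed(9)
  lr <- rt(600, df = 4)
  sm <- sdart:::psis_smooth(lr)
  expect_length(sm$lw, 600)
  expect_lte(max(sm$lw), max(lr) + 1e-12)
  # only the tail is touched; the bulk is untouched
  expect_gt(mean(sm$lw == lr), 0.75)
  # order of tail weights preserved
  ord <- order(lr)
  expect_true(all(diff(sm$lw[ord]) >= -1e-12))
})
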