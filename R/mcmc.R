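## Adaptive Metropolis-within-Gibbs sampler for the SDA hierarchy.
##
## Update blocks per sweep:
##   1. rho1, rho2: log-scale random-walk proposals for all occupied cells
##      at once (cells are conditionally independent given theta, psi),
##      plus a joint co-scaling pass along the rho1-rho2 posterior ridge;
##   2. theta_j: random walk on a logit transform of theta_j / min RT_j,
##      which enforces the posterior support 0 < theta_j < min_i y_ij
##      (log transform when a participant has no trials, e.g. prior-only);
##   3. a shift-transport move: theta_j + delta with every cell's location
##      parameter adjusted to keep the cell's expected RT fixed, a
##      deterministic diffeomorphism whose Jacobian enters the MH ratio
##      (decorrelates theta from rho, which single-site walks cannot);
##   4. psi: rate hyperparameters by conjugate Gibbs draws (Gamma
##      likelihood x Gamma prior), shape hyperparameters by log-scale
##      Metropolis, plus a joint (shape, rate) co-scaling move.
## Proposal scales adapt toward 0.44 acceptance during warmup only.
##
## Internally trials are sorted by cell (cells are ordered by participant,
## band, length), so per-cell and per-participant log-likelihood sums are
## contiguous-group cumulative sums, and densities are evaluated from
## per-cell constants with a cached log(y - theta).

sda_prep <- function(data, prior) {
  C <- nrow(data$cells)
  J <- length(data$participants)
  L <- length(data$lengths)
  li <- match(data$cells$length, data$lengths)
  ord <- order(data$cell_id)
  n_part <- tabulate(data$part_id, J)
  list(y = data$y[ord], cell = data$cell_id[ord], part = data$part_id[ord],
       C = C, J = J, L = L, li = li, cellj = data$cells$j,
       n_cell = data$cells$n,
       ends_cell = cumsum(data$cells$n),
       ends_part = cumsum(n_part),
       has_all_parts = all(n_part > 0L),
       m = participant_min_rt(data),
       cells_by_length = split(seq_len(C), li),
       ends_cellj = cumsum(tabulate(data$cells$j, J)),
       a = prior$a, b = prior$b, lengths = data$lengths,
       fixed = prior$psi_fixed)
}

## grouped sums over a vector already sorted so groups are contiguous;
## `ends` are the cumulative group sizes (last element = length(v))
gsum <- function(v, ends) {
  cs <- cumsum(v)[ends]
  c(cs[1L], diff(cs))
}

rowsum_vec <- function(v, g, n) {
  out <- numeric(n)
  if (length(v)) {
    rs <- rowsum(v, g)
    out[as.integer(rownames(rs))] <- rs[, 1L]
  }
  out
}

accept_prob <- function(logr) {
  ap <- exp(pmin(logr, 0))
  ap[!is.finite(ap)] <- 0
  ap
}

## method-of-moments cell initialisation on x = y - theta
init_rho <- function(x, cell, n_cell, family, C) {
  mx <- rowsum_vec(x, cell, C) / n_cell
  vx <- pmax(rowsum_vec(x^2, cell, C) / n_cell - mx^2, 1e-8)
  mx <- pmax(mx, 1e-6)
  if (family == "lognormal") {
    ml <- rowsum_vec(log(pmax(x, 1e-12)), cell, C) / n_cell
    vl <- pmax(rowsum_vec(log(pmax(x, 1e-12))^2, cell, C) / n_cell - ml^2, 1e-4)
    r1 <- pmax(ml, 1e-3); r2 <- vl
  } else if (family == "wald") {
    r1 <- mx; r2 <- pmax(mx^3 / vx, 1e-6)
  } else {
    r1 <- pmax(mx^2 / vx, 1e-4); r2 <- pmax(mx / vx, 1e-8)
  }
  list(r1 = pmin(pmax(r1, 1e-6), 1e8), r2 = pmin(pmax(r2, 1e-8), 1e8))
}

## moment-match a gamma to positive values (hyperparameter initialisation)
gamma_mom <- function(v) {
  m <- mean(v); s2 <- stats::var(v)
  if (!is.finite(s2) || s2 <= 0) s2 <- (0.2 * m)^2 + 1e-12
  c(shape = min(max(m^2 / s2, 1e-3), 1e6),
    rate = min(max(m / s2, 1e-9), 1e6))
}

sda_chain <- function(pre, family, draws, warmup, thin, seed) {
  set.seed(seed)
  C <- pre$C; J <- pre$J; L <- pre$L
  y <- pre$y; cell <- pre$cell; part <- pre$part; li <- pre$li
  m <- pre$m
  has_data <- length(y) > 0L && pre$has_all_parts
  if (length(y) > 0L && !pre$has_all_parts)
    stop("internal: participants without trials in a non-empty dataset")
  finite_m <- is.finite(m)
  ec <- pre$ends_cell; ep <- pre$ends_part
  LOG2PI <- log(2 * pi)

  ## per-trial log density from per-cell parameters, x > 0 assumed
  ld_cells <- function(x, lx, q1, q2) {
    if (family == "lognormal") {
      (-0.5 * (LOG2PI + log(q2)))[cell] - lx - (lx - q1[cell])^2 / (2 * q2)[cell]
    } else if (family == "wald") {
      (0.5 * (log(q2) - LOG2PI))[cell] - 1.5 * lx -
        (q2 / (2 * q1^2))[cell] * (x - q1[cell])^2 / x
    } else {
      (q1 * log(q2) - lgamma(q1))[cell] + (q1 - 1)[cell] * lx - q2[cell] * x
    }
  }

  ## ---- initial state, overdispersed across chains ----
  th <- ifelse(finite_m, m * stats::runif(J, 0.30, 0.85), stats::rexp(J) + 0.5)
  x <- if (has_data) y - th[part] else numeric(0)
  if (has_data) {
    r <- init_rho(x, cell, pre$n_cell, family, C)
    r1 <- r$r1 * exp(stats::rnorm(C, 0, 0.05))
    r2 <- r$r2 * exp(stats::rnorm(C, 0, 0.05))
  } else {
    r1 <- stats::rexp(C) + 0.5
    r2 <- stats::rexp(C) + 0.5
  }
  if (is.null(pre$fixed)) {
    A1 <- B1 <- A2 <- B2 <- numeric(L)
    for (l in seq_len(L)) {
      g1 <- gamma_mom(r1[pre$cells_by_length[[l]]])
      g2 <- gamma_mom(r2[pre$cells_by_length[[l]]])
      A1[l] <- g1[1]; B1[l] <- g1[2]; A2[l] <- g2[1]; B2[l] <- g2[2]
    }
    gt <- gamma_mom(th)
    Ath <- gt[1]; Bth <- gt[2]
    jit <- function(v) v * exp(stats::rnorm(length(v), 0, 0.1))
    A1 <- jit(A1); B1 <- jit(B1); A2 <- jit(A2); B2 <- jit(B2)
    Ath <- jit(Ath); Bth <- jit(Bth)
  } else {
    A1 <- pre$fixed$alpha1; B1 <- pre$fixed$beta1
    A2 <- pre$fixed$alpha2; B2 <- pre$fixed$beta2
    Ath <- pre$fixed$alpha_theta; Bth <- pre$fixed$beta_theta
  }

  u <- ifelse(finite_m, stats::qlogis(pmin(pmax(th / m, 1e-9), 1 - 1e-9)), log(th))
  lx <- if (has_data) log(x) else numeric(0)
  lf <- if (has_data) ld_cells(x, lx, r1, r2) else numeric(0)
  llc <- if (has_data) gsum(lf, ec) else numeric(C)

  ## proposal scales (log / logit random walks)
  s1 <- rep(0.25, C); s2 <- rep(0.25, C); s3 <- rep(0.25, C)
  sth <- rep(0.5, J)
  stm <- rep(5, J)               # shift-transport step (ms)
  sA <- rep(0.25, 4L * L + 1L)   # shape-hyperparameter scales
  sAB <- rep(0.25, 2L * L + 1L)  # joint (shape, rate) co-scaling scales

  S <- draws %/% thin
  out_th <- matrix(NA_real_, S, J)
  out_r1 <- matrix(NA_real_, S, C)
  out_r2 <- matrix(NA_real_, S, C)
  out_psi <- matrix(NA_real_, S, 4L * L + 2L)
  acc_cnt <- c(rho = 0, theta = 0)

  ## psi shape-block Metropolis on log scale; rate blocks conjugate Gibbs
  upd_shape <- function(A, B, nv, slog, a, b, s) {
    tgt <- function(Av) nv * (Av * log(B) - lgamma(Av)) + (Av - 1) * slog +
      stats::dgamma(Av, a, rate = b, log = TRUE)
    prop <- A * exp(stats::rnorm(1, 0, s))
    logr <- tgt(prop) - tgt(A) + log(prop) - log(A)
    ap <- accept_prob(logr)
    list(A = if (stats::runif(1) < ap) prop else A, ap = ap)
  }
  ## joint co-scaling of (shape, rate) along their posterior ridge
  upd_scaleAB <- function(A, B, nv, slog, sv, aA, bA, aB, bB, s) {
    tgt <- function(Av, Bv) nv * (Av * log(Bv) - lgamma(Av)) +
      (Av - 1) * slog - Bv * sv +
      stats::dgamma(Av, aA, rate = bA, log = TRUE) +
      stats::dgamma(Bv, aB, rate = bB, log = TRUE)
    sc <- exp(stats::rnorm(1, 0, s))
    logr <- tgt(A * sc, B * sc) - tgt(A, B) + 2 * log(sc)
    ap <- accept_prob(logr)
    if (stats::runif(1) < ap) list(A = A * sc, B = B * sc, ap = ap)
    else list(A = A, B = B, ap = ap)
  }

  total <- warmup + draws
  keep_i <- 0L
  for (t in seq_len(total)) {
    adapting <- t <= warmup
    step <- min(0.25, 2 / sqrt(t))

    ## ---- rho updates: single-component passes + joint co-scaling ----
    for (comp in 1:3) {
      if (comp == 3L) {
        sc <- exp(stats::rnorm(C, 0, s3))
        p1 <- r1 * sc; p2 <- r2 * sc
      } else {
        s <- if (comp == 1L) s1 else s2
        cur <- if (comp == 1L) r1 else r2
        prop <- cur * exp(stats::rnorm(C, 0, s))
        if (comp == 1L) { p1 <- prop; p2 <- r2 } else { p1 <- r1; p2 <- prop }
      }
      if (has_data) {
        lfp <- ld_cells(x, lx, p1, p2)
        llcp <- gsum(lfp, ec)
      } else llcp <- llc
      if (comp == 3L) {
        logr <- (llcp - llc) +
          stats::dgamma(p1, A1[li], rate = B1[li], log = TRUE) -
          stats::dgamma(r1, A1[li], rate = B1[li], log = TRUE) +
          stats::dgamma(p2, A2[li], rate = B2[li], log = TRUE) -
          stats::dgamma(r2, A2[li], rate = B2[li], log = TRUE) +
          2 * log(sc)
      } else {
        Ac <- if (comp == 1L) A1[li] else A2[li]
        Bc <- if (comp == 1L) B1[li] else B2[li]
        logr <- (llcp - llc) +
          stats::dgamma(prop, Ac, rate = Bc, log = TRUE) -
          stats::dgamma(cur, Ac, rate = Bc, log = TRUE) +
          log(prop) - log(cur)
      }
      ap <- accept_prob(logr)
      acc <- stats::runif(C) < ap
      if (any(acc)) {
        if (comp == 3L) {
          r1[acc] <- p1[acc]
          r2[acc] <- p2[acc]
        } else if (comp == 1L) r1[acc] <- p1[acc] else r2[acc] <- p2[acc]
        llc[acc] <- llcp[acc]
        if (has_data) {
          hit <- acc[cell]
          lf[hit] <- lfp[hit]
        }
      }
      if (adapting) {
        if (comp == 3L) {
          s3 <- pmin(pmax(s3 * exp(step * (ap - 0.44)), 1e-3), 10)
        } else {
          s <- pmin(pmax(s * exp(step * (ap - 0.44)), 1e-3), 10)
          if (comp == 1L) s1 <- s else s2 <- s
        }
      }
      if (!adapting) acc_cnt["rho"] <- acc_cnt["rho"] + mean(ap) / 3
    }

    ## ---- theta updates (one vectorised pass; thp < m by construction) ----
    up <- u + stats::rnorm(J, 0, sth)
    thp <- ifelse(finite_m, m * stats::plogis(up), exp(up))
    if (has_data) {
      xp <- y - thp[part]
      lxp <- log(xp)
      lfp <- ld_cells(xp, lxp, r1, r2)
      llj <- gsum(lf, ep)
      lljp <- gsum(lfp, ep)
    } else llj <- lljp <- numeric(J)
    jac_cur <- ifelse(finite_m, log(th) + log(m - th), log(th))
    jac_prop <- ifelse(finite_m, log(thp) + log(pmax(m - thp, 1e-300)), log(thp))
    logr <- (lljp - llj) +
      stats::dgamma(thp, Ath, rate = Bth, log = TRUE) -
      stats::dgamma(th, Ath, rate = Bth, log = TRUE) +
      jac_prop - jac_cur
    ap <- accept_prob(logr)
    acc <- stats::runif(J) < ap
    if (any(acc)) {
      th[acc] <- thp[acc]
      u[acc] <- up[acc]
      if (has_data) {
        hit <- acc[part]
        x[hit] <- xp[hit]
        lx[hit] <- lxp[hit]
        lf[hit] <- lfp[hit]
        llc <- gsum(lf, ec)
      }
    }
    if (adapting) sth <- pmin(pmax(sth * exp(step * (ap - 0.44)), 1e-3), 10)
    else acc_cnt["theta"] <- acc_cnt["theta"] + mean(ap)

    ## ---- shift-transport move ----
    if (has_data) {
      delta <- stats::rnorm(J, 0, stm)
      thp <- th + delta
      dcell <- delta[pre$cellj]
      if (family == "lognormal") {
        mc <- exp(r1 + r2 / 2)
        mcp <- mc - dcell
        r1p <- log(pmax(mcp, 1e-300)) - r2 / 2
        jac_c <- log(mc) - log(pmax(mcp, 1e-300))
        p1 <- r1p; p2 <- r2
        ok_c <- mcp > 0 & r1p > 0  # lognormal mu must stay positive (prior)
      } else if (family == "wald") {
        p1 <- r1 - dcell; p2 <- r2
        jac_c <- 0 * dcell
        ok_c <- p1 > 0
        p1 <- pmax(p1, 1e-300)
      } else {
        mc <- r1 / r2
        mcp <- mc - dcell
        p2 <- r1 / pmax(mcp, 1e-300)
        p1 <- r1
        jac_c <- 2 * (log(p2) - log(r2))
        ok_c <- mcp > 0
      }
      ok_j <- (thp > 0) & (!finite_m | thp < m) &
        (gsum(as.numeric(!ok_c), pre$ends_cellj) == 0)
      xp <- pmax(y - thp[part], 1e-300)  # clamped; invalid js are rejected
      lxp <- log(xp)
      lfp <- ld_cells(xp, lxp, p1, p2)
      llj <- gsum(lf, ep)
      lljp <- gsum(lfp, ep)
      pri_c <- if (family == "gamma") {
        stats::dgamma(p2, A2[li], rate = B2[li], log = TRUE) -
          stats::dgamma(r2, A2[li], rate = B2[li], log = TRUE)
      } else {
        stats::dgamma(pmax(p1, 1e-300), A1[li], rate = B1[li], log = TRUE) -
          stats::dgamma(r1, A1[li], rate = B1[li], log = TRUE)
      }
      pri_c[!ok_c] <- 0  # masked below via ok_j
      logr <- (lljp - llj) +
        stats::dgamma(thp, Ath, rate = Bth, log = TRUE) -
        stats::dgamma(th, Ath, rate = Bth, log = TRUE) +
        gsum(pri_c + jac_c, pre$ends_cellj)
      logr[!ok_j] <- -Inf
      ap <- accept_prob(logr)
      acc <- stats::runif(J) < ap
      if (any(acc)) {
        th[acc] <- thp[acc]
        u[acc] <- ifelse(finite_m[acc], stats::qlogis(
          pmin(pmax(th[acc] / m[acc], 1e-12), 1 - 1e-12)), log(th[acc]))
        ca <- acc[pre$cellj]
        if (family == "gamma") r2[ca] <- p2[ca] else r1[ca] <- p1[ca]
        hit <- acc[part]
        x[hit] <- xp[hit]
        lx[hit] <- lxp[hit]
        lf[hit] <- lfp[hit]
        llc <- gsum(lf, ec)
      }
      if (adapting) stm <- pmin(pmax(stm * exp(step * (ap - 0.30)), 1e-3), 200)
    }

    ## ---- psi updates ----
    if (is.null(pre$fixed)) {
      k <- 0L; k2 <- 0L
      for (l in seq_len(L)) {
        idx <- pre$cells_by_length[[l]]
        nv <- length(idx)
        for (comp in 1:2) {
          v <- if (comp == 1L) r1[idx] else r2[idx]
          A <- if (comp == 1L) A1[l] else A2[l]
          aA <- pre$a[paste0("alpha", comp, "_", pre$lengths[l])]
          bA <- pre$b[paste0("alpha", comp, "_", pre$lengths[l])]
          aB <- pre$a[paste0("beta", comp, "_", pre$lengths[l])]
          bB <- pre$b[paste0("beta", comp, "_", pre$lengths[l])]
          B <- stats::rgamma(1, shape = aB + nv * A, rate = bB + sum(v))
          k <- k + 1L
          r <- upd_shape(A, B, nv, sum(log(v)), aA, bA, sA[k])
          k2 <- k2 + 1L
          r2ab <- upd_scaleAB(r$A, B, nv, sum(log(v)), sum(v),
                              aA, bA, aB, bB, sAB[k2])
          if (adapting) {
            sA[k] <- min(max(sA[k] * exp(step * (r$ap - 0.44)), 1e-3), 10)
            sAB[k2] <- min(max(sAB[k2] * exp(step * (r2ab$ap - 0.44)), 1e-3), 10)
          }
          if (comp == 1L) { A1[l] <- r2ab$A; B1[l] <- r2ab$B }
          else { A2[l] <- r2ab$A; B2[l] <- r2ab$B }
        }
      }
      aA <- pre$a["alpha_theta"]; bA <- pre$b["alpha_theta"]
      aB <- pre$a["beta_theta"]; bB <- pre$b["beta_theta"]
      Bth <- stats::rgamma(1, shape = aB + J * Ath, rate = bB + sum(th))
      k <- k + 1L
      r <- upd_shape(Ath, Bth, J, sum(log(th)), aA, bA, sA[k])
      k2 <- k2 + 1L
      r2ab <- upd_scaleAB(r$A, Bth, J, sum(log(th)), sum(th),
                          aA, bA, aB, bB, sAB[k2])
      if (adapting) {
        sA[k] <- min(max(sA[k] * exp(step * (r$ap - 0.44)), 1e-3), 10)
        sAB[k2] <- min(max(sAB[k2] * exp(step * (r2ab$ap - 0.44)), 1e-3), 10)
      }
      Ath <- r2ab$A; Bth <- r2ab$B
    }

    if (!adapting && ((t - warmup) %% thin == 0L)) {
      keep_i <- keep_i + 1L
      out_th[keep_i, ] <- th
      out_r1[keep_i, ] <- r1
      out_r2[keep_i, ] <- r2
      out_psi[keep_i, ] <- c(psi_interleave(A1, B1, A2, B2), Ath, Bth)
    }
  }

  list(theta = out_th[seq_len(keep_i), , drop = FALSE],
       rho1 = out_r1[seq_len(keep_i), , drop = FALSE],
       rho2 = out_r2[seq_len(keep_i), , drop = FALSE],
       psi = out_psi[seq_len(keep_i), , drop = FALSE],
       accept = acc_cnt / max(draws, 1))
}

## order matching psi_names(): per length, (alpha1, beta1, alpha2, beta2)
psi_interleave <- function(A1, B1, A2, B2) {
  L <- length(A1)
  v <- numeric(4L * L)
  for (l in seq_len(L)) v[(4L * (l - 1L)) + 1:4] <- c(A1[l], B1[l], A2[l], B2[l])
  v
}
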