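#' Posterior predictive replicated datasets
#'
#' Draws \code{R} replicated datasets from the posterior predictive
#' distribution: each replicate selects one joint posterior draw and
#' samples every cell's RTs from the shifted family at that draw's
#' \eqn{(\theta_j, \rho_{jkl})}; cell sizes match the observed data, so
#' replicates are cell-aligned with the trial vector.
#'
#' @param fit an \code{\link{sda_fit}}.
#' @param R number of replicates.
#' @param seed integer seed (reproducible replicates).
#' @return object of class \code{"sda_ppred"}: list with \code{yrep}
#'   (trials x R matrix, rows aligned with \code{fit$data$y}), the draw
#'   index used per replicate, and the cell structure.
#' @export
posterior_predict <- function(fit, R = 100, seed = NULL) {
  stopifnot(inherits(fit, "sda_fit"), R >= 1)
  d <- fit$data
  if (!length(d$y)) stop("no observed trials to align replicates with",
                         call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  S <- nrow(fit$theta)
  draw_idx <- sample.int(S, R, replace = TRUE)
  n <- length(d$y)
  yrep <- matrix(NA_real_, n, R)
  fam <- as.character(fit$family)
  for (r in seq_len(R)) {
    s <- draw_idx[r]
    th <- fit$theta[s, d$cells$j][d$cell_id]
    r1 <- fit$rho1[s, d$cell_id]
    r2 <- fit$rho2[s, d$cell_id]
    yrep[, r] <- rshifted(n, fam, th, r1, r2)
  }
  structure(list(yrep = yrep, draw_idx = draw_idx, cell_id = d$cell_id,
                 cells = d$cells, family = fit$family),
            class = "sda_ppred")
}

#' @export
print.sda_ppred <- function(x, ...) {
  cat("posterior predictive replicates:", ncol(x$yrep), "datasets x",
      nrow(x$yrep), "trials\n")
  invisible(x)
}

#' Posterior predictive p-values
#'
#' For each (participant, band, length) cell, the proportion of replicated
#' datasets whose cell statistic (default: the mean) is greater than or
#' equal to the observed cell statistic; ties count toward the numerator.
#' Values near 0.5 indicate good fit; near 0 or 1, misfit.
#'
#' @param fit an \code{\link{sda_fit}}.
#' @param ppred an \code{"sda_ppred"} from \code{\link{posterior_predict}};
#'   generated on the fly (with \code{R} replicates and \code{seed}) when
#'   omitted.
#' @param statistic cell statistic, default \code{mean}.
#' @param R,seed used only when \code{ppred} is missing.
#' @param by \code{"cell"} (finest) or \code{"participant"} aggregation
#'   level for the statistic.
#' @return data.frame with the grouping columns, \code{n}, and \code{ppp};
#'   attribute \code{R}.
#' @export
ppp_values <- function(fit, ppred = NULL, statistic = mean, R = 200,
                       seed = NULL, by = c("cell", "participant")) {
  by <- match.arg(by)
  if (is.null(ppred)) ppred <- posterior_predict(fit, R = R, seed = seed)
  d <- fit$data
  g <- if (by == "cell") d$cell_id else d$part_id
  ng <- if (by == "cell") nrow(d$cells) else length(d$participants)
  obs <- vapply(split(d$y, g), statistic, numeric(1))
  reps <- apply(ppred$yrep, 2, function(col)
    vapply(split(col, g), statistic, numeric(1)))
  reps <- matrix(reps, nrow = length(obs))
  ppp <- rowMeans(reps >= obs)
  out <- if (by == "cell") {
    data.frame(d$cells[c("participant", "band", "length", "n")], ppp = ppp)
  } else {
    data.frame(participant = d$participants[as.integer(names(obs))],
               n = as.integer(table(g)), ppp = ppp)
  }
  attr(out, "R") <- ncol(ppred$yrep)
  out
}

#' Pointwise log predictive density
#'
#' For each trial, \eqn{\log S^{-1} \sum_s f(y_i \mid \theta^{(s)},
#' \rho^{(s)})}: the log of the posterior-averaged family density
#' (log-mean-exp over draws). Trials below every drawn shift contribute
#' \code{-Inf} and are flagged.
#'
#' @param fit an \code{\link{sda_fit}}.
#' @return numeric vector, one value per trial; attribute
#'   \code{n_unsupported} counts \code{-Inf} trials.
#' @export
pointwise_log_predictive <- function(fit) {
  lm <- loglik_matrix(fit)
  out <- row_log_mean_exp(lm)
  attr(out, "n_unsupported") <- sum(!is.finite(out))
  out
}

## trials x draws matrix of log f(y_i | draw s), chunked for memory
loglik_matrix <- function(fit, chunk = 500L) {
  d <- fit$data
  S <- nrow(fit$theta)
  n <- length(d$y)
  fam <- as.character(fit$family)
  out <- matrix(NA_real_, n, S)
  pj <- d$cells$j[d$cell_id]   # participant per trial
  for (s0 in seq(1L, S, by = chunk)) {
    ss <- s0:min(s0 + chunk - 1L, S)
    ## n x |ss| blocks, gathered row-wise then one vectorised pass
    X <- d$y - t(fit$theta[ss, , drop = FALSE])[pj, , drop = FALSE]
    R1 <- t(fit$rho1[ss, , drop = FALSE])[d$cell_id, , drop = FALSE]
    R2 <- t(fit$rho2[ss, , drop = FALSE])[d$cell_id, , drop = FALSE]
    out[, ss] <- shifted_logdens(X, fam, R1, R2)
  }
  out
}

## row-wise log-mean-exp of a matrix (finite-safe)
row_log_mean_exp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), na.rm = TRUE))
  out <- mx + log(rowMeans(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

#' Expected log pointwise predictive density
#'
#' Estimates the elpd of a fitted model. \code{method = "loo-is"} (default)
#' uses Pareto-smoothed importance-sampling leave-one-out with a per-trial
#' tail-shape diagnostic (\code{k > 0.7} flags unreliable points);
#' \code{"waic"} subtracts the pointwise posterior variance of the log
#' density; \code{"lpd"} is the in-sample log predictive density.
#'
#' @param fit an \code{\link{sda_fit}}.
#' @param method \code{"loo-is"}, \code{"waic"} or \code{"lpd"}.
#' @param label model label used in comparison tables; defaults to the
#'   family name.
#' @return object of class \code{"sda_elpd"}: list with \code{label},
#'   \code{method}, \code{elpd} (total), \code{pointwise}, \code{se}
#'   (of the total), and \code{flags} (logical per trial: unreliable
#'   importance weights or unsupported trials).
#' @export
elpd <- function(fit, method = c("loo-is", "waic", "lpd"), label = NULL) {
  method <- match.arg(method)
  if (is.null(label)) label <- as.character(fit$family)
  lm <- loglik_matrix(fit)
  n <- nrow(lm); S <- ncol(lm)
  lpd_i <- row_log_mean_exp(lm)
  flags <- !is.finite(lpd_i)
  if (method == "lpd") {
    pw <- lpd_i
  } else if (method == "waic") {
    pw <- lpd_i - (rowMeans(lm^2) - rowMeans(lm)^2) * S / (S - 1)
  } else {
    pw <- numeric(n)
    khat <- numeric(n)
    for (i in seq_len(n)) {
      lr <- -lm[i, ]              # log 1/f: leave-one-out ratios
      if (all(is.finite(lr))) {
        sm <- psis_smooth(lr)
        lw <- sm$lw - log_sum_exp(sm$lw)
        pw[i] <- log_sum_exp(lw + lm[i, ])
        khat[i] <- sm$k
      } else {
        pw[i] <- -Inf
        khat[i] <- Inf
      }
    }
    flags <- flags | khat > 0.7
  }
  total <- sum(pw)
  structure(list(label = label, method = method, elpd = total,
                 pointwise = pw, se = sqrt(n) * stats::sd(pw),
                 n = n, flags = flags),
            class = "sda_elpd")
}

#' @export
print.sda_elpd <- function(x, ...) {
  cat("elpd (", x$method, ") for model '", x$label, "': ",
      format(x$elpd, digits = 8), " (se ", round(x$se, 1), ", n = ", x$n,
      ")\n", sep = "")
  if (any(x$flags)) cat(sum(x$flags), "pointwise estimate(s) flagged\n")
  invisible(x)
}

#' Rank models by elpd difference
#'
#' The model with the highest elpd is the reference and is reported with
#' \eqn{\Delta}elpd = 0 and se = 0; every other model's \eqn{\Delta}elpd is
#' its elpd minus the reference elpd (\eqn{\le 0}), with the paired
#' standard error \eqn{\sqrt{n}\,\mathrm{sd}(\text{pointwise differences})}.
#' Models are sorted by decreasing elpd (increasing \eqn{|\Delta|}).
#'
#' @param ... \code{sda_elpd} objects (or a single list of them), all
#'   computed on the identical trial set.
#' @return data.frame of class \code{"sda_model_comparison"} with columns
#'   \code{model}, \code{delta_elpd}, \code{se}, \code{elpd}.
#' @export
compare_elpd <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && !inherits(mods[[1]], "sda_elpd")) mods <- mods[[1]]
  stopifnot(length(mods) >= 1, all(vapply(mods, inherits, TRUE, "sda_elpd")))
  ns <- vapply(mods, `[[`, 1L, "n")
  if (length(unique(ns)) != 1L)
    stop("models were evaluated on different trial sets", call. = FALSE)
  totals <- vapply(mods, `[[`, numeric(1), "elpd")
  ref <- which.max(totals)
  n <- ns[1]
  delta <- totals - totals[ref]
  se <- vapply(seq_along(mods), function(m) {
    if (m == ref) return(0)
    dif <- mods[[m]]$pointwise - mods[[ref]]$pointwise
    sqrt(n) * stats::sd(dif)
  }, numeric(1))
  out <- data.frame(model = vapply(mods, `[[`, "", "label"),
                    delta_elpd = delta, se = se, elpd = totals,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$elpd), ]
  rownames(out) <- NULL
  class(out) <- c("sda_model_comparison", "data.frame")
  attr(out, "reference") <- mods[[ref]]$label
  out
}

#' @export
print.sda_model_comparison <- function(x, ...) {
  cat("model comparison (reference: ", attr(x, "reference"), ")\n", sep = "")
  print.data.frame(cbind(x["model"],
                         delta_elpd = round(x$delta_elpd, 2),
                         se = round(x$se, 2)), row.names = FALSE)
  invisible(x)
}
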