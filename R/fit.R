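#' Fit the stratified distributional model
#'
#' Draws from the joint posterior of the SDA hierarchy for one shifted
#' family: participant shifts \eqn{\theta_j}, cell parameters
#' \eqn{\rho_{jkl}}, and hyperparameters \eqn{\psi}, by adaptive
#' Metropolis-within-Gibbs MCMC (see \code{vignette("sda-methods")}).
#' Shifts are sampled on a logit-transformed scale that enforces
#' \eqn{0 < \theta_j < \min_i y_{ij..}}; cell parameters are proposed on
#' the log scale; rate hyperparameters use conjugate Gibbs draws.
#'
#' Split-chain R-hat is computed for every scalar quantity; a warning is
#' raised when any exceeds 1.01 (draws are still returned, flagged in
#' \code{$diagnostics$converged}).
#'
#' @param data a stratified dataset from \code{\link{stratify}}. Zero-trial
#'   data yields draws from the prior (useful for prior predictive checks).
#' @param family an \code{\link{sda_family}} or name.
#' @param prior an \code{\link{sda_prior}}; default
#'   \code{sda_prior(data$lengths)}.
#' @param draws post-warmup draws per chain.
#' @param warmup adaptation iterations per chain (discarded).
#' @param chains number of independent chains.
#' @param thin keep every \code{thin}-th draw.
#' @param seed integer seed; chains use distinct derived seeds.
#' @param min_cell_n cells with fewer trials are still modelled (the
#'   hierarchy shrinks them) but flagged in \code{$sparse_cells}.
#' @return object of class \code{"sda_fit"}: draw matrices \code{theta}
#'   (draws x participants), \code{rho1}, \code{rho2} (draws x cells),
#'   \code{psi}, a \code{chain} index per draw, the data, family, prior,
#'   acceptance rates and diagnostics.
#' @seealso \code{\link{posterior_medians}}, \code{\link{ppp_values}},
#'   \code{\link{elpd}}, \code{\link{compare_elpd}}
#' @export
sda_fit <- function(data, family, prior = NULL, draws = 1000, warmup = 1000,
                    chains = 4, thin = 1, seed = 1, min_cell_n = 5) {
  stopifnot(inherits(data, "sda_data"), draws >= 1, chains >= 1, warmup >= 0)
  family <- sda_family(as.character(family))
  if (is.null(prior)) prior <- sda_prior(data$lengths)
  if (!identical(prior$lengths, data$lengths))
    stop("prior lengths ", paste(prior$lengths, collapse = ","),
         " do not match data lengths ", paste(data$lengths, collapse = ","),
         call. = FALSE)
  pre <- sda_prep(data, prior)
  res <- lapply(seq_len(chains), function(ch)
    sda_chain(pre, as.character(family), draws, warmup, thin,
              seed = as.integer(seed) + 7919L * ch))
  theta <- do.call(rbind, lapply(res, `[[`, "theta"))
  rho1 <- do.call(rbind, lapply(res, `[[`, "rho1"))
  rho2 <- do.call(rbind, lapply(res, `[[`, "rho2"))
  psi <- do.call(rbind, lapply(res, `[[`, "psi"))
  chain <- rep(seq_len(chains), vapply(res, function(r) nrow(r$theta), 1L))
  colnames(theta) <- as.character(data$participants)
  cell_key <- paste(data$cells$participant, data$cells$band,
                    data$cells$length, sep = ":")
  colnames(rho1) <- colnames(rho2) <- cell_key
  colnames(psi) <- psi_names(data$lengths)

  rhat <- c(diag_over(theta, chain, split_rhat),
            diag_over(rho1, chain, split_rhat),
            diag_over(rho2, chain, split_rhat),
            if (is.null(prior$psi_fixed)) diag_over(psi, chain, split_rhat))
  names(rhat) <- c(paste0("theta[", colnames(theta), "]"),
                   paste0("rho1[", cell_key, "]"),
                   paste0("rho2[", cell_key, "]"),
                   if (is.null(prior$psi_fixed)) colnames(psi))
  converged <- all(is.na(rhat) | rhat <= 1.01)
  if (!converged && chains > 1)
    warning("split R-hat > 1.01 for ", sum(rhat > 1.01, na.rm = TRUE),
            " quantities (max ", round(max(rhat, na.rm = TRUE), 3),
            "); consider longer chains", call. = FALSE)

  structure(list(theta = theta, rho1 = rho1, rho2 = rho2, psi = psi,
                 chain = chain, family = family, data = data, prior = prior,
                 seed = as.integer(seed), chains = chains, warmup = warmup,
                 thin = thin,
                 accept = Reduce(`+`, lapply(res, `[[`, "accept")) / chains,
                 sparse_cells = data$cells$cell[data$cells$n < min_cell_n],
                 diagnostics = list(rhat = rhat, converged = converged)),
            class = "sda_fit")
}

#' Posterior medians of model quantities
#'
#' One median per participant (\code{"theta"}), per cell (\code{"rho1"},
#' \code{"rho2"}), per cell expected RT (\code{"cell_mean"}, which applies
#' \code{\link{shifted_mean}} draw-wise), or per hyperparameter
#' (\code{"psi"}). With an even number of draws the usual midpoint
#' convention applies (mean of the two central order statistics).
#'
#' @param fit an \code{\link{sda_fit}}.
#' @param quantity one of \code{"theta"}, \code{"rho1"}, \code{"rho2"},
#'   \code{"cell_mean"}, \code{"psi"}.
#' @return named numeric vector of medians.
#' @export
posterior_medians <- function(fit, quantity = c("theta", "rho1", "rho2",
                                                "cell_mean", "psi")) {
  quantity <- match.arg(quantity)
  m <- if (quantity == "cell_mean") cell_mean_draws(fit) else fit[[quantity]]
  apply(m, 2, stats::median)
}

## draws x cells matrix of expected RTs theta_j + E[X | rho_jkl]
cell_mean_draws <- function(fit) {
  thm <- fit$theta[, fit$data$cells$j, drop = FALSE]
  out <- thm + switch(as.character(fit$family),
    lognormal = exp(fit$rho1 + fit$rho2 / 2),
    wald = fit$rho1,
    gamma = fit$rho1 / fit$rho2)
  colnames(out) <- colnames(fit$rho1)
  out
}

#' Central credible intervals
#'
#' @param fit an \code{\link{sda_fit}}.
#' @param quantity as in \code{\link{posterior_medians}}.
#' @param level central interval mass, default 0.95.
#' @return matrix with columns \code{lower}, \code{median}, \code{upper}.
#' @export
credible_interval <- function(fit, quantity = "theta", level = 0.95) {
  m <- if (quantity == "cell_mean") cell_mean_draws(fit) else fit[[quantity]]
  a <- (1 - level) / 2
  t(apply(m, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)) |>
    `colnames<-`(c("lower", "median", "upper"))
}

#' @export
print.sda_fit <- function(x, ...) {
  cat("SDA fit: shifted ", as.character(x$family), " family\n", sep = "")
  cat("  ", length(x$data$y), " trials, ", length(x$data$participants),
      " participants, ", nrow(x$data$cells), " cells\n", sep = "")
  cat("  ", nrow(x$theta), " draws (", x$chains, " chain(s), warmup ",
      x$warmup, ")\n", sep = "")
  rh <- x$diagnostics$rhat
  cat("  max split R-hat: ",
      if (all(is.na(rh))) "NA" else round(max(rh, na.rm = TRUE), 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.sda_fit <- function(object, level = 0.95, ...) {
  th <- credible_interval(object, "theta", level)
  cm <- credible_interval(object, "cell_mean", level)
  out <- list(family = as.character(object$family),
              theta = data.frame(participant = object$data$participants, th),
              cell_mean = data.frame(object$data$cells[c("participant", "band",
                                                         "length", "n")], cm),
              rhat_max = suppressWarnings(max(object$diagnostics$rhat,
                                              na.rm = TRUE)),
              accept = object$accept,
              sparse_cells = object$sparse_cells)
  class(out) <- "summary.sda_fit"
  out
}

#' @export
print.summary.sda_fit <- function(x, ...) {
  cat("SDA fit (", x$family, " family)\n\n", sep = "")
  cat("Participant shifts theta_j (ms):\n")
  print(utils::head(x$theta, 10), row.names = FALSE)
  if (nrow(x$theta) > 10) cat("  ... ", nrow(x$theta) - 10, " more\n")
  cat("\nCell expected RTs (ms), first cells:\n")
  print(utils::head(x$cell_mean, 10), row.names = FALSE)
  cat("\nmax split R-hat: ", round(x$rhat_max, 3),
      "; mean acceptance (rho, theta): ",
      paste(round(x$accept, 2), collapse = ", "), "\n", sep = "")
  if (length(x$sparse_cells))
    cat(length(x$sparse_cells), "sparse cell(s) flagged (hierarchically shrunk)\n")
  invisible(x)
}

#' @export
coef.sda_fit <- function(object, ...) {
  list(theta = posterior_medians(object, "theta"),
       rho1 = posterior_medians(object, "rho1"),
       rho2 = posterior_medians(object, "rho2"))
}

#' Posterior expected response times
#'
#' \code{type = "mean"} returns the posterior median of each cell's expected
#' RT \eqn{\theta_j + E[X]}; \code{type = "quantile"} returns posterior
#' medians of the RT distribution quantile \code{p} per cell.
#'
#' @param object an \code{\link{sda_fit}}.
#' @param type \code{"mean"} or \code{"quantile"}.
#' @param p RT quantile when \code{type = "quantile"}.
#' @param ... unused.
#' @return data.frame of cells with a \code{fit} column (ms).
#' @export
predict.sda_fit <- function(object, type = c("mean", "quantile"), p = 0.5, ...) {
  type <- match.arg(type)
  val <- if (type == "mean") {
    posterior_medians(object, "cell_mean")
  } else {
    th <- posterior_medians(object, "theta")[object$data$cells$j]
    r1 <- posterior_medians(object, "rho1")
    r2 <- posterior_medians(object, "rho2")
    q <- switch(as.character(object$family),
      lognormal = stats::qlnorm(p, r1, sqrt(r2)),
      wald = statmod::qinvgauss(p, mean = r1, shape = r2),
      gamma = stats::qgamma(p, shape = r1, rate = r2))
    th + q
  }
  data.frame(object$data$cells[c("participant", "band", "length", "n")],
             fit = as.numeric(val))
}

#' Posterior predictive simulation (S3 interface)
#'
#' Each replicate selects one posterior draw and samples every cell's RTs
#' from the shifted family at that draw's parameters, so replicate r has
#' the observed cell sizes. Thin wrapper around
#' \code{\link{posterior_predict}}.
#'
#' @param object an \code{\link{sda_fit}}.
#' @param nsim number of replicated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return see \code{\link{posterior_predict}}.
#' @export
simulate.sda_fit <- function(object, nsim = 1, seed = NULL, ...) {
  posterior_predict(object, R = nsim, seed = seed)
}

#' Randomised quantile residuals
#'
#' For each trial, the fitted-family CDF evaluated at the observed RT
#' (using posterior-median parameters) mapped through the standard normal
#' quantile function; approximately N(0,1) under a well-specified model.
#'
#' @param object an \code{\link{sda_fit}}.
#' @param ... unused.
#' @return numeric vector, one residual per trial.
#' @export
residuals.sda_fit <- function(object, ...) {
  d <- object$data
  th <- posterior_medians(object, "theta")[d$part_id]
  r1 <- posterior_medians(object, "rho1")[d$cell_id]
  r2 <- posterior_medians(object, "rho2")[d$cell_id]
  u <- pshifted(d$y, object$family, th, r1, r2)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Plot an SDA fit
#'
#' \code{which = "theta"} shows the distribution of posterior-median shifts
#' across participants; \code{which = "cell_mean"} shows posterior-median
#' expected RTs against frequency band (one line per length, averaged over
#' participants).
#'
#' @param x an \code{\link{sda_fit}}.
#' @param which \code{"theta"} or \code{"cell_mean"}.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.sda_fit <- function(x, which = c("theta", "cell_mean"), ...) {
  which <- match.arg(which)
  if (which == "theta") {
    graphics::hist(posterior_medians(x, "theta"), breaks = "FD",
                   main = paste("Posterior median shifts,",
                                as.character(x$family)),
                   xlab = "theta_j (ms)", ...)
  } else {
    pm <- posterior_medians(x, "cell_mean")
    cells <- x$data$cells
    agg <- stats::aggregate(pm, list(band = cells$band, length = cells$length),
                            mean)
    lens <- sort(unique(agg$length))
    graphics::plot(range(agg$band), range(agg$x), type = "n",
                   xlab = "frequency band", ylab = "expected RT (ms)",
                   main = paste("Cell means,", as.character(x$family)), ...)
    for (i in seq_along(lens)) {
      a <- agg[agg$length == lens[i], ]
      graphics::lines(a$band, a$x, col = i, type = "b", pch = 16)
    }
    graphics::legend("topright", legend = paste("len", lens),
                     col = seq_along(lens), lty = 1, pch = 16, bty = "n")
  }
  invisible(x)
}
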