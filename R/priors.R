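#' Hyperprior configuration
#'
#' The hierarchy places gamma priors on every positive quantity: cell-level
#' parameters \eqn{\rho_{jkl}[1] \sim Gamma(\alpha_l[1], \beta_l[1])},
#' \eqn{\rho_{jkl}[2] \sim Gamma(\alpha_l[2], \beta_l[2])} (length-specific),
#' shifts \eqn{\theta_j \sim Gamma(\alpha_\theta, \beta_\theta)}, and each
#' element \eqn{\phi_i} of the hyperparameter set
#' \eqn{\psi = (\alpha_l[1], \beta_l[1], \alpha_l[2], \beta_l[2],
#' \alpha_\theta, \beta_\theta)} in turn carries a
#' \eqn{Gamma(a_i, b_i)} hyperprior fixed before the analysis. With seven
#' modelled lengths \eqn{\psi} has 30 elements. The default \eqn{a_i = b_i}
#' = 0.01 makes every hyperprior mean 1 with variance 100: weakly
#' informative on all scales, and deliberately diffuse for the shift
#' hyperpair so that \eqn{\theta_j} is essentially unconstrained a priori.
#'
#' @param lengths integer vector of modelled word lengths (subset of 4:10).
#' @param a,b default hyperprior shape and rate applied to every element of
#'   \eqn{\psi}; scalars or named vectors over
#'   \code{names(sda_prior(lengths)$a)} for element-wise control.
#' @param psi_fixed optional list fixing \eqn{\psi} entirely (elements
#'   \code{alpha1}, \code{beta1}, \code{alpha2}, \code{beta2} -- vectors
#'   over \code{lengths} -- plus \code{alpha_theta}, \code{beta_theta}).
#'   When supplied the sampler treats \eqn{\psi} as known constants.
#' @return object of class \code{"sda_prior"}: list with \code{lengths},
#'   named vectors \code{a}, \code{b} (one entry per element of
#'   \eqn{\psi}), and \code{psi_fixed}.
#' @examples
#' sda_prior(4:10)          # the full 30-element configuration
#' sda_prior(c(4, 7, 10))   # 14 elements for three lengths
#' @export
sda_prior <- function(lengths = 4:10, a = 0.01, b = 0.01, psi_fixed = NULL) {
  lengths <- sort(unique(as.integer(lengths)))
  nm <- psi_names(lengths)
  av <- rep_len(0, length(nm)); names(av) <- nm
  bv <- av
  av[] <- if (length(a) == 1L) a else a[nm]
  bv[] <- if (length(b) == 1L) b else b[nm]
  if (any(!is.finite(av)) || any(av <= 0) || any(!is.finite(bv)) || any(bv <= 0))
    stop("all hyperprior shapes/rates must be positive", call. = FALSE)
  if (!is.null(psi_fixed)) {
    need <- c("alpha1", "beta1", "alpha2", "beta2", "alpha_theta", "beta_theta")
    if (!all(need %in% names(psi_fixed)))
      stop("psi_fixed must supply: ", paste(need, collapse = ", "), call. = FALSE)
    for (f in c("alpha1", "beta1", "alpha2", "beta2"))
      psi_fixed[[f]] <- rep_len(psi_fixed[[f]], length(lengths))
    if (any(unlist(psi_fixed) <= 0))
      stop("fixed hyperparameters must be positive", call. = FALSE)
  }
  structure(list(lengths = lengths, a = av, b = bv, psi_fixed = psi_fixed),
            class = "sda_prior")
}

psi_names <- function(lengths) {
  c(t(outer(c("alpha1_", "beta1_", "alpha2_", "beta2_"), lengths, paste0)),
    "alpha_theta", "beta_theta")
}

## flatten a psi list into the named vector order of psi_names()
psi_flatten <- function(psi, lengths) {
  v <- c(rbind(psi$alpha1, psi$beta1, psi$alpha2, psi$beta2))
  ## rbind interleaves per length: alpha1_l, beta1_l, alpha2_l, beta2_l
  out <- numeric(4 * length(lengths) + 2)
  names(out) <- psi_names(lengths)
  out[paste0("alpha1_", lengths)] <- psi$alpha1
  out[paste0("beta1_", lengths)] <- psi$beta1
  out[paste0("alpha2_", lengths)] <- psi$alpha2
  out[paste0("beta2_", lengths)] <- psi$beta2
  out["alpha_theta"] <- psi$alpha_theta
  out["beta_theta"] <- psi$beta_theta
  out
}

#' @export
print.sda_prior <- function(x, ...) {
  cat("SDA hyperprior: ", length(x$a), " Gamma(a_i, b_i) elements over lengths {",
      paste(x$lengths, collapse = ","), "}\n", sep = "")
  if (!is.null(x$psi_fixed)) cat("(hyperparameters psi fixed, not sampled)\n")
  invisible(x)
}

#' Unnormalised log joint posterior density
#'
#' Composes the shifted-family log-likelihood over all trials with the
#' gamma priors on cell parameters (length-specific), shifts, and the
#' gamma hyperpriors on \eqn{\psi}. Returns \code{-Inf} whenever a shift
#' reaches a participant's minimum RT (zero likelihood) or any positivity
#' constraint fails. Exported mainly for transparency and for low-dimensional
#' quadrature cross-checks of the sampler.
#'
#' @param data an \code{\link{stratify}} result (may have zero trials).
#' @param family an \code{\link{sda_family}} or name.
#' @param theta numeric vector of shifts, one per participant.
#' @param rho1,rho2 numeric vectors, one per occupied cell (in
#'   \code{data$cells} order).
#' @param psi list with \code{alpha1}, \code{beta1}, \code{alpha2},
#'   \code{beta2} (vectors over \code{data$lengths}), \code{alpha_theta},
#'   \code{beta_theta}.
#' @param prior an \code{\link{sda_prior}} over the same lengths.
#' @return scalar log density (unnormalised), possibly \code{-Inf}.
#' @export
log_joint <- function(data, family, theta, rho1, rho2, psi, prior) {
  family <- sda_family(as.character(family))
  C <- nrow(data$cells); J <- length(data$participants)
  if (length(rho1) != C || length(rho2) != C)
    stop("rho vectors must match the ", C, " occupied cells", call. = FALSE)
  if (length(theta) != J)
    stop("theta must have one entry per participant (", J, ")", call. = FALSE)
  if (!identical(prior$lengths, data$lengths))
    stop("prior lengths do not match data lengths", call. = FALSE)
  if (any(theta < 0) || any(rho1 <= 0) || any(rho2 <= 0)) return(-Inf)
  li <- match(data$cells$length, data$lengths)

  ll <- 0
  if (length(data$y)) {
    x <- data$y - theta[data$part_id]
    lf <- shifted_logdens(x, family, rho1[data$cell_id], rho2[data$cell_id])
    ll <- sum(lf)
    if (!is.finite(ll)) return(-Inf)
  }
  lp <- sum(stats::dgamma(rho1, psi$alpha1[li], rate = psi$beta1[li], log = TRUE)) +
    sum(stats::dgamma(rho2, psi$alpha2[li], rate = psi$beta2[li], log = TRUE)) +
    sum(stats::dgamma(theta, psi$alpha_theta, rate = psi$beta_theta, log = TRUE))
  lh <- 0
  if (is.null(prior$psi_fixed)) {
    pv <- psi_flatten(psi, data$lengths)
    lh <- sum(stats::dgamma(pv, prior$a, rate = prior$b, log = TRUE))
  }
  ll + lp + lh
}
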