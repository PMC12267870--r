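#' Shifted response-time distribution families
#'
#' SDA models a response time as \eqn{Y = \theta + X}, where \eqn{\theta}
#' is a deterministic shift (nondecision time, ms) and \eqn{X > 0} follows
#' one of three positively skewed families. Densities are evaluated at
#' \eqn{y - \theta} on the support \eqn{y > \theta}:
#' \describe{
#'   \item{lognormal}{parameters \code{rho1} = \eqn{\mu} (log-ms scale) and
#'     \code{rho2} = \eqn{\sigma^2}.}
#'   \item{wald}{inverse Gaussian with mean \code{rho1} = \eqn{\mu} (ms) and
#'     shape \code{rho2} = \eqn{\lambda} (ms).}
#'   \item{gamma}{shape \code{rho1} = \eqn{\alpha} and rate
#'     \code{rho2} = \eqn{\beta} (1/ms).}
#' }
#' \code{rho2} must be strictly positive, as must \code{rho1} for the Wald
#' and gamma families; the lognormal \eqn{\mu} may be any finite real at the
#' density level, although the hierarchical model constrains it to be
#' positive through its gamma prior. \code{theta} must be nonnegative. Work
#' in milliseconds: on the ms scale typical \eqn{\ln(y-\theta)} values
#' exceed 1, so a positive lognormal \eqn{\mu} is meaningful.
#'
#' @param name one of \code{"lognormal"}, \code{"wald"}, \code{"gamma"}.
#' @return \code{sda_family} returns a character scalar of class
#'   \code{"sda_family"}.
#' @examples
#' fam <- sda_family("gamma")
#' dshifted(450, fam, theta = 250, rho1 = 4, rho2 = 0.02)
#' shifted_mean(fam, theta = 250, rho1 = 4, rho2 = 0.02)  # 450 ms
#' @export
sda_family <- function(name) {
  name <- match.arg(name, sda_families())
  structure(name, class = "sda_family")
}

#' @rdname sda_family
#' @export
sda_families <- function() c("lognormal", "wald", "gamma")

## The hierarchical model constrains rho1 > 0 through its gamma prior, but
## the lognormal density itself is defined for any real mu, so only the
## Wald mean and gamma shape are required to be strictly positive here.
check_shifted_params <- function(theta, rho1, rho2, family = NULL) {
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("'theta' must be finite and >= 0", call. = FALSE)
  strict1 <- is.null(family) || as.character(family) != "lognormal"
  if (any(!is.finite(rho1)) || (strict1 && any(rho1 <= 0)))
    stop("'rho1' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(rho2)) || any(rho2 <= 0))
    stop("'rho2' must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

## log-density kernels on x = y - theta > 0; vectorised over everything.
## x <= 0 (including x == 0, the right-limit convention) maps to -Inf.
shifted_logdens <- function(x, family, rho1, rho2) {
  kernel <- function(x1, r1, r2) switch(as.character(family),
    lognormal = stats::dlnorm(x1, meanlog = r1, sdlog = sqrt(r2), log = TRUE),
    wald = 0.5 * (log(r2) - log(2 * pi) - 3 * log(x1)) -
      r2 * (x1 - r1)^2 / (2 * r1^2 * x1),
    gamma = stats::dgamma(x1, shape = r1, rate = r2, log = TRUE),
    stop("unknown family: ", family, call. = FALSE))
  ok <- is.finite(x) & x > 0
  if (all(ok)) return(as.numeric(kernel(x, rho1, rho2)))  # fast common path
  out <- rep_len(-Inf, length(x))
  if (!any(ok)) return(out)
  r1 <- if (length(rho1) > 1L) rho1[ok] else rho1
  r2 <- if (length(rho2) > 1L) rho2[ok] else rho2
  out[ok] <- kernel(x[ok], r1, r2)
  out
}

#' @rdname sda_family
#' @param y,q response times (ms).
#' @param family an \code{sda_family} or family name.
#' @param theta shift (nondecision time, ms), \code{>= 0}.
#' @param rho1,rho2 family parameters, \code{> 0} (see Details).
#' @param log,log.p logical; return log density / log probability.
#' @export
dshifted <- function(y, family, theta, rho1, rho2, log = FALSE) {
  family <- sda_family(as.character(family))
  check_shifted_params(theta, rho1, rho2, family)
  ld <- shifted_logdens(y - theta, family, rho1, rho2)
  if (log) ld else exp(ld)
}

#' @rdname sda_family
#' @export
pshifted <- function(q, family, theta, rho1, rho2, log.p = FALSE) {
  family <- sda_family(as.character(family))
  check_shifted_params(theta, rho1, rho2, family)
  x <- pmax(q - theta, 0)
  p <- switch(as.character(family),
    lognormal = stats::plnorm(x, meanlog = rho1, sdlog = sqrt(rho2)),
    wald = ifelse(x <= 0, 0, statmod::pinvgauss(x, mean = rho1, shape = rho2)),
    gamma = stats::pgamma(x, shape = rho1, rate = rho2)
  )
  if (log.p) log(p) else p
}

#' @rdname sda_family
#' @param n number of draws.
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @export
rshifted <- function(n, family, theta, rho1, rho2, seed = NULL) {
  family <- sda_family(as.character(family))
  check_shifted_params(theta, rho1, rho2, family)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  x <- switch(as.character(family),
    lognormal = stats::rlnorm(n, meanlog = rho1, sdlog = sqrt(rho2)),
    wald = statmod::rinvgauss(n, mean = rho1, shape = rho2),
    gamma = stats::rgamma(n, shape = rho1, rate = rho2)
  )
  theta + x
}

#' @rdname sda_family
#' @details \code{shifted_mean} returns the expected response time:
#'   \eqn{\theta + e^{\mu + \sigma^2/2}} (lognormal), \eqn{\theta + \mu}
#'   (Wald), \eqn{\theta + \alpha/\beta} (gamma).
#' @export
shifted_mean <- function(family, theta, rho1, rho2) {
  family <- sda_family(as.character(family))
  check_shifted_params(theta, rho1, rho2, family)
  theta + switch(as.character(family),
    lognormal = exp(rho1 + rho2 / 2),
    wald = rho1 + 0 * rho2,
    gamma = rho1 / rho2
  )
}

#' @export
print.sda_family <- function(x, ...) {
  cat("shifted", unclass(x), "family (support y > theta, ms scale)\n")
  invisible(x)
}
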