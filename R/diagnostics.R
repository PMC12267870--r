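## Convergence diagnostics: split-chain R-hat and a Geyer-style effective
## sample size, computed per scalar quantity.

#' Split-chain R-hat
#'
#' Potential-scale-reduction diagnostic computed after splitting each chain
#' in half, so within-chain drift is detected even with a single chain.
#'
#' @param x iterations x chains matrix of draws for one quantity.
#' @return scalar R-hat (\code{NA} for constant draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1L):n, , drop = FALSE])
  W <- mean(apply(xs, 2, stats::var))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- half * stats::var(colMeans(xs))
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size for a posterior mean
#'
#' Initial-positive-sequence autocorrelation estimate computed per chain
#' and summed across chains.
#'
#' @param x iterations x chains matrix of draws.
#' @return scalar effective sample size.
#' @export
ess_mean <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  per_chain <- apply(x, 2, function(v) {
    if (stats::var(v) <= 0) return(length(v))
    ac <- stats::acf(v, lag.max = min(n - 1L, 250L), plot = FALSE,
                     demean = TRUE)$acf[-1L, 1L, 1L]
    ## Geyer: sum consecutive pairs while positive
    npair <- length(ac) %/% 2L
    ssum <- 0
    for (p in seq_len(npair)) {
      pair <- ac[2L * p - 1L] + ac[2L * p]
      if (!is.finite(pair) || pair <= 0) break
      ssum <- ssum + pair
    }
    length(v) / (1 + 2 * ssum)
  })
  sum(per_chain)
}

## apply a diagnostic over the columns of a (draws x chains x quantity) set
diag_over <- function(mat, chain_id, fun) {
  chains <- sort(unique(chain_id))
  vapply(seq_len(ncol(mat)), function(j) {
    fun(vapply(chains, function(ch) mat[chain_id == ch, j],
               numeric(sum(chain_id == chains[1]))))
  }, numeric(1))
}
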