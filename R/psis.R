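## Pareto-smoothed importance sampling (PSIS) for leave-one-out weights.
##
## The generalised Pareto tail fit follows the Zhang-Stephens profile
## estimator: density f(x) = (1/sigma) (1 + k x / sigma)^(-1/k - 1),
## reparametrised by th = -k/sigma; for fixed th the profile MLE is
## k(th) = -mean(log1p(-th x)), sigma = -k/th, giving profile log-likelihood
## n * (log(-th/k) + k - 1) up to sign bookkeeping, averaged over a grid of
## th values weighted by profile likelihood.

gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- prior_bs + floor(sqrt(n))
  quart <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * quart)
  ks <- rowMeans(log1p(-outer(bs, x)))
  ratio <- -bs / ks                  # positive: b and k have opposite signs
  l <- ifelse(ratio > 0 & is.finite(ratio), n * (log(ratio) - ks - 1), -Inf)
  if (!any(is.finite(l))) return(c(k = NaN, sigma = NaN))
  w <- exp(l - max(l))
  b_hat <- sum(bs * w) / sum(w)
  k_hat <- mean(log1p(-b_hat * x))   # k > 0: heavy (polynomial) tail
  c(k = k_hat, sigma = -k_hat / b_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else (sigma / k) * ((1 - p)^(-k) - 1)
}

## Smooth one vector of log importance ratios; returns the smoothed
## log-weights (unnormalised) and the Pareto k diagnostic.
psis_smooth <- function(lr) {
  S <- length(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L || stats::var(lr) == 0) return(list(lw = lr, k = -Inf))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1L):S]
  cutoff <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids] - cutoff) - 1   # exceedances on the ratio scale
  exc <- pmax(exc, 0)
  if (all(exc <= 0)) return(list(lw = lr, k = -Inf))
  fit <- gpd_fit(exc[exc > 0])
  if (!is.finite(fit["k"])) return(list(lw = lr, k = Inf))
  p <- (seq_len(M) - 0.5) / M
  smoothed <- cutoff + log1p(gpd_quantile(p, fit["k"], fit["sigma"]))
  smoothed <- pmin(smoothed, max(lr))   # never exceed the largest raw weight
  lw <- lr
  lw[tail_ids] <- sort(smoothed)  # tail_ids are already in ascending lr order
  list(lw = lw, k = unname(fit["k"]))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))
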