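#' Synthetic-study design
#'
#' Describes a ground-truth lexical-decision simulation: a Zipf-distributed
#' lexicon over a set of word lengths, participant shifts and cell
#' parameters drawn from the model's own gamma priors at known
#' hyperparameter values \eqn{\psi^*}, and trial RTs from a chosen shifted
#' family. The defaults are the package's desk-scale study conditions
#' (20 participants x 4 bands x 3 lengths, 50 trials per cell; see
#' \code{vignette("sda-methods")}).
#'
#' @param n_participants number of participants.
#' @param lengths modelled word lengths (subset of 4:10).
#' @param n_words words per length (multiple of \code{n_bands} keeps cell
#'   sizes balanced).
#' @param n_bands ground-truth frequency bands.
#' @param trials_per_word repetitions of each word per participant.
#' @param zipf_exponent Zipf exponent of the occurrence values (> 0).
#' @param family generating shifted family.
#' @param psi_true true hyperparameters: list with \code{alpha1},
#'   \code{beta1}, \code{alpha2}, \code{beta2} (scalars or vectors over
#'   \code{lengths}), \code{alpha_theta}, \code{beta_theta}. Defaults are
#'   family-specific values producing realistic lexical-decision RTs
#'   (shifts around 250 ms, stochastic components around 200 ms).
#' @param theta_true optional fixed shifts (scalar or one per participant);
#'   overrides the gamma draw.
#' @param band_effect optional multiplier (length \code{n_bands}) applied
#'   to each band's stochastic-component mean, for simulating a frequency
#'   effect (e.g. \code{seq(1.3, 0.8, length.out = n_bands)} for faster
#'   high-frequency responses). Default: none (cell parameters depend on
#'   length only, as in the model's priors).
#' @param accuracy_rate Bernoulli accuracy of generated flags.
#' @param rank_corr rank correlation between the WF measure and the
#'   DCD/UCD measures of the generated lexicon.
#' @param nonword_frac nonword trials as a fraction of word trials
#'   (placeholder items, \code{is_word = 0}).
#' @return list of class \code{"sda_design"}.
#' @export
sda_design <- function(n_participants = 20, lengths = c(4, 7, 10),
                       n_words = 40, n_bands = 4, trials_per_word = 5,
                       zipf_exponent = 1, family = "lognormal",
                       psi_true = NULL, theta_true = NULL,
                       band_effect = NULL, accuracy_rate = 0.97,
                       rank_corr = 0.9, nonword_frac = 0) {
  stopifnot(n_participants >= 1, n_words >= 1, n_bands >= 1,
            trials_per_word >= 1, zipf_exponent > 0,
            all(lengths %in% 4:10))
  family <- sda_family(as.character(family))
  lengths <- sort(unique(as.integer(lengths)))
  if (is.null(psi_true)) psi_true <- default_psi_true(family)
  for (f in c("alpha1", "beta1", "alpha2", "beta2"))
    psi_true[[f]] <- rep_len(psi_true[[f]], length(lengths))
  if (!is.null(band_effect)) band_effect <- rep_len(band_effect, n_bands)
  structure(list(n_participants = n_participants, lengths = lengths,
                 n_words = n_words, n_bands = n_bands,
                 trials_per_word = trials_per_word,
                 zipf_exponent = zipf_exponent, family = family,
                 psi_true = psi_true, theta_true = theta_true,
                 band_effect = band_effect, accuracy_rate = accuracy_rate,
                 rank_corr = rank_corr, nonword_frac = nonword_frac),
            class = "sda_design")
}

## realistic ms-scale truths: shifts ~ 250 ms, stochastic mean ~ 200 ms
default_psi_true <- function(family) {
  base <- list(alpha_theta = 50, beta_theta = 0.2)
  switch(as.character(family),
    lognormal = c(base, list(alpha1 = 400, beta1 = 75,     # mu ~ 5.33 (0.27)
                             alpha2 = 9, beta2 = 36)),     # sigma^2 ~ 0.25
    wald = c(base, list(alpha1 = 25, beta1 = 0.1,          # mu ~ 250 (50) ms
                        alpha2 = 16, beta2 = 0.008)),      # lambda ~ 2000 ms
    gamma = c(base, list(alpha1 = 16, beta1 = 4,           # shape ~ 4 (1)
                         alpha2 = 4, beta2 = 200)))        # rate ~ 0.02 /ms
}

#' Generate a synthetic lexicon
#'
#' Words (random letter strings) of the design's lengths, with Zipf-like
#' occurrence values: the word of rank r has occurrence proportional to
#' \eqn{r^{-s}}. Three measures (WF, DCD, UCD) are emitted; DCD and UCD
#' have rank correlation \code{rank_corr} with WF via a Gaussian copula
#' (1 gives identical ranks).
#'
#' @param design an \code{\link{sda_design}}.
#' @param seed integer seed.
#' @return lexicon data.frame (word, length, pos, WF, DCD, UCD).
#' @export
gen_lexicon <- function(design, seed = 1) {
  stopifnot(inherits(design, "sda_design"))
  set.seed(as.integer(seed))
  nw <- design$n_words
  words <- unlist(lapply(design$lengths, function(l) {
    w <- character(0)
    while (length(w) < nw)
      w <- unique(c(w, vapply(seq_len(nw * 2), function(i)
        paste(sample(letters, l, replace = TRUE), collapse = ""),
        character(1))))
    w[seq_len(nw)]
  }))
  n <- length(words)
  ranks <- sample.int(n)                        # WF rank of each word
  zipf_vals <- 1e5 * (seq_len(n))^(-design$zipf_exponent)
  wf <- zipf_vals[ranks]
  corr_rank <- function(rc) {
    z <- stats::qnorm((n + 1 - ranks - stats::runif(n)) / (n + 1))
    z2 <- rc * z + sqrt(max(0, 1 - rc^2)) * stats::rnorm(n)
    zipf_vals[rank(-z2, ties.method = "first")]
  }
  data.frame(word = words,
             length = rep(design$lengths, each = nw),
             pos = sample(c("noun", "verb", "adjective"), n, replace = TRUE,
                          prob = c(0.6, 0.25, 0.15)),
             WF = wf,
             DCD = corr_rank(design$rank_corr),
             UCD = corr_rank(design$rank_corr),
             stringsAsFactors = FALSE)
}

#' Generate ground-truth trials
#'
#' Draws shifts \eqn{\theta_j^* \sim Gamma(\alpha_\theta^*,
#' \beta_\theta^*)} (unless fixed), cell parameters \eqn{\rho_{jkl}^*} from
#' the length-specific gamma priors at \eqn{\psi^*}, and RTs from the
#' shifted family. Every trial's generating (participant, band, length)
#' cell is recorded; within each length, words are assigned to bands by
#' occurrence rank (equal word counts per band), emulating quantile
#' banding on trial-weighted occurrence values.
#'
#' @param design an \code{\link{sda_design}}.
#' @param seed integer seed (full reproducibility).
#' @param lexicon optional lexicon from \code{\link{gen_lexicon}};
#'   generated internally (same seed) when omitted.
#' @param measure occurrence measure used for banding the truth.
#' @return list with \code{trials} (canonical trial data.frame plus
#'   \code{length}, \code{band}, \code{occurrence} columns) and
#'   \code{truth}: \code{theta} (named by participant), \code{cells}
#'   (participant, band, length, rho1, rho2), \code{word_band},
#'   \code{design}.
#' @export
gen_trials <- function(design, seed = 1, lexicon = NULL, measure = "WF") {
  stopifnot(inherits(design, "sda_design"))
  if (is.null(lexicon)) lexicon <- gen_lexicon(design, seed = seed)
  set.seed(as.integer(seed) + 1L)
  J <- design$n_participants
  K <- design$n_bands
  psi <- design$psi_true
  fam <- as.character(design$family)

  ## band assignment: within each length, ascending occurrence -> bands 1..K
  lex <- lexicon[order(lexicon$length, lexicon[[measure]]), ]
  lex$band <- unlist(lapply(split(seq_len(nrow(lex)), lex$length), function(ix) {
    nw <- length(ix)
    rep(seq_len(K), each = ceiling(nw / K))[seq_len(nw)]
  }))

  theta <- if (!is.null(design$theta_true)) {
    rep_len(design$theta_true, J)
  } else {
    stats::rgamma(J, shape = psi$alpha_theta, rate = psi$beta_theta)
  }
  names(theta) <- sprintf("p%02d", seq_len(J))

  cells <- expand.grid(j = seq_len(J), band = seq_len(K),
                       length = design$lengths, KEEP.OUT.ATTRS = FALSE)
  li <- match(cells$length, design$lengths)
  cells$rho1 <- stats::rgamma(nrow(cells), shape = psi$alpha1[li],
                              rate = psi$beta1[li])
  cells$rho2 <- stats::rgamma(nrow(cells), shape = psi$alpha2[li],
                              rate = psi$beta2[li])
  if (!is.null(design$band_effect)) {
    g <- design$band_effect[cells$band]
    if (fam == "lognormal") cells$rho1 <- cells$rho1 + log(g)
    else if (fam == "wald") cells$rho1 <- cells$rho1 * g
    else cells$rho2 <- cells$rho2 / g
  }
  cells$participant <- names(theta)[cells$j]

  ## one block of trials per participant x word
  tw <- design$trials_per_word
  widx <- rep(seq_len(nrow(lex)), each = tw)
  blocks <- lapply(seq_len(J), function(j) {
    ci <- match(paste(j, lex$band[widx], lex$length[widx]),
                paste(cells$j, cells$band, cells$length))
    rt <- rshifted(length(widx), fam, theta[j], cells$rho1[ci], cells$rho2[ci])
    data.frame(participant = names(theta)[j],
               item = lex$word[widx],
               rt = rt,
               accuracy = stats::rbinom(length(widx), 1, design$accuracy_rate),
               is_word = 1L,
               length = lex$length[widx],
               band = lex$band[widx],
               occurrence = lex[[measure]][widx],
               stringsAsFactors = FALSE)
  })
  trials <- do.call(rbind, blocks)

  if (design$nonword_frac > 0) {
    nnw <- round(design$nonword_frac * nrow(lex) * tw)
    nw_blocks <- lapply(seq_len(J), function(j) {
      data.frame(participant = names(theta)[j],
                 item = sprintf("nw%04d", seq_len(nnw)),
                 rt = rshifted(nnw, "gamma", theta[j], 4, 0.02),
                 accuracy = stats::rbinom(nnw, 1, design$accuracy_rate),
                 is_word = 0L, length = NA_integer_, band = NA_integer_,
                 occurrence = NA_real_, stringsAsFactors = FALSE)
    })
    trials <- rbind(trials, do.call(rbind, nw_blocks))
  }
  rownames(trials) <- NULL
  list(trials = trials,
       truth = list(theta = theta,
                    cells = cells[c("participant", "j", "band", "length",
                                    "rho1", "rho2")],
                    word_band = lex[c("word", "length", "band")],
                    design = design,
                    lexicon = lexicon))
}

#' Contaminated trials for exercising the participant filters
#'
#' Starts from \code{\link{gen_trials}} and injects, per participant, an
#' exact number of fast (< 150 ms) and slow (> 2000 ms) RTs --
#' \code{round(frac * n)} trials each -- plus optional low-accuracy
#' participants whose accuracy flags alternate 1, 0 (exactly 50\% correct),
#' so the 60\% / 150--2000 ms / 20\% exclusions are analytically
#' predictable.
#'
#' @param design an \code{\link{sda_design}}.
#' @param fast_frac,slow_frac fractions in [0, 1); scalars or one value per
#'   participant (recycled).
#' @param low_acc_participants how many participants (taken first) receive
#'   the alternating accuracy pattern.
#' @param seed integer seed.
#' @return list as \code{\link{gen_trials}}, with contaminated
#'   \code{trials} and an added \code{truth$contamination} record.
#' @export
gen_contaminated <- function(design, fast_frac = 0, slow_frac = 0,
                             low_acc_participants = 0, seed = 1) {
  stopifnot(all(fast_frac >= 0), all(slow_frac >= 0),
            all(fast_frac + slow_frac < 1))
  sim <- gen_trials(design, seed = seed)
  set.seed(as.integer(seed) + 2L)
  trials <- sim$trials
  parts <- sort(unique(trials$participant))
  ff <- rep_len(fast_frac, length(parts))
  sf <- rep_len(slow_frac, length(parts))
  record <- data.frame(participant = parts, n_fast = 0L, n_slow = 0L,
                       low_acc = FALSE, stringsAsFactors = FALSE)
  for (p in seq_along(parts)) {
    ix <- which(trials$participant == parts[p])
    n <- length(ix)
    nf <- round(ff[p] * n); ns <- round(sf[p] * n)
    pick <- sample(ix, nf + ns)
    if (nf > 0) trials$rt[pick[seq_len(nf)]] <- stats::runif(nf, 50, 149)
    if (ns > 0) trials$rt[pick[nf + seq_len(ns)]] <- stats::runif(ns, 2001, 4000)
    record$n_fast[p] <- nf; record$n_slow[p] <- ns
    if (p <= low_acc_participants) {
      trials$accuracy[ix] <- rep_len(c(1L, 0L), n)
      record$low_acc[p] <- TRUE
    }
  }
  sim$trials <- trials
  sim$truth$contamination <- record
  sim
}

#' @export
print.sda_design <- function(x, ...) {
  cat("synthetic SDA design: ", x$n_participants, " participants x ",
      x$n_bands, " bands x ", length(x$lengths), " lengths (",
      paste(x$lengths, collapse = ","), "), ", x$n_words,
      " words/length x ", x$trials_per_word, " trials, ",
      as.character(x$family), " family\n", sep = "")
  invisible(x)
}
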