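#' Pipeline configuration
#'
#' Declarative description of a full SDA run: data source (synthetic design
#' or trial/lexicon files), occurrence measures and families to cross,
#' filter thresholds, banding floor, prior and sampler settings. Every
#' field has a working default, so \code{sda_config()} alone describes a
#' small synthetic run.
#'
#' @param mode \code{"simulate"} or \code{"files"}.
#' @param sim list of \code{\link{sda_design}} arguments (simulate mode).
#' @param trials_path,lexicon_path,dialect,exclude_files file-mode inputs.
#' @param measures occurrence measures to analyse (subset of lexicon
#'   columns, e.g. \code{c("WF", "DCD", "UCD")}).
#' @param families shifted families to fit.
#' @param lengths,pos_exclude lexicon merge settings.
#' @param min_accuracy,rt_low,rt_high,max_out_fraction participant filters.
#' @param band_min_count observations-per-band floor.
#' @param prior list of \code{\link{sda_prior}} arguments (\code{a},
#'   \code{b}).
#' @param draws,warmup,chains sampler settings.
#' @param ppp_replicates posterior predictive replicate count.
#' @param elpd_method \code{"loo-is"}, \code{"waic"} or \code{"lpd"}.
#' @param out_dir output directory (created); \code{NULL} for none.
#' @param seed master seed for the whole run.
#' @return list of class \code{"sda_config"}.
#' @export
sda_config <- function(mode = c("simulate", "files"), sim = list(),
                       trials_path = NULL, lexicon_path = NULL,
                       dialect = "csv", exclude_files = character(),
                       measures = "WF",
                       families = c("lognormal", "wald", "gamma"),
                       lengths = 4:10, pos_exclude = character(),
                       min_accuracy = 0.60, rt_low = 150, rt_high = 2000,
                       max_out_fraction = 0.20, band_min_count = 50,
                       prior = list(a = 0.01, b = 0.01),
                       draws = 500, warmup = 500, chains = 2,
                       ppp_replicates = 200, elpd_method = "loo-is",
                       out_dir = NULL, seed = 1) {
  cfg <- list(mode = match.arg(mode), sim = sim, trials_path = trials_path,
              lexicon_path = lexicon_path, dialect = dialect,
              exclude_files = exclude_files, measures = measures,
              families = families, lengths = lengths,
              pos_exclude = pos_exclude, min_accuracy = min_accuracy,
              rt_low = rt_low, rt_high = rt_high,
              max_out_fraction = max_out_fraction,
              band_min_count = band_min_count, prior = prior,
              draws = draws, warmup = warmup, chains = chains,
              ppp_replicates = ppp_replicates, elpd_method = elpd_method,
              out_dir = out_dir, seed = as.integer(seed))
  if (!length(cfg$families)) stop("at least one family required", call. = FALSE)
  class(cfg) <- "sda_config"
  cfg
}

#' @rdname sda_config
#' @param path YAML file with \code{sda_config} fields.
#' @export
read_config <- function(path) {
  do.call(sda_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[order(names(cfg))], f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full SDA pipeline
#'
#' Executes simulate/load, participant filtering, lexicon merge, frequency
#' banding, stratification, posterior sampling, posterior predictive
#' assessment and elpd model comparison for every requested family x
#' measure combination, and writes the report tables plus a JSON manifest
#' (seeds, config hash, per-stage trial counts) when \code{out_dir} is set.
#'
#' @param config an \code{\link{sda_config}} (or YAML path).
#' @return list with \code{fits} (named \code{measure_family}),
#'   \code{ppp}, \code{comparison}, \code{report} (see
#'   \code{\link{sda_report}}) and \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "sda_config"))
  manifest <- list(package = as.character(utils::packageVersion("sdart")),
                   r_version = R.version.string,
                   seed = config$seed, config_hash = config_hash(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  stage <- function(name, n_in, n_out)
    manifest$stages[[name]] <<- list(status = "complete",
                                     n_in = n_in, n_out = n_out)
  out <- tryCatch({
    ## ---- stage 1: acquire trials + lexicon ----
    if (config$mode == "simulate") {
      design <- do.call(sda_design, config$sim)
      sim <- gen_trials(design, seed = config$seed)
      trials <- sim$trials[c("participant", "item", "rt", "accuracy", "is_word")]
      lexicon <- sim$truth$lexicon
    } else {
      dialect <- if (is.character(config$dialect))
        dialect_preset(config$dialect) else config$dialect
      trials <- read_trials(config$trials_path, dialect,
                            exclude_files = config$exclude_files)
      lexicon <- read_lexicon(config$lexicon_path)
      sim <- NULL
    }
    stage("acquire", NA_integer_, nrow(trials))

    ## ---- stage 2: participant filters ----
    filt <- filter_participants(trials, config$min_accuracy, config$rt_low,
                                config$rt_high, config$max_out_fraction)
    stage("filter_participants", nrow(trials), nrow(filt$trials))
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(filt$report,
                       file.path(config$out_dir, "exclusions.csv"),
                       row.names = FALSE)
    }

    fits <- list()
    ppp_tab <- NULL
    elpds <- list()
    for (measure in config$measures) {
      ## ---- stage 3-4: merge + band + stratify ----
      ann <- merge_lexicon(filt$trials, lexicon, measure = measure,
                           lengths = config$lengths,
                           pos_exclude = config$pos_exclude)
      bands <- frequency_bands(ann, min_count = config$band_min_count,
                               measure = measure)
      strat <- stratify(ann, bands)
      stage(paste0("stratify_", measure), nrow(filt$trials), length(strat$y))

      for (fam in config$families) {
        label <- paste(measure, fam, sep = "_")
        prior <- sda_prior(strat$lengths, a = config$prior$a,
                           b = config$prior$b)
        fit <- sda_fit(strat, fam, prior = prior, draws = config$draws,
                       warmup = config$warmup, chains = config$chains,
                       seed = config$seed)
        fits[[label]] <- fit
        stage(paste0("fit_", label), length(strat$y), nrow(fit$theta))

        pp <- ppp_values(fit, R = config$ppp_replicates,
                         seed = config$seed + 13L)
        pp <- data.frame(model = label, measure = measure, family = fam, pp,
                         stringsAsFactors = FALSE)
        ppp_tab <- rbind(ppp_tab, pp)
        elpds[[label]] <- elpd(fit, method = config$elpd_method,
                               label = label)
        stage(paste0("assess_", label), length(strat$y), nrow(pp))
      }
    }

    ## ---- stage 5: model comparison (identical trial sets only) ----
    ns <- vapply(elpds, `[[`, 1L, "n")
    comparison <- if (length(unique(ns)) == 1L) {
      compare_elpd(elpds)
    } else {
      do.call(rbind, lapply(unique(sub("_[^_]+$", "", names(elpds))),
                            function(me) {
        cmp <- compare_elpd(elpds[grep(paste0("^", me, "_"), names(elpds))])
        cmp
      }))
    }
    stage("compare", length(elpds), nrow(comparison))

    rep_tabs <- sda_report(fits, ppp = ppp_tab, comparison = comparison,
                           out_dir = config$out_dir)
    stage("report", length(fits), length(rep_tabs))
    list(fits = fits, ppp = ppp_tab, comparison = comparison,
         report = rep_tabs, truth = if (!is.null(sim)) sim$truth)
  }, error = function(e) {
    manifest$status <<- "partial"
    manifest$error <<- conditionMessage(e)
    if (!is.null(config$out_dir)) write_manifest(manifest, config$out_dir)
    stop(e)
  })
  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (!is.null(config$out_dir)) write_manifest(manifest, config$out_dir)
  out$manifest <- manifest
  out
}

write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Summary report tables
#'
#' Builds the pipeline's canonical numeric outputs from one or more fits:
#' per-participant posterior-median shifts; cell expected-RT posteriors
#' amalgamated over length (effect of frequency band) and over band
#' (effect of length); the ppp table; and the \eqn{\Delta}elpd comparison.
#' All RT columns are in milliseconds and every row carries its model
#' label. Tables are written as csv (with a JSON sidecar listing them)
#' when \code{out_dir} is given.
#'
#' @param fits named list of \code{\link{sda_fit}} objects (names become
#'   model labels).
#' @param ppp optional ppp table (from \code{\link{ppp_values}}).
#' @param comparison optional \code{\link{compare_elpd}} table.
#' @param out_dir optional output directory.
#' @param probs quantiles summarising the amalgamated posteriors.
#' @return named list of data.frames: \code{theta_medians},
#'   \code{cell_means_by_band}, \code{cell_means_by_length}, and when
#'   supplied \code{ppp}, \code{elpd_comparison}.
#' @export
sda_report <- function(fits, ppp = NULL, comparison = NULL, out_dir = NULL,
                       probs = c(0.25, 0.5, 0.75)) {
  if (inherits(fits, "sda_fit")) fits <- list(model = fits)
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) as.character(f$family), "")

  one <- function(label, fit) {
    th <- posterior_medians(fit, "theta")
    data.frame(model = label, participant = names(th),
               theta_median_ms = as.numeric(th), stringsAsFactors = FALSE)
  }
  theta_tab <- do.call(rbind, Map(one, names(fits), fits))

  amalg <- function(label, fit, by) {
    pm <- posterior_medians(fit, "cell_mean")
    g <- fit$data$cells[[by]]
    qs <- do.call(rbind, lapply(split(pm, g), stats::quantile, probs = probs,
                                names = FALSE))
    colnames(qs) <- paste0("q", probs * 100)
    data.frame(model = label, group = as.integer(rownames(qs)),
               mean_rt_ms = as.numeric(vapply(split(pm, g), mean, 1)), qs,
               n_cells = as.integer(table(g)), stringsAsFactors = FALSE)
  }
  by_band <- do.call(rbind, Map(function(l, f) {
    d <- amalg(l, f, "band"); names(d)[2] <- "band"; d
  }, names(fits), fits))
  by_len <- do.call(rbind, Map(function(l, f) {
    d <- amalg(l, f, "length"); names(d)[2] <- "length"; d
  }, names(fits), fits))
  rownames(theta_tab) <- rownames(by_band) <- rownames(by_len) <- NULL

  tabs <- list(theta_medians = theta_tab, cell_means_by_band = by_band,
               cell_means_by_length = by_len)
  if (!is.null(ppp)) tabs$ppp <- ppp
  if (!is.null(comparison)) tabs$elpd_comparison <- as.data.frame(comparison)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tabs))
      utils::write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(list(tables = names(tabs), units = "ms"),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  tabs
}

#' Serialise posterior draws as tidy delimited text
#'
#' One row per draw x quantity (long format) plus a JSON metadata sidecar
#' with seed, chains and convergence diagnostics.
#'
#' @param fit an \code{\link{sda_fit}}.
#' @param path output csv path; the sidecar gets extension
#'   \code{.meta.json}.
#' @return invisibly, \code{path}.
#' @export
write_draws <- function(fit, path) {
  long <- function(mat, what) {
    data.frame(draw = rep(seq_len(nrow(mat)), ncol(mat)),
               chain = rep(fit$chain, ncol(mat)),
               quantity = rep(paste0(what, "[", colnames(mat), "]"),
                              each = nrow(mat)),
               value = as.numeric(mat), stringsAsFactors = FALSE)
  }
  out <- rbind(long(fit$theta, "theta"), long(fit$rho1, "rho1"),
               long(fit$rho2, "rho2"), long(fit$psi, "psi"))
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(family = as.character(fit$family), seed = fit$seed,
               chains = fit$chains, warmup = fit$warmup, thin = fit$thin,
               draws = nrow(fit$theta),
               rhat_max = suppressWarnings(max(fit$diagnostics$rhat,
                                               na.rm = TRUE)),
               converged = fit$diagnostics$converged,
               prior = list(a = as.list(fit$prior$a), b = as.list(fit$prior$b)))
  jsonlite::write_json(meta, sub("\\.csv$", ".meta.json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
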