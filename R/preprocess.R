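#' Delimited-text dialects for trial archives
#'
#' Megastudy single-trial archives differ in delimiter and column naming.
#' A dialect maps the file's columns onto the canonical trial fields
#' (\code{participant}, \code{item}, \code{rt}, \code{accuracy},
#' \code{is_word}). Two presets are provided: \code{"elp"} (tab-separated,
#' one file per session) and \code{"blp"} (tab-separated, single table);
#' \code{"csv"} is the package's own comma-separated format.
#'
#' @param sep field separator.
#' @param participant,item,rt,accuracy,is_word column names in the file.
#' @return a list of class \code{"trial_dialect"}.
#' @export
trial_dialect <- function(sep = ",", participant = "participant",
                          item = "item", rt = "rt", accuracy = "accuracy",
                          is_word = "is_word") {
  structure(list(sep = sep, participant = participant, item = item,
                 rt = rt, accuracy = accuracy, is_word = is_word),
            class = "trial_dialect")
}

#' @rdname trial_dialect
#' @param preset one of \code{"csv"}, \code{"elp"}, \code{"blp"}.
#' @export
dialect_preset <- function(preset = c("csv", "elp", "blp")) {
  switch(match.arg(preset),
    csv = trial_dialect(),
    elp = trial_dialect(sep = "\t", participant = "Sub_ID", item = "item",
                        rt = "rt", accuracy = "accuracy", is_word = "type"),
    blp = trial_dialect(sep = "\t", participant = "participant", item = "spelling",
                        rt = "rt", accuracy = "accuracy", is_word = "lexicality"))
}

#' Read trial-level response-time archives
#'
#' Reads one or more delimited trial files into a canonical trial table.
#' Files whose base name appears in \code{exclude_files} are skipped (the
#' archives ship known-corrupt session files). Rows with a missing or
#' non-positive RT, a missing participant/item, or an accuracy flag outside
#' \{0, 1\} are dropped and the count reported via \code{message()} and the
#' \code{"n_dropped"} attribute.
#'
#' @param paths files and/or directories (directories are expanded,
#'   non-recursively).
#' @param dialect a \code{\link{trial_dialect}}; default the csv preset.
#' @param exclude_files character vector of base names to skip.
#' @return data.frame with columns \code{participant}, \code{item},
#'   \code{rt} (ms), \code{accuracy}, \code{is_word}; attributes
#'   \code{n_dropped}, \code{files_read}, \code{files_excluded}.
#' @export
read_trials <- function(paths, dialect = trial_dialect(),
                        exclude_files = character()) {
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p
  }))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("trial file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  excluded <- files[basename(files) %in% exclude_files]
  files <- setdiff(files, excluded)
  if (!length(files)) stop("no trial files left after exclusions", call. = FALSE)

  dropped <- 0L
  parts <- lapply(files, function(f) {
    raw <- utils::read.table(f, sep = dialect$sep, header = TRUE,
                             stringsAsFactors = FALSE, fill = TRUE,
                             quote = "\"", comment.char = "")
    need <- c(dialect$participant, dialect$item, dialect$rt, dialect$accuracy)
    if (!all(need %in% names(raw)))
      stop("file ", f, " lacks required columns: ",
           paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
    d <- data.frame(
      participant = as.character(raw[[dialect$participant]]),
      item = as.character(raw[[dialect$item]]),
      rt = suppressWarnings(as.numeric(raw[[dialect$rt]])),
      accuracy = suppressWarnings(as.numeric(raw[[dialect$accuracy]])),
      is_word = if (dialect$is_word %in% names(raw))
        as.integer(raw[[dialect$is_word]]) else 1L,
      stringsAsFactors = FALSE)
    bad <- !is.finite(d$rt) | d$rt <= 0 | is.na(d$participant) |
      d$participant == "" | is.na(d$item) | d$item == "" |
      !(d$accuracy %in% c(0, 1)) | is.na(d$is_word)
    dropped <<- dropped + sum(bad)
    d[!bad, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (!nrow(out)) stop("no parseable trial rows in input", call. = FALSE)
  if (dropped > 0L) message("read_trials: dropped ", dropped, " malformed row(s)")
  attr(out, "n_dropped") <- dropped
  attr(out, "files_read") <- files
  attr(out, "files_excluded") <- excluded
  out
}

#' Write a trial table as a delimited archive
#'
#' Inverse of \code{\link{read_trials}} for the csv dialect; used to
#' round-trip synthetic data through the file interface. With
#' \code{split_by_participant = TRUE} one file per participant is written
#' (ELP-style archive layout).
#'
#' @param trials canonical trial data.frame.
#' @param path output file, or directory when splitting.
#' @param split_by_participant write one file per participant.
#' @return invisibly, the file path(s) written.
#' @export
write_trials <- function(trials, path, split_by_participant = FALSE) {
  if (split_by_participant) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(split(trials, trials$participant), function(d) {
      f <- file.path(path, paste0("sub_", d$participant[1], ".csv"))
      utils::write.csv(d, f, row.names = FALSE, quote = FALSE)
      f
    }, character(1))
    invisible(files)
  } else {
    utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
    invisible(path)
  }
}

#' Participant-level exclusion filters
#'
#' Applies the two participant filters in their documented order:
#' \enumerate{
#'   \item overall accuracy (across all trials, words and nonwords) must be
#'     at least \code{min_accuracy} (inclusive: exactly 60\% is retained);
#'   \item the fraction of RTs outside \code{[rt_low, rt_high]} must not be
#'     larger than \code{max_out_fraction} (strict: exactly 20\% is
#'     retained).
#' }
#' Only participants are excluded; out-of-range trials of retained
#' participants are kept (no trial-level trimming).
#'
#' @param trials canonical trial data.frame.
#' @param min_accuracy minimum proportion correct, default 0.60.
#' @param rt_low,rt_high RT window in ms, defaults 150 and 2000.
#' @param max_out_fraction maximum tolerated out-of-window fraction,
#'   default 0.20.
#' @return list with \code{trials} (retained rows) and \code{report}, a
#'   data.frame of excluded participants with columns \code{participant},
#'   \code{reason} (\code{"accuracy"} or \code{"rt_window"}), \code{value}
#'   (the offending proportion) and \code{rule_order}.
#' @export
filter_participants <- function(trials, min_accuracy = 0.60,
                                rt_low = 150, rt_high = 2000,
                                max_out_fraction = 0.20) {
  stopifnot(min_accuracy > 0, min_accuracy <= 1, rt_low < rt_high)
  acc <- tapply(trials$accuracy, trials$participant, mean)
  bad_acc <- names(acc)[acc < min_accuracy]
  rep1 <- data.frame(participant = bad_acc, reason = rep("accuracy", length(bad_acc)),
                     value = as.numeric(acc[bad_acc]),
                     rule_order = rep(1L, length(bad_acc)),
                     stringsAsFactors = FALSE)
  keep <- trials[!(trials$participant %in% bad_acc), , drop = FALSE]

  out <- tapply(keep$rt < rt_low | keep$rt > rt_high, keep$participant, mean)
  bad_rt <- names(out)[out > max_out_fraction]
  rep2 <- data.frame(participant = bad_rt, reason = rep("rt_window", length(bad_rt)),
                     value = as.numeric(out[bad_rt]),
                     rule_order = rep(2L, length(bad_rt)),
                     stringsAsFactors = FALSE)
  keep <- keep[!(keep$participant %in% bad_rt), , drop = FALSE]
  rownames(keep) <- NULL
  list(trials = keep, report = rbind(rep1, rep2))
}

#' Read or write a lexicon table
#'
#' The lexicon is a delimited table with columns \code{word}, \code{length},
#' \code{pos} and one or more word-occurrence measures (\code{WF} word-form
#' frequency, \code{DCD} discourse contextual diversity, \code{UCD} user
#' contextual diversity).
#'
#' @param path file path.
#' @param sep field separator, default tab.
#' @return data.frame.
#' @export
read_lexicon <- function(path, sep = "\t") {
  lex <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"")
  need <- c("word", "length", "pos")
  if (!all(need %in% names(lex)))
    stop("lexicon lacks columns: ", paste(setdiff(need, names(lex)), collapse = ", "),
         call. = FALSE)
  lex
}

#' @rdname read_lexicon
#' @param lexicon lexicon data.frame.
#' @export
write_lexicon <- function(lexicon, path, sep = "\t") {
  utils::write.table(lexicon, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annotate word trials with lexicon information
#'
#' Keeps only word trials whose item is present in the lexicon with a
#' non-missing value of the chosen occurrence measure, whose length lies in
#' \code{lengths}, and whose part of speech is not excluded. Nonword trials
#' are dropped: only word RTs are modelled.
#'
#' @param trials canonical trial data.frame (post participant filtering).
#' @param lexicon lexicon data.frame (see \code{\link{read_lexicon}}).
#' @param measure occurrence-measure column, one of \code{"WF"},
#'   \code{"DCD"}, \code{"UCD"} (or any column present in the lexicon).
#' @param lengths retained word lengths (characters), default 4:10.
#' @param pos_exclude part-of-speech labels to drop (e.g. \code{"minor"}
#'   for ELP-style lexicons).
#' @return trial data.frame with added columns \code{length},
#'   \code{occurrence} (the chosen measure) and \code{measure} attribute.
#' @export
merge_lexicon <- function(trials, lexicon, measure = "WF", lengths = 4:10,
                          pos_exclude = character()) {
  if (!measure %in% names(lexicon))
    stop("measure '", measure, "' not present in lexicon", call. = FALSE)
  lex <- lexicon[!is.na(lexicon[[measure]]) & lexicon[[measure]] > 0 &
                   lexicon$length %in% lengths &
                   !(lexicon$pos %in% pos_exclude), , drop = FALSE]
  keep <- trials$is_word == 1L
  idx <- match(trials$item, lex$word)
  keep <- keep & !is.na(idx)
  out <- trials[keep, , drop = FALSE]
  out$length <- lex$length[idx[keep]]
  out$occurrence <- lex[[measure]][idx[keep]]
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  out
}

#' Quantile word-frequency bands
#'
#' Divides trial-level occurrence values into \code{k} quantile bands such
#' that every band holds at least \code{min_count} observations and every
#' occurrence value belongs to exactly one band. \code{k} is chosen as the
#' largest band count satisfying the floor once tied occurrence values are
#' moved wholly into a single band (values equal to a boundary fall in the
#' lower band). Quantile boundaries use the linear-interpolation definition
#' (\code{\link[stats]{quantile}} type 7). Bands are indexed 1..k in
#' ascending occurrence.
#'
#' @param x trial-level occurrence values (one per observation), or an
#'   annotated trial data.frame with an \code{occurrence} column.
#' @param min_count minimum observations per band (the megastudy analyses
#'   use 40000; pick a value suited to your data size).
#' @param measure measure label stored in the result.
#' @return object of class \code{"band_spec"}: list with \code{measure},
#'   \code{boundaries} (strictly ascending interior boundaries), \code{k},
#'   \code{min_count}, \code{counts}.
#' @export
frequency_bands <- function(x, min_count, measure = NULL) {
  if (is.data.frame(x)) {
    if (is.null(measure)) measure <- attr(x, "measure")
    x <- x$occurrence
  }
  if (is.null(measure)) measure <- "occurrence"
  stopifnot(is.numeric(x), length(x) > 0, min_count >= 1)
  n <- length(x)
  if (n < min_count) {
    warning("fewer observations (", n, ") than min_count (", min_count,
            "); using a single band")
    return(make_band_spec(measure, numeric(0), min_count, n))
  }
  kmax <- max(1L, n %/% as.integer(min_count))
  for (k in seq(kmax, 1L)) {
    bounds <- band_boundaries(x, k)
    if (length(bounds) != k - 1L) next  # ties collapsed a boundary
    counts <- tabulate(band_of(x, bounds), nbins = k)
    if (all(counts >= min_count))
      return(make_band_spec(measure, bounds, min_count, counts))
  }
  make_band_spec(measure, numeric(0), min_count, n)
}

band_boundaries <- function(x, k) {
  if (k <= 1L) return(numeric(0))
  b <- stats::quantile(x, probs = seq_len(k - 1L) / k, type = 7, names = FALSE)
  unique(b[b > min(x) & b < max(x)])
}

make_band_spec <- function(measure, boundaries, min_count, counts) {
  structure(list(measure = measure, boundaries = boundaries,
                 k = length(boundaries) + 1L, min_count = min_count,
                 counts = counts),
            class = "band_spec")
}

#' @rdname frequency_bands
#' @param boundaries ascending interior boundaries, or a \code{band_spec}.
#' @details \code{band_of} maps occurrence values to band indices; a value
#'   exactly equal to a boundary belongs to the lower band, so band
#'   membership is a function of the occurrence value alone (tie safety).
#' @export
band_of <- function(x, boundaries) {
  if (inherits(boundaries, "band_spec")) boundaries <- boundaries$boundaries
  findInterval(x, boundaries, left.open = TRUE) + 1L
}

#' @export
print.band_spec <- function(x, ...) {
  cat("frequency bands on", x$measure, "-", x$k, "band(s), floor",
      x$min_count, "obs/band\n")
  if (x$k > 1) cat("interior boundaries:",
                   paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Stratify annotated trials into (participant, band, length) cells
#'
#' Partitions the retained word trials into the cells of the SDA hierarchy.
#' Every trial lands in exactly one cell; cell sizes sum to the trial count.
#'
#' @param trials annotated trials from \code{\link{merge_lexicon}} (or any
#'   data.frame with \code{participant}, \code{rt}, \code{length},
#'   \code{occurrence}; alternatively a precomputed \code{band} column is
#'   honoured when \code{band_spec} is \code{NULL}).
#' @param band_spec a \code{\link{frequency_bands}} specification built on
#'   the same measure.
#' @return object of class \code{"sda_data"}: list with the trial vectors
#'   (\code{y}, \code{cell_id}, \code{part_id}), the cell table
#'   (\code{cells}: cell, participant, band, length, n), participant
#'   labels, modelled lengths, and the band spec.
#' @export
stratify <- function(trials, band_spec = NULL) {
  band <- if (!is.null(band_spec)) band_of(trials$occurrence, band_spec)
          else if (!is.null(trials$band)) as.integer(trials$band)
          else stop("need either band_spec or a 'band' column", call. = FALSE)
  participants <- sort(unique(trials$participant))
  lengths <- sort(unique(as.integer(trials$length)))
  j <- match(trials$participant, participants)
  key <- paste(j, band, trials$length, sep = ".")
  ukey <- unique(key[order(j, band, trials$length)])  # (j, k, l) cell order
  cell_id <- match(key, ukey)
  ord <- match(ukey, key)
  cells <- data.frame(cell = seq_along(ukey),
                      participant = participants[j[ord]],
                      j = j[ord], band = band[ord],
                      length = as.integer(trials$length[ord]),
                      n = as.integer(tabulate(cell_id, nbins = length(ukey))),
                      stringsAsFactors = FALSE)
  structure(list(y = as.numeric(trials$rt), cell_id = cell_id, part_id = j,
                 cells = cells, participants = participants,
                 lengths = lengths, band_spec = band_spec),
            class = "sda_data")
}

#' @export
print.sda_data <- function(x, ...) {
  cat("stratified RT dataset: ", length(x$y), " trials, ",
      length(x$participants), " participants, ",
      length(unique(x$cells$band)), " band(s) x ",
      length(x$lengths), " length(s); ", nrow(x$cells), " occupied cells\n",
      sep = "")
  invisible(x)
}

## per-participant minimum RT (posterior support bound for theta)
participant_min_rt <- function(data) {
  m <- rep(Inf, length(data$participants))
  if (length(data$y))
    m[as.integer(names(tapply(data$y, data$part_id, min)))] <-
      as.numeric(tapply(data$y, data$part_id, min))
  m
}
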