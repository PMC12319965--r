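#' Study design grid
#'
#' Describes the participant x drug x condition crossing that defines a
#' cohort. Every downstream result table is keyed by this grid; cells for
#' which no recording exists must be declared in `missing_cells`, never
#' silently dropped.
#'
#' @param participant_ids character vector of unique participant labels.
#' @param drug_levels exactly two labels; the first is treated as the
#'   control level, the second as the drug level.
#' @param condition_levels one or more condition labels. Defaults to the
#'   four standard recording conditions.
#' @param missing_cells optional data.frame with columns `participant`,
#'   `drug`, `condition` naming grid cells with no data.
#' @return an object of class `study_design`.
#' @export
study_design <- function(participant_ids,
                         drug_levels = c("control", "drug"),
                         condition_levels = c("Open", "Closed", "Music", "Video"),
                         missing_cells = NULL) {
  participant_ids <- as.character(participant_ids)
  if (anyDuplicated(participant_ids) > 0L)
    stop("participant_ids must be unique")
  if (length(drug_levels) != 2L || anyDuplicated(drug_levels) > 0L)
    stop("exactly two distinct drug_levels are required")
  if (length(condition_levels) < 1L)
    stop("at least one condition level is required")
  if (!is.null(missing_cells)) {
    stopifnot(is.data.frame(missing_cells),
              all(c("participant", "drug", "condition") %in% names(missing_cells)))
  }
  structure(
    list(participant_ids = participant_ids,
         drug_levels = as.character(drug_levels),
         condition_levels = as.character(condition_levels),
         missing_cells = missing_cells),
    class = "study_design")
}

#' Full dataset grid of a study design
#'
#' @param design a [study_design()].
#' @param drop_missing drop declared missing cells from the grid.
#' @return data.frame with columns participant, drug, condition (one row per
#'   dataset).
#' @export
design_grid <- function(design, drop_missing = TRUE) {
  stopifnot(inherits(design, "study_design"))
  g <- expand.grid(condition = design$condition_levels,
                   drug = design$drug_levels,
                   participant = design$participant_ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("participant", "drug", "condition")]
  if (drop_missing && !is.null(design$missing_cells) && nrow(design$missing_cells)) {
    key <- function(d) paste(d$participant, d$drug, d$condition, sep = "\r")
    g <- g[!key(g) %in% key(design$missing_cells), , drop = FALSE]
  }
  rownames(g) <- NULL
  g
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", length(x$participant_ids), " participants x ",
      paste(x$drug_levels, collapse = "/"), " x ",
      length(x$condition_levels), " conditions (",
      nrow(design_grid(x)), " datasets)\n", sep = "")
  invisible(x)
}

#' Epoched amplitude-envelope container
#'
#' Holds a 3-axis array of envelope values, `[epoch, region, sample]`,
#' together with the sampling rate and region labels. All values must be
#' finite; every epoch has the same length `round(fs * epoch_length_s)`.
#'
#' @param values numeric array `[n_epochs, n_regions, n_samples]`.
#' @param fs sampling rate in Hz.
#' @param region_labels character vector, one per region. Default `R1..Rn`.
#' @param epoch_length_s epoch duration in seconds; default inferred from
#'   the array and `fs`.
#' @return object of class `envelope_epochs`.
#' @export
envelope_epochs <- function(values, fs, region_labels = NULL,
                            epoch_length_s = dim(values)[3] / fs) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-axis array [epochs x regions x samples]")
  if (!all(is.finite(values)))
    stop("envelope values must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar sampling rate in Hz")
  d <- dim(values)
  if (d[3] != round(fs * epoch_length_s))
    stop("n_samples (", d[3], ") != round(fs * epoch_length_s) (",
         round(fs * epoch_length_s), ")")
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(d[2]))
  if (length(region_labels) != d[2])
    stop("region_labels length must equal the number of regions")
  structure(
    list(values = values, fs = fs,
         region_labels = as.character(region_labels),
         epoch_length_s = epoch_length_s),
    class = "envelope_epochs")
}

#' @export
print.envelope_epochs <- function(x, ...) {
  d <- dim(x$values)
  cat("<envelope_epochs> ", d[1], " epochs x ", d[2], " regions x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' @export
dim.envelope_epochs <- function(x) dim(x$values)

n_epochs  <- function(env) dim(env$values)[1]
n_regions <- function(env) dim(env$values)[2]
n_samples <- function(env) dim(env$values)[3]

#' Extract one epoch as a regions x samples matrix
#'
#' @param env an [envelope_epochs()] object.
#' @param i epoch index.
#' @return numeric matrix with region labels as rownames.
#' @export
epoch_matrix <- function(env, i) {
  stopifnot(inherits(env, "envelope_epochs"),
            i >= 1L, i <= n_epochs(env))
  m <- env$values[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # single-region edge case
  rownames(m) <- env$region_labels
  m
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. Seeds are mandatory for
#' every stochastic stage: forgetting one is an error, not a silent default,
#' so that permutation and classifier results are always replayable.
#'
#' @param tau_samples positive integer lag, in samples.
#' @param threshold_percentile percentile in (0, 100) used when averaging
#'   irreversibility and asymmetry values (default 95).
#' @param window_length_s sliding-window length in seconds (default 1).
#' @param window_overlap fractional overlap of consecutive windows in
#'   `[0, 1)` (default 0.8).
#' @param n_permutations permutations for label-shuffling tests.
#' @param seeds named list of integer seeds, one per stochastic stage
#'   (e.g. `list(permutation = 1L, classifier = 2L, surrogate = 3L)`).
#' @param n_folds folds for cross-validated lag selection (default 8).
#' @param threshold logical; FALSE computes unthresholded (plain-mean)
#'   variants of the irreversibility summaries.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(tau_samples,
                            threshold_percentile = 95,
                            window_length_s = 1.0,
                            window_overlap = 0.8,
                            n_permutations = 1000L,
                            seeds = NULL,
                            n_folds = 8L,
                            threshold = TRUE) {
  stopifnot(is.numeric(tau_samples), length(tau_samples) == 1L,
            tau_samples >= 1, tau_samples == round(tau_samples))
  if (threshold_percentile <= 0 || threshold_percentile >= 100)
    stop("threshold_percentile must lie strictly between 0 and 100")
  if (window_overlap < 0 || window_overlap >= 1)
    stop("window_overlap must lie in [0, 1)")
  if (is.null(seeds) || length(seeds) == 0L)
    stop("seeds are mandatory: supply a named list with one integer seed per ",
         "stochastic stage")
  if (is.null(names(seeds)) || any(names(seeds) == ""))
    stop("seeds must be a *named* list")
  structure(
    list(tau_samples = as.integer(tau_samples),
         threshold_percentile = threshold_percentile,
         window_length_s = window_length_s,
         window_overlap = window_overlap,
         n_permutations = as.integer(n_permutations),
         seeds = lapply(seeds, as.integer),
         n_folds = as.integer(n_folds),
         threshold = isTRUE(threshold)),
    class = "analysis_config")
}

# Required seed lookup; absence is an error by design.
config_seed <- function(config, stage) {
  s <- config$seeds[[stage]]
  if (is.null(s)) stop("no seed configured for stage '", stage, "'")
  s
}

#' Validate a long-format result table
#'
#' A result table has one row per (dataset, metric): columns `participant`,
#' `drug`, `condition`, `metric`, `value`, and optionally `tau` plus extra
#' keys. Values must be finite unless flagged in a logical `missing` column.
#'
#' @param table data.frame to validate.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_result_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("participant", "drug", "condition", "metric", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("result table missing columns: ", paste(miss, collapse = ", "))
  ok <- is.finite(table$value)
  if (!is.null(table$missing)) ok <- ok | table$missing
  if (!all(ok))
    stop("non-finite value(s) in rows ", paste(which(!ok), collapse = ", "),
         " without a missing flag")
  invisible(table)
}
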