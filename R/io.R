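#' Write an envelope container
#'
#' Plain-text container for epoched envelopes: a directory holding one TSV
#' per epoch (`epoch_0001.tsv`, ... — samples as rows, regions as columns
#' with labels in the header) plus a `meta.json` sidecar recording the
#' sampling rate, epoch length and region labels.
#'
#' @param env an [envelope_epochs()] object.
#' @param path directory to create (must not be an existing file).
#' @return `path`, invisibly.
#' @export
write_envelopes <- function(env, path) {
  stopifnot(inherits(env, "envelope_epochs"))
  if (file.exists(path) && !dir.exists(path))
    stop("path exists and is not a directory: ", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(fs = env$fs, epoch_length_s = env$epoch_length_s,
               region_labels = env$region_labels, n_epochs = n_epochs(env))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (e in seq_len(n_epochs(env))) {
    d <- as.data.frame(t(epoch_matrix(env, e)))
    names(d) <- env$region_labels
    utils::write.table(d, file.path(path, sprintf("epoch_%04d.tsv", e)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an envelope container
#'
#' Reads the TSV container written by [write_envelopes()]. A single TSV
#' *file* (one epoch, regions as columns) is also accepted; the sampling
#' rate must then be supplied via `fs`.
#'
#' @param path container directory or single-epoch TSV file.
#' @param format `"tsv"` (the plain-text container). `"hdf5"` is
#'   recognized for interface compatibility but not available in this
#'   build.
#' @param fs sampling rate override, required for bare single-epoch TSVs.
#' @return an [envelope_epochs()] object.
#' @export
read_envelopes <- function(path, format = c("tsv", "hdf5"), fs = NULL) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 containers are not supported by this build; use the TSV container")
  if (dir.exists(path)) {
    metafile <- file.path(path, "meta.json")
    if (!file.exists(metafile))
      stop("schema error: container missing meta.json (no sampling rate)")
    meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("schema error: meta.json has no fs attribute")
    files <- sort(list.files(path, pattern = "^epoch_\\d+\\.tsv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("container has no epoch files")
    eps <- lapply(files, function(f)
      as.matrix(utils::read.delim(f, check.names = FALSE)))
    shapes <- vapply(eps, dim, integer(2))
    if (length(unique(shapes[1, ])) > 1 || length(unique(shapes[2, ])) > 1)
      stop("shape error: ragged epochs (",
           paste(apply(shapes, 2, paste, collapse = "x"), collapse = ", "), ")")
    vals <- array(0, dim = c(length(eps), ncol(eps[[1]]), nrow(eps[[1]])))
    for (e in seq_along(eps)) vals[e, , ] <- t(eps[[e]])
    envelope_epochs(vals, fs = meta$fs,
                    region_labels = meta$region_labels %||% colnames(eps[[1]]),
                    epoch_length_s = meta$epoch_length_s %||%
                      (dim(vals)[3] / meta$fs))
  } else if (file.exists(path)) {
    if (is.null(fs)) stop("schema error: single-file TSV has no sampling rate; ",
                          "supply fs")
    m <- as.matrix(utils::read.delim(path, check.names = FALSE))
    vals <- array(t(m), dim = c(1, ncol(m), nrow(m)))
    envelope_epochs(vals, fs = fs, region_labels = colnames(m))
  } else stop("no such file or directory: ", path)
}

#' Write a result table
#'
#' Validates and writes a long-format result table as TSV (or JSON by
#' extension). Tables round-trip through [read_results()].
#'
#' @param table result data.frame (see [validate_result_table()]).
#' @param path output path (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  validate_result_table(table)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  tb <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  validate_result_table(tb)
  tb
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file mirroring the [analysis_config()] fields.
#' @return an `analysis_config` object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y)
}

#' Run the full pipeline on a cohort of envelope containers
#'
#' Executes the analysis stages in order on one dataset per design-grid
#' cell — irreversibility (at the configured lag), hierarchy summaries,
#' recurrence dynamics, undirected FC — then the cohort-level inference
#' (paired permutation tests per condition, repeated-measures ANOVA), and
#' returns a long result table plus a machine-readable run manifest
#' carrying every seed. Reruns with the same configuration and seeds are
#' bit-identical.
#'
#' @param config an [analysis_config()] (seeds required).
#' @param design a [study_design()].
#' @param data data source: either a directory containing one envelope
#'   container per cell named `participant_drug_condition`, or a named
#'   list of [envelope_epochs()] keyed `"participant|drug|condition"`
#'   (e.g. from [make_cohort()]).
#' @param stages subset of `c("irreversibility", "hierarchy", "dynamics",
#'   "ufc")` to run (default all).
#' @param verbose log each stage (default TRUE).
#' @return list of class `pipeline_result`: `table` (long results),
#'   `tests` (per-condition paired permutation p per metric), `anova`
#'   (rm-ANOVA per metric), `manifest`.
#' @export
run_pipeline <- function(config, design, data,
                         stages = c("irreversibility", "hierarchy",
                                    "dynamics", "ufc"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "analysis_config"), inherits(design, "study_design"))
  stages <- match.arg(stages, several.ok = TRUE)
  grid <- design_grid(design)
  key <- paste(grid$participant, grid$drug, grid$condition, sep = "|")
  log_msg <- function(...) if (verbose) message("[pipeline] ", ...)
  if (is.character(data) && length(data) == 1L) {
    dirnames <- file.path(data, paste(grid$participant, grid$drug,
                                      grid$condition, sep = "_"))
    missing_cells <- !dir.exists(dirnames)
    if (any(missing_cells))
      stop("missing envelope container(s) for cell(s): ",
           paste(utils::head(key[missing_cells], 5), collapse = ", "))
    log_msg("reading ", length(dirnames), " containers from ", data)
    datasets <- lapply(dirnames, read_envelopes)
    names(datasets) <- key
  } else {
    datasets <- data
    missing_keys <- setdiff(key, names(datasets))
    if (length(missing_keys))
      stop("missing dataset(s) for cell(s): ",
           paste(utils::head(missing_keys, 5), collapse = ", "))
  }
  ns <- n_samples(datasets[[key[1]]])
  if (config$tau_samples >= ns)
    stop("tau_samples (", config$tau_samples, ") must be < n_samples (", ns, ")")
  rows <- list()
  add <- function(k, metric, value, region = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(
      participant = grid$participant[k], drug = grid$drug[k],
      condition = grid$condition[k], metric = metric, value = value,
      tau = config$tau_samples, region = region, stringsAsFactors = FALSE)
  for (k in seq_along(key)) {
    env <- datasets[[key[k]]]
    if ("irreversibility" %in% stages) {
      ir <- dataset_irrev(env, config$tau_samples, config$threshold_percentile,
                          threshold = config$threshold)
      add(k, "irreversibility", ir$r)
    }
    if ("hierarchy" %in% stages) {
      pr <- asymmetry_profile(env, config$tau_samples,
                              config$threshold_percentile)
      add(k, "coherence", pr$coherence)
      add(k, "inhomogeneity", pr$inhomogeneity)
    }
    if ("ufc" %in% stages) add(k, "ufc", mean_undirected_fc(env))
    if ("dynamics" %in% stages) {
      ts <- sliding_metric(env, "irreversibility", config$tau_samples,
                           config$threshold_percentile,
                           config$window_length_s, config$window_overlap)
      add(k, "recurrence_rate", as.numeric(metric_recurrence_rate(ts)))
    }
  }
  table <- do.call(rbind, rows)
  log_msg("computed ", nrow(table), " metric values over ", length(key),
          " datasets")
  control <- design$drug_levels[1]
  metrics <- unique(table$metric)
  perm_seed <- config_seed(config, "permutation")
  tests <- do.call(rbind, lapply(metrics, function(mt) {
    do.call(rbind, lapply(design$condition_levels, function(cond) {
      sub <- table[table$metric == mt & table$condition == cond, ]
      sub <- sub[order(sub$participant), ]
      a <- sub$value[sub$drug == control]
      b <- sub$value[sub$drug != control]
      data.frame(metric = mt, condition = cond,
                 mean_control = mean(a), mean_drug = mean(b),
                 p = paired_permutation(a, b, config$n_permutations,
                                        seed = perm_seed)$p)
    }))
  }))
  # single-level factors cannot enter the ANOVA (e.g. one-condition designs)
  anova_factors <- c("drug", "condition")[c(TRUE,
                                            length(design$condition_levels) > 1)]
  anovas <- lapply(stats::setNames(metrics, metrics), function(mt)
    rm_anova(table[table$metric == mt, ], factors = anova_factors))
  log_msg("inference complete")
  manifest <- list(config = unclass(config),
                   design = unclass(design)[c("participant_ids", "drug_levels",
                                              "condition_levels")],
                   stages = stages, n_datasets = length(key))
  structure(list(table = table, tests = tests, anova = anovas,
                 manifest = manifest),
            class = "pipeline_result")
}
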