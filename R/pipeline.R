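#' Build an end-to-end run configuration
#'
#' Describes a complete evaluation run: the cohort to simulate (or a
#' directory of recordings to load), which identification and authentication
#' arms to execute, template options, and the global seed that fans out to
#' every stochastic stage.
#'
#' Identification arms are lists with `method` ("classifier" or "distance"),
#' and for classifiers `classifier` ("lda"/"knn"/"dt"/"svm") plus
#' `config` ("20/20" or "60/60"); distance arms take `config` ("1/1" or
#' "1/3") and `kind` ("cycles" or "scalograms"). Authentication arms take
#' `config`, `kind`, and `ica` (logical). All arms take `normalized`.
#'
#' @param cohort a [cohort_spec()], an `ecg_cohort`, or a directory path
#'   written by [write_cohort()].
#' @param identify list of identification arms.
#' @param authenticate list of authentication arms.
#' @param scalogram_size side length for scalogram templates.
#' @param n_components ICA components (default: number of subjects).
#' @param out_dir optional directory for JSON reports and the run manifest.
#' @param seed global integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       identify = list(list(method = "classifier",
                                            classifier = "lda",
                                            config = "60/60",
                                            normalized = TRUE)),
                       authenticate = list(list(config = "1/1",
                                                kind = "cycles",
                                                normalized = FALSE,
                                                ica = TRUE)),
                       scalogram_size = 56, n_components = NULL,
                       out_dir = NULL, seed = 1) {
  structure(list(cohort = cohort, identify = identify,
                 authenticate = authenticate,
                 scalogram_size = scalogram_size,
                 n_components = n_components, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

arm_k <- function(config) {
  switch(config, "20/20" = 20L, "60/60" = 60L, "1/1" = 20L, "1/3" = 60L,
         stop(sprintf("unknown configuration label '%s'", config)))
}

# enrollment/presentation matrices for a distance or authentication arm;
# session-2 data never touches the ICA fit (session firewall)
arm_matrices <- function(sets1, sets2, arm, fs, scalogram_size,
                         n_components, seed) {
  kind <- arm$kind %||% "cycles"
  row_templates <- function(cset) {
    if (kind == "cycles") cset$cycles
    else scalogram_templates(cset, fs, size = scalogram_size)
  }
  split3 <- function(cset) {
    stopifnot(cset$k == 60L)
    lapply(0:2, function(b) {
      s <- cset; s$cycles <- cset$cycles[(b * 20 + 1):(b * 20 + 20)]
      s$k <- 20L; s
    })
  }
  train <- concatenate_subject_templates(lapply(sets1, row_templates))
  if (arm$config == "1/1") {
    tests <- list(concatenate_subject_templates(lapply(sets2, row_templates)))
  } else {
    blocks <- lapply(sets2, split3)
    tests <- lapply(1:3, function(m)
      concatenate_subject_templates(lapply(blocks, function(b)
        row_templates(b[[m]]))))
  }
  if (isTRUE(arm$ica) || is.null(arm$ica)) {
    d <- n_components %||% nrow(train)
    model <- fit_ica(train, n_components = d, seed = seed)
    train <- transform_with_ica(train, model)
    tests <- lapply(tests, transform_with_ica, model = model)
  }
  list(train = train, tests = tests)
}

#' Execute an end-to-end evaluation run
#'
#' Stages run in order: simulate (or load) the cohort, preprocess both
#' sessions into cycle template sets, build the requested templates, and
#' evaluate every identification and authentication arm. Session-2 data
#' never influences a fitted component (classifier or ICA model). Reports
#' are returned and, when `out_dir` is set, written as JSON alongside a run
#' manifest with content digests.
#'
#' @param config a [run_config()].
#' @return list with `reports` (named list of `ident_report`/`auth_report`)
#'   and `manifest` (data frame of stage outputs with md5 digests).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("run_pipeline: config must be a run_config")
  cohort <- config$cohort
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  else if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!inherits(cohort, "ecg_cohort")) stop("run_pipeline: invalid cohort input")
  recs1 <- cohort_session(cohort, 1)
  recs2 <- cohort_session(cohort, 2)
  fs <- recs1[[1]]$fs

  cache <- new.env(parent = emptyenv())
  get_sets <- function(session, k, normalized) {
    key <- sprintf("s%d_k%d_n%d", session, k, normalized)
    if (!is.null(cache[[key]])) return(cache[[key]])
    recs <- if (session == 1) recs1 else recs2
    sets <- lapply(recs, extract_cycle_templates, k = k,
                   normalize = normalized)
    cache[[key]] <- sets
    sets
  }

  reports <- list()
  for (arm in config$identify) {
    normalized <- isTRUE(arm$normalized)
    if (arm$method == "classifier") {
      k <- arm_k(arm$config)
      rep <- identify_with_classifier(get_sets(1, k, normalized),
                                      get_sets(2, k, normalized),
                                      classifier = arm$classifier,
                                      seed = config$seed)
    } else if (arm$method == "distance") {
      mats <- arm_matrices(get_sets(1, 20L, normalized),
                           get_sets(2, arm_k(arm$config), normalized),
                           arm, fs, config$scalogram_size,
                           config$n_components, config$seed)
      test <- if (arm$config == "1/1") mats$tests[[1]] else mats$tests
      rep <- identify_with_distance(mats$train, test, config = arm$config)
    } else stop(sprintf("run_pipeline: unknown identify method '%s'", arm$method))
    nm <- sprintf("identify_%s_%s_%s",
                  if (arm$method == "classifier") arm$classifier else "distance",
                  gsub("/", "-", arm$config),
                  if (normalized) "norm" else "raw")
    reports[[nm]] <- rep
  }
  for (arm in config$authenticate) {
    normalized <- isTRUE(arm$normalized)
    mats <- arm_matrices(get_sets(1, 20L, normalized),
                         get_sets(2, arm_k(arm$config), normalized),
                         arm, fs, config$scalogram_size,
                         config$n_components, config$seed)
    test <- if (arm$config == "1/1") mats$tests[[1]] else mats$tests
    rep <- authenticate(mats$train, test, config = arm$config)
    nm <- sprintf("authenticate_%s_%s_%s", arm$kind %||% "cycles",
                  gsub("/", "-", arm$config),
                  if (normalized) "norm" else "raw")
    reports[[nm]] <- rep
  }

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(reports), function(nm) {
      p <- file.path(config$out_dir, paste0(nm, ".json"))
      write_report(reports[[nm]], p)
      p
    }, character(1))
    manifest <- data.frame(stage = names(reports), path = paths,
                           md5 = unname(tools::md5sum(paths)),
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                           row.names = NULL, stringsAsFactors = FALSE)
    utils::write.csv(manifest,
                     file.path(config$out_dir, "run_manifest.csv"),
                     row.names = FALSE)
  }
  list(reports = reports, manifest = manifest)
}

#' Load a run configuration from YAML or JSON
#'
#' The file mirrors [run_config()]: top-level `cohort` (fields of
#' [cohort_spec()], or a `dir` to load), `identify` and `authenticate` arm
#' lists, and the scalar options.
#'
#' @param path YAML (.yml/.yaml, requires the yaml package) or JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_run_config: the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- if (!is.null(cfg$cohort$dir)) cfg$cohort$dir
            else do.call(cohort_spec, cfg$cohort %||% list())
  as_arms <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
    lapply(x, as.list)
  }
  run_config(cohort = cohort,
             identify = as_arms(cfg$identify) %||% list(),
             authenticate = as_arms(cfg$authenticate) %||% list(),
             scalogram_size = cfg$scalogram_size %||% 56,
             n_components = cfg$n_components,
             out_dir = cfg$out_dir, seed = cfg$seed %||% 1)
}
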