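## Session persistence (plain-text store: per-channel CSV + JSON metadata,
## cohort manifest) and the adapter for real recordings (MAT files read via
## a python/scipy bridge; the package's own CSV store read natively).

#' Write a session to a plain-text directory store
#'
#' One directory per session: `<channel>.csv` (single `value` column) per
#' channel and a `meta.json` carrying subject id, scenario, per-channel
#' sampling rates, the ground-truth interval table and the generator seed.
#'
#' @param session an `hr_session`
#' @param dir target directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_session_dir <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(session$channels)) {
    ch <- session$channels[[nm]]
    # 17 significant digits: doubles survive the text round trip exactly
    writeLines(c("value", sprintf("%.17g", ch$samples)),
               file.path(dir, paste0(nm, ".csv")))
  }
  meta <- list(subject_id = session$subject_id, scenario = session$scenario,
               fs = lapply(session$channels, `[[`, "fs"),
               ground_truth = session$ground_truth,
               seed = session$seed %||% NA)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a session back from the plain-text store
#'
#' @param dir session directory written by [write_session_dir()]
#' @return an `hr_session` (without the generator script/config)
#' @export
read_session_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  chans <- list()
  for (nm in names(meta$fs)) {
    v <- read.csv(file.path(dir, paste0(nm, ".csv")))$value
    chans[[nm]] <- channel(nm, v, meta$fs[[nm]])
  }
  structure(list(subject_id = meta$subject_id, scenario = meta$scenario,
                 channels = chans,
                 ground_truth = as.data.frame(meta$ground_truth),
                 seed = meta$seed),
            class = "hr_session")
}

#' Write a cohort with a manifest
#'
#' Each session goes into `<out_dir>/<subject>_<scenario>/`; a
#' `manifest.csv` (subject_id, scenario, dir, seed) indexes the cohort.
#'
#' @param cohort list of `hr_session`
#' @param out_dir output directory
#' @return manifest data.frame, invisibly
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(subject_id = character(0), scenario = character(0),
                         dir = character(0), seed = integer(0))
  for (sess in cohort) {
    sub <- paste0(sess$subject_id, "_", sess$scenario)
    write_session_dir(sess, file.path(out_dir, sub))
    manifest <- rbind(manifest,
                      data.frame(subject_id = sess$subject_id,
                                 scenario = sess$scenario, dir = sub,
                                 seed = sess$seed %||% NA_integer_))
  }
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a real recording session
#'
#' Adapter for externally recorded sessions. Channel names in the source
#' file are not hard-coded: `channel_map` maps each canonical channel name
#' (`radar_i`, `radar_q`, `ecg1`, `ecg2`, `icg`, `bp`, `z0`, `marker`) to
#' the variable name used in the file, and `fs_map` gives the sampling rate
#' per canonical channel (required for formats that do not store it).
#'
#' Supported sources: a directory in the package's CSV session store (read
#' natively; `channel_map`/`fs_map` optional), or a MATLAB `.mat` file,
#' which is converted through the `python` + `scipy.io.loadmat` bridge.
#'
#' @param path session directory or `.mat` file
#' @param channel_map named character vector, canonical -> source name
#' @param fs_map named numeric vector of sampling rates (Hz) per canonical
#'   channel
#' @param scenario scenario tag of the session
#' @param subject_id subject identifier
#' @return an `hr_session`
#' @export
load_real_session <- function(path, channel_map = NULL, fs_map = NULL,
                              scenario = "Resting", subject_id = "unknown") {
  canonical <- c("radar_i", "radar_q", "ecg1", "ecg2", "icg", "bp", "z0",
                 "marker")
  if (dir.exists(path)) {
    sess <- read_session_dir(path)
    if (!is.null(channel_map)) {
      missing <- setdiff(canonical, names(channel_map))
      if (length(missing)) {
        stop("channel_map does not name: ", paste(missing, collapse = ", "))
      }
      chans <- list()
      for (nm in canonical) {
        src <- channel_map[[nm]]
        if (is.null(sess$channels[[src]])) {
          stop("source is missing mapped variable '", src, "' for ", nm)
        }
        ch <- sess$channels[[src]]
        chans[[nm]] <- channel(nm, ch$samples,
                               fs_map[[nm]] %||% ch$fs)
      }
      sess$channels <- chans
    }
    return(sess)
  }
  if (!file.exists(path)) stop("no such session source: ", path)
  if (!grepl("\\.mat$", path, ignore.case = TRUE)) {
    stop("unsupported session source: ", path)
  }
  if (is.null(channel_map) || is.null(fs_map)) {
    stop("MAT sources need a channel_map and an fs_map")
  }
  missing <- setdiff(canonical, names(channel_map))
  if (length(missing)) {
    stop("channel_map does not name: ", paste(missing, collapse = ", "))
  }
  tmp <- tempfile("matbridge")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  vars <- unname(channel_map[canonical])
  script <- paste(
    "import sys, csv",
    "from scipy.io import loadmat",
    "m = loadmat(sys.argv[1], squeeze_me=True)",
    "out = sys.argv[2]",
    "for v in sys.argv[3].split(','):",
    "    if v not in m: sys.exit('missing variable: ' + v)",
    "    vals = m[v].ravel()",
    "    with open(out + '/' + v + '.csv', 'w', newline='') as fh:",
    "        w = csv.writer(fh); w.writerow(['value'])",
    "        for x in vals: w.writerow([float(x)])",
    sep = "\n")
  res <- system2("python", c("-c", shQuote(script), shQuote(path),
                             shQuote(tmp), paste(vars, collapse = ",")),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status") %||% 0
  if (status != 0) {
    stop("MAT bridge failed: ", paste(res, collapse = "\n"))
  }
  chans <- list()
  for (nm in canonical) {
    src <- channel_map[[nm]]
    f <- file.path(tmp, paste0(src, ".csv"))
    if (!file.exists(f)) stop("source is missing mapped variable '", src,
                              "' for ", nm)
    chans[[nm]] <- channel(nm, read.csv(f)$value, fs_map[[nm]])
  }
  structure(list(subject_id = subject_id, scenario = scenario,
                 channels = chans,
                 ground_truth = data.frame(start = numeric(0),
                                           end = numeric(0),
                                           class = character(0))),
            class = "hr_session")
}

#' Write experiment results to plain-text files
#'
#' Emits a JSON experiment summary, a per-fold metrics CSV, the mean
#' row-normalized confusion matrix CSV, and a long-format per-epoch history
#' CSV (train/validation accuracy and loss per fold).
#'
#' @param experiment an `hr_experiment`
#' @param out_dir output directory
#' @param prefix file-name prefix
#' @return character vector of written paths, invisibly
#' @export
write_experiment <- function(experiment, out_dir, prefix = "experiment") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- experiment$config
  summary <- list(modality = cfg$modality, data_type = cfg$data_type,
                  k = cfg$k, fold_mode = cfg$fold_mode,
                  leakage = cfg$leakage, rng_seed = cfg$rng_seed,
                  n_instances = cfg$n_instances,
                  hyperparams = unclass(cfg$hp),
                  mean_accuracy = experiment$mean_accuracy,
                  fold_accuracies = experiment$fold_accuracies)
  p1 <- file.path(out_dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summary, p1, auto_unbox = TRUE, digits = NA)
  folds <- data.frame(
    fold = vapply(experiment$folds, `[[`, 1, "fold"),
    accuracy = vapply(experiment$folds, `[[`, 1, "accuracy"),
    n_test = vapply(experiment$folds, `[[`, 1, "n_test"),
    border_subjects = vapply(experiment$folds, `[[`, 1, "border_subjects"))
  p2 <- file.path(out_dir, paste0(prefix, "_folds.csv"))
  write.csv(folds, p2, row.names = FALSE)
  p3 <- file.path(out_dir, paste0(prefix, "_confusion.csv"))
  write.csv(as.data.frame(experiment$mean_confusion), p3)
  hist <- do.call(rbind, lapply(experiment$folds, function(fr) {
    cbind(fold = fr$fold, fr$history)
  }))
  p4 <- file.path(out_dir, paste0(prefix, "_history.csv"))
  write.csv(hist, p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
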