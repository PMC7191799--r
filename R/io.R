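## Episode CSV schema, transition-model archives, and run manifests.
##
## Episode CSV: comma-separated, UTF-8, '.' decimal, mandatory header with
## columns time_h, bg_mmol_L (blank when no measurement), insulin_bolus_U,
## insulin_rate_U_h, enteral_pct_gf, dextrose_bolus_mmol. An optional
## leading comment line "# goal_feed_mmol_h: <value>" carries the
## patient-specific goal feed (default 65 mmol/h when absent).

.episode_cols <- c("time_h", "bg_mmol_L", "insulin_bolus_U",
                   "insulin_rate_U_h", "enteral_pct_gf",
                   "dextrose_bolus_mmol")

#' Read an episode record from CSV
#'
#' @param path CSV file (one episode per file).
#' @param patient_id identifier; default the file name without extension.
#' @return an \code{\link{episode_record}}.
#' @export
read_episode_csv <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stopf("episode file not found: %s", path)
  first <- readLines(path, n = 1)
  gf <- 65
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("goal_feed_mmol_h:\\s*([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) gf <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(.episode_cols, names(df))
  if (length(missing))
    stopf("episode CSV %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  df <- df[, .episode_cols]
  if (is.unsorted(df$time_h, strictly = TRUE)) {
    bad <- which(diff(df$time_h) <= 0)[1] + 1L
    stopf("time_h not strictly increasing at row %d of %s", bad, path)
  }
  for (col in .episode_cols[3:6]) {
    neg <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(neg)) stopf("negative %s at row %d of %s", col, neg[1], path)
  }
  meas <- df[!is.na(df$bg_mmol_L), c("time_h", "bg_mmol_L")]
  pick <- function(col, out_names) {
    keep <- !is.na(df[[col]])   # zero entries are meaningful (rate -> 0)
    if (!any(keep)) return(NULL)
    stats::setNames(df[keep, c("time_h", col)], out_names)
  }
  inputs <- input_schedule(
    insulin_boluses = pick("insulin_bolus_U", c("time_h", "units")),
    insulin_rates = pick("insulin_rate_U_h", c("time_h", "rate_U_h")),
    enteral = pick("enteral_pct_gf", c("time_h", "pct_gf")),
    dextrose = pick("dextrose_bolus_mmol", c("time_h", "mmol")),
    goal_feed = gf)
  episode_record(patient_id %||% tools::file_path_sans_ext(basename(path)),
                 meas, inputs)
}

#' Write an episode record as CSV (canonical form)
#'
#' All event times are merged onto one strictly increasing time column;
#' empty cells mean "no entry". Reading the file back reproduces the
#' record.
#'
#' @param episode an \code{\link{episode_record}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_episode_csv <- function(episode, path) {
  stopifnot(inherits(episode, "episode_record"))
  inp <- episode$inputs
  times <- sort(unique(c(episode$measurements$time_h,
                         inp$insulin_boluses$time_h, inp$insulin_rates$time_h,
                         inp$enteral$time_h, inp$dextrose$time_h)))
  df <- data.frame(time_h = times)
  put <- function(src, valcol) {
    out <- rep(NA_real_, length(times))
    if (nrow(src)) out[match(src$time_h, times)] <- src[[valcol]]
    out
  }
  df$bg_mmol_L <- put(episode$measurements, "bg_mmol_L")
  df$insulin_bolus_U <- put(inp$insulin_boluses, "units")
  df$insulin_rate_U_h <- put(inp$insulin_rates, "rate_U_h")
  df$enteral_pct_gf <- put(inp$enteral, "pct_gf")
  df$dextrose_bolus_mmol <- put(inp$dextrose, "mmol")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# goal_feed_mmol_h: %.17g", inp$goal_feed), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Save transition models to a JSON archive
#'
#' Stores kernel centres, bandwidths, positive-domain normalisers, horizon
#' and training provenance for every horizon (and fold, for a model set) at
#' full double precision, so a reload is bit-exact.
#'
#' @param models an \code{si_transition}, a per-horizon list of them, or an
#'   \code{si_transition_set}.
#' @param path output file (.json).
#' @return \code{path}, invisibly.
#' @export
save_transition_models <- function(models, path) {
  payload <- list(format = "stargc-transition-models", version = 1L,
                  package_version = as.character(utils::packageVersion("stargc")))
  strip <- function(m) unclass(m)
  if (inherits(models, "si_transition")) {
    payload$kind <- "single"
    payload$model <- strip(models)
  } else if (inherits(models, "si_transition_set")) {
    payload$kind <- "set"
    payload$horizons <- models$horizons
    payload$seed <- models$seed
    payload$assignment <- list(patient_id = models$assignment$patient_id,
                               fold = models$assignment$fold)
    payload$folds <- lapply(models$folds, function(f)
      list(train_patients = f$train_patients,
           test_patients = f$test_patients,
           models = lapply(f$models, strip)))
  } else if (is.list(models)) {
    payload$kind <- "horizon_list"
    payload$models <- lapply(models, strip)
  } else stopf("unsupported models object")
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load transition models saved by \code{\link{save_transition_models}}
#'
#' @param path archive path.
#' @return the reconstructed object.
#' @export
load_transition_models <- function(path) {
  if (!file.exists(path)) stopf("model archive not found: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "stargc-transition-models"))
    stopf("%s is not a transition-model archive", path)
  dress <- function(m) {
    m$train_patients <- as.character(m$train_patients)
    for (f in c("cx", "cy", "sx", "sy", "px", "py", "grid", "si_range",
                "sigma_min", "horizon"))
      m[[f]] <- as.numeric(m[[f]])
    m$n <- as.integer(m$n)
    m$k <- as.integer(m$k)
    structure(m, class = "si_transition")
  }
  if (payload$kind == "single") return(dress(payload$model))
  if (payload$kind == "horizon_list") {
    out <- lapply(payload$models, dress)
    return(out)
  }
  folds <- lapply(payload$folds, function(f)
    list(train_patients = as.character(f$train_patients),
         test_patients = as.character(f$test_patients),
         models = lapply(f$models, dress)))
  assignment <- data.frame(
    patient_id = as.character(payload$assignment$patient_id),
    fold = as.integer(payload$assignment$fold),
    stringsAsFactors = FALSE)
  structure(list(folds = folds, horizons = as.integer(payload$horizons),
                 assignment = assignment, seed = payload$seed),
            class = "si_transition_set")
}

#' Run manifest
#'
#' A provenance record for an output directory: configuration snapshot,
#' seeds, input-file hashes and package version. Contains no wall-clock
#' fields so identical runs yield identical manifests.
#'
#' @param config a list (or classed config object) describing the run.
#' @param seed integer seed(s) used.
#' @param files character vector of input files to hash (md5).
#' @return a \code{run_manifest} list.
#' @export
run_manifest <- function(config = list(), seed = NA_integer_,
                         files = character()) {
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  structure(list(package = "stargc",
                 package_version = as.character(utils::packageVersion("stargc")),
                 seed = seed,
                 config = unclass(config),
                 file_md5 = hashes),
            class = "run_manifest")
}

#' Write a manifest to a directory
#'
#' @param manifest \code{run_manifest}.
#' @param dir output directory (one manifest per directory).
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
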