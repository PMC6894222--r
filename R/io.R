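mouse_public_cols <- c("mouse_id", "experiment_id", "group",
                       "develops_arthritis", "responder_class")

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a cohort dataset to a directory
#'
#' Writes `mice.csv` (public columns only) and `observations.csv` as plain
#' UTF-8 CSV with a header row, `.` decimal separator and empty fields for
#' missing values (e.g. the paw of whole-mouse modalities).
#'
#' @param dataset an `"arthrism_dataset"`.
#' @param dir output directory, created if needed.
#' @return the two file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mice_path <- file.path(dir, "mice.csv")
  obs_path <- file.path(dir, "observations.csv")
  write_table(dataset$mice[intersect(mouse_public_cols, names(dataset$mice))],
              mice_path)
  write_table(dataset$observations, obs_path)
  invisible(c(mice_path, obs_path))
}

#' Read and validate a cohort dataset
#'
#' Reads `mice.csv` and `observations.csv` from a directory and enforces the
#' schema: known groups and paw labels, finite values, integer clinical
#' scores in `[0, 10]`, withdrawal latencies within the 20 s cutoff,
#' referential integrity (every observation's mouse exists) and uniqueness
#' of (mouse, day, paw, modality) keys. Violations report offending rows.
#'
#' @param dir directory containing the two CSV files.
#' @return an `"arthrism_dataset"`.
#' @export
read_dataset <- function(dir) {
  mice_path <- file.path(dir, "mice.csv")
  obs_path <- file.path(dir, "observations.csv")
  for (p in c(mice_path, obs_path))
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
  mice <- utils::read.csv(mice_path, stringsAsFactors = FALSE,
                          na.strings = "", fileEncoding = "UTF-8")
  observations <- utils::read.csv(obs_path, stringsAsFactors = FALSE,
                                  na.strings = "", fileEncoding = "UTF-8",
                                  colClasses = c(paw = "character"))
  validate_dataset(mice, observations)
  structure(list(mice = mice, observations = observations),
            class = "arthrism_dataset")
}

validate_dataset <- function(mice, observations) {
  bad_rows <- function(cond, what) {
    if (any(cond)) {
      rows <- utils::head(which(cond), 10)
      stop(what, " (rows ", paste(rows, collapse = ", "),
           if (sum(cond) > 10) ", ..." else "", ")", call. = FALSE)
    }
  }
  need <- c("mouse_id", "experiment_id", "group")
  if (!all(need %in% names(mice)))
    stop("mice table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  need <- c("mouse_id", "day", "paw", "modality", "value")
  if (!all(need %in% names(observations)))
    stop("observations table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad_rows(!mice$group %in% valid_groups, "unknown group label in mice table")
  bad_rows(duplicated(mice$mouse_id), "duplicate mouse_id in mice table")
  bad_rows(!observations$mouse_id %in% mice$mouse_id,
           "observation refers to unknown mouse_id")
  bad_rows(!is.na(observations$paw) & !observations$paw %in% paw_levels,
           "paw label outside {LF, RF, LH, RH}")
  bad_rows(!is.finite(observations$value), "non-finite observation value")
  key <- paste(observations$mouse_id, observations$day, observations$paw,
               observations$modality, sep = "\r")
  bad_rows(duplicated(key), "duplicate (mouse, day, paw, modality) key")
  cs <- observations$modality == "clinical_score"
  bad_rows(cs & (observations$value < 0 | observations$value > 10 |
                   observations$value != round(observations$value)),
           "clinical score outside the integer grid [0, 10]")
  lat <- observations$modality == "latency_s"
  bad_rows(lat & (observations$value <= 0 | observations$value > 20),
           "withdrawal latency outside (0, 20] s")
  invisible(TRUE)
}

#' Serialize a deficit scale to JSON
#'
#' One entry per modality: slope, intercept, Spearman r, p, n_pairs,
#' reference, deficit_slope_per_pct, max_score; plus pairing, space and
#' optional provenance. Numbers are written with enough digits to
#' round-trip doubles exactly.
#'
#' @param object an `"arthrism"` scale.
#' @param path output path (conventionally `scale.json`).
#' @param provenance optional named list recorded verbatim.
#' @return `path`, invisibly.
#' @export
write_scale <- function(object, path, provenance = NULL) {
  stopifnot(inherits(object, "arthrism"))
  doc <- list(pairing = object$pairing, space = object$space,
              gaps = object$gaps,
              modalities = object$scale,
              provenance = provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Load a deficit scale from JSON
#'
#' Reconstructs an `"arthrism"` object usable with [predict.arthrism()],
#' [invert_scale()], [responsiveness_ratio()] and [plot.arthrism()]. The
#' pooled pairs and coefficient covariances are not stored in the file, so
#' [residuals.arthrism()] and [deficit_slope_ci()] are unavailable on a
#' loaded scale.
#'
#' @param path path to a `scale.json` written by [write_scale()].
#' @return an `"arthrism"` scale.
#' @export
read_scale <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  scale_tbl <- as.data.frame(doc$modalities, stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(scale_tbl)), function(i) as.list(scale_tbl[i, ]))
  names(fits) <- scale_tbl$modality
  structure(list(scale = scale_tbl, fits = fits, pairs = list(),
                 pairing = doc$pairing, space = doc$space,
                 gaps = unlist(doc$gaps) %||% character(),
                 provenance = doc$provenance, call = NULL),
            class = "arthrism")
}

# Order-insensitive-enough stable hash of the config for provenance lines
# (FNV-1a over the canonical JSON encoding).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = I(17))
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Chains simulate, score, normalize, build-scale and predict, writing each
#' stage's artifact to `out_dir`: `mice.csv`, `observations.csv`,
#' `scorecards.csv`, `responders.csv`, `relative_observations.csv`,
#' `scale.json` and `predictions.csv`. Fully deterministic for a fixed
#' config and seed (artifacts carry no timestamps), so repeated runs are
#' bitwise identical.
#'
#' @param config an [arthrism_config()]; `seed`, if given, overrides
#'   `config$seed`.
#' @param out_dir output directory.
#' @param stages subset of
#'   `c("simulate", "score", "normalize", "build-scale", "predict")`;
#'   later stages require the earlier ones' outputs in `out_dir`.
#' @param seed optional integer overriding `config$seed`.
#' @param pairing,space,strict passed to [arthrism()].
#' @param predict_score_pct scores (percent of maximum) tabulated into
#'   `predictions.csv`.
#' @return named character vector of the artifact paths, invisibly.
#' @export
run_pipeline <- function(config = arthrism_config(), out_dir,
                         stages = c("simulate", "score", "normalize",
                                    "build-scale", "predict"),
                         seed = NULL, pairing = "per-paw", space = "raw",
                         strict = FALSE,
                         predict_score_pct = c(10, 25, 50, 75, 100)) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(seed)) { config$seed <- as.integer(seed); validate_config(config) }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()

  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(config)
    write_dataset(cohort, out_dir)
    artifacts <- c(mice = file.path(out_dir, "mice.csv"),
                   observations = file.path(out_dir, "observations.csv"))
  }
  dataset <- read_dataset(out_dir)

  if ("score" %in% stages) {
    scorecards <- build_scorecards(dataset$observations)
    write_table(scorecards, file.path(out_dir, "scorecards.csv"))
    responders <- responder_table(scorecards, dataset$mice)
    write_table(responders, file.path(out_dir, "responders.csv"))
    artifacts <- c(artifacts,
                   scorecards = file.path(out_dir, "scorecards.csv"),
                   responders = file.path(out_dir, "responders.csv"))
  }

  if ("normalize" %in% stages) {
    rel <- relativize(dataset$observations, dataset$mice)
    write_table(rel, file.path(out_dir, "relative_observations.csv"))
    artifacts <- c(artifacts,
                   relative_observations = file.path(out_dir,
                                                     "relative_observations.csv"))
  }

  scale <- NULL
  if ("build-scale" %in% stages) {
    scale <- arthrism(dataset, pairing = pairing, space = space,
                      strict = strict)
    write_scale(scale, file.path(out_dir, "scale.json"),
                provenance = list(seed = config$seed,
                                  config_hash = config_hash(config)))
    artifacts <- c(artifacts, scale = file.path(out_dir, "scale.json"))
  }

  if ("predict" %in% stages) {
    if (is.null(scale)) scale <- read_scale(file.path(out_dir, "scale.json"))
    preds <- predict(scale, score_pct = predict_score_pct)
    write_table(preds, file.path(out_dir, "predictions.csv"))
    artifacts <- c(artifacts, predictions = file.path(out_dir, "predictions.csv"))
  }
  invisible(artifacts)
}
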