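#' Simulation configuration for CIA-like cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()]. Defaults emulate the pooled three-experiment design
#' of a typical collagen-induced-arthritis (CIA) study: naive, adjuvant-only
#' (CFA), untreated CIA and methotrexate (MTX)-treated groups, scored weekly
#' from the pre-boost baseline (day 14) to day 49, with 87.5% arthritis
#' incidence among immunized untreated mice and heterogeneous MTX response.
#'
#' @param n_per_group named integer vector or list giving mice per group and
#'   per experiment; names must be among `"naive"`, `"cfa"`, `"cia"`,
#'   `"cia_mtx"`. Defaults to 8/5/8/8 so that three experiments yield group
#'   totals of 24, 15, 24 and 24 animals.
#' @param n_experiments number of independent experiments.
#' @param timepoints strictly increasing study days on which every modality
#'   is measured. Default `c(14, 28, 35, 42, 49)`.
#' @param incidence probability that an immunized mouse develops arthritis.
#' @param responder_mix named probabilities of the `poor`, `mild` and `high`
#'   MTX responder classes; must sum to 1.
#' @param responder_ranges named list of length-2 numeric ranges for the
#'   multiplicative severity attenuation (`response_factor`) drawn within
#'   each responder class. 1 means no attenuation.
#' @param modality_params named list; each element is a list with fields
#'   `baseline` (naive value), `true_slope` (fractional change of the
#'   noiseless value at the maximal paired score; positive = loss), `noise_sd`
#'   (Gaussian noise SD), `level` (`"paw"` or `"mouse"`), and for paw-level
#'   modalities `lower`/`upper` physical truncation bounds (optional).
#' @param onset_day_mean,onset_day_sd mean and SD of the (Gaussian) arthritis
#'   onset day; onset is truncated to be after the immunization boost.
#' @param growth_rate logistic growth rate of the severity trajectory
#'   (per day).
#' @param rise_days days from onset to the logistic midpoint.
#' @param ceiling_range per-paw severity ceiling range (uniform draw) on the
#'   0-10 clinical grid.
#' @param missing_rate probability that any single observation is dropped.
#' @param seed integer seed; all randomness is derived from it.
#'
#' @return an object of class `"arthrism_config"` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
arthrism_config <- function(n_per_group = c(naive = 8L, cfa = 5L, cia = 8L, cia_mtx = 8L),
                            n_experiments = 3L,
                            timepoints = c(14, 28, 35, 42, 49),
                            incidence = 0.875,
                            responder_mix = c(poor = 6 / 23, mild = 6 / 23, high = 11 / 23),
                            responder_ranges = list(poor = c(0.8, 1.0),
                                                    mild = c(0.3, 0.7),
                                                    high = c(0.0, 0.2)),
                            modality_params = default_modality_params(),
                            onset_day_mean = 30,
                            onset_day_sd = 3,
                            growth_rate = 0.5,
                            rise_days = 6,
                            ceiling_range = c(5, 10),
                            missing_rate = 0,
                            seed = 1L) {
  cfg <- list(n_per_group = unlist(n_per_group),
              n_experiments = as.integer(n_experiments),
              timepoints = as.numeric(timepoints),
              incidence = incidence,
              responder_mix = unlist(responder_mix),
              responder_ranges = responder_ranges,
              modality_params = modality_params,
              onset_day_mean = onset_day_mean,
              onset_day_sd = onset_day_sd,
              growth_rate = growth_rate,
              rise_days = rise_days,
              ceiling_range = as.numeric(ceiling_range),
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "arthrism_config"
  validate_config(cfg)
  cfg
}

#' Default per-modality generator parameters
#'
#' Baselines are naive-mouse values in physical units; `true_slope` is the
#' fractional change of the noiseless value at the maximal paired score
#' (per-paw score 10 for paw-level modalities, total score 40 for whole-mouse
#' modalities). Positive slopes are functional losses; skin temperature has a
#' negative slope because inflamed paws are warmer, so its raw value rises
#' with the score.
#'
#' @return named list of modality parameter lists.
#' @export
default_modality_params <- function() {
  list(
    latency_s = list(baseline = 10, true_slope = 0.26, noise_sd = 1.2,
                     level = "paw", lower = 1e-6, upper = 20),
    print_area_mm2 = list(baseline = 40, true_slope = 0.55, noise_sd = 5,
                          level = "paw", lower = 0, upper = Inf),
    distance_cm = list(baseline = 4000, true_slope = 0.55, noise_sd = 450,
                       level = "mouse", lower = 0, upper = Inf),
    skin_temp_C = list(baseline = 25.6, true_slope = -0.12, noise_sd = 0.5,
                       level = "paw", lower = 15, upper = 45),
    paw_swelling_mm = list(baseline = 2.05, true_slope = -0.24, noise_sd = 0.08,
                           level = "paw", lower = 0.5, upper = 10)
  )
}

valid_groups <- c("naive", "cfa", "cia", "cia_mtx")
paw_levels <- c("LF", "RF", "LH", "RH")

validate_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  if (is.null(names(cfg$n_per_group)) ||
      !all(names(cfg$n_per_group) %in% valid_groups))
    stop_field("n_per_group", paste("names must be among",
                                    paste(valid_groups, collapse = ", ")))
  if (any(cfg$n_per_group < 1))
    stop_field("n_per_group", "every group needs at least 1 mouse")
  if (cfg$n_experiments < 1)
    stop_field("n_experiments", "must be >= 1")
  if (length(cfg$timepoints) < 1 || any(diff(cfg$timepoints) <= 0))
    stop_field("timepoints", "must be strictly increasing")
  if (!is.finite(cfg$incidence) || cfg$incidence < 0 || cfg$incidence > 1)
    stop_field("incidence", "must be a probability in [0, 1]")
  if (length(cfg$responder_mix) != 3 ||
      !setequal(names(cfg$responder_mix), c("poor", "mild", "high")))
    stop_field("responder_mix", "needs probabilities named poor, mild, high")
  if (any(cfg$responder_mix < 0) || any(cfg$responder_mix > 1) ||
      abs(sum(cfg$responder_mix) - 1) > 1e-9)
    stop_field("responder_mix", "must be probabilities summing to 1")
  for (cls in c("poor", "mild", "high")) {
    rng <- cfg$responder_ranges[[cls]]
    if (is.null(rng) || length(rng) != 2 || rng[1] > rng[2] ||
        rng[1] < 0 || rng[2] > 1)
      stop_field("responder_ranges", sprintf("class '%s' needs a range within [0, 1]", cls))
  }
  if (length(cfg$modality_params) == 0)
    stop_field("modality_params", "at least one modality required")
  for (m in names(cfg$modality_params)) {
    p <- cfg$modality_params[[m]]
    if (is.null(p$baseline) || is.null(p$true_slope) || is.null(p$noise_sd) ||
        is.null(p$level))
      stop_field("modality_params", sprintf("'%s' needs baseline, true_slope, noise_sd, level", m))
    if (p$noise_sd < 0)
      stop_field("modality_params", sprintf("'%s' noise_sd must be >= 0", m))
    if (!p$level %in% c("paw", "mouse"))
      stop_field("modality_params", sprintf("'%s' level must be 'paw' or 'mouse'", m))
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_field("missing_rate", "must be in [0, 1)")
  if (cfg$ceiling_range[1] < 0 || cfg$ceiling_range[2] > 10 ||
      cfg$ceiling_range[1] > cfg$ceiling_range[2])
    stop_field("ceiling_range", "must be an increasing range within [0, 10]")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' The file is a flat key-value document; keys mirror the arguments of
#' [arthrism_config()]. Unknown keys raise an error. Keys that are absent
#' keep their defaults.
#'
#' @param path path to a YAML config file.
#' @return an `"arthrism_config"` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(arthrism_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$n_per_group)) raw$n_per_group <- unlist(raw$n_per_group)
  if (!is.null(raw$responder_mix)) raw$responder_mix <- unlist(raw$responder_mix)
  do.call(arthrism_config, raw)
}

#' @export
print.arthrism_config <- function(x, ...) {
  cat("CIA cohort simulation configuration\n")
  cat("  groups/experiment:",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = ", "),
      sprintf("(x%d experiments)\n", x$n_experiments))
  cat("  timepoints (days):", paste(x$timepoints, collapse = ", "), "\n")
  cat("  incidence:", x$incidence,
      " responder mix:", paste(sprintf("%s=%.3f", names(x$responder_mix),
                                       x$responder_mix), collapse = ", "), "\n")
  cat("  modalities:", paste(names(x$modality_params), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
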