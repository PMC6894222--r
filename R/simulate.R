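#' Simulate a longitudinal CIA-like cohort
#'
#' Generates mouse records and tidy longitudinal observations with the
#' statistical structure a collagen-induced arthritis study assumes: naive
#' and CFA controls never score, immunized untreated mice develop arthritis
#' with the configured incidence, MTX-treated mice attenuate their severity
#' trajectory by a responder-class-specific factor, and every functional
#' readout is linear in its paired clinical score plus Gaussian noise.
#'
#' Each mouse owns a private pseudo-random stream derived from
#' `(config$seed, mouse index)`, so enlarging the cohort never perturbs the
#' data of existing mice and identical configurations reproduce identical
#' tables bit for bit.
#'
#' @param config an [arthrism_config()] object.
#' @return an object of class `"arthrism_dataset"`: a list with data frames
#'   `mice` (one row per animal, including latent simulation parameters) and
#'   `observations` (mouse_id, day, paw, modality, value).
#' @examples
#' cohort <- simulate_cohort(arthrism_config(
#'   n_per_group = c(naive = 2, cia = 2), n_experiments = 1, seed = 42))
#' head(cohort$observations)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "arthrism_config"))
  validate_config(config)

  groups <- rep(names(config$n_per_group), config$n_per_group)
  plan <- expand.grid(idx = seq_along(groups),
                      experiment_id = seq_len(config$n_experiments))
  plan$group <- groups[plan$idx]
  n_mice <- nrow(plan)

  mice <- vector("list", n_mice)
  obs <- vector("list", n_mice)
  counter <- stats::ave(seq_len(n_mice),
                        paste(plan$experiment_id, plan$group),
                        FUN = seq_along)
  for (i in seq_len(n_mice)) {
    grp <- plan$group[i]
    exp_id <- plan$experiment_id[i]
    mouse_id <- sprintf("E%d_%s_%02d", exp_id, grp, counter[i])
    set.seed(mix_seed(config$seed, i))
    mouse <- draw_mouse(mouse_id, exp_id, grp, config)
    mice[[i]] <- mouse
    obs[[i]] <- simulate_mouse_observations(mouse, config)
  }

  mice <- bind_rows_fast(mice)
  observations <- bind_rows_fast(obs)
  structure(list(mice = mice, observations = observations,
                 config = config),
            class = "arthrism_dataset")
}

# Per-mouse stream seed: multipliers kept small enough that the arithmetic
# stays exact in doubles; result is always a valid 32-bit seed.
mix_seed <- function(seed, id) {
  as.integer((abs(seed) %% 2147483647) * 69069 %% 2147483647 + id * 101) %% 2147483647L
}

draw_mouse <- function(mouse_id, exp_id, grp, config) {
  immunized <- grp %in% c("cia", "cia_mtx")
  develops <- immunized && stats::runif(1) < config$incidence
  responder_class <- NA_character_
  response_factor <- 1
  if (grp == "cia_mtx") {
    responder_class <- sample(names(config$responder_mix), 1,
                              prob = config$responder_mix)
    rng <- config$responder_ranges[[responder_class]]
    response_factor <- stats::runif(1, rng[1], rng[2])
  }
  onset <- max(22, stats::rnorm(1, config$onset_day_mean, config$onset_day_sd))
  ceilings <- stats::runif(4, config$ceiling_range[1], config$ceiling_range[2])
  out <- data.frame(mouse_id = mouse_id, experiment_id = exp_id, group = grp,
                    develops_arthritis = develops,
                    responder_class = responder_class,
                    response_factor = response_factor,
                    onset_day = onset,
                    stringsAsFactors = FALSE)
  out[paste0("ceiling_", paw_levels)] <- as.list(ceilings)
  out
}

#' Latent per-paw severity trajectory
#'
#' Continuous disease severity of one mouse on the 0-10 per-paw scale:
#' zero before onset, then a logistic rise towards each paw's severity
#' ceiling, attenuated multiplicatively by the mouse's treatment
#' `response_factor`. Clinical scores are this severity rounded (half-up) to
#' the integer grid when emitted.
#'
#' @param mouse one row of the `mice` table (or an equivalent list) carrying
#'   `develops_arthritis`, `response_factor`, `onset_day` and
#'   `ceiling_LF` ... `ceiling_RH`.
#' @param day numeric vector of study days.
#' @param config an [arthrism_config()] object.
#' @return numeric matrix, `length(day)` rows by 4 paw columns (LF, RF, LH,
#'   RH), values in `[0, 10]`.
#' @export
severity_trajectory <- function(mouse, day, config) {
  mouse <- as.list(mouse)
  ceilings <- unlist(mouse[paste0("ceiling_", paw_levels)])
  sev <- matrix(0, nrow = length(day), ncol = 4,
                dimnames = list(NULL, paw_levels))
  if (!isTRUE(mouse$develops_arthritis)) return(sev)
  mid <- mouse$onset_day + config$rise_days
  shape <- stats::plogis(config$growth_rate * (day - mid))
  shape[day < mouse$onset_day] <- 0
  sev[] <- outer(shape, ceilings * mouse$response_factor)
  pmin(pmax(sev, 0), 10)
}

#' Emit a functional readout from its paired clinical score
#'
#' The generator's ground truth is linear:
#' `value = baseline * (1 - true_slope * score / max_score) + noise`,
#' where `max_score` is 10 for paw-level modalities (per-paw score) and 40
#' for whole-mouse modalities (total score). Noise is Gaussian, truncated by
#' clipping to the modality's physical range (e.g. withdrawal latency to the
#' 20 s heat-source cutoff). A negative `true_slope` produces values that
#' rise with the score (skin temperature, paw swelling).
#'
#' @param modality modality name present in `config$modality_params`.
#' @param paired_score numeric vector of clinical scores the values pair to.
#' @param config an [arthrism_config()] object.
#' @return numeric vector of simulated values, same length as `paired_score`.
#' @export
emit_functional_value <- function(modality, paired_score, config) {
  p <- config$modality_params[[modality]]
  if (is.null(p)) stop("unknown modality: ", modality, call. = FALSE)
  max_score <- if (p$level == "paw") 10 else 40
  noiseless <- p$baseline * (1 - p$true_slope * paired_score / max_score)
  value <- noiseless + stats::rnorm(length(paired_score), 0, p$noise_sd)
  lower <- if (is.null(p$lower)) -Inf else p$lower
  upper <- if (is.null(p$upper)) Inf else p$upper
  pmin(pmax(value, lower), upper)
}

round_half_up <- function(x) floor(x + 0.5)

simulate_mouse_observations <- function(mouse, config) {
  days <- config$timepoints
  sev <- severity_trajectory(mouse, days, config)
  scores <- round_half_up(sev)  # integer clinical grid, 0-10 per paw

  rows <- list()
  # clinical score, one row per paw and day
  rows$clinical <- data.frame(
    mouse_id = mouse$mouse_id,
    day = rep(days, times = 4),
    paw = rep(paw_levels, each = length(days)),
    modality = "clinical_score",
    value = as.vector(scores),
    stringsAsFactors = FALSE)

  total_scores <- rowSums(scores)
  for (m in names(config$modality_params)) {
    p <- config$modality_params[[m]]
    if (p$level == "paw") {
      # hind paws only: front-paw functional readouts are not consumed
      paired <- as.vector(scores[, c("LH", "RH")])
      rows[[m]] <- data.frame(
        mouse_id = mouse$mouse_id,
        day = rep(days, times = 2),
        paw = rep(c("LH", "RH"), each = length(days)),
        modality = m,
        value = emit_functional_value(m, paired, config),
        stringsAsFactors = FALSE)
    } else {
      rows[[m]] <- data.frame(
        mouse_id = mouse$mouse_id,
        day = days,
        paw = NA_character_,
        modality = m,
        value = emit_functional_value(m, total_scores, config),
        stringsAsFactors = FALSE)
    }
  }

  # endpoint histology: three 0-3 subscores per hind paw, stored as totals
  end_sev <- sev[length(days), c("LH", "RH")]
  hist_total <- vapply(end_sev, function(s) {
    subs <- round_half_up(3 * s / 10 + stats::rnorm(3, 0, 0.3))
    sum(pmin(pmax(subs, 0), 3))
  }, numeric(1))
  rows$histology <- data.frame(
    mouse_id = mouse$mouse_id,
    day = days[length(days)],
    paw = c("LH", "RH"),
    modality = "histology",
    value = hist_total,
    stringsAsFactors = FALSE)

  out <- bind_rows_fast(rows)
  if (config$missing_rate > 0) {
    droppable <- out$modality != "clinical_score"
    drop <- droppable & stats::runif(nrow(out)) < config$missing_rate
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @export
print.arthrism_dataset <- function(x, ...) {
  cat(sprintf("CIA dataset: %d mice, %d observations\n",
              nrow(x$mice), nrow(x$observations)))
  print(table(x$mice$group))
  invisible(x)
}
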