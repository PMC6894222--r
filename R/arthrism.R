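#' Fit an arthritis sensory-motor deficit scale
#'
#' The central model of the package. Pools every (clinical score, functional
#' value) pair across groups, experiments and time points, fits one ordinary
#' least-squares line per functional modality, and converts each line into a
#' relative-deficit curve anchored at the score-0 prediction: the result is
#' a per-modality linear map from clinical score (expressed as percent of
#' the maximal score) to percent functional deficit, usable as a bedside
#' scale for CIA cohorts.
#'
#' @param data an `"arthrism_dataset"` (from [simulate_cohort()] or
#'   [read_dataset()]) or a plain observations data frame.
#' @param modalities functional modalities to fit; the default is the
#'   three-parameter scale (thermal withdrawal latency, traveled distance,
#'   paw print area).
#' @param pairing how paw-level modalities pair with the score: same-side
#'   hind paw 0-10 (`"per-paw"`, default) or the two-hind-paw sum 0-20
#'   (`"summed-hind"`).
#' @param space fit raw values (`"raw"`, default) or naive-relative values
#'   (`"relative"`; requires a `mice` table).
#' @param mice mice table; taken from `data` when it is a dataset.
#' @param scorecards optional precomputed [build_scorecards()] table.
#' @param strict if `TRUE`, an unfittable modality is an error; otherwise it
#'   is an explicit gap in the scale (with a warning).
#' @return an object of class `"arthrism"` with components `scale` (one row
#'   per fitted modality: slope, intercept, Spearman r, p, n_pairs,
#'   reference, deficit slope per percent of maximal score, max_score),
#'   `fits`, `pairs`, `pairing`, `space`, `gaps` and `call`. Methods:
#'   [print.arthrism()], [summary.arthrism()], [coef.arthrism()],
#'   [predict.arthrism()], [plot.arthrism()], [residuals.arthrism()].
#' @examples
#' cohort <- simulate_cohort(arthrism_config(seed = 7))
#' scale <- arthrism(cohort)
#' scale
#' predict(scale, score_pct = 50)
#' @export
arthrism <- function(data,
                     modalities = c("latency_s", "distance_cm", "print_area_mm2"),
                     pairing = c("per-paw", "summed-hind"),
                     space = c("raw", "relative"),
                     mice = NULL, scorecards = NULL, strict = FALSE) {
  pairing <- match.arg(pairing)
  space <- match.arg(space)
  if (inherits(data, "arthrism_dataset")) {
    observations <- data$observations
    mice <- mice %||% data$mice
  } else {
    observations <- data
  }
  if (nrow(observations) == 0) stop("empty dataset", call. = FALSE)
  scorecards <- scorecards %||% build_scorecards(observations)
  if (space == "relative") {
    if (is.null(mice))
      stop("space = 'relative' requires a mice table", call. = FALSE)
    observations <- relativize(observations, mice)
  }

  fits <- list(); pairs <- list(); rows <- list(); gaps <- character()
  for (m in modalities) {
    res <- tryCatch({
      pp <- pool_pairs(observations, scorecards, m, pairing, space)
      fit <- fit_linear(pp$score, pp$value)
      curve <- build_deficit_curve(fit, attr(pp, "max_score"))
      list(pp = pp, curve = curve)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (strict)
        stop("modality '", m, "' unfittable: ", conditionMessage(res),
             call. = FALSE)
      warning("modality '", m, "' unfittable (gap in scale): ",
              conditionMessage(res), call. = FALSE)
      gaps <- c(gaps, m)
      next
    }
    fits[[m]] <- res$curve
    pairs[[m]] <- res$pp
    rows[[m]] <- data.frame(
      modality = m, n_pairs = res$curve$n,
      slope = res$curve$slope, intercept = res$curve$intercept,
      r = res$curve$r, p = res$curve$p,
      reference = res$curve$reference,
      deficit_slope_per_pct = res$curve$deficit_slope_per_pct,
      max_score = res$curve$max_score,
      degenerate = res$curve$degenerate,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no modality could be fitted", call. = FALSE)
  scale_tbl <- bind_rows_fast(rows)
  structure(list(scale = scale_tbl, fits = fits, pairs = pairs,
                 pairing = pairing, space = space, gaps = gaps,
                 call = match.call()),
            class = "arthrism")
}

#' Motor-to-sensory responsiveness ratio
#'
#' How much more responsive motor deficits are to a change in clinical
#' score than sensory deficits: the mean of the motor deficit slopes
#' divided by the sensory deficit slope.
#'
#' @param object an `"arthrism"` scale.
#' @param motor names of the motor modalities (default traveled distance
#'   and print area).
#' @param sensory name of the sensory modality (default withdrawal latency).
#' @return a single ratio.
#' @export
responsiveness_ratio <- function(object, motor = c("distance_cm", "print_area_mm2"),
                                 sensory = "latency_s") {
  stopifnot(inherits(object, "arthrism"))
  s <- object$scale
  need <- c(motor, sensory)
  if (!all(need %in% s$modality))
    stop("scale is missing: ",
         paste(setdiff(need, s$modality), collapse = ", "), call. = FALSE)
  sens <- s$deficit_slope_per_pct[s$modality == sensory]
  if (sens == 0) stop("zero sensory deficit slope: ratio undefined",
                      call. = FALSE)
  mot <- mean(s$deficit_slope_per_pct[s$modality %in% motor])
  mot / sens
}

#' Confidence intervals for the deficit slopes
#'
#' Delta-method intervals for the per-modality deficit slope
#' `-slope * max_score / intercept`, propagating the OLS coefficient
#' covariance through the ratio.
#'
#' @param object an `"arthrism"` scale.
#' @param level confidence level, default 0.95.
#' @return data frame (modality, estimate, se, lower, upper).
#' @export
deficit_slope_ci <- function(object, level = 0.95) {
  stopifnot(inherits(object, "arthrism"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(names(object$fits), function(m) {
    f <- object$fits[[m]]
    a <- f$slope; b <- f$intercept; M <- f$max_score
    grad <- c(a * M / b^2, -M / b)  # d/d(intercept), d/d(slope)
    se <- sqrt(drop(t(grad) %*% f$vcov %*% grad))
    est <- f$deficit_slope_per_pct
    data.frame(modality = m, estimate = est, se = se,
               lower = est - z * se, upper = est + z * se,
               stringsAsFactors = FALSE)
  })
  bind_rows_fast(rows)
}

#' @export
print.arthrism <- function(x, digits = 4, ...) {
  cat("Arthritis sensory-motor deficit scale\n")
  cat(sprintf("  pairing: %s score, space: %s values\n\n", x$pairing, x$space))
  tbl <- x$scale
  out <- data.frame(modality = tbl$modality, n = tbl$n_pairs,
                    slope = signif(tbl$slope, digits),
                    intercept = signif(tbl$intercept, digits),
                    spearman_r = signif(tbl$r, digits),
                    p = signif(tbl$p, 3),
                    deficit_slope = signif(tbl$deficit_slope_per_pct, digits))
  print(out, row.names = FALSE)
  cat("\n(deficit_slope: % functional deficit per % of maximal clinical score)\n")
  if (length(x$gaps))
    cat("unfitted modalities:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.arthrism <- function(object, ...) {
  ratio <- tryCatch(responsiveness_ratio(object), error = function(e) NA_real_)
  structure(list(scale = object$scale, pairing = object$pairing,
                 space = object$space, gaps = object$gaps,
                 ci = deficit_slope_ci(object),
                 responsiveness_ratio = ratio),
            class = "summary.arthrism")
}

#' @export
print.summary.arthrism <- function(x, digits = 4, ...) {
  cat("Arthritis sensory-motor deficit scale: summary\n")
  cat(sprintf("  pairing: %s, space: %s\n\n", x$pairing, x$space))
  tbl <- merge(x$scale, x$ci, by = "modality")
  out <- data.frame(modality = tbl$modality, n = tbl$n_pairs,
                    deficit_slope = signif(tbl$deficit_slope_per_pct, digits),
                    ci95 = sprintf("[%.3f, %.3f]", tbl$lower, tbl$upper),
                    spearman_r = signif(tbl$r, digits),
                    p = signif(tbl$p, 3))
  print(out, row.names = FALSE)
  if (is.finite(x$responsiveness_ratio))
    cat(sprintf("\nmotor/sensory responsiveness ratio: %.3f\n",
                x$responsiveness_ratio))
  invisible(x)
}

#' @export
coef.arthrism <- function(object, ...) {
  m <- as.matrix(object$scale[c("slope", "intercept", "deficit_slope_per_pct")])
  rownames(m) <- object$scale$modality
  m
}

#' @export
residuals.arthrism <- function(object, modality = NULL, ...) {
  mods <- modality %||% names(object$pairs)
  res <- lapply(mods, function(m) {
    pp <- object$pairs[[m]]
    f <- object$fits[[m]]
    pp$value - (f$intercept + f$slope * pp$score)
  })
  names(res) <- mods
  if (length(res) == 1) res[[1]] else res
}

#' Predict functional deficits from a clinical score
#'
#' Applies the linear deficit scale: for each modality the predicted
#' relative deficit is `deficit_slope_per_pct * score_pct`. Scores may be
#' given directly as percent of the maximal score (`score_pct`) or as an
#' absolute score with its maximum (`score`, `max_score`). Scores outside
#' `[0, 100]` percent are extrapolations: they are flagged and warned
#' about, not refused.
#'
#' @param object an `"arthrism"` scale.
#' @param score_pct numeric clinical score(s) as percent of maximum.
#' @param score absolute clinical score(s); converted using `max_score`.
#' @param max_score maximum for converting `score`; default 40 (whole-mouse
#'   total).
#' @param modalities subset of modalities to predict; default all fitted.
#' @param ... unused.
#' @return data frame of class `"arthrism_prediction"`: score_pct,
#'   modality, deficit_pct, extrapolated.
#' @export
predict.arthrism <- function(object, score_pct = NULL, score = NULL,
                             max_score = 40, modalities = NULL, ...) {
  if (is.null(score_pct)) {
    if (is.null(score))
      stop("supply score_pct or score", call. = FALSE)
    score_pct <- 100 * score / max_score
  }
  mods <- modalities %||% object$scale$modality
  missing_mods <- setdiff(mods, object$scale$modality)
  if (length(missing_mods))
    stop("scale has no entry for: ", paste(missing_mods, collapse = ", "),
         call. = FALSE)
  extrap <- score_pct < 0 | score_pct > 100
  if (any(extrap))
    warning("score outside [0, 100]% of maximum: extrapolating beyond the scale",
            call. = FALSE)
  slopes <- object$scale$deficit_slope_per_pct[match(mods, object$scale$modality)]
  out <- data.frame(
    score_pct = rep(score_pct, times = length(mods)),
    modality = rep(mods, each = length(score_pct)),
    deficit_pct = as.vector(outer(score_pct, slopes)),
    extrapolated = rep(extrap, times = length(mods)),
    stringsAsFactors = FALSE)
  class(out) <- c("arthrism_prediction", "data.frame")
  out
}

#' Invert the deficit scale
#'
#' Maps a target relative deficit back to the clinical score (as percent of
#' maximum) that the scale predicts would produce it.
#'
#' @param object an `"arthrism"` scale.
#' @param modality modality whose curve to invert.
#' @param deficit_pct relative deficit(s) in percent.
#' @return clinical score(s) as percent of maximum.
#' @export
invert_scale <- function(object, modality, deficit_pct) {
  stopifnot(inherits(object, "arthrism"))
  row <- object$scale[object$scale$modality == modality, , drop = FALSE]
  if (nrow(row) == 0) stop("scale has no entry for: ", modality, call. = FALSE)
  if (row$deficit_slope_per_pct == 0)
    stop("zero deficit slope: scale not invertible for ", modality,
         call. = FALSE)
  deficit_pct / row$deficit_slope_per_pct
}

#' Plot the deficit scale
#'
#' Draws the per-modality deficit lines against the clinical score expressed
#' as percent of its maximum — the scale chart itself.
#'
#' @param x an `"arthrism"` scale.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.arthrism <- function(x, ...) {
  s <- seq(0, 100, length.out = 101)
  y <- sapply(x$scale$deficit_slope_per_pct, function(b) b * s)
  graphics::matplot(s, y, type = "l", lty = 1, lwd = 2,
                    xlab = "clinical score (% of maximum)",
                    ylab = "relative functional deficit (%)", ...)
  graphics::legend("topleft", legend = x$scale$modality, lty = 1, lwd = 2,
                   col = seq_len(nrow(x$scale)), bty = "n")
  invisible(x)
}

#' Human-readable scale report
#'
#' Formats a fitted scale, optional predictions, and (when all three default
#' modalities are present) the motor/sensory responsiveness ratio as plain
#' text.
#'
#' @param object an `"arthrism"` scale.
#' @param predictions optional [predict.arthrism()] result.
#' @return the report lines, invisibly; printed as a side effect.
#' @export
report <- function(object, predictions = NULL) {
  stopifnot(inherits(object, "arthrism"))
  lines <- utils::capture.output(print(object))
  ratio <- tryCatch(responsiveness_ratio(object), error = function(e) NULL)
  if (!is.null(ratio))
    lines <- c(lines, sprintf("motor/sensory responsiveness ratio: %.3f", ratio))
  if (!is.null(predictions) && nrow(predictions) > 0) {
    lines <- c(lines, "", "predictions:",
               utils::capture.output(print.data.frame(predictions,
                                                      row.names = FALSE)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
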