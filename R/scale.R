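#' Pool (clinical score, functional value) pairs for one modality
#'
#' Pools observations across groups, experiments and time points, pairing
#' every functional measurement with its clinical score: paw-level
#' modalities (withdrawal latency, print area, skin temperature) pair with
#' the same-side hind-paw score (0-10; or the two-hind-paw sum 0-20 under
#' `pairing = "summed-hind"`), whole-mouse modalities (traveled distance)
#' pair with the total score (0-40). Pairs with a missing side are dropped
#' and counted.
#'
#' @param observations observations table.
#' @param scorecards output of [build_scorecards()].
#' @param modality modality to pool.
#' @param pairing `"per-paw"` (default) or `"summed-hind"` for paw-level
#'   modalities.
#' @param space `"raw"` to pair raw values, `"relative"` to pair the
#'   `relative_value` column (which must then be present, see
#'   [relativize()]).
#' @return data frame of class `"arthrism_pairs"` with columns mouse_id,
#'   day, paw, score, value and attributes `modality`, `max_score`,
#'   `n_dropped`.
#' @export
pool_pairs <- function(observations, scorecards, modality,
                       pairing = c("per-paw", "summed-hind"),
                       space = c("raw", "relative")) {
  pairing <- match.arg(pairing)
  space <- match.arg(space)
  ob <- observations[observations$modality == modality, , drop = FALSE]
  if (nrow(ob) == 0 && !modality %in% observations$modality)
    stop("unknown modality: ", modality, call. = FALSE)
  val <- if (space == "relative") {
    if (is.null(ob$relative_value))
      stop("space = 'relative' needs a relative_value column; run relativize()",
           call. = FALSE)
    ob$relative_value
  } else ob$value

  paw_level <- !all(is.na(ob$paw))
  if (paw_level) {
    if (pairing == "per-paw") {
      key <- paste(ob$mouse_id, ob$day, ob$paw, sep = "\r")
      long <- data.frame(
        key = c(paste(scorecards$mouse_id, scorecards$day, "LH", sep = "\r"),
                paste(scorecards$mouse_id, scorecards$day, "RH", sep = "\r"),
                paste(scorecards$mouse_id, scorecards$day, "LF", sep = "\r"),
                paste(scorecards$mouse_id, scorecards$day, "RF", sep = "\r")),
        score = c(scorecards$LH, scorecards$RH, scorecards$LF, scorecards$RF))
      score <- long$score[match(key, long$key)]
      max_score <- 10
    } else {
      key <- paste(ob$mouse_id, ob$day, sep = "\r")
      sc_key <- paste(scorecards$mouse_id, scorecards$day, sep = "\r")
      score <- scorecards$hind_paw_total[match(key, sc_key)]
      max_score <- 20
    }
  } else {
    key <- paste(ob$mouse_id, ob$day, sep = "\r")
    sc_key <- paste(scorecards$mouse_id, scorecards$day, sep = "\r")
    score <- scorecards$total[match(key, sc_key)]
    max_score <- 40
  }

  keep <- !is.na(score) & !is.na(val)
  out <- data.frame(mouse_id = ob$mouse_id[keep], day = ob$day[keep],
                    paw = ob$paw[keep], score = score[keep],
                    value = val[keep], stringsAsFactors = FALSE)
  structure(out, class = c("arthrism_pairs", "data.frame"),
            modality = modality, max_score = max_score,
            n_dropped = sum(!keep))
}

#' Ordinary least squares line with Spearman rank correlation
#'
#' Fits functional value on clinical score by OLS and reports Spearman's
#' rank correlation (average ranks for ties) with a two-sided p-value from
#' the large-sample t approximation. A sample whose functional values have
#' zero variance is reported as a degenerate fit (slope 0, r = 0) rather
#' than an error, so batch runs survive pathological inputs.
#'
#' @param score,value numeric vectors of equal length, n >= 3; `score` must
#'   have positive variance.
#' @return list of class `"arthrism_fit"`: slope, intercept, r, p, n,
#'   degenerate flag, and the OLS coefficient covariance matrix `vcov`
#'   (rows/cols: intercept, slope).
#' @export
fit_linear <- function(score, value) {
  stopifnot(length(score) == length(value))
  keep <- !is.na(score) & !is.na(value)
  score <- score[keep]; value <- value[keep]
  n <- length(score)
  if (n < 3) stop("need at least 3 pairs to fit", call. = FALSE)
  if (stats::var(score) == 0)
    stop("zero variance in clinical scores: line undefined", call. = FALSE)

  if (stats::var(value) == 0) {
    return(structure(list(slope = 0, intercept = value[1], r = 0, p = NA_real_,
                          n = n, degenerate = TRUE,
                          vcov = matrix(0, 2, 2,
                                        dimnames = list(c("intercept", "slope"),
                                                        c("intercept", "slope")))),
                     class = "arthrism_fit"))
  }

  fit <- stats::lm(value ~ score)
  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))  # perfect fits warn in summary.lm
  dimnames(vc) <- list(c("intercept", "slope"), c("intercept", "slope"))
  r <- stats::cor(score, value, method = "spearman")
  p <- spearman_p(r, n)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r = r, p = p, n = n, degenerate = FALSE, vcov = vc),
            class = "arthrism_fit")
}

# Two-sided p for Spearman's r via the t approximation on n - 2 df.
spearman_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Turn a fitted line into a relative-deficit curve
#'
#' The predicted value at score 0 (the OLS intercept) is the reference;
#' the relative functional deficit at score `s` is
#' `(reference - (intercept + slope * s)) / reference * 100`, which is
#' linear through the origin: `deficit(s) = -100 * slope * s / intercept`.
#' Re-parameterised on the percent-of-maximal-score axis, the deficit slope
#' per percent of maximal score is `-slope * max_score / intercept`.
#'
#' @param fit an [fit_linear()] result.
#' @param max_score maximal clinical score of the pairing (10, 20 or 40).
#' @return list: reference, deficit_slope_per_pct, max_score, plus the
#'   source fit fields.
#' @export
build_deficit_curve <- function(fit, max_score) {
  stopifnot(max_score > 0)
  if (fit$intercept == 0)
    stop("zero intercept: deficit reference undefined", call. = FALSE)
  list(reference = fit$intercept,
       deficit_slope_per_pct = -fit$slope * max_score / fit$intercept,
       max_score = max_score,
       slope = fit$slope, intercept = fit$intercept,
       r = fit$r, p = fit$p, n = fit$n, degenerate = fit$degenerate,
       vcov = fit$vcov)
}

#' @export
print.arthrism_fit <- function(x, ...) {
  cat(sprintf("OLS fit: value = %.6g %+.6g * score  (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("Spearman r = %.4f, p = %.3g%s\n", x$r, x$p,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}
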