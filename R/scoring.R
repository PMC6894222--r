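#' Total clinical score of one mouse
#'
#' Sums the four per-paw clinical scores. Each paw is graded 0-10, so the
#' total ranges 0-40 per mouse.
#'
#' @param paw_scores numeric vector of exactly 4 integer paw scores, each in
#'   `[0, 10]`. Names, if present, must be among LF, RF, LH, RH.
#' @return integer total in `[0, 40]`.
#' @examples
#' total_clinical_score(c(LF = 3, RF = 2, LH = 4, RH = 1))
#' @export
total_clinical_score <- function(paw_scores) {
  if (length(paw_scores) != 4 || anyNA(paw_scores))
    stop("exactly 4 non-missing paw scores required", call. = FALSE)
  if (any(paw_scores < 0 | paw_scores > 10) ||
      any(paw_scores != round(paw_scores)))
    stop("paw scores must be integers in [0, 10]", call. = FALSE)
  if (!is.null(names(paw_scores)) && !all(names(paw_scores) %in% paw_levels))
    stop("paw names must be among ", paste(paw_levels, collapse = ", "),
         call. = FALSE)
  as.integer(sum(paw_scores))
}

#' Arthritic classification from the endpoint total score
#'
#' A mouse is considered arthritic when its total clinical score at the
#' study endpoint (day 49) strictly exceeds the threshold of 10.
#'
#' @param total_at_end integer total clinical score(s) in `[0, 40]`.
#' @param threshold classification threshold, strict; default 10.
#' @return logical vector.
#' @export
is_arthritic <- function(total_at_end, threshold = 10) {
  stopifnot(all(total_at_end >= 0 & total_at_end <= 40, na.rm = TRUE))
  total_at_end > threshold
}

#' Arthritis incidence among immunized untreated mice
#'
#' @param arthritic logical vector, one element per immunized mouse.
#' @return percentage in `[0, 100]`: `100 * sum(arthritic) / length(arthritic)`.
#' @examples
#' incidence(rep(c(TRUE, FALSE), c(21, 3)))  # 87.5
#' @export
incidence <- function(arthritic) {
  if (length(arthritic) == 0)
    stop("incidence undefined for an empty immunized set", call. = FALSE)
  100 * sum(arthritic) / length(arthritic)
}

#' Arthritis improvement (AI) score
#'
#' Percent improvement of a treated mouse's endpoint total clinical score
#' relative to the mean endpoint score of the untreated CIA group, mimicking
#' the ACR20/50/70 clinical response criteria. Negative values (mouse worse
#' than the untreated mean) are reported as-is, not clamped.
#'
#' @param mouse_total_end endpoint total clinical score(s) of treated mice.
#' @param untreated_mean_end mean endpoint total score of the untreated
#'   group; must be positive.
#' @return AI score(s) in percent: `100 * (ref - mouse) / ref`.
#' @export
ai_score <- function(mouse_total_end, untreated_mean_end) {
  if (!is.finite(untreated_mean_end) || untreated_mean_end <= 0)
    stop("untreated group mean must be positive (reference undefined)",
         call. = FALSE)
  if (any(mouse_total_end < 0))
    stop("endpoint scores must be >= 0", call. = FALSE)
  100 * (untreated_mean_end - mouse_total_end) / untreated_mean_end
}

#' Responder class from an AI score
#'
#' Bands mimic ACR20/50/70: below the first boundary, poor responders; at or
#' above the second, high responders; mild in between. Bands are left-closed
#' so every finite AI maps to exactly one class; the more-improved class wins
#' at a boundary.
#'
#' @param ai numeric AI score(s), percent.
#' @param boundaries two increasing cut points, default `c(20, 70)`.
#' @return factor with levels poor, mild, high.
#' @export
classify_responder <- function(ai, boundaries = c(20, 70)) {
  if (any(!is.finite(ai)))
    stop("AI scores must be finite", call. = FALSE)
  stopifnot(length(boundaries) == 2, boundaries[1] < boundaries[2])
  cls <- ifelse(ai < boundaries[1], "poor",
                ifelse(ai < boundaries[2], "mild", "high"))
  factor(cls, levels = c("poor", "mild", "high"))
}

#' Histology score of one paw
#'
#' Sum of three histopathological subscores (synovial inflammation, bone
#' erosion, cartilage erosion), each graded 0 (healthy) to 3 (severe), for a
#' maximal score of 9 per paw.
#'
#' @param subscores numeric vector of exactly 3 integers in `{0, 1, 2, 3}`.
#' @return integer total in `[0, 9]`.
#' @export
histology_total <- function(subscores) {
  if (length(subscores) != 3 || anyNA(subscores))
    stop("exactly 3 non-missing subscores required", call. = FALSE)
  if (any(!subscores %in% 0:3))
    stop("subscores must be integers in {0, 1, 2, 3}", call. = FALSE)
  as.integer(sum(subscores))
}

#' Build per-mouse, per-day clinical scorecards
#'
#' Pivots the tidy `clinical_score` observations into one row per
#' (mouse, day) with the four paw scores plus the derived hind-paw total
#' (LH + RH, 0-20) and whole-mouse total (0-40).
#'
#' @param observations observations data frame (mouse_id, day, paw,
#'   modality, value) as produced by [simulate_cohort()] or read from disk.
#' @return data frame with columns mouse_id, day, LF, RF, LH, RH,
#'   hind_paw_total, total.
#' @export
build_scorecards <- function(observations) {
  cs <- observations[observations$modality == "clinical_score", , drop = FALSE]
  if (nrow(cs) == 0) stop("no clinical_score observations", call. = FALSE)
  if (any(!cs$paw %in% paw_levels))
    stop("clinical scores must carry a paw label", call. = FALSE)
  if (any(cs$value < 0 | cs$value > 10 | cs$value != round(cs$value)))
    stop("clinical scores must be integers in [0, 10]", call. = FALSE)
  wide <- stats::reshape(cs[c("mouse_id", "day", "paw", "value")],
                         idvar = c("mouse_id", "day"), timevar = "paw",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  missing_paws <- setdiff(paw_levels, names(wide))
  if (length(missing_paws))
    stop("missing paw scores for: ", paste(missing_paws, collapse = ", "),
         call. = FALSE)
  if (anyNA(wide[paw_levels]))
    stop("incomplete scorecard: every (mouse, day) needs all 4 paws",
         call. = FALSE)
  wide <- wide[c("mouse_id", "day", paw_levels)]
  wide$hind_paw_total <- wide$LH + wide$RH
  wide$total <- wide$LF + wide$RF + wide$LH + wide$RH
  wide <- wide[order(wide$mouse_id, wide$day), ]
  rownames(wide) <- NULL
  wide
}

#' AI scores and responder classes for the treated arm
#'
#' Computes each MTX-treated mouse's AI score against the untreated CIA
#' group's mean total clinical score at the endpoint day, then classifies
#' responders.
#'
#' @param scorecards output of [build_scorecards()].
#' @param mice mice table with `mouse_id` and `group` columns.
#' @param endpoint_day day used as the improvement endpoint; defaults to the
#'   last scored day present in `scorecards`.
#' @param boundaries responder band cut points, see [classify_responder()].
#' @return data frame (mouse_id, total_end, ai, class), one row per treated
#'   mouse.
#' @export
responder_table <- function(scorecards, mice, endpoint_day = NULL,
                            boundaries = c(20, 70)) {
  endpoint_day <- endpoint_day %||% max(scorecards$day)
  end <- scorecards[scorecards$day == endpoint_day, , drop = FALSE]
  if (nrow(end) == 0)
    stop("no scorecards at endpoint day ", endpoint_day, call. = FALSE)
  grp <- mice$group[match(end$mouse_id, mice$mouse_id)]
  ref <- mean(end$total[grp == "cia"])
  treated <- end[grp == "cia_mtx", , drop = FALSE]
  if (nrow(treated) == 0)
    stop("no MTX-treated mice at endpoint day ", endpoint_day, call. = FALSE)
  ai <- ai_score(treated$total, ref)
  data.frame(mouse_id = treated$mouse_id, total_end = treated$total,
             ai = ai, class = classify_responder(ai, boundaries),
             stringsAsFactors = FALSE)
}
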