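#' Naive-group reference table
#'
#' Mean value of each modality in the naive group, computed separately per
#' experiment and per study day. These means are the denominators used to
#' express each mouse's readout as a ratio to healthy animals measured at
#' the same time point, which is what makes independent experiments
#' poolable. Paw-level modalities pool all naive hind-paw measurements at
#' that day.
#'
#' @param observations observations table.
#' @param mice mice table (`mouse_id`, `experiment_id`, `group`).
#' @return data frame (experiment_id, day, modality, reference, n_naive).
#'   Score-like modalities (clinical score, histology) are excluded.
#' @export
build_reference <- function(observations, mice) {
  idx <- match(observations$mouse_id, mice$mouse_id)
  if (anyNA(idx))
    stop("observations refer to unknown mice", call. = FALSE)
  ob <- observations
  ob$experiment_id <- mice$experiment_id[idx]
  naive <- ob[mice$group[idx] == "naive" &
                !ob$modality %in% score_modalities, , drop = FALSE]
  if (nrow(naive) == 0)
    stop("no naive observations: reference undefined", call. = FALSE)
  agg <- stats::aggregate(value ~ experiment_id + day + modality, data = naive,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ experiment_id + day + modality, data = naive,
                          FUN = length)
  names(agg)[names(agg) == "value"] <- "reference"
  agg$n_naive <- cnt$value
  agg <- agg[order(agg$experiment_id, agg$day, agg$modality), ]
  rownames(agg) <- NULL
  agg
}

#' Express observations relative to the naive reference
#'
#' Divides every non-clinical observation by the naive-group mean for the
#' same (experiment, day, modality); naive mice are relativized against
#' their own group mean, so their relative values average exactly 1.
#' Score-like modalities (clinical score, histology) are passed through
#' unchanged: they are already on a common semi-quantitative scale and are
#' never expressed as naive ratios.
#'
#' @param observations observations table.
#' @param mice mice table.
#' @param reference optional precomputed [build_reference()] table.
#' @return the observations table with an added `relative_value` column
#'   (`NA` for clinical scores).
#' @export
relativize <- function(observations, mice, reference = NULL) {
  reference <- reference %||% build_reference(observations, mice)
  idx <- match(observations$mouse_id, mice$mouse_id)
  if (anyNA(idx))
    stop("observations refer to unknown mice", call. = FALSE)
  key <- paste(mice$experiment_id[idx], observations$day,
               observations$modality, sep = "\r")
  ref_key <- paste(reference$experiment_id, reference$day, reference$modality,
                   sep = "\r")
  ref <- reference$reference[match(key, ref_key)]
  functional <- !observations$modality %in% score_modalities
  if (any(functional & is.na(ref))) {
    miss <- unique(key[functional & is.na(ref)])
    stop("missing naive reference for: ",
         paste(gsub("\r", "/", utils::head(miss, 5)), collapse = ", "),
         call. = FALSE)
  }
  if (any(functional & ref == 0, na.rm = TRUE))
    stop("zero naive reference mean: relative value undefined", call. = FALSE)
  out <- observations
  out$relative_value <- ifelse(functional, observations$value / ref, NA_real_)
  out
}

# modalities that are semi-quantitative scores, never naive-relativized
score_modalities <- c("clinical_score", "histology")
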