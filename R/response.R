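#' Response rate of an imaging biomarker
#'
#' Percent change of a feature at a treatment timepoint relative to its
#' baseline value: `100 * (followup - baseline) / baseline`. Negative
#' values indicate shrinkage/decrease.
#'
#' @param baseline,followup Feature values in the same units; `baseline`
#'   must be nonzero.
#' @return Percent change (vectorised).
#' @examples
#' response_rate(40, 20)  # -50
#' @export
response_rate <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(baseline == 0)) {
    stop("response rate is undefined for a zero (or non-finite) baseline",
         call. = FALSE)
  }
  100 * (followup - baseline) / baseline
}

.feature_names <- c("longest_diameter", "volume", "ser_mean", "ser_median",
                    "adc_mean", "adc_median")

#' Build a per-lesion treatment-response table
#'
#' Pairs each subject's lesion feature at the baseline timepoint with the
#' same lesion at follow-up and computes the response rate. Subjects or
#' lesions missing either timepoint are returned in an exclusion table, not
#' dropped silently.
#'
#' @param features Tibble of lesion features as produced by
#'   [extract_lesion_features()] (rows for both timepoints).
#' @param feature_name One of `longest_diameter`, `volume`, `ser_mean`,
#'   `ser_median`, `adc_mean`, `adc_median`.
#' @param baseline_tp,followup_tp Timepoint labels; the current design
#'   compares pre-treatment `"T0"` against on-treatment `"T1"`.
#' @return List with `records` (one row per subject x lesion: both values,
#'   dates, modality, `response_rate` in percent) and `exclusions`
#'   (subject, lesion, reason).
#' @export
build_response_table <- function(features, feature_name = "longest_diameter",
                                 baseline_tp = "T0", followup_tp = "T1") {
  if (!feature_name %in% .feature_names) {
    stop("unknown feature name: ", feature_name, call. = FALSE)
  }
  empty_rec <- tibble::tibble(
    subject_id = character(), cohort = character(), lesion_label = character(),
    feature_name = character(), baseline_value = numeric(),
    followup_value = numeric(), response_rate = numeric(),
    baseline_date = character(), followup_date = character(),
    modality = character()
  )
  empty_exc <- tibble::tibble(subject_id = character(),
                              lesion_label = character(), reason = character())
  if (is.null(features) || nrow(features) == 0L) {
    return(list(records = empty_rec, exclusions = empty_exc))
  }
  base <- features[features$timepoint == baseline_tp, , drop = FALSE]
  fup <- features[features$timepoint == followup_tp, , drop = FALSE]
  keys <- unique(rbind(base[c("subject_id", "lesion_label")],
                       fup[c("subject_id", "lesion_label")]))
  recs <- list(); excs <- list()
  for (i in seq_len(nrow(keys))) {
    sid <- keys$subject_id[i]; lab <- keys$lesion_label[i]
    b <- base[base$subject_id == sid & base$lesion_label == lab, ]
    f <- fup[fup$subject_id == sid & fup$lesion_label == lab, ]
    if (nrow(b) == 0L || nrow(f) == 0L) {
      excs[[length(excs) + 1L]] <- tibble::tibble(
        subject_id = sid, lesion_label = lab,
        reason = paste0("missing ", if (nrow(b) == 0L) baseline_tp else followup_tp))
      next
    }
    bv <- b[[feature_name]][1]; fv <- f[[feature_name]][1]
    recs[[length(recs) + 1L]] <- tibble::tibble(
      subject_id = sid, cohort = b$cohort[1], lesion_label = lab,
      feature_name = feature_name, baseline_value = bv, followup_value = fv,
      response_rate = if (is.finite(bv) && bv != 0)
        response_rate(bv, fv) else NA_real_,
      baseline_date = as.character(b$study_date[1]),
      followup_date = as.character(f$study_date[1]),
      modality = b$modality[1]
    )
  }
  list(
    records = if (length(recs)) do.call(rbind, recs) else empty_rec,
    exclusions = if (length(excs)) do.call(rbind, excs) else empty_exc
  )
}

#' Order response records for a waterfall plot
#'
#' Sorts records ascending by response rate (smallest, i.e. best response,
#' first), breaking ties lexicographically by subject id. Cohorts are
#' ordered independently so the patient and PDX waterfalls can be drawn
#' side by side.
#'
#' @param records Response-record tibble from [build_response_table()]; all
#'   rows must share one `feature_name`.
#' @return The same rows, reordered, with cohorts kept contiguous
#'   (patient block first when both are present).
#' @export
waterfall_order <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (length(unique(records$feature_name)) > 1L) {
    stop("waterfall ordering requires a single feature", call. = FALSE)
  }
  parts <- lapply(split(records, factor(records$cohort,
                                        levels = unique(records$cohort))),
                  function(d) d[order(d$response_rate, d$subject_id), ,
                                drop = FALSE])
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Waterfall bar chart of per-subject response
#'
#' @param records Ordered or unordered response records; [waterfall_order()]
#'   is applied.
#' @return A ggplot object, one panel per cohort.
#' @export
plot_waterfall <- function(records) {
  ord <- waterfall_order(records)
  ord$subject_id <- factor(ord$subject_id, levels = unique(ord$subject_id))
  ggplot2::ggplot(ord, ggplot2::aes(x = .data$subject_id,
                                    y = .data$response_rate,
                                    fill = .data$response_rate < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~cohort, scales = "free_x") +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s change from baseline (%%)",
                              ord$feature_name[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
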