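# Participant-level aggregation of trip predictions: the frequency-based
# risk score (proportion of a driver's trips flagged impaired), threshold
# flags, the majority-vote comparison baseline, and the
# sensitivity/specificity curve over a threshold grid. Because mild
# impairment expresses sporadically, a low flagging threshold on the risk
# score detects drivers a majority vote would miss.

#' Frequency-based participant risk scores
#'
#' @param predictions Tibble (or data frame) with one row per trip:
#'   `participant_id`, a binary trip prediction `pred` (1 = impaired) and,
#'   when available, the true participant `label` (0/1 or
#'   `"healthy"`/`"mci"`) used to compute per-participant trip accuracy.
#' @param prob_column Optional name of a probability column to average
#'   instead of hard labels (probability-mean risk variant); `NULL` (the
#'   default) uses the hard `pred` column, matching a screening rule that
#'   counts trips classified as impaired.
#' @return A `risk_report` tibble: `participant_id`, `label`, `n_trips`,
#'   `n_flagged`, `risk_score` in `[0, 1]`, `trip_accuracy`.
#' @examples
#' risk_score(tibble::tibble(
#'   participant_id = c("A", "A", "A"), pred = c(1, 0, 0), label = c(1, 1, 1)
#' ))
#' @export
risk_score <- function(predictions, prob_column = NULL) {
  predictions <- as_tibble(predictions)
  if (!"participant_id" %in% names(predictions)) abort("`participant_id` column required")
  if (is.null(prob_column) && !"pred" %in% names(predictions)) {
    abort("`pred` column (binary trip prediction) required")
  }
  has_label <- "label" %in% names(predictions)
  if (has_label) predictions$label <- normalize_labels(predictions$label)
  score_col <- if (is.null(prob_column)) "pred" else prob_column
  if (any(is.na(predictions[[score_col]]))) abort("every trip needs a prediction")

  out <- predictions %>%
    group_by(.data$participant_id) %>%
    summarise(
      label = if (has_label) .data$label[1] else NA_integer_,
      n_trips = n(),
      n_flagged = sum(.data[[score_col]] >= 0.5),
      risk_score = mean(.data[[score_col]]),
      trip_accuracy = if (has_label) {
        mean(as.integer(.data[[score_col]] >= 0.5) == .data$label)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  class(out) <- c("risk_report", class(out))
  out
}

#' Flag participants at one or more risk thresholds
#'
#' A participant is flagged at threshold `t` when `risk_score >= t`, so
#' lowering the threshold never unflags anyone. The conventional screening
#' thresholds are 0.1 (sensitivity-first early detection) and 0.5
#' (precision-first).
#'
#' @param report A `risk_report` from [risk_score()].
#' @param thresholds Numeric thresholds in `(0, 1]` (default `c(0.1, 0.5)`).
#' @return The report with one logical `flag_<t>` column per threshold.
#' @export
apply_thresholds <- function(report, thresholds = c(0.1, 0.5)) {
  if (any(thresholds <= 0 | thresholds > 1)) abort("thresholds must lie in (0, 1]")
  for (t in thresholds) {
    report[[sprintf("flag_%g", t)]] <- report$risk_score >= t
  }
  report
}

#' Majority-vote participant labels
#'
#' The comparison baseline the risk score replaces: a participant is labeled
#' impaired when more than half of their trips are flagged; an exact half
#' split breaks toward impaired (sensitivity-first tie-break).
#'
#' @param report A `risk_report`.
#' @return The report with a logical `majority_impaired` column.
#' @export
majority_vote <- function(report) {
  report$majority_impaired <- report$risk_score >= 0.5
  report
}

#' Sensitivity/specificity across a risk-threshold grid
#'
#' @param report A `risk_report` with true labels.
#' @param thresholds Threshold grid (default 101 points over `[0, 1]`).
#' @return An object of class `threshold_curve`: tibble `threshold`,
#'   `sensitivity`, `specificity`, `n_flagged`.
#' @export
threshold_curve <- function(report, thresholds = seq(0, 1, length.out = 101)) {
  if (any(is.na(report$label))) abort("true labels required for the threshold curve")
  pos <- report$risk_score[report$label == 1]
  neg <- report$risk_score[report$label == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both classes must be present to compute sensitivity and specificity")
  }
  out <- tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thresholds, function(t) mean(neg < t), numeric(1)),
    n_flagged = vapply(thresholds, function(t) sum(report$risk_score >= t), numeric(1))
  )
  class(out) <- c("threshold_curve", class(out))
  out
}
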