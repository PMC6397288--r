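## Survey evaluation framework. A survey is summarized by three counts:
## K_obs, the number of collared (ground-truthed) animals present;
## K_detected, the number of those correctly identified; and K_false, the
## number of signatures falsely identified or unidentifiable ("other").
## From these: probability of detection Pd = K_detected / K_obs, precision
## rate PR = K_detected / (K_obs + K_false), and across surveys the
## per-survey count errors give RMSE and MAE.

#' Probability of detection
#'
#' `100 * k_detected / k_obs`, in percent (unrounded; survey reports round
#' half away from zero to integers). Vectorized over surveys.
#'
#' @param k_detected true positives per survey.
#' @param k_obs ground-truthed animals present per survey.
#' @return percent, numeric.
#' @export
probability_of_detection <- function(k_detected, k_obs) {
  if (any(k_obs <= 0)) stop("k_obs must be positive", call. = FALSE)
  if (any(k_detected < 0 | k_detected > k_obs))
    stop("need 0 <= k_detected <= k_obs", call. = FALSE)
  100 * k_detected / k_obs
}

#' Precision rate
#'
#' `100 * k_detected / (k_obs + k_false)`, in percent. With `k_false = 0`
#' this equals the probability of detection.
#'
#' @inheritParams probability_of_detection
#' @param k_false unmatched/unidentifiable signatures per survey.
#' @return percent, numeric.
#' @export
precision_rate <- function(k_detected, k_obs, k_false) {
  if (any(k_false < 0)) stop("k_false must be >= 0", call. = FALSE)
  den <- k_obs + k_false
  if (any(den <= 0)) stop("k_obs + k_false must be positive", call. = FALSE)
  100 * k_detected / den
}

#' Pooled probability of detection
#'
#' `100 * sum(k_detected) / sum(k_obs)` across surveys.
#'
#' @inheritParams probability_of_detection
#' @return percent, numeric scalar.
#' @export
pooled_probability_of_detection <- function(k_detected, k_obs) {
  if (!length(k_obs) || sum(k_obs) <= 0)
    stop("need surveys with k_obs > 0", call. = FALSE)
  100 * sum(k_detected) / sum(k_obs)
}

#' Per-survey count error: RMSE and MAE
#'
#' Root mean square and mean absolute error of `k_obs - k_detected` over a
#' series of surveys.
#'
#' @inheritParams probability_of_detection
#' @return numeric scalar.
#' @export
survey_rmse <- function(k_detected, k_obs) {
  if (!length(k_obs)) stop("empty survey series", call. = FALSE)
  sqrt(mean((k_obs - k_detected)^2))
}

#' @rdname survey_rmse
#' @export
survey_mae <- function(k_detected, k_obs) {
  if (!length(k_obs)) stop("empty survey series", call. = FALSE)
  mean(abs(k_obs - k_detected))
}

#' False-positive composition
#'
#' Share of each false-positive class (kangaroo, car, human, other) among
#' all misidentified objects, as integer percents (half away from zero).
#' The denominator is the sum of the class counts.
#'
#' @param counts named non-negative counts per class.
#' @return named integer percents.
#' @export
fp_composition <- function(counts) {
  counts <- unlist(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("no false positives to compose", call. = FALSE)
  round_half_up(100 * counts / tot)
}

#' Survey report table
#'
#' Renders per-survey and pooled detection statistics for one or more
#' methods. Percentages are rounded half away from zero to integers, the
#' convention of printed survey tables.
#'
#' @param counts long-format data frame with columns `survey_id`,
#'   `method`, `k_obs`, `k_detected` and optionally `k_false` (NA allowed
#'   when unknown; PR is then NA).
#' @return data frame of class `survey_report` with columns `survey_id`,
#'   `method`, `k_obs`, `k_detected`, `k_false`, `pd_pct`, `pr_pct`,
#'   including one pooled row per method (`survey_id = "(pooled)"`).
#' @export
survey_report <- function(counts) {
  need <- c("survey_id", "method", "k_obs", "k_detected")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(counts$k_false))
    counts$k_false <- rep(NA_real_, nrow(counts))
  out <- list()
  for (m in unique(counts$method)) {
    cm <- counts[counts$method == m, , drop = FALSE]
    pd <- round_half_up(probability_of_detection(cm$k_detected, cm$k_obs))
    pr <- ifelse(is.na(cm$k_false), NA_real_,
                 round_half_up(100 * cm$k_detected /
                                 (cm$k_obs + cm$k_false)))
    out[[length(out) + 1L]] <- data.frame(
      survey_id = cm$survey_id, method = m, k_obs = cm$k_obs,
      k_detected = cm$k_detected, k_false = cm$k_false,
      pd_pct = pd, pr_pct = pr)
    if (nrow(cm)) {
      kf <- if (all(!is.na(cm$k_false))) sum(cm$k_false) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        survey_id = "(pooled)", method = m, k_obs = sum(cm$k_obs),
        k_detected = sum(cm$k_detected), k_false = kf,
        pd_pct = round_half_up(
          pooled_probability_of_detection(cm$k_detected, cm$k_obs)),
        pr_pct = if (is.na(kf)) NA_real_ else round_half_up(
          100 * sum(cm$k_detected) / (sum(cm$k_obs) + kf)))
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(survey_id = character(), method = character(),
               k_obs = numeric(), k_detected = numeric(),
               k_false = numeric(), pd_pct = numeric(),
               pr_pct = numeric())
  row.names(out) <- NULL
  class(out) <- c("survey_report", "data.frame")
  out
}

#' @export
print.survey_report <- function(x, ...) {
  cat("Survey detection report\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Bundled koala survey counts (Petrie, Queensland)
#'
#' Per-survey counts from eleven aerial thermal koala surveys over a
#' radio-collared population at Petrie, Queensland (two sites, North and
#' South; `role` marks whether a survey's imagery contributed to detector
#' training): ground-survey count `k_obs` and the koalas detected by the
#' automated pipeline (`k_auto`) and by manual frame-by-frame review
#' (`k_manual`). `petrie_false_positive_counts()` gives the composition of
#' falsely identified objects for both methods.
#'
#' @return data frame.
#' @export
petrie_survey_counts <- function() {
  read_csv_plain(system.file("extdata", "petrie_survey_counts.csv",
                             package = "heatfuse"))
}

#' @rdname petrie_survey_counts
#' @export
petrie_false_positive_counts <- function() {
  read_csv_plain(system.file("extdata", "petrie_false_positives.csv",
                             package = "heatfuse"))
}
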