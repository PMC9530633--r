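#' Index of microcirculatory resistance
#'
#' `IMR = hyperaemic Pd (mmHg) x mean transit time (s)`, in units U.
#'
#' @param pd_hyperaemic mean distal coronary pressure at hyperaemia, mmHg.
#' @param transit_time mean hyperaemic transit time, s.
#' @return IMR in U (vectorised).
#' @export
compute_imr <- function(pd_hyperaemic, transit_time) {
  if (any(pd_hyperaemic <= 0, na.rm = TRUE) ||
      any(transit_time <= 0, na.rm = TRUE))
    stop("pd_hyperaemic and transit_time must be positive", call. = FALSE)
  pd_hyperaemic * transit_time
}

#' Dichotomise microvascular-injury indices
#'
#' Applies the clinically significant IMR threshold (strictly above 40 U)
#' and the prognostically significant MVO threshold (strictly above 1.55%
#' of LV mass); `severe` flags patients above both. Missing indices give
#' missing flags.
#'
#' @param records data.frame with (optional) `imr` and `mvo` columns.
#' @param imr_cut,mvo_cut thresholds (defaults 40 U and 1.55%).
#' @return `records` with logical columns `imr_high`, `mvo_high`, `severe`.
#' @export
dichotomize <- function(records, imr_cut = 40, mvo_cut = 1.55) {
  records$imr_high <- if ("imr" %in% names(records)) records$imr > imr_cut else NA
  records$mvo_high <- if ("mvo" %in% names(records)) records$mvo > mvo_cut else NA
  records$severe <- records$imr_high & records$mvo_high
  records
}

#' Filter the cohort to adequately thrombectomised patients
#'
#' Keeps records whose angiographic thrombus score is in `eligible_scores`
#' AND whose imaged thrombus area fraction is at least `area_threshold`
#' (the threshold is a minimum, hence `>=`; scores outside the eligible set
#' are dropped regardless of area). Idempotent and order-independent.
#'
#' @param records data.frame with `area_fraction` and `thrombus_score`.
#' @param area_threshold minimum adequate area fraction (default 0.22).
#' @param eligible_scores thrombus scores the rule applies to (default 4:5).
#' @return list with `records` (the kept subset) and `audit`, a per-record
#'   data.frame of `patient_id`, `thrombus_score`, `area_fraction`,
#'   `score_eligible`, `area_pass`, `kept`.
#' @export
filter_successful <- function(records, area_threshold = 0.22,
                              eligible_scores = 4:5) {
  stopifnot(all(c("area_fraction", "thrombus_score") %in% names(records)))
  score_ok <- records$thrombus_score %in% eligible_scores
  area_ok <- records$area_fraction >= area_threshold
  kept <- score_ok & area_ok
  audit <- data.frame(
    patient_id = if ("patient_id" %in% names(records)) records$patient_id
                 else seq_len(nrow(records)),
    thrombus_score = records$thrombus_score,
    area_fraction = records$area_fraction,
    score_eligible = score_ok,
    area_pass = area_ok,
    kept = kept)
  list(records = records[kept, , drop = FALSE], audit = audit)
}
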