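# KDIGO acute kidney injury staging from creatinine and urine-output
# series, evaluated over the first 7 days (168 h) of an ICU stay.
#
# Creatinine arm: stage 1 at a 1.5-1.9x rise over baseline or a >= 0.3
# mg/dL rise within any 48 h window; stage 2 at 2.0-2.9x; stage 3 at
# >= 3.0x or an absolute value >= 4.0 mg/dL. Baseline is the minimum value
# charted in the first 24 h (the cohort excludes admission AKI, so early
# values approximate the pre-injury baseline).
#
# Urine arm: rates in mL/kg/h, each charted value covering the interval
# back to the previous observation; stage 1 at < 0.5 sustained >= 6 h,
# stage 2 at < 0.5 sustained >= 12 h, stage 3 at < 0.3 sustained >= 24 h or
# anuria (rate 0) sustained >= 12 h. An inter-observation gap > 2 h breaks
# a span. Renal replacement therapy is not modelled (no such channel in
# the schema).

KDIGO_WINDOW_H <- 168
KDIGO_CRITERIA <- c("creatinine_ratio", "creatinine_delta48",
                    "creatinine_absolute", "urine_rate", "anuria")

missing_baseline_error <- function(stay_id = NA) {
  stop(structure(class = c("icushift_missing_baseline", "error", "condition"),
                 list(message = sprintf(
                   "no creatinine value in the first 24 h%s",
                   if (is.na(stay_id)) "" else sprintf(" (stay %s)", stay_id)),
                   call = NULL)))
}

#' Baseline creatinine of a stay
#'
#' The minimum creatinine charted in the first 24 h from ICU admission.
#'
#' @param times hours from ICU admission, strictly increasing.
#' @param values creatinine values in mg/dL.
#' @return baseline in mg/dL.
#' @export
baseline_creatinine <- function(times, values) {
  check_series(times, values)
  in24 <- times <= 24
  if (!any(in24)) missing_baseline_error()
  min(values[in24])
}

check_series <- function(times, values) {
  if (length(times) != length(values) || length(times) < 1)
    stop_input("series must have matching, non-empty times and values")
  if (anyNA(times) || anyNA(values) || any(!is.finite(values)))
    stop_input("series must be finite")
  if (any(values < 0)) stop_input("series values must be >= 0")
  if (is.unsorted(times, strictly = TRUE))
    stop_input("series times must be strictly increasing")
  invisible(TRUE)
}

no_stage <- function() list(stage = 0L, onset = NA_real_,
                            criterion = NA_character_)

#' Creatinine arm of KDIGO staging
#'
#' @inheritParams baseline_creatinine
#' @param baseline baseline creatinine in mg/dL (> 0).
#' @return list(stage, onset, criterion); onset is the earliest time the
#'   returned stage's condition first holds.
#' @export
stage_from_creatinine <- function(times, values, baseline) {
  check_series(times, values)
  if (!is.numeric(baseline) || baseline <= 0)
    stop_input("baseline must be > 0")
  keep <- times <= KDIGO_WINDOW_H
  t <- times[keep]; v <- values[keep]
  if (!length(t)) return(no_stage())
  ratio <- v / baseline

  first_time <- function(flag) if (any(flag)) t[which(flag)[1]] else Inf
  t3_ratio <- first_time(ratio >= 3)
  t3_abs <- first_time(v >= 4.0)
  t2 <- first_time(ratio >= 2 & ratio < 3)
  t1_ratio <- first_time(ratio >= 1.5 & ratio < 2)

  # 48 h sliding-window rise >= 0.3 mg/dL, qualifying at the later time
  t1_delta <- Inf
  if (length(t) >= 2) {
    for (j in 2:length(t)) {
      i <- which(t >= t[j] - 48 & t < t[j])
      if (length(i) && v[j] - min(v[i]) >= 0.3) { t1_delta <- t[j]; break }
    }
  }

  if (is.finite(t3_ratio) || is.finite(t3_abs)) {
    if (t3_ratio <= t3_abs)
      list(stage = 3L, onset = t3_ratio, criterion = "creatinine_ratio")
    else
      list(stage = 3L, onset = t3_abs, criterion = "creatinine_absolute")
  } else if (is.finite(t2)) {
    list(stage = 2L, onset = t2, criterion = "creatinine_ratio")
  } else if (is.finite(t1_ratio) || is.finite(t1_delta)) {
    if (t1_ratio <= t1_delta)
      list(stage = 1L, onset = t1_ratio, criterion = "creatinine_ratio")
    else
      list(stage = 1L, onset = t1_delta, criterion = "creatinine_delta48")
  } else no_stage()
}

# spans of consecutive below-threshold intervals; returns earliest
# end-of-qualification time (span start + dur) or Inf
urine_qualify <- function(int_start, int_end, below, valid, dur) {
  ok <- below & valid
  if (!any(ok)) return(Inf)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  best <- Inf
  for (s in which(r$values)) {
    i0 <- starts[s]; i1 <- ends[s]
    span_start <- int_start[i0]
    span_len <- int_end[i1] - span_start
    if (span_len >= dur) best <- min(best, span_start + dur)
  }
  best
}

#' Urine arm of KDIGO staging
#'
#' @param times hours from ICU admission (right end of each charting
#'   interval), strictly increasing.
#' @param values urine output in mL/h.
#' @param weight_kg patient weight in kg (> 0).
#' @return list(stage, onset, criterion); onset is the earliest qualifying
#'   span's end-of-qualification time.
#' @export
stage_from_urine <- function(times, values, weight_kg) {
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop_input("weight_kg must be > 0")
  check_series(times, values)
  keep <- times <= KDIGO_WINDOW_H
  t <- times[keep]; v <- values[keep]
  if (length(t) < 2) return(no_stage())
  rate <- v[-1] / weight_kg        # rate on interval (t[i-1], t[i]]
  int_start <- t[-length(t)]
  int_end <- t[-1]
  valid <- (int_end - int_start) <= 2

  q1 <- urine_qualify(int_start, int_end, rate < 0.5, valid, 6)
  q2 <- urine_qualify(int_start, int_end, rate < 0.5, valid, 12)
  q3 <- urine_qualify(int_start, int_end, rate < 0.3, valid, 24)
  qa <- urine_qualify(int_start, int_end, rate == 0, valid, 12)

  if (is.finite(q3) || is.finite(qa)) {
    if (q3 <= qa) list(stage = 3L, onset = q3, criterion = "urine_rate")
    else list(stage = 3L, onset = qa, criterion = "anuria")
  } else if (is.finite(q2)) {
    list(stage = 2L, onset = q2, criterion = "urine_rate")
  } else if (is.finite(q1)) {
    list(stage = 1L, onset = q1, criterion = "urine_rate")
  } else no_stage()
}

#' KDIGO stage of one ICU stay
#'
#' Combines the creatinine and urine arms: the stay's stage is the maximum
#' over arms, the onset the earliest among arms attaining that stage (ties
#' at equal onset report the creatinine criterion). The urine arm is
#' optional; with no urine channel the stage comes from creatinine alone.
#'
#' @param observations data.frame with columns `time_h`, `channel`,
#'   `value` for one stay; channels `creatinine` and optionally
#'   `urine_output`.
#' @param weight_kg patient weight in kg.
#' @return list with `stage`, `onset_time_h`, `criterion`,
#'   `baseline_creatinine`.
#' @export
#' @examples
#' tr <- trajectory_from_stage(1, weight_kg = 70, seed = 4)
#' kdigo_stage(tr, weight_kg = 70)$stage
kdigo_stage <- function(observations, weight_kg) {
  cr <- observations[observations$channel == "creatinine", , drop = FALSE]
  cr <- cr[order(cr$time_h), , drop = FALSE]
  if (!nrow(cr)) missing_baseline_error()
  bl <- baseline_creatinine(cr$time_h, cr$value)
  arm_c <- stage_from_creatinine(cr$time_h, cr$value, bl)
  ur <- observations[observations$channel == "urine_output", , drop = FALSE]
  arm_u <- if (nrow(ur)) {
    ur <- ur[order(ur$time_h), , drop = FALSE]
    stage_from_urine(ur$time_h, ur$value, weight_kg)
  } else no_stage()
  combine_arms(arm_c, arm_u, bl)
}

combine_arms <- function(arm_c, arm_u, baseline) {
  stage <- max(arm_c$stage, arm_u$stage)
  if (stage == 0L)
    return(list(stage = 0L, onset_time_h = NA_real_,
                criterion = NA_character_, baseline_creatinine = baseline))
  oc <- if (arm_c$stage == stage) arm_c$onset else Inf
  ou <- if (arm_u$stage == stage) arm_u$onset else Inf
  if (oc <= ou)   # tie at equal onset -> creatinine criterion
    list(stage = stage, onset_time_h = oc, criterion = arm_c$criterion,
         baseline_creatinine = baseline)
  else
    list(stage = stage, onset_time_h = ou, criterion = arm_u$criterion,
         baseline_creatinine = baseline)
}

#' Label every stay of a cohort with its KDIGO stage
#'
#' @param cohort a `generated_cohort` or a list with `observations` and
#'   `patients`/`stays` tables in the cohort schema.
#' @param on_missing_baseline `"error"` or `"drop"` (drop the stay and
#'   record it; cohort extraction uses drop).
#' @return `data.table` (stay_id, stage, onset_time_h, criterion,
#'   baseline_creatinine).
#' @export
label_cohort <- function(cohort, on_missing_baseline = c("error", "drop")) {
  on_missing_baseline <- match.arg(on_missing_baseline)
  obs <- data.table::as.data.table(cohort$observations)
  wmap <- merge(cohort$stays[, c("stay_id", "patient_id")],
                cohort$patients[, c("patient_id", "weight_kg")],
                by = "patient_id")
  weights <- stats::setNames(wmap$weight_kg, wmap$stay_id)
  sub <- obs[obs$channel %in% c("creatinine", "urine_output"), ]
  data.table::setkey(sub, stay_id, time_h)
  parts <- split(sub, by = "stay_id", keep.by = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    sid <- p$stay_id[1]
    res <- tryCatch(kdigo_stage(p, weights[[as.character(sid)]]),
                    icushift_missing_baseline = function(e) e)
    if (inherits(res, "condition")) {
      if (on_missing_baseline == "error") missing_baseline_error(sid)
      out[[i]] <- data.table::data.table(
        stay_id = sid, stage = NA_integer_, onset_time_h = NA_real_,
        criterion = "missing_baseline", baseline_creatinine = NA_real_)
    } else {
      out[[i]] <- data.table::data.table(
        stay_id = sid, stage = res$stage, onset_time_h = res$onset_time_h,
        criterion = res$criterion,
        baseline_creatinine = res$baseline_creatinine)
    }
  }
  data.table::rbindlist(out)[order(stay_id)]
}
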