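# Synthetic ICU cohort generator.
#
# Stage-bearing series (creatinine, urine output) are constructed with
# bounded noise so that KDIGO staging recovers the intended stage with a
# margin for every stay; `noise_sd` scales only the nuisance vitals/labs
# channels. The generator therefore satisfies an exact round-trip contract
# with the KDIGO labeler rather than a statistical one.

GENERATOR_VERSION <- "1.0.0"

# channel -> (mu, loading on x1..x5, stage loading, obs sd, clamp, unit)
channel_catalog <- function() {
  # loadings express latent severity x1..x4 in vitals/labs; x5 appears only
  # in urine output (handled separately)
  data.frame(
    channel = c("heart_rate", "sbp", "dbp", "map", "resp_rate", "spo2",
                "temperature", "bun", "hemoglobin", "wbc", "sodium",
                "potassium", "glucose"),
    group   = c(rep("vitals", 7), rep("labs", 6)),
    mu      = c(85, 120, 65, 83, 17, 97, 37, 22, 11.5, 10, 139, 4.1, 135),
    a1      = c(8, 0, 0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 15),
    a2      = c(0, -10, -6, -8, 0, 0, 0, 0, 0, 0, 1.5, 0, 0),
    a3      = c(0, 0, 2, 0, 3.5, 0, 0, 6, 0, 0, 0, 0.25, 0),
    a4      = c(0, 0, 0, 0, 0, -1.5, 0.3, 0, -0.8, 0, 0, 0, 0),
    # prodromal (first-day) AKI signal is expressed only through the urine
    # channel, so the urine feature group carries independent label signal
    astage  = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    sd      = c(6, 9, 7, 7, 2.5, 1.2, 0.35, 4, 0.8, 1.8, 2.5, 0.3, 20),
    lo      = c(20, 50, 20, 30, 4, 60, 34, 1, 3, 0.5, 115, 2, 30),
    hi      = c(220, 260, 160, 200, 60, 100, 42, 150, 20, 60, 170, 9, 600),
    unit    = c("bpm", "mmHg", "mmHg", "mmHg", "breaths/min", "%",
                "degC", "mg/dL", "g/dL", "K/uL", "mEq/L", "mEq/L", "mg/dL"),
    stringsAsFactors = FALSE
  )
}

channel_units <- function() {
  cat <- channel_catalog()
  c(stats::setNames(cat$unit, cat$channel),
    creatinine = "mg/dL", urine_output = "mL/h")
}

# jittered sampling grid shared by all stays: start + cadence * (0:k),
# per-observation jitter uniform in +/- 20% of the cadence
jitter_grid <- function(n_stays, start, cadence, end) {
  base <- seq(start, end, by = cadence)
  k <- length(base)
  jit <- matrix(stats::runif(n_stays * k, -0.2 * cadence, 0.2 * cadence),
                nrow = n_stays)
  sweep(jit, 2, base, `+`)
}

# --- creatinine -------------------------------------------------------------
# Pre-onset values sit in [b, b + 0.1]; AKI stays ramp from the observed
# 24 h minimum (the labeler's baseline) to a peak at ratio r_s of it, hold a
# 24 h plateau (so the 12 h cadence is guaranteed to chart the peak band),
# then decay. Ratio bands keep a safety margin inside every KDIGO boundary.
creat_ratio_band <- function(stage) {
  lo <- c(NA, 1.62, 2.15, 3.30)[stage + 1]
  hi <- c(NA, 1.85, 2.80, 3.80)[stage + 1]
  cbind(lo, hi)
}

gen_creatinine <- function(stage, cadence) {
  n <- length(stage)
  tt <- jitter_grid(n, 2, cadence, 160)
  k <- ncol(tt)
  b <- stats::runif(n, 0.6, 1.1)
  vals <- b + matrix(stats::runif(n * k, 0, 0.1), n, k)
  in24 <- tt <= 24
  vv <- vals; vv[!in24] <- Inf
  b_obs <- apply(vv, 1, min)

  aki <- stage > 0
  if (any(aki)) {
    t_r <- stats::runif(n, 30, 60)
    t_p <- t_r + stats::runif(n, 24, 48)
    band <- creat_ratio_band(pmax(stage, 1L))
    r <- stats::runif(n, band[, 1], band[, 2])
    peak <- b_obs * r
    floorv <- b
    for (j in seq_len(k)) {
      t <- tt[, j]
      ramp <- aki & t > t_r & t < t_p
      plat <- aki & t >= t_p & t <= t_p + 24
      decay <- aki & t > t_p + 24
      if (any(ramp)) {
        f <- (t[ramp] - t_r[ramp]) / (t_p[ramp] - t_r[ramp])
        v <- b_obs[ramp] + (peak[ramp] - b_obs[ramp]) * f +
          stats::runif(sum(ramp), -0.05, 0)
        vals[ramp, j] <- clamp(v, floorv[ramp], peak[ramp])
      }
      if (any(plat)) {
        v <- peak[plat] + stats::runif(sum(plat), -0.04, 0)
        vals[plat, j] <- clamp(v, b_obs[plat], peak[plat])
      }
      if (any(decay)) {
        f <- pmin(1, (t[decay] - t_p[decay] - 24) / 72)
        v <- peak[decay] - (peak[decay] - 1.15 * b[decay]) * f +
          stats::runif(sum(decay), -0.05, 0.02)
        vals[decay, j] <- clamp(v, floorv[decay], peak[decay])
      }
    }
  }
  list(times = tt, values = vals, baseline = b)
}

# --- urine output -----------------------------------------------------------
# Rates are in mL/kg/h internally; charted values are mL/h (rate * weight).
# The pre-oliguric band encodes x5 and the intended stage (prodromal
# depression), which is the planted signal of the urine feature group. The
# oliguric window after hour 26 realizes the KDIGO urine criterion of the
# intended stage with margins on depth and duration.
urine_window_pars <- function(stage) {
  dur_lo <- c(NA, 6.5, 14, 26)[stage + 1]
  dur_hi <- c(NA, 9.5, 19, 30)[stage + 1]
  dep_lo <- c(NA, 0.32, 0.32, 0.08)[stage + 1]
  dep_hi <- c(NA, 0.42, 0.42, 0.22)[stage + 1]
  cbind(dur_lo, dur_hi, dep_lo, dep_hi)
}

gen_urine <- function(stage, x5, cadence) {
  n <- length(stage)
  tt <- jitter_grid(n, cadence, cadence, 168)
  k <- ncol(tt)
  base_lo <- ifelse(stage == 0, 0.70, 0.55)
  # severity depresses urine output: the negative x5 loading aligns with
  # x5's positive risk weight (oliguric-leaning stays are the high-risk
  # ones), and the high base keeps most of the range clear of the floor
  rate0 <- clamp(1.35 - 0.22 * x5 - 0.05 * stage, base_lo, 2.5)
  rates <- rate0 + matrix(stats::runif(n * k, -0.12, 0.12), n, k)
  rates <- pmax(rates, base_lo)  # never graze the 0.5 threshold off-window

  aki <- stage > 0
  if (any(aki)) {
    pars <- urine_window_pars(pmax(stage, 1L))
    t_u <- stats::runif(n, 26, 40)
    dur <- stats::runif(n, pars[, 1], pars[, 2])
    dep <- stats::runif(n, pars[, 3], pars[, 4])
    clamp_lo <- ifelse(stage == 3, 0.05, 0.31)
    clamp_hi <- ifelse(stage == 3, 0.27, 0.45)
    inwin <- aki & tt >= t_u & tt <= t_u + dur
    if (any(inwin)) {
      idx <- which(inwin, arr.ind = TRUE)
      v <- dep[idx[, 1]] + stats::runif(nrow(idx), -0.015, 0.015)
      rates[inwin] <- clamp(v, clamp_lo[idx[, 1]], clamp_hi[idx[, 1]])
    }
  }
  list(times = tt, rates = rates)
}

# --- nuisance channels ------------------------------------------------------
gen_channel_block <- function(stay_id, stage, x, cat_row, cadence, span,
                              noise_sd) {
  n <- length(stay_id)
  start <- if (cat_row$group == "vitals") cadence else cadence / 2
  tt <- jitter_grid(n, start, cadence, span)
  k <- ncol(tt)
  mu <- cat_row$mu + cat_row$a1 * x[, 1] + cat_row$a2 * x[, 2] +
    cat_row$a3 * x[, 3] + cat_row$a4 * x[, 4] + cat_row$astage * stage
  vals <- mu + matrix(stats::rnorm(n * k, 0, cat_row$sd * noise_sd), n, k)
  vals <- clamp(vals, cat_row$lo, cat_row$hi)
  data.table::data.table(
    stay_id = rep(stay_id, each = k),
    time_h = as.vector(t(tt)),
    channel = cat_row$channel,
    value = as.vector(t(vals))
  )
}

# assemble the long observations table for a set of stays
make_observations <- function(stay_id, stage, weight_kg, x, config) {
  cad <- config$obs_cadence
  cr <- gen_creatinine(stage, cad[["creatinine"]])
  k <- ncol(cr$times)
  obs <- list(data.table::data.table(
    stay_id = rep(stay_id, each = k),
    time_h = as.vector(t(cr$times)),
    channel = "creatinine",
    value = as.vector(t(cr$values))
  ))
  if (config$urine_available) {
    ur <- gen_urine(stage, x[, 5], cad[["urine"]])
    ku <- ncol(ur$times)
    obs <- c(obs, list(data.table::data.table(
      stay_id = rep(stay_id, each = ku),
      time_h = as.vector(t(ur$times)),
      channel = "urine_output",
      value = as.vector(t(ur$rates)) * rep(weight_kg, each = ku)
    )))
  }
  cat <- channel_catalog()
  for (i in seq_len(nrow(cat))) {
    row <- cat[i, ]
    span <- if (row$group == "vitals") 48 else 156
    cadence <- cad[[row$group]]
    obs <- c(obs, list(gen_channel_block(stay_id, stage, x, row, cadence,
                                         span, config$noise_sd)))
  }
  out <- data.table::rbindlist(obs)
  units <- channel_units()
  out[, units := units[channel]]
  data.table::setkey(out, stay_id, channel, time_h)
  out[]
}

#' Generate one synthetic ICU stay's observation series from its AKI stage
#'
#' Emits a 7-day creatinine series (and, iff `urine_available`, an hourly
#' urine-output series) constructed so that [kdigo_stage()] recovers
#' `stage`, together with noisy vitals and labs channels. Stage-0 series
#' keep a margin below every KDIGO threshold.
#'
#' @param stage intended KDIGO stage, 0--3.
#' @param weight_kg patient weight in kg (> 0), used to chart urine output
#'   in mL/h from the internal mL/kg/h rates.
#' @param urine_available logical, whether a urine channel is charted.
#' @param seed integer seed.
#' @return a `data.table` with columns stay_id, time_h, channel, value,
#'   units.
#' @export
#' @examples
#' tr <- trajectory_from_stage(2, weight_kg = 80, seed = 1)
#' table(tr$channel)
trajectory_from_stage <- function(stage, weight_kg, urine_available = TRUE,
                                  seed = 1L) {
  if (!stage %in% 0:3) stop_input("stage must be one of 0, 1, 2, 3")
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop_input("weight_kg must be > 0")
  cfg <- cohort_config(1, seed = seed, urine_available = urine_available)
  with_seed(seed, make_observations(1L, as.integer(stage), weight_kg,
                                    matrix(0, 1, 5), cfg))
}

#' Generate a synthetic ICU cohort
#'
#' Draws a relational cohort — patients, ICU stays, a long observation
#' table and ground-truth labels — whose empirical AKI-stage, EMR-epoch and
#' ethnicity mixtures converge to the configured mixes as the cohort grows.
#' Each stay's creatinine (and optional urine-output) series is constructed
#' from its true stage so that KDIGO staging recovers it exactly. The
#' drift magnitude rotates the post-epoch feature-to-risk coefficients and
#' the subgroup effect rotates the non-White ones, which is what the
#' deployment scenarios exploit. Deterministic given the configuration.
#'
#' @param config a [cohort_config()].
#' @return an object of class `generated_cohort`: a list of `data.table`s
#'   `patients`, `stays`, `observations`, `truth`, plus `manifest`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_stays = 50, seed = 7))
#' nrow(co$stays)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_input("config must be a cohort_config object")
  n <- config$n_stays
  with_seed(config$seed, {
    stay_id <- seq_len(n)
    ethnicity <- sample(names(config$ethnicity_mix), n, replace = TRUE,
                        prob = config$ethnicity_mix)
    epoch <- sample(names(config$epoch_mix), n, replace = TRUE,
                    prob = config$epoch_mix)
    # crossover stays straddle the system change: realize a 50/50 mixture of
    # the two regimes (they are excluded from drift splits anyway)
    regime <- ifelse(epoch == "crossover",
                     ifelse(stats::runif(n) < 0.5, "pre", "post"), epoch)
    age <- floor(stats::runif(n, 18, 91))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    weight <- stats::runif(n, 60, 110)
    x <- matrix(stats::rnorm(n * 5), n, 5)
    xt <- expand_basis(x)

    # comorbidity flags; the three severity-linked ones load on x
    comorb <- data.table::data.table(
      chf = stats::runif(n) < stats::plogis(-2.2 + 0.5 * x[, 1]),
      hypertension = stats::runif(n) < stats::plogis(-0.6 + 0.4 * x[, 2]),
      diabetes = stats::runif(n) < stats::plogis(-1.4 + 0.4 * x[, 3]),
      copd = stats::runif(n) < 0.12,
      afib = stats::runif(n) < 0.15,
      cad = stats::runif(n) < 0.18,
      stroke = stats::runif(n) < 0.07,
      liver_disease = stats::runif(n) < 0.06,
      cancer = stats::runif(n) < 0.10,
      obesity = stats::runif(n) < 0.25
    )
    ckd <- stats::runif(n) < 0.03

    # AKI labels: Bernoulli on the context-resolved risk, intercept
    # calibrated so the marginal prevalence matches the stage mixture;
    # stage within AKI drawn from the renormalized mixture
    lp <- risk_linear_predictor(xt, regime, ethnicity, config, "aki")
    p_aki <- sum(config$stage_mix[c("1", "2", "3")])
    aki <- rep(FALSE, n)
    if (p_aki > 0 && p_aki < 1) {
      ic <- calibrate_intercept(lp, p_aki)
      aki <- stats::runif(n) < stats::plogis(lp + ic)
    } else if (p_aki >= 1) aki <- rep(TRUE, n)
    stage <- integer(n)
    if (any(aki)) {
      ps <- config$stage_mix[c("1", "2", "3")]
      ps <- if (sum(ps) > 0) ps / sum(ps) else c(1, 0, 0)
      stage[aki] <- sample(1:3, sum(aki), replace = TRUE, prob = ps)
    }

    # stay timing (hours from ICU admission)
    icu_dis <- stats::runif(n, 170, 340)
    hosp_dis <- icu_dis + stats::runif(n, 24, 240)

    # readmission: Bernoulli on its own context-resolved risk, calibrated so
    # the 72 h readmission rate matches config; gaps from a two-component
    # log-normal mixture (early bounce-back vs late return)
    mix_w <- 0.55
    p72_given <- mix_w * stats::plnorm(72, log(30), 0.6) +
      (1 - mix_w) * stats::plnorm(72, log(300), 0.7)
    readmit <- rep(FALSE, n)
    if (config$readmission_rate_72h > 0) {
      target_any <- min(0.95, config$readmission_rate_72h / p72_given)
      lp_r <- risk_linear_predictor(xt, regime, ethnicity, config,
                                    "readmission")
      ic_r <- calibrate_intercept(lp_r, target_any)
      readmit <- stats::runif(n) < stats::plogis(lp_r + ic_r)
    }
    gap <- rep(NA_real_, n)
    if (any(readmit)) {
      # higher-risk readmissions return earlier: the early mixture
      # component is assigned to the top mix_w fraction of a noisy risk
      # ranking, keeping the marginal component weights (and hence the
      # 72 h calibration) intact
      m <- sum(readmit)
      escore <- lp_r[readmit] + 2 * stats::rlogis(m)
      early <- escore >= stats::quantile(escore, 1 - mix_w)
      g <- ifelse(early, stats::rlnorm(m, log(30), 0.6),
                  stats::rlnorm(m, log(300), 0.7))
      gap[readmit] <- g
    }
    readmission_time <- icu_dis + gap

    observations <- make_observations(stay_id, stage, weight, x, config)

    patients <- data.table::data.table(
      patient_id = stay_id, ethnicity = ethnicity, age_years = age,
      sex = sex, weight_kg = weight, ckd = ckd)
    patients <- cbind(patients, comorb)
    stays <- data.table::data.table(
      stay_id = stay_id, patient_id = stay_id,
      icu_admit_time = 0, icu_discharge_time = icu_dis,
      hospital_discharge_time = hosp_dis,
      emr_epoch = epoch, readmission_time = readmission_time)
    truth <- data.table::data.table(
      stay_id = stay_id, true_aki_stage = stage,
      true_readmission_gap_h = gap)

    for (mixname in c("stage_mix", "epoch_mix", "ethnicity_mix")) {
      mx <- config[[mixname]]
      got <- switch(mixname, stage_mix = as.character(stage),
                    epoch_mix = epoch, ethnicity_mix = ethnicity)
      missing_lv <- setdiff(names(mx)[mx > 0], unique(got))
      if (length(missing_lv))
        warning(sprintf("empty stratum in %s: %s (n_stays too small)",
                        mixname, paste(missing_lv, collapse = ", ")),
                call. = FALSE)
    }

    structure(list(
      patients = patients, stays = stays, observations = observations,
      truth = truth,
      manifest = list(config = unclass(config),
                      generator_version = GENERATOR_VERSION)
    ), class = "generated_cohort")
  })
}

#' @export
print.generated_cohort <- function(x, ...) {
  cat(sprintf("<generated_cohort> %d stays, %d observations (v%s)\n",
              nrow(x$stays), nrow(x$observations),
              x$manifest$generator_version))
  cat("  stage counts:",
      paste(sprintf("%s=%d", 0:3,
                    tabulate(x$truth$true_aki_stage + 1L, 4)),
            collapse = " "), "\n")
  invisible(x)
}
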