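# Independent brute-force oracles and fixture builders shared by the
# suite. These deliberately avoid the package's vectorized/short-circuit
# code paths: everything is plain nested loops over raw observations.

# O(n^2) pairwise-concordance AUROC
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# brute-force KDIGO staging: scan every observation / pair / interval run
oracle_kdigo <- function(observations, weight_kg) {
  cr <- observations[observations$channel == "creatinine", , drop = FALSE]
  cr <- cr[order(cr$time_h), , drop = FALSE]
  cr <- cr[cr$time_h <= 168, , drop = FALSE]
  bl_vals <- cr$value[cr$time_h <= 24]
  if (!length(bl_vals)) return(NULL)
  bl <- min(bl_vals)

  # creatinine arm: earliest qualifying time per rule
  t_ratio15 <- t_ratio2 <- t_ratio3 <- t_abs4 <- t_d48 <- Inf
  for (j in seq_len(nrow(cr))) {
    v <- cr$value[j]; tj <- cr$time_h[j]
    r <- v / bl
    if (r >= 1.5 && r < 2 && tj < t_ratio15) t_ratio15 <- tj
    if (r >= 2 && r < 3 && tj < t_ratio2) t_ratio2 <- tj
    if (r >= 3 && tj < t_ratio3) t_ratio3 <- tj
    if (v >= 4.0 && tj < t_abs4) t_abs4 <- tj
    if (j > 1) for (i in 1:(j - 1)) {
      if (cr$time_h[i] >= tj - 48 &&
          v - cr$value[i] >= 0.3 && tj < t_d48) t_d48 <- tj
    }
  }
  if (is.finite(t_ratio3) || is.finite(t_abs4)) {
    arm_c <- if (t_ratio3 <= t_abs4)
      list(stage = 3L, onset = t_ratio3, criterion = "creatinine_ratio")
    else list(stage = 3L, onset = t_abs4, criterion = "creatinine_absolute")
  } else if (is.finite(t_ratio2)) {
    arm_c <- list(stage = 2L, onset = t_ratio2,
                  criterion = "creatinine_ratio")
  } else if (is.finite(t_ratio15) || is.finite(t_d48)) {
    arm_c <- if (t_ratio15 <= t_d48)
      list(stage = 1L, onset = t_ratio15, criterion = "creatinine_ratio")
    else list(stage = 1L, onset = t_d48, criterion = "creatinine_delta48")
  } else arm_c <- list(stage = 0L, onset = NA_real_,
                       criterion = NA_character_)

  # urine arm: check every contiguous run of intervals for every rule
  ur <- observations[observations$channel == "urine_output", , drop = FALSE]
  ur <- ur[order(ur$time_h), , drop = FALSE]
  ur <- ur[ur$time_h <= 168, , drop = FALSE]
  arm_u <- list(stage = 0L, onset = NA_real_, criterion = NA_character_)
  if (nrow(ur) >= 2) {
    t <- ur$time_h; rate <- ur$value[-1] / weight_kg
    n_int <- length(rate)
    qual <- function(pred, dur) {
      best <- Inf
      for (i in seq_len(n_int)) for (j in i:n_int) {
        ok <- TRUE
        for (k in i:j)
          if (!pred(rate[k]) || (t[k + 1] - t[k]) > 2) { ok <- FALSE; break }
        if (ok && (t[j + 1] - t[i]) >= dur)
          best <- min(best, t[i] + dur)
      }
      best
    }
    q1 <- qual(function(r) r < 0.5, 6)
    q2 <- qual(function(r) r < 0.5, 12)
    q3 <- qual(function(r) r < 0.3, 24)
    qa <- qual(function(r) r == 0, 12)
    if (is.finite(q3) || is.finite(qa)) {
      arm_u <- if (q3 <= qa)
        list(stage = 3L, onset = q3, criterion = "urine_rate")
      else list(stage = 3L, onset = qa, criterion = "anuria")
    } else if (is.finite(q2)) {
      arm_u <- list(stage = 2L, onset = q2, criterion = "urine_rate")
    } else if (is.finite(q1)) {
      arm_u <- list(stage = 1L, onset = q1, criterion = "urine_rate")
    }
  }

  stage <- max(arm_c$stage, arm_u$stage)
  if (stage == 0L)
    return(list(stage = 0L, onset_time_h = NA_real_,
                criterion = NA_character_, baseline_creatinine = bl))
  oc <- if (arm_c$stage == stage) arm_c$onset else Inf
  ou <- if (arm_u$stage == stage) arm_u$onset else Inf
  if (oc <= ou)
    list(stage = stage, onset_time_h = oc, criterion = arm_c$criterion,
         baseline_creatinine = bl)
  else
    list(stage = stage, onset_time_h = ou, criterion = arm_u$criterion,
         baseline_creatinine = bl)
}

# adversarial random series: values straddle the KDIGO thresholds so the
# comparison exercises boundaries, not only the generator's safe margins
random_kdigo_case <- function(seed) {
  set.seed(seed)
  n_cr <- sample(3:12, 1)
  t_cr <- sort(runif(n_cr, 0.5, 180))
  if (min(t_cr) > 24) t_cr[1] <- runif(1, 1, 23)  # keep baseline computable
  t_cr <- sort(t_cr)
  base <- runif(1, 0.5, 1.6)
  v_cr <- base * sample(c(0.9, 1, 1.2, 1.45, 1.5, 1.6, 1.9, 2, 2.5, 3, 3.5),
                        n_cr, replace = TRUE) + rnorm(n_cr, 0, 0.05)
  v_cr <- pmax(v_cr, 0.05)
  obs <- data.frame(time_h = t_cr, channel = "creatinine", value = v_cr)
  if (runif(1) < 0.8) {
    n_u <- sample(10:60, 1)
    t_u <- cumsum(runif(n_u, 0.4, 3))
    w <- runif(1, 50, 110)
    r_u <- sample(c(0, 0.1, 0.25, 0.29, 0.3, 0.45, 0.5, 0.7, 1.2),
                  n_u, replace = TRUE)
    obs <- rbind(obs, data.frame(time_h = t_u, channel = "urine_output",
                                 value = r_u * w))
  } else {
    w <- runif(1, 50, 110)
  }
  list(observations = obs, weight_kg = w)
}

# small cohorts cached per (n, seed, delta, eta) across tests in a session
.cohort_cache <- new.env(parent = emptyenv())
test_cohort <- function(n = 500, seed = 42, delta = 0.6, eta = 0.5, ...) {
  key <- paste(n, seed, delta, eta, ...)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(cohort_config(
      n_stays = n, seed = seed, drift_magnitude = delta,
      subgroup_effect = eta, ...))
  .cohort_cache[[key]]
}

# hand-built observation frame for one stay
obs_frame <- function(times, values, channel = "creatinine") {
  data.frame(time_h = times, channel = channel, value = values)
}
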