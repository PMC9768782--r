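# Deployment-scenario engine: realizes baseline, drift, change-of-features,
# scarcity and change-of-population as split-generation + evaluation
# procedures over a generated cohort, and quantifies split confounding.

#' Scenario specification
#'
#' @param kind one of "baseline", "drift", "feature_change", "scarcity",
#'   "population".
#' @param task model task (see [model_spec()]); readmission tasks also set
#'   `readmission_window`.
#' @param seeds integer vector of replicate seeds (>= 1 seed).
#' @param fractions increasing training fractions in (0, 1] for scarcity
#'   and feature_change.
#' @param train_group,test_groups ethnicity groups for population.
#' @param include_urine whether the feature matrix carries the urine group
#'   (baseline/drift/scarcity/population).
#' @param readmission_window one of the [readmission_labels()] columns.
#' @param size_match_test if TRUE, test sides are subsampled to the
#'   baseline test size (20\% of the cohort) for size-matched comparison;
#'   raw test sides are the default.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("baseline", "drift", "feature_change",
                                   "scarcity", "population"),
                          task = "aki_binary",
                          seeds = 1:5,
                          fractions = seq(0.05, 1, by = 0.05),
                          train_group = "White",
                          test_groups = c("Black", "Latinx"),
                          include_urine = TRUE,
                          readmission_window = "w72h",
                          size_match_test = FALSE) {
  kind <- match.arg(kind)
  if (!length(seeds)) stop_input("seeds must be non-empty")
  fractions <- as.numeric(fractions)
  if (any(fractions <= 0) || any(fractions > 1))
    stop_input("fractions must lie in (0, 1]")
  if (is.unsorted(fractions, strictly = TRUE))
    stop_input("fractions must be strictly increasing")
  structure(list(kind = kind, task = task, seeds = as.integer(seeds),
                 fractions = fractions, train_group = train_group,
                 test_groups = test_groups, include_urine = include_urine,
                 readmission_window = readmission_window,
                 size_match_test = size_match_test),
            class = "scenario_spec")
}

# labels for the configured task over the eligible stays
scenario_labels <- function(spec, cohort, extraction) {
  ids <- extraction$stay_ids
  if (spec$task == "aki_binary") {
    lab <- extraction$labels
    as.integer(lab$stage[match(ids, lab$stay_id)] >= 1)
  } else if (spec$task == "aki_stage") {
    lab <- extraction$labels
    as.integer(lab$stage[match(ids, lab$stay_id)])
  } else {
    rl <- readmission_labels(cohort$stays)
    as.integer(rl[[spec$readmission_window]][match(ids, rl$stay_id)])
  }
}

# normalize (train rows only), fit, score the test side; asserts split
# soundness before touching any data
eval_on_split <- function(fm, labels, split, mspec, extra_excluded = NULL) {
  ids <- fm$stay_ids
  sp <- split[match(ids, split$stay_id)]
  sp$role[is.na(sp$role)] <- "excluded"
  tr <- sp$role == "train"; te <- sp$role == "test"
  stopifnot(!any(tr & te), sum(tr) >= 1, sum(te) >= 1)
  nf <- normalize_features(fm, tr)
  model <- train(nf$normalized[tr, , drop = FALSE], labels[tr], mspec)
  p <- predict_proba(model, nf$normalized[te, , drop = FALSE])
  mv <- auroc(p, labels[te])
  list(auroc = mv$value, n_train = sum(tr), n_test = sum(te), model = model,
       scores = p, test_labels = labels[te])
}

result_row <- function(scenario, arm, seed, auroc, n_train, n_test,
                       fraction = NA_real_, group = NA_character_) {
  data.table::data.table(scenario = scenario, arm = arm, seed = seed,
                         fraction = fraction, group = group, auroc = auroc,
                         n_train = n_train, n_test = n_test)
}

maybe_size_match <- function(split, spec, seed, target) {
  if (!spec$size_match_test) return(split)
  te <- which(split$role == "test")
  if (length(te) <= target) return(split)
  drop <- with_seed(derive_seed(seed, 23L),
                    sample(te, length(te) - target))
  split$role[drop] <- "excluded"
  split$note[drop] <- "size_match"
  split
}

#' Run a deployment scenario over a cohort
#'
#' Applies the cohort exclusions, derives task labels, and for each
#' replicate seed (and fraction or test group where the scenario calls for
#' them) builds the scenario's split, fits features with train-only
#' normalization, trains the model and scores the test side by AUROC.
#' The change-of-features scenario runs three arms over the fraction
#' grid: without urine features, with urine trained from scratch, and with
#' urine via layer-freezing transfer from the full-data no-urine model.
#' Scarcity trains on a random sub-sample of the cohort of the given
#' fraction and tests on the remainder.
#'
#' @param spec a [scenario_spec()].
#' @param cohort a `generated_cohort`.
#' @param mspec a [model_spec()] (replicate seeds are derived per run).
#' @param extraction optional precomputed [extract_cohort()] result.
#' @param keep_scores if TRUE, attach the per-run test scores and labels
#'   (for bootstrap intervals) as the `"scores"` attribute, a list aligned
#'   with the result rows.
#' @return `data.table` of evaluation results: scenario, arm, seed,
#'   fraction, group, auroc, n_train, n_test.
#' @export
run_scenario <- function(spec, cohort, mspec = model_spec(),
                         extraction = NULL, keep_scores = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(mspec, "model_spec"))
  if (is.null(extraction)) extraction <- extract_cohort(cohort)
  ids <- extraction$stay_ids
  labels <- scenario_labels(spec, cohort, extraction)
  baseline_test_n <- round(0.2 * length(ids))
  out <- list()
  scores <- list()

  if (spec$kind == "feature_change") {
    return(run_feature_change(spec, cohort, mspec, extraction, labels))
  }

  fm <- build_features(cohort, include_urine = spec$include_urine,
                       stay_ids = ids)
  stays_elig <- data.table::as.data.table(cohort$stays)[stay_id %in% ids]

  for (seed in spec$seeds) {
    ms <- mspec; ms$seed <- derive_seed(seed, 7L)
    if (spec$kind == "baseline") {
      sp <- split_baseline(ids, labels, seed)
      r <- eval_on_split(fm, labels, sp, ms)
      out[[length(out) + 1]] <- result_row("baseline", "baseline", seed,
                                           r$auroc, r$n_train, r$n_test)
      scores[[length(out)]] <- list(scores = r$scores,
                                    labels = r$test_labels)
    } else if (spec$kind == "drift") {
      sp <- split_drift(stays_elig)
      sp <- maybe_size_match(sp, spec, seed, baseline_test_n)
      r <- eval_on_split(fm, labels, sp, ms)
      out[[length(out) + 1]] <- result_row("drift", "drift", seed,
                                           r$auroc, r$n_train, r$n_test)
      scores[[length(out)]] <- list(scores = r$scores,
                                    labels = r$test_labels)
    } else if (spec$kind == "population") {
      for (g in spec$test_groups) {
        sp <- split_population(cohort, spec$train_group, g)
        sp <- sp[sp$stay_id %in% ids]
        sp <- maybe_size_match(sp, spec, seed, baseline_test_n)
        r <- eval_on_split(fm, labels, sp, ms)
        out[[length(out) + 1]] <- result_row(
          "population", "population", seed, r$auroc, r$n_train, r$n_test,
          group = paste(spec$train_group, g, sep = "-"))
        scores[[length(out)]] <- list(scores = r$scores,
                                      labels = r$test_labels)
      }
    } else if (spec$kind == "scarcity") {
      # nested sub-samples per seed (one permutation, growing prefixes):
      # models the accrual of a data collection and keeps adjacent
      # fractions comparable
      perm <- with_seed(derive_seed(seed, 1000L), sample(ids))
      for (f in spec$fractions) {
        n_tr <- max(2L, round(f * length(ids)))
        if (n_tr >= length(ids)) n_tr <- length(ids) - 1L
        tr_ids <- perm[seq_len(n_tr)]
        role <- ifelse(ids %in% tr_ids, "train", "test")
        sp <- split_assignment(ids, role)
        r <- eval_on_split(fm, labels, sp, ms)
        out[[length(out) + 1]] <- result_row("scarcity", "scarcity", seed,
                                             r$auroc, r$n_train, r$n_test,
                                             fraction = f)
        scores[[length(out)]] <- list(scores = r$scores,
                                      labels = r$test_labels)
      }
    }
  }
  res <- data.table::rbindlist(out)
  if (keep_scores) data.table::setattr(res, "scores", scores)
  res
}

# three-arm change-of-features runs over the fraction grid
run_feature_change <- function(spec, cohort, mspec, extraction, labels) {
  ids <- extraction$stay_ids
  fm_no <- build_features(cohort, include_urine = FALSE, stay_ids = ids)
  fm_wu <- build_features(cohort, include_urine = TRUE, stay_ids = ids)
  if (!all(urine_feature_group() %in% fm_wu$feature_names) ||
      anyNA(fm_wu$values[, urine_feature_group()]))
    stop_input("feature_change scenario needs a cohort with urine charted")
  urine_cols <- urine_feature_group()
  old_names <- fm_no$feature_names
  out <- list()

  for (seed in spec$seeds) {
    ms <- mspec; ms$seed <- derive_seed(seed, 7L)
    sp <- split_baseline(ids, labels, seed)
    tr_all <- sp$role[match(ids, sp$stay_id)] == "train"
    te <- sp$role[match(ids, sp$stay_id)] == "test"

    nf_no_full <- normalize_features(fm_no, tr_all)
    old_model <- train(nf_no_full$normalized[tr_all, , drop = FALSE],
                       labels[tr_all], ms)
    tsp <- transfer_spec(default_frozen_layers(length(ms$hidden)),
                         urine_cols)
    tr_idx <- with_seed(derive_seed(seed, 2000L), sample(which(tr_all)))

    for (f in spec$fractions) {
      k <- max(2L, min(length(tr_idx), round(f * length(tr_idx))))
      sub <- tr_idx[seq_len(k)]   # nested accrual, as in scarcity
      sub_mask <- seq_along(ids) %in% sub

      for (arm in c("no_urine", "with_urine")) {
        fm <- if (arm == "no_urine") fm_no else fm_wu
        nf <- normalize_features(fm, sub_mask)
        m <- train(nf$normalized[sub_mask, , drop = FALSE],
                   labels[sub_mask], ms)
        p <- predict_proba(m, nf$normalized[te, , drop = FALSE])
        out[[length(out) + 1]] <- result_row(
          "feature_change", arm, seed, auroc(p, labels[te])$value,
          sum(sub_mask), sum(te), fraction = f)
      }

      # transfer arm: old columns keep the deployed model's normalization;
      # urine columns are normalized on the fine-tuning rows only
      ur_raw <- fm_wu$values[, urine_cols, drop = FALSE]
      mu <- colMeans(ur_raw[sub_mask, , drop = FALSE])
      sdv <- apply(ur_raw[sub_mask, , drop = FALSE], 2, stats::sd)
      sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
      ur_norm <- sweep(sweep(ur_raw, 2, mu), 2, sdv, `/`)
      Xt <- cbind(nf_no_full$normalized, ur_norm)
      colnames(Xt) <- c(old_names, urine_cols)
      tm <- transfer_train(old_model, Xt[sub_mask, , drop = FALSE],
                           labels[sub_mask], tsp)
      p <- predict_proba(tm, Xt[te, , drop = FALSE])
      out[[length(out) + 1]] <- result_row(
        "feature_change", "with_urine_transfer", seed,
        auroc(p, labels[te])$value, sum(sub_mask), sum(te), fraction = f)
    }
  }
  data.table::rbindlist(out)
}

#' Aggregate scenario results into a learning curve
#'
#' @param results a [run_scenario()] result (one arm's rows).
#' @param arm optionally restrict to one arm.
#' @return `data.table` (fraction, mean_auroc, sd_auroc, n_train) of class
#'   `learning_curve`.
#' @export
learning_curve <- function(results, arm = NULL) {
  r <- data.table::as.data.table(results)
  if (!is.null(arm)) r <- r[r$arm == arm]
  if (!nrow(r) || all(is.na(r$fraction)))
    stop_input("results carry no fraction grid")
  cv <- r[, .(mean_auroc = mean(auroc),
              sd_auroc = if (.N > 1) stats::sd(auroc) else 0,
              n_train = mean(n_train)), by = fraction][order(fraction)]
  data.table::setattr(cv, "class",
                      c("learning_curve", class(cv)))
  cv
}

#' Smallest training fraction reaching a reference AUROC
#'
#' @param curve a [learning_curve()].
#' @param reference_auroc reference level (e.g. the full-data AUROC of the
#'   model without the new features).
#' @return the smallest grid fraction whose mean AUROC is >= the
#'   reference, or NA if never reached.
#' @export
crossover_fraction <- function(curve, reference_auroc) {
  stopifnot(nrow(curve) >= 1)
  hit <- which(curve$mean_auroc >= reference_auroc)
  if (!length(hit)) NA_real_ else curve$fraction[min(hit)]
}

#' Cross-tabulated split confounding
#'
#' Percentage of each level of partition B within each level of partition
#' A, plus a whole-cohort row. Levels of B omitted from `b_levels` (e.g.
#' the drift cross-over phase) absorb the remainder, so listed cells may
#' sum to less than 100.
#'
#' @param cohort a `generated_cohort`.
#' @param partition_a,partition_b either the name of a built-in stay
#'   partition ("ethnicity", "ethnicity_binary", "drift") or a vector of
#'   level labels aligned with the cohort's stays.
#' @param b_levels B levels to tabulate (default: all).
#' @return `data.table` of class `confounding_table`.
#' @export
confounding_table <- function(cohort, partition_a, partition_b,
                              b_levels = NULL) {
  a <- resolve_partition(cohort, partition_a)
  b <- resolve_partition(cohort, partition_b)
  stopifnot(length(a) == length(b))
  if (is.null(b_levels)) b_levels <- sort(unique(b))
  rows <- c("whole", sort(unique(a)))
  cells <- matrix(NA_real_, length(rows), length(b_levels),
                  dimnames = list(rows, b_levels))
  for (i in seq_along(rows)) {
    sel <- if (rows[i] == "whole") rep(TRUE, length(a)) else a == rows[i]
    for (j in seq_along(b_levels))
      cells[i, j] <- 100 * sum(b[sel] == b_levels[j]) / sum(sel)
  }
  out <- data.table::data.table(partition = rows)
  for (j in seq_along(b_levels)) out[[b_levels[j]]] <- cells[, j]
  data.table::setattr(out, "class", c("confounding_table", class(out)))
  out
}

resolve_partition <- function(cohort, p) {
  stays <- data.table::as.data.table(cohort$stays)
  if (is.character(p) && length(p) == 1) {
    if (p == "drift") return(stays$emr_epoch)
    eth <- merge(stays[, c("stay_id", "patient_id")],
                 data.table::as.data.table(
                   cohort$patients)[, c("patient_id", "ethnicity")],
                 by = "patient_id")
    eth <- eth$ethnicity[match(stays$stay_id, eth$stay_id)]
    if (p == "ethnicity") return(eth)
    if (p == "ethnicity_binary")
      return(ifelse(eth == "White", "White", "Other"))
    stop_input("unknown built-in partition '%s'", p)
  }
  if (length(p) != nrow(stays))
    stop_input("partition vector must align with the cohort's stays")
  as.character(p)
}
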