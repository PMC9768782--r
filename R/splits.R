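# Split generation for the deployment scenarios. A split assignment maps
# every stay to exactly one of train / test / excluded.

split_assignment <- function(stay_id, role, note = NA_character_) {
  out <- data.table::data.table(stay_id = stay_id, role = role,
                                note = note)
  check_split(out)
  out
}

check_split <- function(split) {
  stopifnot(all(split$role %in% c("train", "test", "excluded")))
  if (anyDuplicated(split$stay_id))
    stop_input("split assigns a stay more than once")
  tr <- split$stay_id[split$role == "train"]
  te <- split$stay_id[split$role == "test"]
  if (length(intersect(tr, te)))
    stop_input("train and test overlap")   # internal soundness assertion
  invisible(split)
}

#' Random stratified 80/20 baseline split
#'
#' @param stay_ids eligible stay ids.
#' @param labels 0/1 (or small integer) labels aligned with `stay_ids`;
#'   stratification keeps train and test prevalence equal up to rounding.
#' @param seed split seed.
#' @param train_frac training fraction (default 0.8).
#' @return a split assignment (`data.table`: stay_id, role, note).
#' @export
split_baseline <- function(stay_ids, labels, seed = 1L, train_frac = 0.8) {
  n <- length(stay_ids)
  if (n < 5) stop_input("cannot stratify fewer than 5 stays")
  stopifnot(length(labels) == n)
  role <- rep("train", n)
  with_seed(derive_seed(seed, 11L), {
    for (lv in unique(labels)) {
      rows <- which(labels == lv)
      k <- round(length(rows) * (1 - train_frac))
      if (k > 0) role[sample(rows, k)] <- "test"
    }
  })
  if (!any(role == "test") || !any(role == "train"))
    stop_input("degenerate split: empty train or test side")
  split_assignment(stay_ids, role)
}

#' Temporal-drift split: train pre-epoch, test post-epoch
#'
#' Stays from the EMR cross-over phase are excluded from both sides to
#' keep the time cut-off clean.
#'
#' @param stays cohort `stays` table (column `emr_epoch`).
#' @return a split assignment.
#' @export
split_drift <- function(stays) {
  s <- data.table::as.data.table(stays)
  if (!"emr_epoch" %in% names(s)) stop_input("stays lacks emr_epoch")
  role <- ifelse(s$emr_epoch == "pre", "train",
                 ifelse(s$emr_epoch == "post", "test", "excluded"))
  if (!any(role == "train") || !any(role == "test"))
    stop_input("drift split infeasible: an epoch side is empty")
  split_assignment(s$stay_id, role,
                   ifelse(role == "excluded", "crossover", NA_character_))
}

#' Population split: train on one ethnicity group, test on another
#'
#' @param cohort a `generated_cohort` (patients + stays), or any list with
#'   those two tables.
#' @param train_group,test_group ethnicity groups (distinct).
#' @return a split assignment.
#' @export
split_population <- function(cohort, train_group, test_group) {
  if (identical(train_group, test_group))
    stop_input("degenerate transfer: train_group equals test_group")
  pp <- merge(data.table::as.data.table(cohort$stays)[, c("stay_id",
                                                          "patient_id")],
              data.table::as.data.table(cohort$patients)[, c("patient_id",
                                                             "ethnicity")],
              by = "patient_id")
  role <- ifelse(pp$ethnicity == train_group, "train",
                 ifelse(pp$ethnicity == test_group, "test", "excluded"))
  if (!any(role == "train") || !any(role == "test"))
    stop_input("population split infeasible: a group is empty")
  split_assignment(pp$stay_id, role,
                   ifelse(role == "excluded", "other_group", NA_character_))
}
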