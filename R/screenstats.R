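## Screening-program statistics: per-infant ledger, cohort category
## summary with printed-precision percentages, referral confirmation rate,
## and rolling follow-up-rate learning curves.

INITIAL_OUTCOMES <- c("COULD_NOT_SCAN", "NORMAL", "SUBOPTIMAL", "FOLLOW_UP")
FU_OUTCOMES <- c("NORMAL", "DYSPLASTIC", "NONE")
REFERRAL_OUTCOMES <- c("TREATED", "NOT_TREATED", "NONE")
USER_ROLES <- c("RN", "LPN", "sonographer", "physician", "unknown")

#' Validate a screening ledger
#'
#' One row per infant (latest status). Required columns: `subject_id`,
#' `scan_date` (ISO-8601), `site`, `user_role`, `initial_outcome`,
#' `internal_fu_outcome`, `referred`, `referral_outcome`; optional `sex`
#' (`"F"`/`"M"`). Internal follow-up outcomes other than `NONE` are only
#' allowed after a `SUBOPTIMAL` or `FOLLOW_UP` initial outcome; a referral
#' outcome other than `NONE` requires `referred = TRUE`.
#'
#' @param records data.frame ledger.
#' @return the validated data.frame (with `scan_date` as `Date`), invisibly
#'   usable downstream.
#' @export
validate_ledger <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    hs_validation_error("the screening ledger must be a non-empty data.frame")
  need <- c("subject_id", "scan_date", "site", "user_role", "initial_outcome",
            "internal_fu_outcome", "referred", "referral_outcome")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    hs_validation_error(paste("ledger lacks columns:",
                              paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(records$subject_id))
    hs_validation_error("duplicate subject_id in ledger (one row per infant)")
  if (!all(records$initial_outcome %in% INITIAL_OUTCOMES))
    hs_validation_error("invalid initial_outcome value")
  if (!all(records$internal_fu_outcome %in% FU_OUTCOMES))
    hs_validation_error("invalid internal_fu_outcome value")
  if (!all(records$referral_outcome %in% REFERRAL_OUTCOMES))
    hs_validation_error("invalid referral_outcome value")
  bad_fu <- records$internal_fu_outcome != "NONE" &
    !(records$initial_outcome %in% c("SUBOPTIMAL", "FOLLOW_UP"))
  if (any(bad_fu))
    hs_validation_error("internal_fu_outcome set without a FU-triggering initial outcome")
  if (any(records$referral_outcome != "NONE" & !records$referred))
    hs_validation_error("referral_outcome set for non-referred infant")
  records$scan_date <- as.Date(records$scan_date)
  if (anyNA(records$scan_date))
    hs_validation_error("scan_date must be ISO-8601 parseable")
  records
}

#' Read / write a screening ledger CSV
#'
#' @param path CSV file with the ScreeningRecord columns (ISO-8601 dates).
#' @return data.frame ledger.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) hs_io_error(sprintf("no ledger at '%s'", path))
  validate_ledger(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ledger
#' @param records ledger data.frame.
#' @export
write_ledger <- function(records, path) {
  records <- validate_ledger(records)
  records$scan_date <- format(records$scan_date, "%Y-%m-%d")
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

default_rounding <- function() {
  list(could_not_scan = 1, normal_first_scan = 0, suboptimal_fu = 1,
       ai_follow_up = 0, fu_resolved_normal = 1, dysplastic_treated = 1,
       female = 0)
}

#' Summarize a screening cohort
#'
#' Category counts and percentages over unique infants: could not scan,
#' normal at first scan, suboptimal-triggered internal follow-up,
#' AI-triggered follow-up, follow-up resolved normal, and dysplastic
#' (treated). Percentages are `100 * count / total_infants`, rounded half
#' away from zero to the per-field precision in `rounding_spec`, so every
#' reported percentage recomputes exactly from its integer count. When the
#' ledger carries a `sex` column the female percentage is included.
#'
#' @param records ledger data.frame (one row per infant).
#' @param rounding_spec named list of decimal places per category.
#' @return object of class `cohort_summary` with `total_infants`, `counts`,
#'   `percentages`, `rounding_spec`.
#' @export
summarize_cohort <- function(records, rounding_spec = default_rounding()) {
  records <- validate_ledger(records)
  n <- nrow(records)
  counts <- list(
    could_not_scan = sum(records$initial_outcome == "COULD_NOT_SCAN"),
    normal_first_scan = sum(records$initial_outcome == "NORMAL"),
    suboptimal_fu = sum(records$initial_outcome == "SUBOPTIMAL"),
    ai_follow_up = sum(records$initial_outcome == "FOLLOW_UP"),
    fu_resolved_normal = sum(records$initial_outcome == "FOLLOW_UP" &
                               records$internal_fu_outcome == "NORMAL"),
    dysplastic_treated = sum(records$referred &
                               records$referral_outcome == "TREATED"))
  if ("sex" %in% names(records))
    counts$female <- sum(records$sex == "F")
  pct <- lapply(names(counts), function(nm) {
    digits <- rounding_spec[[nm]]
    if (is.null(digits)) digits <- 1
    round_half_up(100 * counts[[nm]] / n, digits)
  })
  names(pct) <- names(counts)
  structure(list(total_infants = n, counts = counts, percentages = pct,
                 rounding_spec = rounding_spec),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Screening cohort: %d infants\n", x$total_infants))
  for (nm in names(x$counts))
    cat(sprintf("  %-20s %4d (%s%%)\n", nm, x$counts[[nm]],
                format(x$percentages[[nm]])))
  invisible(x)
}

#' Serialize a cohort summary to JSON
#'
#' @param summary a `cohort_summary`.
#' @param path optional file to write.
#' @return JSON string (invisibly when `path` is given).
#' @export
summary_to_json <- function(summary, path = NULL) {
  obj <- list(total_infants = summary$total_infants, counts = summary$counts,
              percentages = summary$percentages)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Referral confirmation rate
#'
#' Percentage of externally referred infants whose referral outcome was
#' treatment for DDH. Undefined (an error, not 0) when no infant was
#' referred.
#'
#' @param records ledger data.frame.
#' @return percentage in \[0, 100\].
#' @export
referral_confirmation_rate <- function(records) {
  records <- validate_ledger(records)
  ref <- records[records$referred, , drop = FALSE]
  if (nrow(ref) == 0)
    hs_undefined_rate_error("no referrals in ledger; confirmation rate undefined")
  100 * sum(ref$referral_outcome == "TREATED") / nrow(ref)
}

#' Rolling follow-up rate (learning curve)
#'
#' Orders records by scan date (ties broken by subject_id) and computes,
#' for every position from `window_size` onward, the proportion of the
#' trailing `window_size` records whose initial outcome triggered internal
#' follow-up (`SUBOPTIMAL` or `FOLLOW_UP`). Optionally one series per site
#' or user role.
#'
#' @param records ledger data.frame.
#' @param window_size trailing window length (>= 1).
#' @param group_by `NULL`, `"site"` or `"user_role"`.
#' @return data.frame with columns `index`, `rate` (and `group` when
#'   grouped); empty when a group has fewer records than the window.
#' @export
rolling_fu_rate <- function(records, window_size = 20, group_by = NULL) {
  records <- validate_ledger(records)
  check_scalar(window_size, "window_size", min = 1, integer = TRUE)
  if (!is.null(group_by) && !group_by %in% c("site", "user_role"))
    hs_validation_error("'group_by' must be NULL, 'site' or 'user_role'")
  one_series <- function(df, label = NULL) {
    df <- df[order(df$scan_date, df$subject_id), , drop = FALSE]
    n <- nrow(df)
    if (window_size > n)
      return(data.frame(index = integer(0), rate = numeric(0)))
    ind <- as.numeric(df$initial_outcome %in% c("SUBOPTIMAL", "FOLLOW_UP"))
    cs <- c(0, cumsum(ind))
    i <- window_size:n
    out <- data.frame(index = i,
                      rate = (cs[i + 1] - cs[i + 1 - window_size]) / window_size)
    if (!is.null(label)) out$group <- label
    out
  }
  if (is.null(group_by)) return(one_series(records))
  groups <- sort(unique(records[[group_by]]))
  do.call(rbind, lapply(groups, function(g)
    one_series(records[records[[group_by]] == g, , drop = FALSE], g)))
}

#' Combine two per-hip decisions into the infant-level outcome
#'
#' The worst hip governs the infant's management: any `FOLLOW_UP` hip makes
#' the infant `FOLLOW_UP`; otherwise any `INCONCLUSIVE` hip makes the visit
#' `SUBOPTIMAL` (repeat); otherwise `NORMAL`.
#'
#' @param left,right `sweep_decision` objects or their label strings.
#' @return `"FOLLOW_UP"`, `"SUBOPTIMAL"` or `"NORMAL"`.
#' @export
infant_outcome <- function(left, right) {
  lab <- function(x) if (inherits(x, "sweep_decision")) x$label else x
  labels <- c(lab(left), lab(right))
  if (!all(labels %in% DECISION_LABELS))
    hs_validation_error("hip decisions must be HEALTHY/FOLLOW_UP/INCONCLUSIVE")
  if (any(labels == "FOLLOW_UP")) return("FOLLOW_UP")
  if (any(labels == "INCONCLUSIVE")) return("SUBOPTIMAL")
  "NORMAL"
}

#' Synthetic pilot-study ledger (306 infants)
#'
#' A deterministic synthetic cohort whose marginal counts mirror the pilot
#' screening program this package models: 306 infants of whom 18 could not
#' be scanned, 244 were normal at first scan, 12 had a suboptimal scan
#' (all resolving normal at internal follow-up), and 32 received an AI
#' follow-up recommendation (26 normal at internal follow-up, 6 referred
#' and all treated for DDH); 156 infants are female, 5 of the 6 treated.
#' Row order, dates, sites and user roles are synthetic plumbing; only the
#' marginal counts are meaningful. A CSV copy ships as
#' `system.file("extdata", "pilot_ledger_synthetic.csv", package =
#' "hipscreen")`.
#'
#' @return validated ledger data.frame with 306 rows.
#' @export
pilot_ledger <- function() {
  n <- 306
  outcomes <- c(rep("COULD_NOT_SCAN", 18), rep("NORMAL", 244),
                rep("SUBOPTIMAL", 12), rep("FOLLOW_UP", 32))
  ## deterministic interleave so the learning-curve plot is non-trivial
  perm <- withr::with_seed(42L, sample(n))
  outcomes <- outcomes[perm]
  fu <- rep("NONE", n)
  fu[outcomes == "SUBOPTIMAL"] <- "NORMAL"
  fu_idx <- which(outcomes == "FOLLOW_UP")
  fu[fu_idx] <- c(rep("NORMAL", 26), rep("DYSPLASTIC", 6))
  referred <- fu == "DYSPLASTIC"
  referral <- ifelse(referred, "TREATED", "NONE")
  ## 156 female, 5 of the 6 dysplastic-treated infants female
  sex <- rep("M", n)
  treated_idx <- which(referred)
  sex[treated_idx[1:5]] <- "F"
  remaining <- setdiff(seq_len(n), treated_idx)
  sex[remaining[seq_len(151)]] <- "F"
  roles <- c(rep("RN", 158), rep("LPN", 49), rep("sonographer", 24),
             rep("physician", 65), rep("unknown", 10))[order(perm)]
  site <- c(RN = "Center1", LPN = "Center2", sonographer = "Center1",
            physician = "Center3", unknown = "Center2")[roles]
  dates <- seq(as.Date("2021-02-01"), as.Date("2022-03-31"), length.out = n)
  validate_ledger(data.frame(
    subject_id = sprintf("INF%03d", seq_len(n)),
    scan_date = format(dates, "%Y-%m-%d"),
    site = unname(site), user_role = roles, sex = sex,
    initial_outcome = outcomes, internal_fu_outcome = fu,
    referred = referred, referral_outcome = referral,
    stringsAsFactors = FALSE))
}
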