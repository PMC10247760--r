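# Screening-program statistics: cohort summary arithmetic, referral
# confirmation, rolling follow-up rates, infant-level roll-up, validation.

test_that("the synthetic pilot ledger reproduces its printed percentages", {
  led <- pilot_ledger()
  expect_equal(nrow(led), 306)
  s <- summarize_cohort(led)
  expect_equal(s$percentages$could_not_scan, 5.9)
  expect_equal(s$percentages$normal_first_scan, 80)
  expect_equal(s$percentages$suboptimal_fu, 3.9)
  expect_equal(s$percentages$ai_follow_up, 10)
  expect_equal(s$percentages$dysplastic_treated, 2.0)
  expect_equal(s$percentages$female, 51)
  ## 26/306 computes to 8.5 under the declared rounding
  expect_equal(s$counts$fu_resolved_normal, 26)
  expect_equal(s$percentages$fu_resolved_normal, 8.5)
  ## category counts partition the cohort
  expect_equal(s$counts$could_not_scan + s$counts$normal_first_scan +
                 s$counts$suboptimal_fu + s$counts$ai_follow_up,
               s$total_infants)
})

test_that("the packaged fixture CSV matches the generator", {
  path <- system.file("extdata", "pilot_ledger_synthetic.csv",
                      package = "hipscreen")
  expect_true(nzchar(path))
  led <- read_ledger(path)
  gen <- pilot_ledger()
  expect_equal(led$initial_outcome, gen$initial_outcome)
  expect_equal(led$sex, gen$sex)
  expect_equal(summarize_cohort(led)$percentages,
               summarize_cohort(gen)$percentages)
})

test_that("percentages recompute from counts under the declared rounding", {
  led <- pilot_ledger()
  s <- summarize_cohort(led)
  for (nm in names(s$counts)) {
    digits <- s$rounding_spec[[nm]]
    if (is.null(digits)) digits <- 1
    expect_equal(s$percentages[[nm]],
                 round_half_up(100 * s$counts[[nm]] / s$total_infants, digits))
  }
  ## half-away-from-zero, not banker's rounding
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(3.45, 1), 3.5)
})

test_that("single-record and small ledgers summarize correctly", {
  one <- data.frame(subject_id = "A", scan_date = "2021-06-01",
                    site = "Center1", user_role = "RN",
                    initial_outcome = "NORMAL", internal_fu_outcome = "NONE",
                    referred = FALSE, referral_outcome = "NONE")
  s <- summarize_cohort(one)
  expect_equal(s$percentages$normal_first_scan, 100)
})

test_that("referral confirmation rate and its undefined case", {
  led <- pilot_ledger()
  expect_equal(referral_confirmation_rate(led), 100)

  mixed <- led
  ref_idx <- which(mixed$referred)
  mixed$referral_outcome[ref_idx[1:3]] <- "NOT_TREATED"
  expect_equal(referral_confirmation_rate(mixed), 50)

  none <- led[!led$referred, ]
  expect_error(referral_confirmation_rate(none),
               class = "hipscreen_undefined_rate_error")
})

test_that("ledger validation rejects malformed records", {
  led <- pilot_ledger()
  dup <- rbind(led, led[1, ])
  expect_error(summarize_cohort(dup), "duplicate",
               class = "hipscreen_validation_error")
  expect_error(summarize_cohort(led[0, ]), class = "hipscreen_validation_error")

  bad <- led
  bad$internal_fu_outcome[bad$initial_outcome == "NORMAL"][1] <- "NORMAL"
  expect_error(validate_ledger(bad), class = "hipscreen_validation_error")

  bad2 <- led
  bad2$referral_outcome[!bad2$referred][1] <- "TREATED"
  expect_error(validate_ledger(bad2), class = "hipscreen_validation_error")
})

make_run_ledger <- function(outcomes, start = "2021-01-01") {
  n <- length(outcomes)
  data.frame(subject_id = sprintf("R%03d", seq_len(n)),
             scan_date = format(as.Date(start) + seq_len(n), "%Y-%m-%d"),
             site = "Center1", user_role = "RN",
             initial_outcome = outcomes,
             internal_fu_outcome = ifelse(
               outcomes %in% c("SUBOPTIMAL", "FOLLOW_UP"), "NORMAL", "NONE"),
             referred = FALSE, referral_outcome = "NONE",
             stringsAsFactors = FALSE)
}

test_that("rolling FU rate matches the analytic sliding count", {
  led <- make_run_ledger(c(rep("FOLLOW_UP", 40), rep("NORMAL", 60)))
  got <- rolling_fu_rate(led, window_size = 20)
  expect_equal(got$index, 20:100)
  analytic <- vapply(20:100, function(i)
    sum(seq(i - 19, i) <= 40) / 20, numeric(1))
  expect_equal(got$rate, analytic)
  expect_equal(got$rate[1], 1.0)
  expect_equal(got$rate[length(got$rate)], 0.0)
})

test_that("rolling FU rate edge cases and invariances", {
  all_norm <- make_run_ledger(rep("NORMAL", 30))
  expect_true(all(rolling_fu_rate(all_norm, 10)$rate == 0))

  led <- make_run_ledger(c("FOLLOW_UP", "NORMAL", "SUBOPTIMAL", "NORMAL"))
  w1 <- rolling_fu_rate(led, 1)
  expect_equal(w1$rate, c(1, 0, 1, 0))

  expect_equal(nrow(rolling_fu_rate(led, 10)), 0)   # window > n

  ## translation invariance in time
  shifted <- led
  shifted$scan_date <- format(as.Date(led$scan_date) + 365, "%Y-%m-%d")
  expect_equal(rolling_fu_rate(led, 2)$rate, rolling_fu_rate(shifted, 2)$rate)

  ## grouped series
  led2 <- make_run_ledger(rep(c("FOLLOW_UP", "NORMAL"), 10))
  led2$site <- rep(c("Center1", "Center2"), each = 10)
  g <- rolling_fu_rate(led2, 5, group_by = "site")
  expect_setequal(unique(g$group), c("Center1", "Center2"))
})

test_that("infant-level outcome takes the worst hip", {
  expect_equal(infant_outcome("HEALTHY", "HEALTHY"), "NORMAL")
  expect_equal(infant_outcome("HEALTHY", "FOLLOW_UP"), "FOLLOW_UP")
  expect_equal(infant_outcome("INCONCLUSIVE", "HEALTHY"), "SUBOPTIMAL")
  expect_equal(infant_outcome("INCONCLUSIVE", "FOLLOW_UP"), "FOLLOW_UP")
  expect_error(infant_outcome("HEALTHY", "MAYBE"),
               class = "hipscreen_validation_error")
})
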