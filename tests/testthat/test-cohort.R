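test_that("monotherapy detection follows the two-fill / 31-day rule", {
  f <- data.frame(person_id = 1, day = c(0, 40), drug = "quetiapine",
                  days_supply = c(30, 15), class = "antipsychotic")
  ep <- detect_monotherapy(f, "quetiapine")
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$index_day, 0)
  expect_equal(ep$window_supply, 45)

  # a single fill never qualifies, whatever its supply
  f1 <- data.frame(person_id = 1, day = 0, drug = "quetiapine",
                   days_supply = 90, class = "antipsychotic")
  expect_equal(nrow(detect_monotherapy(f1, "quetiapine")), 0L)

  # fills 100 days apart share no 90-day window
  f2 <- data.frame(person_id = 1, day = c(0, 100), drug = "quetiapine",
                   days_supply = c(15, 30), class = "antipsychotic")
  expect_equal(nrow(detect_monotherapy(f2, "quetiapine")), 0L)
  expect_true(is.na(brute_mono_index(c(0, 100), c(15, 30))))

  expect_error(detect_monotherapy(
    data.frame(person_id = 1, day = 0, drug = "quetiapine",
               days_supply = -1, class = "antipsychotic"), "quetiapine"),
    "days_supply")
})

test_that("detection agrees with the exhaustive window scan on random fill sets", {
  set.seed(42)
  for (r in 1:300) {
    k <- sample(1:6, 1)
    days <- sort(sample(0:400, k))
    sup <- sample(1:60, k, replace = TRUE)
    f <- data.frame(person_id = 1, day = days, drug = "olanzapine",
                    days_supply = sup, class = "antipsychotic")
    ep <- detect_monotherapy(f, "olanzapine")
    oracle <- brute_mono_index(days, sup)
    if (is.na(oracle)) {
      expect_equal(nrow(ep), 0L)
    } else {
      expect_equal(ep$index_day, oracle)
    }
  }
})

test_that("new-user screen allows own-drug fills and applies the 183-day boundary", {
  ep <- data.frame(person_id = 1, drug = "quetiapine", index_day = 200)
  base <- data.frame(person_id = 1, day = c(200, 230), drug = "quetiapine",
                     days_supply = 30, class = "antipsychotic")
  other_30 <- rbind(base, data.frame(person_id = 1, day = 170,
                                     drug = "haloperidol", days_supply = 30,
                                     class = "antipsychotic"))
  expect_false(screen_new_user(other_30, ep))
  own_30 <- rbind(base, data.frame(person_id = 1, day = 170,
                                   drug = "quetiapine", days_supply = 30,
                                   class = "antipsychotic"))
  expect_true(screen_new_user(own_30, ep))
  # exactly 183 days before index: outside the pre-period window
  other_183 <- rbind(base, data.frame(person_id = 1, day = 200 - 183,
                                      drug = "haloperidol", days_supply = 30,
                                      class = "antipsychotic"))
  expect_true(screen_new_user(other_183, ep))
  other_182 <- rbind(base, data.frame(person_id = 1, day = 200 - 182,
                                      drug = "haloperidol", days_supply = 30,
                                      class = "antipsychotic"))
  expect_false(screen_new_user(other_182, ep))
})

test_that("enrollment filters demand continuity except for covered deaths", {
  idx <- 100L
  mi <- day_to_month(idx)
  ep <- data.frame(person_id = 1, index_day = idx)
  full <- data.frame(person_id = 1,
                     month = seq.int(day_to_month(idx - 182L), mi + 12L))
  alive <- data.frame(person_id = 1, birth_day = -10000L,
                      death_day = NA_integer_)
  expect_true(apply_enrollment_filters(ep, full, alive))

  # gap in post-period month 3, alive
  gap3 <- full[full$month != mi + 3L, ]
  expect_false(apply_enrollment_filters(ep, gap3, alive))

  # death in post-period month 4 with months 1-3 covered
  death_day <- month_start_day(mi + 4L) + 10L
  dead <- data.frame(person_id = 1, birth_day = -10000L,
                     death_day = death_day)
  cov_to_3 <- full[full$month <= mi + 3L, ]
  expect_true(apply_enrollment_filters(ep, cov_to_3, dead))
  # same death but a post-period month before death uncovered
  expect_false(apply_enrollment_filters(
    ep, cov_to_3[cov_to_3$month != mi + 2L, ], dead))
  # pre-period gap fails regardless
  expect_false(apply_enrollment_filters(
    ep, full[full$month != mi - 2L, ], alive))
})

test_that("exclusions fire on pre-period cardiometabolic codes but not type 1 diabetes", {
  ep <- data.frame(person_id = 1, drug = "quetiapine", index_day = 100)
  expect_false(apply_exclusions(ep, dx_row(1, 50, code = "HYPERTENSION")))
  expect_true(apply_exclusions(ep, dx_row(1, 50, code = "T1D")))
  # post-period-only exclusionary claim is not a pre-period exclusion
  expect_true(apply_exclusions(ep, dx_row(1, 150, code = "HYPERTENSION")))
  # boundary: exactly 183 days before index is outside the window
  expect_true(apply_exclusions(ep, dx_row(1, 100 - 183, code = "CVD")))
  expect_false(apply_exclusions(ep, dx_row(1, 100 - 182, code = "CVD")))
  expect_warning(
    apply_exclusions(ep, dx_row(1, 150, code = "MYSTERY")),
    "non-exclusionary")
})

test_that("follow-up resolution takes the earliest event with the declared hierarchy", {
  enr <- data.frame(person_id = 1,
                    month = seq.int(0L, day_to_month(study_period()$study_end)))
  ep <- data.frame(person_id = 1, index_day = 100L)

  # no events: full 3 years
  p <- data.frame(person_id = 1, birth_day = -10000L, death_day = NA_integer_)
  fu <- resolve_followup(ep, enr, p)
  expect_equal(fu$end - fu$start, 1095L)
  expect_equal(fu$reason, "three_years")

  # 65th birthday at index+400, study end at index+500
  p65 <- data.frame(person_id = 1,
                    birth_day = 100L + 400L - as.integer(ceiling(65 * 365.25)),
                    death_day = NA_integer_)
  fu <- resolve_followup(ep, enr, p65, study_end = 600L)
  expect_equal(fu$end, 500L)
  expect_equal(fu$reason, "turned_65")

  # study end and coverage loss on the same day: end_of_study wins
  last_cov_month <- 24L
  enr2 <- data.frame(person_id = 1, month = seq.int(0L, last_cov_month))
  se <- month_start_day(last_cov_month + 1L) - 1L  # last covered day
  fu <- resolve_followup(ep, enr2, p, study_end = se)
  expect_equal(fu$end, se)
  expect_equal(fu$reason, "end_of_study")

  # death before any censoring event
  pd <- data.frame(person_id = 1, birth_day = -10000L, death_day = 300L)
  fu <- resolve_followup(ep, enr, pd)
  expect_equal(fu$end, 300L)
  expect_equal(fu$reason, "death")

  # degenerate: death on the index day is a data error
  pd0 <- data.frame(person_id = 1, birth_day = -10000L, death_day = 100L)
  expect_error(resolve_followup(ep, enr, pd0), "index day")
})

test_that("the toy bundle attrition matches the hand count stage by stage", {
  b <- toy_bundle()
  coh <- build_cohort(b)
  expect_equal(attr(coh, "attrition"),
               c(candidates = 11L, monotherapy = 8L, new_user = 7L,
                 enrolled = 5L, not_excluded = 4L, final = 4L))
  expect_setequal(coh$person_id, c(1, 2, 7, 11))
  expect_equal(nrow(coh), length(unique(coh$person_id)))

  # person-level spot checks from the hand trace
  p2 <- coh[coh$person_id == 2, ]
  expect_equal(p2$fu_reason, "death")
  expect_equal(p2$death, 1L)
  expect_equal(p2$diabetes, 0L)
  p7 <- coh[coh$person_id == 7, ]
  expect_equal(p7$diabetes, 1L)
  expect_equal(p7$pre_expo_days, 28L)
  expect_false(p7$sensitivity_flag)
  expect_true(coh$sensitivity_flag[coh$person_id == 1])
})

test_that("cohort construction is invariant to input row order and idempotent", {
  b <- toy_bundle()
  coh <- build_cohort(b)
  set.seed(8)
  b2 <- b
  b2$fills <- b$fills[sample(nrow(b$fills)), ]
  b2$dx_claims <- b$dx_claims[sample(nrow(b$dx_claims)), ]
  b2$enrollment <- b$enrollment[sample(nrow(b$enrollment)), ]
  coh2 <- build_cohort(b2)
  rownames(coh2) <- rownames(coh) <- NULL
  expect_equal(coh2, coh, ignore_attr = TRUE)
  expect_equal(build_cohort(b), coh)
})

test_that("same-day qualification on two drugs drops the person with a log", {
  b <- toy_bundle()
  # give person 1 a simultaneous qualifying pattern on a second drug
  twin <- b$fills[b$fills$person_id == 1, ]
  twin$drug <- "risperidone"
  b$fills <- rbind(b$fills, twin)
  expect_message(coh <- build_cohort(b), "same day")
  expect_false(1 %in% coh$person_id)
  expect_equal(attr(coh, "dropped_ties"), "1")
})
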