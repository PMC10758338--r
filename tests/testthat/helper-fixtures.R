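# Shared fixtures: hand-built toy bundles and reduced DGP configurations,
# plus the brute-force oracles the episode and outcome rules are checked
# against.

# --- reduced configs -------------------------------------------------------

# One Bernoulli(0.5) confounder with printed logits: closed-form truth is the
# two-point average of logistic values.
one_binary_config <- function(n = 2000, seed = 1) {
  drugs <- study_drugs()
  dgp_config(
    n_persons = n, drugs = drugs,
    confounders = list(cf_bernoulli("w", 0.5)),
    assignment = list(
      intercepts = setNames(rep(0, 6), drugs),
      coefs = matrix(c(0.6, 0, -0.4, 0.2, 0, -0.6), 6, 1,
                     dimnames = list(drugs, "w"))
    ),
    outcomes = list(
      diabetes = list(intercept = -2, coefs = c(w = 1),
                      drug_effects = setNames(c(0, 0, 0, -0.5, 0, -0.5),
                                              drugs)),
      death = list(intercept = -3, coefs = c(w = 0.8),
                   drug_effects = setNames(c(0.4, 0.2, 0, 0.3, 0.25, 0.35),
                                           drugs))
    ),
    seed = seed
  )
}

# --- toy claims bundle ------------------------------------------------------

# Eleven hand-constructed persons, one violation per design filter:
#   p1  qualifies cleanly, no outcome
#   p2  qualifies; dies in post-period month 4 with coverage to the month
#       before death
#   p3  single fill only                      -> fails monotherapy
#   p4  two fills 95 days apart               -> fails monotherapy (window)
#   p5  two fills totalling 30 days supply    -> fails monotherapy (supply)
#   p6  other antipsychotic at index-30       -> fails new-user screen
#   p7  own-drug fill at index-30 only        -> passes screen; has the
#       two-outpatient diabetes claim pattern
#   p8  missing pre-period enrollment month   -> fails enrollment
#   p9  missing post-period month 3, alive    -> fails enrollment
#   p10 pre-period hypertension claim         -> excluded
#   p11 pre-period type-1-diabetes claim only -> retained
# Hand-counted attrition: candidates 11 -> monotherapy 8 -> new-user 7 ->
# enrolled 5 -> not excluded 4 (final p1, p2, p7, p11).
toy_bundle <- function() {
  idx <- 100L  # index day for everyone (October 2008, month 9)
  birth <- idx - as.integer(ceiling(30 * 365.25)) - 50L
  ids <- 1:11
  persons <- data.frame(
    person_id = ids, birth_day = birth,
    sex = rep(c("male", "female"), length.out = 11),
    race = "white", state = "CA", payer = "dual",
    smi_dx = "schizophrenia",
    death_day = ifelse(ids == 2L, idx + 100L, NA_integer_)
  )
  qual <- function(id) data.frame(
    person_id = id, day = c(idx, idx + 30L), drug = "quetiapine",
    days_supply = c(30L, 30L), class = "antipsychotic"
  )
  fills <- rbind(
    qual(1), qual(2),
    data.frame(person_id = 3, day = idx, drug = "quetiapine",
               days_supply = 90L, class = "antipsychotic"),
    data.frame(person_id = 4, day = c(idx, idx + 95L), drug = "quetiapine",
               days_supply = c(15L, 30L), class = "antipsychotic"),
    data.frame(person_id = 5, day = c(idx, idx + 30L), drug = "quetiapine",
               days_supply = c(15L, 15L), class = "antipsychotic"),
    qual(6),
    data.frame(person_id = 6, day = idx - 30L, drug = "haloperidol",
               days_supply = 30L, class = "antipsychotic"),
    qual(7),
    # own-drug pre-period fill 95 days before index: allowed by the screen,
    # tallied as exposure, too far back to anchor an earlier window
    data.frame(person_id = 7, day = idx - 95L, drug = "quetiapine",
               days_supply = 28L, class = "antipsychotic"),
    qual(8), qual(9), qual(10), qual(11)
  )
  dx_claims <- rbind(
    data.frame(person_id = 10, day = idx - 50L, setting = "outpatient",
               position = "secondary", code = "HYPERTENSION"),
    data.frame(person_id = 11, day = idx - 50L, setting = "outpatient",
               position = "secondary", code = "T1D"),
    # p7: two outpatient T2D claims 280 days apart inside follow-up
    data.frame(person_id = 7, day = c(idx + 150L, idx + 430L),
               setting = "outpatient", position = c("primary", "secondary"),
               code = "T2D")
  )
  full_months <- seq.int(day_to_month(idx - 182L),
                         day_to_month(study_period()$study_end))
  enr <- function(id, months) data.frame(person_id = id, month = months)
  mi <- day_to_month(idx)
  enrollment <- rbind(
    enr(1, full_months),
    enr(2, seq.int(min(full_months), day_to_month(idx + 100L) - 1L)),
    enr(3, full_months), enr(4, full_months), enr(5, full_months),
    enr(6, full_months), enr(7, full_months),
    enr(8, setdiff(full_months, day_to_month(idx) - 3L)),
    enr(9, setdiff(full_months, mi + 3L)),
    enr(10, full_months), enr(11, full_months)
  )
  structure(
    list(persons = persons, fills = fills, dx_claims = dx_claims,
         enrollment = enrollment, drugs = study_drugs()),
    class = "claims_bundle"
  )
}

# --- brute-force oracles ----------------------------------------------------

# Exhaustive scan over every fill-anchored 90-day window for one person's
# fills of one drug; returns the earliest qualifying anchor or NA.
brute_mono_index <- function(days, supply) {
  for (t in sort(days)) {
    inw <- days >= t & days < t + 90
    if (sum(inw) >= 2 && sum(supply[inw]) >= 31) return(t)
  }
  NA_integer_
}

# All-pairs scan of the two-outpatient diabetes branch: earliest completion
# day over every claim pair less than 365 days apart, or NA.
brute_two_outpatient <- function(days) {
  days <- sort(days)
  best <- Inf
  if (length(days) >= 2) {
    for (i in seq_len(length(days) - 1)) {
      for (j in seq.int(i + 1, length(days))) {
        if (days[j] - days[i] < 365) best <- min(best, days[j])
      }
    }
  }
  if (is.finite(best)) as.integer(best) else NA_integer_
}

# Minimal follow-up frame for outcome tests.
fu_frame <- function(person_id = 1L, start = 0L, end = 1095L) {
  data.frame(person_id = person_id, start = start, end = end)
}

empty_fills <- function() {
  data.frame(person_id = integer(), day = integer(), drug = character(),
             days_supply = integer(), class = character())
}

dx_row <- function(id, day, setting = "outpatient", position = "secondary",
                   code = "T2D") {
  n <- max(length(id), length(day))
  data.frame(person_id = rep_len(id, n), day = rep_len(day, n),
             setting = rep_len(setting, n), position = rep_len(position, n),
             code = rep_len(code, n))
}
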