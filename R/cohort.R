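#' Detect the earliest qualifying monotherapy episode per person
#'
#' A qualifying episode requires at least two fills of the same index drug
#' inside a 90-day window anchored at a fill of that drug, with summed days
#' supply inside the window of at least 31 days.  Windows are half-open
#' `[t, t + 90)` and must start at some fill day; the episode's index day is
#' the anchor fill of the earliest qualifying window, i.e. the date of the
#' first fill of the episode.
#'
#' @param fills fills table (`person_id`, `day`, `drug`, `days_supply`,
#'   `class`).
#' @param drug the index drug label to scan for.
#' @return data.frame of episodes: `person_id`, `drug`, `index_day`,
#'   `window_fills`, `window_supply` (one row per qualifying person).
#' @export
detect_monotherapy <- function(fills, drug) {
  if (any(fills$days_supply < 1)) {
    stop("fills with days_supply < 1 are invalid", call. = FALSE)
  }
  f <- fills[fills$class == "antipsychotic" & fills$drug == drug, ,
             drop = FALSE]
  if (!nrow(f)) {
    return(data.frame(person_id = integer(), drug = character(),
                      index_day = integer(), window_fills = integer(),
                      window_supply = integer()))
  }
  f <- f[order(f$person_id, f$day), ]
  out <- lapply(split(f, f$person_id), function(pf) {
    days <- pf$day
    sup <- pf$days_supply
    for (k in seq_along(days)) {
      inw <- days >= days[k] & days < days[k] + .MONO_WINDOW_DAYS
      if (sum(inw) >= 2L && sum(sup[inw]) >= 31L) {
        return(data.frame(person_id = pf$person_id[1], drug = drug,
                          index_day = days[k],
                          window_fills = sum(inw),
                          window_supply = sum(sup[inw])))
      }
    }
    NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(person_id = integer(), drug = character(),
                      index_day = integer(), window_fills = integer(),
                      window_supply = integer())
  }
  rownames(out) <- NULL
  out
}

#' Screen episodes for relatively-new antipsychotic use
#'
#' An episode passes when the 183-day pre-period `[index - 183, index)`
#' contains no antipsychotic fill for a drug other than the index drug.
#' Fills of the index drug itself are permitted (their days supply is later
#' tallied as the pre-period exposure confounder).
#'
#' @param fills fills table.
#' @param episodes episode data.frame from [detect_monotherapy()].
#' @return logical vector, one element per episode row.
#' @export
screen_new_user <- function(fills, episodes) {
  ap <- fills[fills$class == "antipsychotic", , drop = FALSE]
  vapply(seq_len(nrow(episodes)), function(i) {
    e <- episodes[i, ]
    pre <- ap[ap$person_id == e$person_id &
                ap$day > e$index_day - .PRE_PERIOD_DAYS &
                ap$day < e$index_day, , drop = FALSE]
    !any(pre$drug != e$drug)
  }, TRUE)
}

# Months covered per person as a named list of integer sets.
covered_months <- function(enrollment) {
  split(enrollment$month, enrollment$person_id)
}

all_covered <- function(months, from, to) {
  if (to < from) return(TRUE)
  all(seq.int(from, to) %in% months)
}

#' Enrollment continuity filters
#'
#' Requires continuous month-level coverage over the pre-period (every month
#' from the month containing `index - 183` through the index month) and over
#' the 6 post-period months, the latter waived for persons who die in the
#' post-period while continuously enrolled up to the month before the month
#' of death.
#'
#' @param episodes episode data.frame (`person_id`, `index_day`).
#' @param enrollment enrollment table (`person_id`, `month`).
#' @param persons person table carrying `death_day` (NA if alive).
#' @return logical vector, one element per episode row.
#' @export
apply_enrollment_filters <- function(episodes, enrollment, persons) {
  cm <- covered_months(enrollment)
  dd <- setNames(persons$death_day, persons$person_id)
  vapply(seq_len(nrow(episodes)), function(i) {
    e <- episodes[i, ]
    months <- cm[[as.character(e$person_id)]]
    if (is.null(months)) return(FALSE)
    mi <- day_to_month(e$index_day)
    pre_ok <- all_covered(months, day_to_month(e$index_day - .PRE_PERIOD_DAYS + 1L),
                          mi)
    if (!pre_ok) return(FALSE)
    if (all_covered(months, mi + 1L, mi + 6L)) return(TRUE)
    ddi <- dd[[as.character(e$person_id)]]
    if (is.null(ddi) || is.na(ddi) || ddi <= e$index_day) return(FALSE)
    # death in the post-period: coverage must reach the month before the
    # month of death
    all_covered(months, mi + 1L, day_to_month(ddi) - 1L)
  }, TRUE)
}

#' Pre-period condition exclusions
#'
#' A person is excluded when the pre-period contains any diagnosis claim in
#' the configured exclusion code sets (type-2 diabetes, dyslipidemia,
#' hypertension, cardiovascular disease, antidiabetic-managed conditions).
#' Type-1 diabetes codes are deliberately absent from the exclusion sets —
#' they contribute to a health-status confounder instead.  Claim codes not
#' named in any configured set trigger a one-time warning and are treated as
#' non-exclusionary.
#'
#' @param episodes episode data.frame.
#' @param dx_claims diagnosis claims table.
#' @param fills fills table (reserved for configurable fill-based
#'   exclusions; the default configuration defines none).
#' @param codes code configuration.
#' @return logical vector: `TRUE` = retained, `FALSE` = excluded.
#' @export
apply_exclusions <- function(episodes, dx_claims, fills = NULL,
                             codes = default_code_config()) {
  unknown <- setdiff(unique(dx_claims$code), known_codes(codes))
  if (length(unknown)) {
    warning(sprintf("unknown claim code(s) treated as non-exclusionary: %s",
                    paste(sort(unknown), collapse = ", ")), call. = FALSE)
  }
  excl <- dx_claims[dx_claims$code %in% codes$exclusions, , drop = FALSE]
  vapply(seq_len(nrow(episodes)), function(i) {
    e <- episodes[i, ]
    !any(excl$person_id == e$person_id &
           excl$day > e$index_day - .PRE_PERIOD_DAYS &
           excl$day < e$index_day)
  }, TRUE)
}

#' Resolve follow-up and its end reason
#'
#' Follow-up runs from the index day to the earliest of: the 3-year cap
#' (1095 days), the administrative end of the study period (2013-12-31), the
#' day of the 65th birthday, the last covered day before a coverage gap,
#' or the day of death.  The recorded end day is the last day under
#' observation (inclusive).  When several events fall on the same day the
#' reason follows a fixed hierarchy: death, then full 3-year follow-up, then
#' end of study, then turning 65, then coverage loss.
#'
#' @param episodes episode data.frame (`person_id`, `index_day`).
#' @param enrollment enrollment table.
#' @param persons person table with `birth_day` and `death_day`.
#' @param study_end last observable study day (defaults to 2013-12-31).
#' @return data.frame `person_id`, `start`, `end`, `reason`.
#' @export
resolve_followup <- function(episodes, enrollment, persons,
                             study_end = .STUDY_END_DAY) {
  cm <- covered_months(enrollment)
  pp <- persons[match(episodes$person_id, persons$person_id), ]
  out <- lapply(seq_len(nrow(episodes)), function(i) {
    start <- episodes$index_day[i]
    turn65 <- pp$birth_day[i] + as.integer(ceiling(65 * 365.25))
    months <- cm[[as.character(episodes$person_id[i])]]
    horizon <- min(start + .FOLLOWUP_DAYS, study_end)
    # coverage gaps caused by death (months at/after the death month) are not
    # censoring events; only gaps while alive count
    last_m <- day_to_month(horizon)
    if (!is.na(pp$death_day[i])) {
      last_m <- min(last_m, day_to_month(pp$death_day[i]) - 1L)
    }
    cov_loss <- Inf
    m1 <- day_to_month(start) + 1L
    if (last_m >= m1) {
      for (m in seq.int(m1, last_m)) {
        if (!(m %in% months)) { cov_loss <- month_start_day(m) - 1L; break }
      }
    }
    cand <- c(death = if (!is.na(pp$death_day[i])) pp$death_day[i] else Inf,
              three_years = start + .FOLLOWUP_DAYS,
              end_of_study = study_end,
              turned_65 = turn65,
              coverage_loss = cov_loss)
    end <- min(cand)
    reason <- names(cand)[which(cand == end)][1]  # vector order = hierarchy
    if (end <= start) {
      stop(sprintf("follow-up for person %s ends on or before its index day",
                   episodes$person_id[i]), call. = FALSE)
    }
    data.frame(person_id = episodes$person_id[i], start = start,
               end = as.integer(end), reason = reason)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the analytic cohort from a claims bundle
#'
#' Composes the full study-design algebra in fixed stage order — candidate
#' persons with any study-drug fill, monotherapy episode detection (earliest
#' qualifying episode across drugs; persons qualifying for two drugs on the
#' same day are dropped with a logged reason), the relatively-new-user
#' screen, the enrollment continuity filters, the pre-period condition
#' exclusions — then resolves follow-up, ascertains both outcomes, measures
#' the pre-period confounders and attaches subgroup labels and the
#' sensitivity-subcohort flag (age < 45 and zero pre-period index-drug
#' exposure).  Every removed person is attributed to exactly one attrition
#' stage; the stage counts are attached as the `"attrition"` attribute.
#'
#' @param bundle a `claims_bundle`.
#' @param codes code configuration.
#' @param drugs study drug labels to scan (defaults to the bundle's drugs or
#'   the standard six).
#' @return data.frame of analytic rows (one per person) with attributes
#'   `attrition` (named stage counts) and `dropped_ties` (person ids dropped
#'   for same-day episodes on two drugs).  Empty cohorts are returned with a
#'   warning.
#' @export
build_cohort <- function(bundle, codes = default_code_config(),
                         drugs = NULL) {
  drugs <- drugs %||% bundle$drugs %||% study_drugs()
  fills <- bundle$fills[order(bundle$fills$person_id, bundle$fills$day), ,
                        drop = FALSE]
  ap <- fills[fills$class == "antipsychotic" & fills$drug %in% drugs, ,
              drop = FALSE]
  n_candidates <- length(unique(ap$person_id))

  eps <- do.call(rbind, lapply(drugs, function(d) detect_monotherapy(fills, d)))
  dropped_ties <- integer(0)
  if (nrow(eps)) {
    eps <- eps[order(eps$person_id, eps$index_day, match(eps$drug, drugs)), ]
    # earliest index day wins; same-day qualification on two different drugs
    # drops the person (no defensible drug attribution)
    min_day <- stats::ave(eps$index_day, eps$person_id, FUN = min)
    at_min <- eps[eps$index_day == min_day, , drop = FALSE]
    n_at_min <- table(at_min$person_id)
    tied <- names(n_at_min)[n_at_min > 1L]
    if (length(tied)) {
      message(sprintf(
        "dropped %d person(s) qualifying for two index drugs on the same day",
        length(tied)))
      dropped_ties <- tied
      at_min <- at_min[!at_min$person_id %in% tied, , drop = FALSE]
    }
    eps <- at_min[!duplicated(at_min$person_id), , drop = FALSE]
  }
  # accrual window: the index fill must fall in the accrual period
  eps <- eps[eps$index_day >= 0L & eps$index_day <= .ACCRUAL_END_DAY, ,
             drop = FALSE]
  n_mono <- nrow(eps)

  keep <- screen_new_user(fills, eps)
  eps <- eps[keep, , drop = FALSE]
  n_new <- nrow(eps)

  keep <- apply_enrollment_filters(eps, bundle$enrollment, bundle$persons)
  eps <- eps[keep, , drop = FALSE]
  n_enr <- nrow(eps)

  keep <- apply_exclusions(eps, bundle$dx_claims, fills, codes)
  eps <- eps[keep, , drop = FALSE]
  n_excl <- nrow(eps)

  attrition <- c(candidates = n_candidates, monotherapy = n_mono,
                 new_user = n_new, enrolled = n_enr, not_excluded = n_excl,
                 final = n_excl)
  if (!nrow(eps)) {
    warning("empty cohort after filtering", call. = FALSE)
    out <- data.frame()
    attr(out, "attrition") <- attrition
    attr(out, "dropped_ties") <- dropped_ties
    return(out)
  }

  fu <- resolve_followup(eps, bundle$enrollment, bundle$persons)
  dia <- ascertain_diabetes(bundle$dx_claims, fills, fu, codes)
  dth <- ascertain_death(
    bundle$persons$death_day[match(fu$person_id, bundle$persons$person_id)],
    fu)

  cov <- make_analytic_covariates(bundle, eps[, c("person_id", "drug",
                                                  "index_day")], codes)
  cov <- cov[match(eps$person_id, cov$person_id), ]

  out <- cov
  lv <- if (all(out$drug %in% study_drugs())) study_drugs() else
    sort(unique(out$drug))
  out$drug <- factor(out$drug, levels = intersect(lv, unique(out$drug)))
  out$fu_start <- fu$start
  out$fu_end <- fu$end
  out$fu_reason <- fu$reason
  out$diabetes <- dia$indicator
  out$death <- dth$indicator
  out$sensitivity_flag <- out$age < 45 & out$pre_expo_days == 0
  rownames(out) <- NULL
  attr(out, "attrition") <- attrition
  attr(out, "dropped_ties") <- dropped_ties
  out
}
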