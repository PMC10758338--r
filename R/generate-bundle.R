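#' Generate a synthetic claims bundle
#'
#' Expresses a sampled cohort as raw claims-style tables.  For every person
#' the generator draws the confounder vector, assigns an index drug from the
#' multinomial-logit model, samples both latent 3-year outcomes, and then
#' emits records that the downstream pipeline can rediscover:
#'
#' * an index fill and (unless suppressed) a second qualifying fill of the
#'   index drug within the 90-day window, totalling at least 31 days supply;
#' * a single pre-period fill of the index drug carrying the pre-period
#'   exposure days, placed at the start of the 183-day pre-period so it can
#'   never anchor an earlier qualifying window;
#' * monthly enrollment from the start of the pre-period through the end of
#'   the study, the month before a coverage gap, or the month of death;
#' * pre-period diagnosis claims encoding the health-status indicators, the
#'   nine utilization counts, metabolic testing, and (for a small random
#'   subset) an exclusionary condition;
#' * post-index claim patterns encoding a positive diabetes outcome through
#'   one of the three ascertainment branches, and a death date for deaths.
#'
#' Outcome evidence is always emitted early enough to fall inside even the
#' shortest possible follow-up (the emitter knows each person's censoring
#' horizon), so the latent outcome equals the claims-ascertained outcome for
#' every person who enters the cohort.  All record suppression flags
#' (monotherapy failure, other-antipsychotic use, exclusionary diagnosis,
#' coverage gap) are drawn independently of covariates, treatment and
#' outcomes: they thin the cohort at random without biasing counterfactual
#' risks.
#'
#' @param config a `dgp_config` whose confounders carry the claims-schema
#'   roles (see [default_dgp_config()]).
#' @param codes a code configuration ([default_code_config()]).
#' @return a `claims_bundle`: list of data.frames `persons`, `fills`,
#'   `dx_claims`, `enrollment`, plus `latent`, the ground-truth table
#'   (assigned drug, index day, latent outcomes, suppression flags) kept for
#'   validation only — the analysis pipeline never reads it.
#' @export
generate_bundle <- function(config, codes = default_code_config()) {
  specs <- config$confounders
  roles <- vapply(specs, `[[`, "", "role")
  need <- c("age", "sex", "payer", "index_year", "state", "race", "smi_dx",
            "pre_exposure")
  missing_roles <- setdiff(need, roles)
  if (length(missing_roles)) {
    stop_config("confounders",
                paste("claims emission needs roles:",
                      paste(missing_roles, collapse = ", ")))
  }
  role1 <- function(r) names(specs)[roles == r][1]
  n <- config$n_persons
  drugs <- config$drugs

  with_seed(config$seed, {
    cov <- sample_covariates(config, n)
    X <- dgp_features(config, cov)
    gp <- assignment_probs(config, X)
    u <- runif(n)
    a_idx <- max.col(u < t(apply(gp, 1, cumsum)), ties.method = "first")
    drug <- drugs[a_idx]
    y_dia <- rbinom(n, 1L, outcome_probs(config, X, drug, "diabetes"))
    y_dth <- rbinom(n, 1L, outcome_probs(config, X, drug, "death"))

    # Index day inside the sampled index year, within the accrual window.
    yr <- as.integer(as.character(cov[[role1("index_year")]]))
    lo <- pmax(0L, date_to_day(as.Date(sprintf("%d-01-01", yr))))
    hi <- pmin(.ACCRUAL_END_DAY, date_to_day(as.Date(sprintf("%d-12-31", yr))))
    index <- lo + floor(runif(n) * (hi - lo + 1L))

    age <- as.integer(cov[[role1("age")]])
    birth <- index - as.integer(ceiling(age * 365.25)) -
      sample(0:175, n, replace = TRUE)
    turn65 <- birth + as.integer(ceiling(65 * 365.25))

    em <- config$emission
    mono_fail <- rbinom(n, 1L, em$p_mono_fail) == 1L
    other_ap <- rbinom(n, 1L, em$p_other_ap) == 1L
    excl <- rbinom(n, 1L, em$p_excl) == 1L
    cov_gap <- rbinom(n, 1L, em$p_cov_gap) == 1L

    gap_month <- ifelse(cov_gap,
                        day_to_month(index) + sample(7:18, n, replace = TRUE),
                        NA_integer_)
    gap_start <- ifelse(cov_gap, month_start_day(ifelse(cov_gap, gap_month, 0L)),
                        .Machine$integer.max)
    censor_excl <- pmin(index + .FOLLOWUP_DAYS, .STUDY_END_DAY + 1L,
                        turn65, gap_start)
    span <- censor_excl - index  # always >= ~182 by construction

    death_day <- rep(NA_integer_, n)
    has_death <- y_dth == 1L
    death_day[has_death] <- index[has_death] + 90L +
      floor(runif(sum(has_death)) * (span[has_death] - 92L))

    ev_max <- pmin(span - 2L, ifelse(has_death, death_day - index - 2L,
                                     .Machine$integer.max))
    has_dia <- y_dia == 1L
    d1 <- rep(NA_integer_, n)
    d1[has_dia] <- 30L + floor(runif(sum(has_dia)) *
                                 pmax(1L, ev_max[has_dia] - 60L))
    branch <- rep(NA_character_, n)
    branch[has_dia] <- sample(names(em$branch_probs), sum(has_dia),
                              replace = TRUE, prob = em$branch_probs)

    persons <- data.frame(
      person_id = seq_len(n),
      birth_day = birth,
      sex = ifelse(cov[[role1("sex")]] == 1, "male", "female"),
      race = as.character(cov[[role1("race")]]),
      state = as.character(cov[[role1("state")]]),
      payer = ifelse(cov[[role1("payer")]] == 1, "dual", "single"),
      smi_dx = as.character(cov[[role1("smi_dx")]]),
      death_day = death_day,
      stringsAsFactors = FALSE
    )

    ## ---- fills ----------------------------------------------------------
    f_id <- list(); f_day <- list(); f_drug <- list(); f_sup <- list()
    f_cls <- list()
    add_fill <- function(id, day, dg, sup, cls) {
      f_id[[length(f_id) + 1L]] <<- id
      f_day[[length(f_day) + 1L]] <<- day
      f_drug[[length(f_drug) + 1L]] <<- dg
      f_sup[[length(f_sup) + 1L]] <<- sup
      f_cls[[length(f_cls) + 1L]] <<- cls
    }
    add_fill(seq_len(n), index, drug,
             sample(20:45, n, replace = TRUE), rep("antipsychotic", n))
    keep2 <- !mono_fail
    add_fill(which(keep2), index[keep2] + sample(25:35, sum(keep2), TRUE),
             drug[keep2], sample(25:40, sum(keep2), TRUE),
             rep("antipsychotic", sum(keep2)))
    pe <- as.integer(cov[[role1("pre_exposure")]])
    haspe <- pe > 0L
    add_fill(which(haspe), index[haspe] - .PRE_PERIOD_DAYS + 1L, drug[haspe],
             pe[haspe], rep("antipsychotic", sum(haspe)))
    if (any(other_ap)) {
      oi <- which(other_ap)
      alt <- vapply(oi, function(i) sample(setdiff(drugs, drug[i]), 1), "")
      add_fill(oi, index[oi] - sample(30:120, length(oi), TRUE), alt,
               rep(30L, length(oi)), rep("antipsychotic", length(oi)))
    }
    rx_names <- names(specs)[roles == "rx_class"]
    for (rx in rx_names) {
      cls <- codes$rx_class[[rx]]
      if (is.null(cls)) stop_config(rx, "no rx_class code configured")
      ri <- which(cov[[rx]] == 1)
      if (length(ri)) {
        add_fill(ri, index[ri] - sample(1:(.PRE_PERIOD_DAYS - 1L), length(ri), TRUE),
                 rep(paste0(cls, "_agent"), length(ri)),
                 rep(30L, length(ri)), rep(cls, length(ri)))
      }
    }
    ci <- which(has_dia & branch == "outpatient_plus_antidiabetic")
    if (length(ci)) {
      add_fill(ci, index[ci] + d1[ci] + 7L,
               rep("oral_antidiabetic_agent", length(ci)),
               rep(30L, length(ci)),
               rep("oral_antidiabetic", length(ci)))
    }
    fills <- data.frame(
      person_id = unlist(f_id), day = as.integer(unlist(f_day)),
      drug = unlist(f_drug), days_supply = as.integer(unlist(f_sup)),
      class = unlist(f_cls), stringsAsFactors = FALSE
    )

    ## ---- diagnosis claims ----------------------------------------------
    c_id <- list(); c_day <- list(); c_set <- list(); c_pos <- list()
    c_code <- list()
    add_dx <- function(id, day, set, pos, code) {
      c_id[[length(c_id) + 1L]] <<- id
      c_day[[length(c_day) + 1L]] <<- day
      c_set[[length(c_set) + 1L]] <<- set
      c_pos[[length(c_pos) + 1L]] <<- pos
      c_code[[length(c_code) + 1L]] <<- code
    }
    hs_names <- names(specs)[roles == "health"]
    for (hs in hs_names) {
      set_codes <- codes$health[[hs]]
      if (is.null(set_codes)) stop_config(hs, "no health code set configured")
      hi2 <- which(cov[[hs]] == 1)
      if (length(hi2)) {
        add_dx(hi2, index[hi2] - sample(1:(.PRE_PERIOD_DAYS - 1L), length(hi2), TRUE),
               rep("outpatient", length(hi2)), rep("secondary", length(hi2)),
               sample(set_codes, length(hi2), replace = TRUE))
      }
    }
    util_names <- names(specs)[roles == "utilization"]
    for (ut in util_names) {
      parts <- strsplit(sub("^util_", "", ut), "_")[[1]]
      code <- codes$util[[parts[1]]]
      setting <- c(inpt = "inpatient", ed = "ed", out = "outpatient")[parts[2]]
      if (is.null(code) || is.na(setting)) {
        stop_config(ut, "utilization name must be util_<psy|inj|oth>_<inpt|ed|out>")
      }
      cnt <- as.integer(cov[[ut]])
      tot <- sum(cnt)
      if (tot) {
        ids <- rep(seq_len(n), cnt)
        add_dx(ids, index[ids] - sample(1:(.PRE_PERIOD_DAYS - 1L), tot, TRUE),
               rep(setting, tot), rep("secondary", tot),
               rep(code, tot))
      }
    }
    mt <- names(specs)[roles == "metab_test"]
    if (length(mt)) {
      mi <- which(cov[[mt[1]]] == 1)
      if (length(mi)) {
        add_dx(mi, index[mi] - sample(1:(.PRE_PERIOD_DAYS - 1L), length(mi), TRUE),
               rep("outpatient", length(mi)), rep("secondary", length(mi)),
               rep(codes$metab_test, length(mi)))
      }
    }
    if (any(excl)) {
      ei <- which(excl)
      add_dx(ei, index[ei] - sample(1:(.PRE_PERIOD_DAYS - 1L), length(ei), TRUE),
             rep("outpatient", length(ei)), rep("secondary", length(ei)),
             sample(codes$exclusions, length(ei), replace = TRUE))
    }
    # diabetes outcome evidence
    bi <- which(has_dia & branch == "inpatient_primary")
    if (length(bi)) {
      add_dx(bi, index[bi] + d1[bi], rep("inpatient", length(bi)),
             rep("primary", length(bi)), rep(codes$t2d, length(bi)))
    }
    bo <- which(has_dia & branch == "two_outpatient_12mo")
    if (length(bo)) {
      add_dx(bo, index[bo] + d1[bo], rep("outpatient", length(bo)),
             sample(c("primary", "secondary"), length(bo), TRUE),
             rep(codes$t2d, length(bo)))
      add_dx(bo, index[bo] + d1[bo] + 30L, rep("outpatient", length(bo)),
             sample(c("primary", "secondary"), length(bo), TRUE),
             rep(codes$t2d, length(bo)))
    }
    if (length(ci)) {
      add_dx(ci, index[ci] + d1[ci], rep("outpatient", length(ci)),
             sample(c("primary", "secondary"), length(ci), TRUE),
             rep(codes$t2d, length(ci)))
    }
    dx_claims <- data.frame(
      person_id = unlist(c_id), day = as.integer(unlist(c_day)),
      setting = unlist(c_set), position = unlist(c_pos),
      code = unlist(c_code), stringsAsFactors = FALSE
    )

    ## ---- enrollment -----------------------------------------------------
    m0 <- day_to_month(index - .PRE_PERIOD_DAYS + 1L)
    m_end <- ifelse(has_death, day_to_month(death_day),
                    ifelse(cov_gap, gap_month - 1L,
                           day_to_month(.STUDY_END_DAY)))
    n_m <- m_end - m0 + 1L
    enrollment <- data.frame(
      person_id = rep(seq_len(n), n_m),
      month = as.integer(unlist(lapply(seq_len(n),
                                       function(i) seq.int(m0[i], m_end[i]))))
    )

    latent <- data.frame(
      person_id = seq_len(n), drug = drug, index_day = as.integer(index),
      diabetes = y_dia, death = y_dth, death_day = death_day,
      mono_fail = mono_fail, other_ap = other_ap, excl = excl,
      cov_gap = cov_gap, stringsAsFactors = FALSE
    )
    latent <- cbind(latent, cov)

    fills <- fills[order(fills$person_id, fills$day), ]
    dx_claims <- dx_claims[order(dx_claims$person_id, dx_claims$day), ]
    rownames(fills) <- rownames(dx_claims) <- NULL

    structure(
      list(persons = persons, fills = fills, dx_claims = dx_claims,
           enrollment = enrollment, latent = latent, drugs = drugs),
      class = "claims_bundle"
    )
  })
}
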