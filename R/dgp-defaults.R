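#' Study drug labels
#'
#' The six antipsychotic monotherapy drugs of the cohort design, with
#' aripiprazole as the active comparator.
#' @return character vector of 6 drug labels.
#' @export
study_drugs <- function() {
  c("quetiapine", "risperidone", "aripiprazole", "olanzapine",
    "ziprasidone", "haloperidol")
}

#' Default synthetic-claims configuration
#'
#' A cohort-like data-generating process for publicly insured adults with
#' serious mental illness (SMI) initiating antipsychotic monotherapy.
#' Marginals follow the cohort description: 52% male, 65% White, 55%
#' schizophrenia, 74% dual coverage, 55% California, 18% with metabolic
#' testing, 81% with some pre-period index-drug exposure (mean 109 days,
#' s.d. 70 among the exposed), ages 18-64.  Treatment assignment is
#' multinomial-logit with intercepts set near the observed drug shares
#' (quetiapine most frequent, haloperidol 6%) and strong channelling of
#' schizophrenia toward haloperidol and away from aripiprazole, plus
#' channelling of cardiometabolic risk factors toward the metabolically safer
#' drugs.  Outcomes are logistic in the confounders with additive per-drug
#' logit effects sized so 3-year diabetes incidence is near 9% and mortality
#' near 5%, with haloperidol and olanzapine carrying lower diabetes risk than
#' aripiprazole and every drug carrying higher mortality risk than
#' aripiprazole.  The nine utilization counts are independent negative
#' binomials (the dependence structure is a free choice; independence is the
#' default and is configurable through `confounders`).
#'
#' @param n_persons cohort size.
#' @param seed generator seed.
#' @param null_effects set every per-drug outcome effect to zero (all true
#'   contrasts are then exactly 0).
#' @param emission overrides for the claims-emission rates (see
#'   [dgp_config()]).
#' @return a `dgp_config`.
#' @export
default_dgp_config <- function(n_persons = 5000, seed = 1L,
                               null_effects = FALSE, emission = list()) {
  drugs <- study_drugs()
  confounders <- list(
    cf_uniform_int("age", 18, 64, role = "age", center = 40, scale = 10),
    cf_bernoulli("male", 0.52, role = "sex"),
    cf_categorical("race", c("white", "black", "latinx", "other"),
                   c(0.65, 0.18, 0.12, 0.05), role = "race"),
    cf_categorical("smi_dx", c("schizophrenia", "bipolar", "mdd"),
                   c(0.55, 0.25, 0.20), role = "smi_dx"),
    cf_categorical("state", c("CA", "GA", "IA", "MS", "OK", "SD", "WV"),
                   c(0.55, 0.12, 0.06, 0.06, 0.09, 0.05, 0.07),
                   role = "state"),
    cf_bernoulli("payer_dual", 0.74, role = "payer"),
    cf_categorical("index_year", as.character(2008:2013),
                   c(0.12, 0.20, 0.20, 0.20, 0.18, 0.10), role = "index_year"),
    cf_bernoulli("hs_chronic", 0.218, role = "health"),
    cf_bernoulli("hs_cardio_risk", 0.15, role = "health"),
    cf_bernoulli("hs_psych", 0.175, role = "health"),
    cf_count("util_psy_inpt", 0.8, size = 1.2, role = "utilization", scale = 2),
    cf_count("util_psy_ed", 0.4, size = 1.2, role = "utilization", scale = 2),
    cf_count("util_psy_out", 4.0, size = 1.5, role = "utilization", scale = 5),
    cf_count("util_inj_inpt", 0.1, size = 1.2, role = "utilization", scale = 2),
    cf_count("util_inj_ed", 0.3, size = 1.2, role = "utilization", scale = 2),
    cf_count("util_inj_out", 0.5, size = 1.5, role = "utilization", scale = 2),
    cf_count("util_oth_inpt", 0.3, size = 1.2, role = "utilization", scale = 2),
    cf_count("util_oth_ed", 0.5, size = 1.2, role = "utilization", scale = 2),
    cf_count("util_oth_out", 3.0, size = 1.5, role = "utilization", scale = 5),
    cf_bernoulli("metab_test", 0.18, role = "metab_test"),
    cf_bernoulli("rx_antidiabetic", 0.05, role = "rx_class"),
    cf_bernoulli("rx_antihtn", 0.10, role = "rx_class"),
    cf_bernoulli("rx_othercm", 0.12, role = "rx_class"),
    cf_exposure_days("pre_expo_days", 0.81, 109, 70)
  )

  coefs <- matrix(0, 6, 0)
  acoef <- function(m, feature, values) {
    m <- cbind(m, setNames(values, NULL))
    colnames(m)[ncol(m)] <- feature
    m
  }
  # order: quetiapine, risperidone, aripiprazole, olanzapine, ziprasidone,
  # haloperidol
  coefs <- acoef(coefs, "smi_dx=bipolar",  c(0.2, -0.2, 0.5, -0.4, 0.0, -1.8))
  coefs <- acoef(coefs, "smi_dx=mdd",      c(0.3, -0.3, 0.6, -0.5, 0.0, -2.0))
  coefs <- acoef(coefs, "hs_cardio_risk",  c(-0.1, 0.0, 0.4, -0.4, 0.3, 0.0))
  coefs <- acoef(coefs, "age",             c(0.05, 0.05, -0.15, 0.05, -0.05, 0.30))
  coefs <- acoef(coefs, "hs_psych",        c(0.2, 0.0, 0.1, 0.3, 0.0, -0.5))
  coefs <- acoef(coefs, "util_psy_inpt",   c(0.0, 0.1, -0.1, 0.15, 0.0, 0.25))
  rownames(coefs) <- drugs
  assignment <- list(
    intercepts = setNames(c(0, -0.075, -0.583, -0.189, -0.735, -0.978),
                          drugs),
    coefs = coefs
  )

  dia_eff <- setNames(c(0.00, -0.07, 0.00, -0.26, 0.00, -0.26), drugs)
  dth_eff <- setNames(c(0.52, 0.28, 0.00, 0.37, 0.33, 0.43), drugs)
  if (null_effects) dia_eff[] <- dth_eff[] <- 0
  outcomes <- list(
    diabetes = list(
      intercept = -2.817,
      coefs = c(age = 0.25, hs_cardio_risk = 0.80, hs_chronic = 0.30,
                rx_othercm = 0.30, metab_test = 0.40, pre_expo_days = 0.30,
                util_oth_out = 0.15, male = -0.10),
      drug_effects = dia_eff
    ),
    death = list(
      intercept = -3.938,
      coefs = c(age = 0.50, hs_chronic = 0.70, male = 0.30,
                util_psy_inpt = 0.15, util_oth_inpt = 0.20,
                `smi_dx=bipolar` = -0.15, `smi_dx=mdd` = -0.10),
      drug_effects = dth_eff
    )
  )

  dgp_config(n_persons, drugs, confounders, assignment, outcomes,
             emission = emission, seed = seed)
}

#' Small all-discrete configuration for estimator simulation studies
#'
#' Three discrete confounders (two binary, one three-level), confounded
#' multinomial-logit assignment, and logistic outcomes.  Because the
#' confounder support has only 12 cells, true counterfactual risks are
#' computable by exact enumeration, which makes this configuration the
#' workhorse for repeated-fit studies (bias, coverage, double robustness).
#' Covariates are `"generic"`: usable with [simulate_analytic()] but not with
#' the claims emitter.
#'
#' @inheritParams default_dgp_config
#' @param confounded if `FALSE`, assignment ignores the covariates
#'   (randomised treatment).
#' @return a `dgp_config`.
#' @export
sim_dgp_config <- function(n_persons = 2000, seed = 1L, null_effects = FALSE,
                           confounded = TRUE) {
  drugs <- study_drugs()
  confounders <- list(
    cf_bernoulli("w1", 0.5),
    cf_bernoulli("w2", 0.3),
    cf_categorical("w3", c("a", "b", "c"), c(0.5, 0.3, 0.2))
  )
  coefs <- matrix(0, 6, 4,
                  dimnames = list(drugs, c("w1", "w2", "w3=b", "w3=c")))
  if (confounded) {
    coefs["haloperidol", ] <- c(0.8, -0.3, 0.2, 0.4)
    coefs["olanzapine", ]  <- c(0.4, -0.2, 0.0, 0.2)
    coefs["aripiprazole", ] <- c(-0.3, 0.5, 0.1, -0.2)
    coefs["quetiapine", ]  <- c(-0.2, 0.3, -0.1, 0.0)
    coefs["ziprasidone", ] <- c(0.1, 0.2, 0.0, -0.1)
  }
  assignment <- list(
    intercepts = setNames(c(0, -0.28, -0.30, -0.50, -0.84, -1.70), drugs),
    coefs = coefs
  )
  dia_eff <- setNames(c(0.00, -0.07, 0.00, -0.26, 0.00, -0.26), drugs)
  dth_eff <- setNames(c(0.52, 0.28, 0.00, 0.37, 0.33, 0.43), drugs)
  if (null_effects) dia_eff[] <- dth_eff[] <- 0
  outcomes <- list(
    diabetes = list(intercept = -2.45,
                    coefs = c(w1 = 0.5, w2 = 0.7, `w3=b` = 0.3, `w3=c` = 0.5),
                    drug_effects = dia_eff),
    death = list(intercept = -3.25,
                 coefs = c(w1 = 0.4, w2 = 0.6, `w3=b` = 0.2, `w3=c` = 0.4),
                 drug_effects = dth_eff)
  )
  dgp_config(n_persons, drugs, confounders, assignment, outcomes, seed = seed)
}

#' Standard confounder columns of an analytic cohort row
#'
#' The column names of the full adjustment set measured by
#' [make_analytic_covariates()]: demographics, payer, index year, the three
#' health-status indicators, the nine utilization counts, metabolic testing,
#' the cardiometabolic pharmacy classes, and pre-period index-drug exposure
#' days.
#' @return character vector of column names.
#' @export
cohort_confounders <- function() {
  c("age", "male", "race", "smi_dx", "state", "payer_dual", "index_year",
    "hs_chronic", "hs_cardio_risk", "hs_psych",
    "util_psy_inpt", "util_psy_ed", "util_psy_out",
    "util_inj_inpt", "util_inj_ed", "util_inj_out",
    "util_oth_inpt", "util_oth_ed", "util_oth_out",
    "metab_test", "rx_antidiabetic", "rx_antihtn", "rx_othercm",
    "pre_expo_days")
}

#' Simulate an analytic table directly from the DGP
#'
#' Draws covariates, treatment and both latent 3-year outcomes without going
#' through claims emission — the fast path for repeated estimator fits.  The
#' returned table has the same covariate, treatment and outcome columns an
#' analytic cohort row carries (claims-derived columns such as follow-up are
#' absent).
#'
#' @param config a `dgp_config`.
#' @param n rows to draw (defaults to `config$n_persons`).
#' @param seed overrides `config$seed` when given.
#' @return data.frame with `person_id`, the confounder columns, `drug`
#'   (factor over the six study drugs), `diabetes`, `death`, and a
#'   `sensitivity_flag` when age and pre-period exposure are among the
#'   confounders.
#' @export
simulate_analytic <- function(config, n = config$n_persons,
                              seed = config$seed) {
  with_seed(seed, {
    cov <- sample_covariates(config, n)
    X <- dgp_features(config, cov)
    gp <- assignment_probs(config, X)
    u <- runif(n)
    cum <- t(apply(gp, 1, cumsum))
    a_idx <- max.col(u < cum, ties.method = "first")
    drug <- factor(config$drugs[a_idx], levels = config$drugs)
    out <- data.frame(person_id = seq_len(n), cov, check.names = FALSE)
    out$drug <- drug
    for (oc in names(config$outcomes)) {
      p <- outcome_probs(config, X, as.character(drug), oc)
      out[[oc]] <- rbinom(n, 1L, p)
    }
    if (all(c("age", "pre_expo_days") %in% names(cov))) {
      out$sensitivity_flag <- out$age < 45 & out$pre_expo_days == 0
    }
    out
  })
}
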