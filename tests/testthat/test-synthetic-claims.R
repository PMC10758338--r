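test_that("configuration validation names the offending field", {
  expect_error(cf_bernoulli("x", 1.5), "x")
  expect_error(cf_categorical("g", c("a", "b"), c(0.6, 0.6)), "g")
  expect_error(
    dgp_config(100, study_drugs()[1:5], list(cf_bernoulli("w", 0.5)),
               list(), list()),
    "drugs")
  cfg <- one_binary_config()
  expect_error(true_psi(cfg, "cancer"), "unknown outcome")
})

test_that("the generator is deterministic given config and seed", {
  cfg <- default_dgp_config(n_persons = 150, seed = 9)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1, b2)
  b3 <- generate_bundle(default_dgp_config(n_persons = 150, seed = 10))
  expect_false(identical(b1$fills, b3$fills))
})

test_that("null per-drug effects make all true contrasts zero", {
  cfg <- default_dgp_config(n_persons = 100, seed = 2, null_effects = TRUE)
  for (oc in c("diabetes", "death")) {
    tt <- true_psi(cfg, oc, mc_n = 5000)
    expect_equal(tt$contrast, rep(0, 6))
    expect_equal(length(unique(tt$risk)), 1L)
  }
})

test_that("true risk with one Bernoulli confounder equals the two-point average", {
  cfg <- one_binary_config()
  tt <- true_psi(cfg, "diabetes", method = "enumerate")
  # hand-computable closed form: average of the two logistic values
  hand <- function(eff) 0.5 * plogis(-2 + eff) + 0.5 * plogis(-2 + 1 + eff)
  expect_equal(tt$risk[tt$drug == "aripiprazole"], hand(0), tolerance = 1e-12)
  expect_equal(tt$risk[tt$drug == "olanzapine"], hand(-0.5), tolerance = 1e-12)
  expect_equal(tt$contrast[tt$drug == "aripiprazole"], 0)
  expect_true(all(tt$risk >= 0 & tt$risk <= 1))
})

test_that("Monte-Carlo truth agrees with enumeration on discrete configs", {
  cfg <- sim_dgp_config(seed = 5)
  for (oc in c("diabetes", "death")) {
    te <- true_psi(cfg, oc, method = "enumerate")
    tm <- true_psi(cfg, oc, method = "mc", mc_n = 50000, seed = 123)
    expect_true(all(abs(te$risk - tm$risk) < 3 * tm$mc_se + 1e-12))
  }
})

test_that("exact enumeration refuses non-discrete confounders", {
  cfg <- default_dgp_config(n_persons = 100)
  expect_error(true_psi(cfg, "diabetes", method = "enumerate"),
               "enumer")
})

test_that("empirical outcome rate matches the enumerated factual rate", {
  cfg <- one_binary_config(n = 2000, seed = 31)
  d <- simulate_analytic(cfg)
  # analytic factual rate: E_w[ sum_a g(a|w) p(y|a,w) ] over the two cells
  X <- dgp_features(cfg, data.frame(w = c(0, 1)))
  g <- assignment_probs(cfg, X)
  p <- vapply(cfg$drugs, function(a) outcome_probs(cfg, X, a, "diabetes"),
              numeric(2))
  rate <- mean(rowSums(g * p))  # w is Bernoulli(0.5): equal cell weights
  mc_se <- sqrt(rate * (1 - rate) / nrow(d))
  expect_lt(abs(mean(d$diabetes) - rate), 3 * mc_se)
})

test_that("measured covariates equal an independent recount of raw claims", {
  cfg <- default_dgp_config(n_persons = 250, seed = 77)
  b <- generate_bundle(cfg)
  idx <- b$latent[, c("person_id", "drug", "index_day")]
  cov <- make_analytic_covariates(b, idx)
  lat <- b$latent[match(cov$person_id, b$latent$person_id), ]

  # generator-recovery: every measured confounder equals its latent value
  for (cl in c("age", "male", "payer_dual", "hs_chronic", "hs_cardio_risk",
               "hs_psych", "metab_test", "rx_antidiabetic", "rx_antihtn",
               "rx_othercm", "pre_expo_days", "util_psy_inpt", "util_psy_ed",
               "util_psy_out", "util_inj_inpt", "util_inj_ed", "util_inj_out",
               "util_oth_inpt", "util_oth_ed", "util_oth_out")) {
    expect_equal(as.numeric(cov[[cl]]), as.numeric(lat[[cl]]), label = cl)
  }
  expect_equal(as.character(cov$race), as.character(lat$race))
  expect_equal(as.character(cov$index_year), as.character(lat$index_year))

  # independent recount with plain subsetting, no package counting code
  for (i in sample(nrow(cov), 25)) {
    pid <- cov$person_id[i]
    t0 <- cov$index_day[i]
    pre <- b$dx_claims[b$dx_claims$person_id == pid &
                         b$dx_claims$day > t0 - 183 &
                         b$dx_claims$day < t0, ]
    expect_equal(cov$util_psy_ed[i],
                 sum(pre$code == "UTIL_PSY" & pre$setting == "ed"))
    expect_equal(cov$util_oth_out[i],
                 sum(pre$code == "UTIL_OTH" & pre$setting == "outpatient"))
    expect_equal(cov$metab_test[i],
                 as.integer(any(pre$code == "METAB_TEST")))
  }
})

test_that("post-index records never leak into measured confounders", {
  cfg <- default_dgp_config(n_persons = 120, seed = 13)
  b <- generate_bundle(cfg)
  idx <- b$latent[, c("person_id", "drug", "index_day")]
  base <- make_analytic_covariates(b, idx)
  # plant post-index utilization, health and pharmacy records for everyone
  extra_dx <- data.frame(
    person_id = idx$person_id, day = idx$index_day + 10L,
    setting = "ed", position = "secondary", code = "UTIL_PSY")
  extra_hs <- data.frame(
    person_id = idx$person_id, day = idx$index_day,
    setting = "outpatient", position = "secondary", code = "OBESITY")
  extra_fl <- data.frame(
    person_id = idx$person_id, day = idx$index_day + 5L,
    drug = "antihypertensive_agent", days_supply = 30L,
    class = "antihypertensive")
  b2 <- b
  b2$dx_claims <- rbind(b$dx_claims, extra_dx, extra_hs)
  b2$fills <- rbind(b$fills, extra_fl)
  expect_identical(make_analytic_covariates(b2, idx), base)
})

test_that("bundle round-trips through CSV on disk", {
  cfg <- default_dgp_config(n_persons = 60, seed = 4)
  b <- generate_bundle(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir, config = cfg)
  expect_true(file.exists(file.path(dir, "truth.json")))
  b2 <- read_bundle(dir)
  for (tb in c("persons", "fills", "dx_claims", "enrollment")) {
    expect_equal(as.data.frame(b2[[tb]]), as.data.frame(b[[tb]]),
                 ignore_attr = TRUE)
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$diabetes$contrast$aripiprazole, 0)
})
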