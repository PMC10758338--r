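# A saturated learner over drug-by-covariate cells, used as a cell-mean
# oracle target for the initial outcome regression.
saturated_learner <- function() {
  sl_learner(
    "saturated",
    fit = function(X, y, task) {
      key <- apply(X, 1, paste, collapse = "|")
      vapply(split(y, key), mean, 0)
    },
    predict = function(model, X, task) {
      key <- apply(X, 1, paste, collapse = "|")
      unname(model[key])
    }
  )
}

test_that("with no covariates and marginal propensities, psi equals the arm means", {
  set.seed(20)
  d <- simulate_analytic(sim_dgp_config(n_persons = 1200, seed = 2,
                                        confounded = FALSE))
  fit <- tmle_categorical(d, "diabetes", covariates = character(0),
                          q_library = list(lrn_glm()),
                          g_library = list(lrn_mean()), seed = 5)
  arm_means <- tapply(d$diabetes, d$drug, mean)
  expect_equal(unname(fit$psi), as.numeric(arm_means[fit$drugs]),
               tolerance = 1e-10)
})

test_that("a saturated learner reproduces the 12 drug-by-stratum cell means", {
  set.seed(21)
  d <- simulate_analytic(sim_dgp_config(n_persons = 3000, seed = 4))
  qi <- fit_initial(d, "diabetes", covariates = "w1",
                    library = list(saturated_learner()), seed = 1)
  for (a in levels(d$drug)) {
    for (w in 0:1) {
      cell <- d$diabetes[d$drug == a & d$w1 == w]
      if (length(cell)) {
        got <- unique(round(qi$Q0[d$w1 == w, a], 12))
        expect_equal(got, round(min(max(mean(cell), 1e-4), 1 - 1e-4), 12))
      }
    }
  }
})

test_that("initial predictions are invariant to person ordering", {
  d <- simulate_analytic(sim_dgp_config(n_persons = 400, seed = 6))
  qi <- fit_initial(d, "diabetes", covariates = c("w1", "w2", "w3"),
                    library = list(lrn_glm()), seed = 2)
  perm <- sample(nrow(d))
  qi2 <- fit_initial(d[perm, ], "diabetes", covariates = c("w1", "w2", "w3"),
                     library = list(lrn_glm()), seed = 2)
  expect_equal(qi2$Q0, qi$Q0[perm, ], tolerance = 1e-10)
})

test_that("propensity fits recover a known multinomial-logit model cell by cell", {
  cfg <- sim_dgp_config(n_persons = 5000, seed = 8)
  d <- simulate_analytic(cfg)
  gi <- fit_propensity(d, covariates = c("w1", "w2", "w3"),
                       library = list(lrn_glm()), bound = 0.001, seed = 3)
  expect_equal(unname(rowSums(gi$g)), rep(1, nrow(d)), tolerance = 1e-9)
  expect_true(all(gi$g >= 0.001 - 1e-12))
  # truth per covariate cell from the configured assignment model
  cells <- unique(d[, c("w1", "w2", "w3")])
  Xc <- dgp_features(cfg, cells)
  g_true <- assignment_probs(cfg, Xc)
  for (ci in seq_len(nrow(cells))) {
    in_cell <- d$w1 == cells$w1[ci] & d$w2 == cells$w2[ci] &
      d$w3 == cells$w3[ci]
    n_c <- sum(in_cell)
    for (a in cfg$drugs) {
      se <- sqrt(g_true[ci, a] * (1 - g_true[ci, a]) / n_c)
      expect_lt(abs(mean(gi$g[in_cell, a]) - g_true[ci, a]), 4 * se + 0.01)
    }
  }
})

test_that("propensity fitting refuses a missing arm", {
  d <- simulate_analytic(sim_dgp_config(n_persons = 300, seed = 9))
  d2 <- d[d$drug != "haloperidol", ]
  d2$drug <- droplevels(d2$drug)
  d2$drug <- factor(as.character(d2$drug), levels = study_drugs())
  expect_error(fit_propensity(d2, covariates = "w1",
                              library = list(lrn_mean())),
               "haloperidol")
})

test_that("targeting solves the score equation exactly for every arm", {
  d <- simulate_analytic(sim_dgp_config(n_persons = 2000, seed = 10))
  for (oc in c("diabetes", "death")) {
    fit <- tmle_categorical(d, oc, covariates = c("w1", "w2", "w3"),
                            q_library = list(lrn_glm()),
                            g_library = list(lrn_glm()), seed = 4)
    expect_lt(max(abs(colMeans(fit$eic))), 1e-6)
    expect_true(all(fit$psi >= 0 & fit$psi <= 1))
  }
})

test_that("correct initial fit and known propensities are a fixed point", {
  cfg <- sim_dgp_config(n_persons = 20000, seed = 11)
  d <- simulate_analytic(cfg)
  X <- dgp_features(cfg, d[, c("w1", "w2", "w3")])
  Q0 <- vapply(cfg$drugs, function(a) outcome_probs(cfg, X, a, "diabetes"),
               numeric(nrow(d)))
  g <- assignment_probs(cfg, X)
  fit <- tmle_target(Q0, g, d$drug, d$diabetes)
  expect_lt(max(abs(fit$epsilon)), 0.02)
  # targeting noise in each arm is of the order of that arm's influence-curve
  # standard error; the update must stay within a few of them
  se_arm <- apply(fit$eic, 2, sd) / sqrt(fit$n)
  expect_true(all(abs(fit$psi - colMeans(Q0)) < 4 * se_arm))
})

test_that("double robustness: misspecified outcome model, true-form propensities", {
  cfg <- sim_dgp_config(n_persons = 5000, seed = 12)
  d <- simulate_analytic(cfg)
  truth <- true_psi(cfg, "diabetes", method = "enumerate")
  fit <- tmle_categorical(d, "diabetes", covariates = c("w1", "w2", "w3"),
                          q_library = list(lrn_mean()),   # intercept-only
                          g_library = list(lrn_glm()), seed = 6)
  se <- apply(fit$eic, 2, sd) / sqrt(fit$n)
  z <- abs(fit$psi - truth$risk[match(fit$drugs, truth$drug)]) / se
  expect_true(all(z < 4))
})

test_that("randomized no-covariate contrasts match the hand-computed influence curve", {
  set.seed(22)
  d <- simulate_analytic(sim_dgp_config(n_persons = 1500, seed = 13,
                                        confounded = FALSE))
  fit <- tmle_categorical(d, "death", covariates = character(0),
                          q_library = list(lrn_glm()),
                          g_library = list(lrn_mean()), seed = 7)
  cmp <- estimate_contrasts(fit, "aripiprazole")
  arm <- tapply(d$death, d$drug, mean)
  share <- as.numeric(table(d$drug) / nrow(d))
  names(share) <- levels(d$drug)
  expect_equal(cmp$diff, as.numeric(arm[cmp$drug] - arm["aripiprazole"]),
               tolerance = 1e-10)
  # hand-built EIC contrast for one drug pair
  a <- "quetiapine"; c0 <- "aripiprazole"
  di <- (d$drug == a) / share[a] * (d$death - arm[as.character(d$drug)]) -
    (d$drug == c0) / share[c0] * (d$death - arm[as.character(d$drug)])
  se_hand <- sd(di) / sqrt(nrow(d))
  expect_equal(cmp$se[cmp$drug == a], unname(se_hand), tolerance = 1e-6)

  # comparator against itself: zero with a zero-width interval
  self <- cmp[cmp$drug == c0, ]
  expect_equal(self$diff, 0)
  expect_equal(self$se, 0)
  expect_equal(self$lo, self$hi)
})

test_that("relative differences reproduce the published arithmetic", {
  expect_equal(relative_difference(1.9, 10.2), 18.6)
  expect_equal(relative_difference(0.5, 10.2), 4.9)
  expect_equal(relative_difference(1.1, 3.4), 32.4)
  expect_equal(relative_difference(2.2, 3.4), 64.7)
  expect_equal(relative_difference(0, 5), 0)
  expect_error(relative_difference(1, 0), "positive")
})

test_that("propensity truncation renormalizes onto the simplex above the bound", {
  g <- matrix(c(0.996, 0.001, 0.001, 0.0005, 0.0005, 0.001,
                rep(1 / 6, 6)), 2, 6, byrow = TRUE,
              dimnames = list(NULL, study_drugs()))
  tg <- truncate_propensity(g, 0.005)
  expect_equal(unname(rowSums(tg)), c(1, 1), tolerance = 1e-12)
  expect_true(all(tg >= 0.005 - 1e-12))
  expect_equal(unname(tg[2, ]), rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("degenerate outcomes are rejected", {
  d <- simulate_analytic(sim_dgp_config(n_persons = 200, seed = 14))
  d$diabetes <- 0L
  expect_error(fit_initial(d, "diabetes", covariates = "w1",
                           library = list(lrn_glm())),
               "degenerate")
})
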