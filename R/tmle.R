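#' Design-matrix builder with stable factor handling
#'
#' Records factor levels at construction and encodes new rows with the same
#' dummy columns; unseen levels are mapped to the reference level with a
#' warning so prediction never fails on a category absent from training.
#'
#' @param data data.frame of model covariates.
#' @param columns character vector of covariate columns.
#' @return a function `f(newdata)` returning the numeric design matrix
#'   (no intercept column).
#' @keywords internal
design_builder <- function(data, columns) {
  stopifnot(all(columns %in% names(data)))
  if (!length(columns)) {
    return(function(newdata) matrix(numeric(0), nrow(newdata), 0))
  }
  df <- data[columns]
  for (cl in columns) if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  lvls <- lapply(df, function(x) if (is.factor(x)) levels(x))
  function(newdata) {
    nd <- newdata[columns]
    for (cl in columns) {
      if (!is.null(lvls[[cl]])) {
        x <- as.character(nd[[cl]])
        bad <- !(x %in% lvls[[cl]]) & !is.na(x)
        if (any(bad)) {
          warning(sprintf(
            "column '%s': %d value(s) at unseen level(s) mapped to '%s'",
            cl, sum(bad), lvls[[cl]][1]), call. = FALSE)
          x[bad] <- lvls[[cl]][1]
        }
        nd[[cl]] <- factor(x, levels = lvls[[cl]])
      } else {
        nd[[cl]] <- as.numeric(nd[[cl]])
      }
    }
    as.matrix(one_hot_first(nd))
  }
}

# Dummy-code every factor against its first (reference) level; numeric
# columns pass through.  Shared by fit and predict so columns always align.
one_hot_first <- function(df) {
  out <- list()
  for (cl in names(df)) {
    x <- df[[cl]]
    if (is.factor(x)) {
      lv <- levels(x)
      for (l in lv[-1]) out[[paste0(cl, "=", l)]] <- as.numeric(x == l)
    } else {
      out[[cl]] <- as.numeric(x)
    }
  }
  as.data.frame(out, optional = TRUE, check.names = FALSE)
}

#' Initial outcome regression for every counterfactual treatment
#'
#' Fits a super learner for `P(Y = 1 | A, W)` with the treatment entered as a
#' categorical covariate, then predicts for every person with the treatment
#' column deterministically set to each drug in turn.  Predictions are clipped
#' to `[1e-4, 1 - 1e-4]` so the logit fluctuation step is well defined.
#'
#' @param data cohort data.frame.
#' @param outcome name of the 0/1 outcome column.
#' @param treatment name of the treatment factor column.
#' @param covariates confounder column names.
#' @param library learner library for the binary task.
#' @param k,seed folds and seed passed to [super_learner()].
#' @return list with `Q0` (n-by-drugs matrix of counterfactual predictions),
#'   `fit` (the `superlearner_fit`) and `predict_q(newdata, drug)`.
#' @export
fit_initial <- function(data, outcome, treatment = "drug", covariates,
                        library = list(lrn_glm()), k = 10, seed = NULL) {
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop(sprintf("outcome '%s' is degenerate (all %d)", outcome, y[1]),
         call. = FALSE)
  }
  a <- data[[treatment]]
  if (!is.factor(a)) a <- factor(a)
  drugs <- levels(a)
  dat <- data
  dat[[treatment]] <- a
  build <- design_builder(dat, c(treatment, covariates))
  X <- build(dat)
  fit <- super_learner(X, y, "binary_outcome", library, k = k, seed = seed)

  predict_q <- function(newdata, drug) {
    nd <- newdata
    nd[[treatment]] <- factor(drug, levels = drugs)
    clip_prob(predict(fit, build(nd)), 1e-4)
  }
  Q0 <- vapply(drugs, function(d) predict_q(data, d), numeric(nrow(data)))
  colnames(Q0) <- drugs
  list(Q0 = Q0, fit = fit, predict_q = predict_q, drugs = drugs)
}

#' Multinomial propensity model with positivity truncation
#'
#' Super-learner estimate of `g(a | W)`, truncated below at `bound` and
#' renormalised (iterated until every entry respects the bound after
#' renormalisation, which protects rare arms against extreme inverse weights).
#'
#' @param data cohort data.frame.
#' @param treatment treatment factor column.
#' @param covariates confounder column names.
#' @param library learner library for the multiclass task.
#' @param bound lower truncation bound on each treatment probability.
#' @param k,seed folds and seed passed to [super_learner()].
#' @return list with `g` (row-stochastic n-by-drugs matrix), `fit`, `bound`.
#' @export
fit_propensity <- function(data, treatment = "drug", covariates,
                           library = list(lrn_glm()), bound = 0.005,
                           k = 10, seed = NULL) {
  a <- data[[treatment]]
  if (!is.factor(a)) a <- factor(a)
  tab <- table(a)
  if (any(tab < 2)) {
    stop(sprintf("treatment level(s) with < 2 observations: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")), call. = FALSE)
  }
  build <- design_builder(data, covariates)
  X <- build(data)
  fit <- super_learner(X, a, "multiclass_treatment", library, k = k,
                       seed = seed)
  g <- predict(fit, X)[, levels(a), drop = FALSE]
  g <- truncate_propensity(g, bound)
  list(g = g, fit = fit, bound = bound, build = build)
}

#' @rdname fit_propensity
#' @param g row-stochastic matrix of treatment probabilities.
#' @export
truncate_propensity <- function(g, bound) {
  if (bound <= 0) return(g / rowSums(g))
  if (bound * ncol(g) >= 1) stop("bound too large for the number of arms",
                                 call. = FALSE)
  for (i in seq_len(50)) {
    g <- pmax(g, bound)
    g <- g / rowSums(g)
    if (all(g >= bound - 1e-12)) break
  }
  pmax(g, bound)
}

# One-parameter logistic fluctuation for a single treatment level: maximum
# likelihood for epsilon in expit(logit(Q0) + eps * H) on the rows actually
# treated with that level, H = 1/g.  The score is monotone in eps, so a root
# bracket plus Newton polish solves it to machine precision.
solve_fluctuation <- function(off, H, y) {
  score <- function(eps) sum(H * (y - plogis(off + eps * H)))
  s0 <- score(0)
  if (abs(s0) < 1e-14) return(0)
  eps <- tryCatch(
    uniroot(score, lower = -20, upper = 20, extendInt = "downX",
            tol = 1e-12)$root,
    error = function(e) {
      # Degenerate arm (e.g. all events); take the boundary that flattens
      # the score.
      if (s0 > 0) 20 else -20
    }
  )
  for (i in 1:4) {  # Newton polish: drive the score to ~0 exactly
    p <- plogis(off + eps * H)
    d <- sum(H^2 * p * (1 - p))
    if (d <= 0) break
    eps <- eps + score(eps) / d
  }
  eps
}

#' Targeting step of the categorical-treatment TMLE
#'
#' For each treatment level `a`, fluctuates the initial predictions along the
#' clever covariate `H_a(A, W) = 1\{A = a\} / g(a | W)`: epsilon is the MLE of
#' the one-parameter logistic submodel with offset `logit Q0(a, W)` and
#' covariate `1/g(a | W)`, fit on the rows with `A = a`.  The targeted
#' prediction is `Q*(a, W) = expit(logit Q0(a, W) + eps_a / g(a | W))`, the
#' counterfactual risk is the plug-in mean `psi_a = mean Q*(a, W)`, and the
#' per-person efficient influence curve is
#' `D*_a = H_a (Y - Q*(A, W)) + Q*(a, W) - psi_a`.  Because epsilon solves
#' the fluctuation score exactly, `mean(D*_a)` is numerically zero for every
#' level.
#'
#' @param Q0 n-by-drugs matrix of initial predictions (from [fit_initial()]).
#' @param g n-by-drugs propensity matrix (from [fit_propensity()]).
#' @param A observed treatment factor.
#' @param Y observed 0/1 outcome.
#' @param outcome label stored on the fit (for reporting).
#' @return a `tmle_fit`: `psi`, `epsilon`, `qstar`, `q0`, `g`, `eic`
#'   (n-by-drugs), `A`, `Y`, `n`, `drugs`, `outcome`.
#' @export
tmle_target <- function(Q0, g, A, Y, outcome = "outcome") {
  drugs <- colnames(Q0)
  stopifnot(identical(colnames(g), drugs), nrow(Q0) == length(Y),
            nrow(g) == length(Y))
  A <- factor(A, levels = drugs)
  n <- length(Y)
  eps <- setNames(numeric(length(drugs)), drugs)
  qstar <- Q0
  for (a in drugs) {
    obs <- which(A == a)
    if (!length(obs)) stop(sprintf("no observations with treatment '%s'", a),
                           call. = FALSE)
    eps[a] <- solve_fluctuation(qlogis(Q0[obs, a]), 1 / g[obs, a], Y[obs])
    qstar[, a] <- plogis(qlogis(Q0[, a]) + eps[a] / g[, a])
  }
  psi <- colMeans(qstar)
  q_at_A <- qstar[cbind(seq_len(n), as.integer(A))]
  eic <- matrix(0, n, length(drugs), dimnames = list(NULL, drugs))
  for (a in drugs) {
    Hobs <- as.numeric(A == a) / g[, a]
    eic[, a] <- Hobs * (Y - q_at_A) + qstar[, a] - psi[a]
  }
  structure(
    list(psi = psi, epsilon = eps, qstar = qstar, q0 = Q0, g = g,
         eic = eic, A = A, Y = Y, n = n, drugs = drugs, outcome = outcome),
    class = "tmle_fit"
  )
}

#' Categorical-treatment TMLE of per-drug counterfactual risks
#'
#' End-to-end estimator: super-learner initial outcome regression
#' ([fit_initial()]), super-learner multinomial propensity with truncation
#' ([fit_propensity()]), and per-level logistic fluctuation targeting
#' ([tmle_target()]).  Returns a `tmle_fit` whose plug-in means `psi_a`
#' estimate the outcome risk had everyone initiated drug `a`, with efficient
#' influence curve values for Wald inference.
#'
#' @param data cohort data.frame (one row per person).
#' @param outcome 0/1 outcome column name (`"diabetes"` or `"death"` in the
#'   standard cohort schema).
#' @param treatment treatment factor column.
#' @param covariates confounder column names.
#' @param q_library,g_library learner libraries for the outcome and
#'   propensity tasks.
#' @param g_bound propensity truncation bound.
#' @param k CV folds for both super learners.
#' @param seed integer seed controlling folds and stochastic learners.
#' @return a `tmle_fit` (see [tmle_target()]), with the super-learner fits
#'   attached as `q_fit` and `g_fit`.
#' @export
tmle_categorical <- function(data, outcome, treatment = "drug", covariates,
                             q_library = list(lrn_glm()),
                             g_library = list(lrn_glm()),
                             g_bound = 0.005, k = 10, seed = NULL) {
  seeds <- with_seed(seed, sample.int(2^31 - 2, 2))
  qi <- fit_initial(data, outcome, treatment, covariates,
                    library = q_library, k = k, seed = seeds[1])
  gi <- fit_propensity(data, treatment, covariates,
                       library = g_library, bound = g_bound, k = k,
                       seed = seeds[2])
  fit <- tmle_target(qi$Q0, gi$g[, qi$drugs, drop = FALSE],
                     data[[treatment]], data[[outcome]], outcome = outcome)
  fit$q_fit <- qi$fit
  fit$g_fit <- gi$fit
  fit
}

#' Pairwise risk differences against a comparator drug
#'
#' For each drug `a`, the absolute difference `psi_a - psi_c` with a 95%
#' Wald interval whose standard error is the sample standard deviation of the
#' per-person influence-curve contrast `D*_a - D*_c` divided by `sqrt(n)`.
#' The comparator row is included with a zero difference and zero-width
#' interval.  Positive differences indicate higher risk than the comparator
#' (an advantage for the comparator).
#'
#' @param fit a `tmle_fit`.
#' @param comparator comparator drug label.
#' @return data.frame with columns `drug`, `psi`, `diff`, `se`, `lo`, `hi`.
#' @export
estimate_contrasts <- function(fit, comparator) {
  if (!comparator %in% fit$drugs) {
    stop(sprintf("comparator '%s' not among the treatment levels", comparator),
         call. = FALSE)
  }
  dcon <- fit$eic - fit$eic[, comparator]
  se <- apply(dcon, 2, sd) / sqrt(fit$n)
  se[comparator] <- 0
  diff <- fit$psi - fit$psi[comparator]
  data.frame(
    drug = fit$drugs,
    psi = unname(fit$psi),
    diff = unname(diff),
    se = unname(se[fit$drugs]),
    lo = unname(diff - 1.96 * se[fit$drugs]),
    hi = unname(diff + 1.96 * se[fit$drugs]),
    row.names = NULL
  )
}

#' Relative difference scaled by the comparator's unadjusted rate
#'
#' `100 * abs_diff / comparator_rate`, rounded to one decimal for reporting,
#' with both arguments on the percent scale: an absolute difference of 1.9
#' percentage points against an unadjusted comparator rate of 10.2% is a
#' relative difference of 18.6%.
#'
#' @param abs_diff absolute risk difference in percentage points.
#' @param comparator_rate unadjusted comparator outcome rate in percent
#'   (must be positive).
#' @return relative difference in percent, rounded to one decimal.
#' @export
relative_difference <- function(abs_diff, comparator_rate) {
  if (any(comparator_rate <= 0)) {
    stop("comparator rate must be positive", call. = FALSE)
  }
  round(100 * abs_diff / comparator_rate, 1)
}
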