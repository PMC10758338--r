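#' Confounder specifications for the synthetic-claims generator
#'
#' A data-generating-process (DGP) configuration describes each baseline
#' confounder with a small spec object.  Specs know how to sample values, how
#' to enumerate their support (discrete types only), and how they are encoded
#' as numeric model features: a Bernoulli spec contributes one 0/1 column, a
#' categorical spec contributes one dummy column per non-reference level, and
#' numeric specs contribute one centred/scaled column.
#'
#' @param name column name in the covariate table.
#' @param p success probability (Bernoulli).
#' @param levels,probs category labels and their probabilities.
#' @param mu,size negative-binomial mean and dispersion for utilization-style
#'   counts (`size = Inf` gives a Poisson).
#' @param min,max inclusive integer bounds.
#' @param center,scale affine feature encoding `(x - center) / scale`.
#' @param role how the claims emitter expresses the confounder; `"generic"`
#'   confounders exist only in the analytic table (usable with
#'   [simulate_analytic()] but not [generate_bundle()]).
#' @return a `cf_spec` object.
#' @name cf_spec
NULL

new_cf_spec <- function(name, type, role, params, center = 0, scale = 1) {
  stopifnot(is.character(name), nchar(name) > 0)
  structure(
    list(name = name, type = type, role = role, params = params,
         center = center, scale = scale),
    class = "cf_spec"
  )
}

#' @rdname cf_spec
#' @export
cf_bernoulli <- function(name, p, role = "generic") {
  if (!is.numeric(p) || p < 0 || p > 1) stop_config(name, "p must be in [0,1]")
  new_cf_spec(name, "bernoulli", role, list(p = p))
}

#' @rdname cf_spec
#' @export
cf_categorical <- function(name, levels, probs, role = "generic") {
  if (length(levels) != length(probs)) {
    stop_config(name, "levels and probs differ in length")
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop_config(name, "probs must be nonnegative and sum to 1")
  }
  new_cf_spec(name, "categorical", role,
              list(levels = as.character(levels), probs = probs))
}

#' @rdname cf_spec
#' @export
cf_count <- function(name, mu, size = Inf, role = "generic", scale = 1) {
  if (mu < 0) stop_config(name, "mu must be nonnegative")
  new_cf_spec(name, "count", role, list(mu = mu, size = size), scale = scale)
}

#' @rdname cf_spec
#' @export
cf_uniform_int <- function(name, min, max, role = "generic",
                           center = 0, scale = 1) {
  if (max < min) stop_config(name, "max < min")
  new_cf_spec(name, "uniform_int", role,
              list(min = as.integer(min), max = as.integer(max)),
              center = center, scale = scale)
}

#' @rdname cf_spec
#' @param p_any probability of any exposure; positive exposures are drawn from
#'   a normal rounded and truncated to `[1, max]`.
#' @param mean,sd moments of the positive-exposure distribution (days).
#' @export
cf_exposure_days <- function(name, p_any, mean, sd, max = 180,
                             role = "pre_exposure", scale = 180) {
  if (p_any < 0 || p_any > 1) stop_config(name, "p_any must be in [0,1]")
  new_cf_spec(name, "exposure_days", role,
              list(p_any = p_any, mean = mean, sd = sd, max = as.integer(max)),
              scale = scale)
}

cf_sample <- function(spec, n) {
  p <- spec$params
  switch(spec$type,
    bernoulli = rbinom(n, 1L, p$p),
    categorical = factor(
      sample(p$levels, n, replace = TRUE, prob = p$probs),
      levels = p$levels
    ),
    count = if (is.infinite(p$size)) stats::rpois(n, p$mu)
            else rnbinom(n, mu = p$mu, size = p$size),
    uniform_int = sample(seq.int(p$min, p$max), n, replace = TRUE),
    exposure_days = {
      any_ <- rbinom(n, 1L, p$p_any)
      d <- pmin(p$max, pmax(1L, as.integer(round(rnorm(n, p$mean, p$sd)))))
      any_ * d
    },
    stop_config(spec$name, "unknown spec type")
  )
}

# Support enumeration for discrete specs: data.frame(value, prob).  Counts and
# exposure days have effectively unbounded / very large supports and are not
# enumerable.
cf_enumerable <- function(spec) spec$type %in% c("bernoulli", "categorical", "uniform_int")

cf_enumerate <- function(spec) {
  p <- spec$params
  switch(spec$type,
    bernoulli = data.frame(value = c(0L, 1L), prob = c(1 - p$p, p$p)),
    categorical = data.frame(value = factor(p$levels, levels = p$levels),
                             prob = p$probs),
    uniform_int = {
      v <- seq.int(p$min, p$max)
      data.frame(value = v, prob = rep(1 / length(v), length(v)))
    },
    stop(sprintf("confounder '%s' (%s) has no finite enumerable support",
                 spec$name, spec$type), call. = FALSE)
  )
}

# Feature column names contributed by one spec.
cf_feature_names <- function(spec) {
  if (spec$type == "categorical") {
    lv <- spec$params$levels
    paste0(spec$name, "=", lv[-1])
  } else {
    spec$name
  }
}

# Encode one covariate column as its numeric feature column(s).
cf_encode <- function(spec, x) {
  if (spec$type == "categorical") {
    lv <- spec$params$levels
    m <- vapply(lv[-1], function(l) as.numeric(x == l), numeric(length(x)))
    m <- matrix(m, nrow = length(x),
                dimnames = list(NULL, cf_feature_names(spec)))
    m
  } else {
    matrix((as.numeric(x) - spec$center) / spec$scale,
           ncol = 1, dimnames = list(NULL, spec$name))
  }
}

#' DGP configuration for the synthetic-claims generator
#'
#' Bundles the cohort size, the six study drug labels, the confounder specs,
#' a multinomial-logit treatment-assignment model, logistic outcome models
#' with additive per-drug effects on the logit scale, and the claims-emission
#' rates.  Treatment assignment and outcomes are generated from the same
#' numeric feature encoding (see [cf_spec]), so true counterfactual risks are
#' computable by enumeration or Monte Carlo with [true_psi()].
#'
#' @param n_persons number of persons to generate.
#' @param drugs character vector of exactly six study drug labels.
#' @param confounders list of [cf_spec] objects.
#' @param assignment list with `intercepts` (named by drug) and `coefs`, a
#'   drugs-by-features matrix of multinomial-logit coefficients (features
#'   named as in [dgp_feature_names()]; missing columns are treated as 0).
#' @param outcomes named list (`diabetes`, `death`), each a list with
#'   `intercept`, `coefs` (named feature coefficients) and `drug_effects`
#'   (named by drug, additive logit shifts).
#' @param emission list of claims-emission rates: `p_mono_fail` (second
#'   qualifying fill suppressed), `p_other_ap` (a different antipsychotic
#'   filled in the pre-period), `p_excl` (a pre-period exclusionary diagnosis
#'   emitted), `p_cov_gap` (coverage lost at a random post-period month after
#'   the sixth), and `branch_probs`, the mix of diabetes evidence patterns
#'   (`inpatient_primary`, `two_outpatient_12mo`,
#'   `outpatient_plus_antidiabetic`).  All emission flags are drawn
#'   independently of covariates, treatment and outcomes, so they thin the
#'   cohort at random without biasing counterfactual risks.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return a `dgp_config` object.
#' @seealso [default_dgp_config()], [sim_dgp_config()], [generate_bundle()],
#'   [true_psi()]
#' @export
dgp_config <- function(n_persons, drugs, confounders, assignment, outcomes,
                       emission = list(), seed = 1L) {
  if (length(drugs) != 6L) stop_config("drugs", "exactly 6 drug labels required")
  if (anyDuplicated(drugs)) stop_config("drugs", "drug labels must be unique")
  if (!is.numeric(n_persons) || n_persons < 1) {
    stop_config("n_persons", "must be a positive count")
  }
  if (!length(confounders) || !all(vapply(confounders, inherits, TRUE, "cf_spec"))) {
    stop_config("confounders", "must be a non-empty list of cf_spec objects")
  }
  nm <- vapply(confounders, `[[`, "", "name")
  if (anyDuplicated(nm)) stop_config("confounders", "duplicate confounder names")
  names(confounders) <- nm

  if (is.null(assignment$intercepts)) assignment$intercepts <- setNames(rep(0, 6), drugs)
  assignment$intercepts <- assignment$intercepts[drugs]
  if (anyNA(assignment$intercepts)) {
    stop_config("assignment$intercepts", "must be named by every drug")
  }
  if (is.null(assignment$coefs)) {
    assignment$coefs <- matrix(0, 6, 0, dimnames = list(drugs, NULL))
  }
  if (!all(rownames(assignment$coefs) == drugs)) {
    stop_config("assignment$coefs", "rows must be named by the drugs, in order")
  }

  for (oc in names(outcomes)) {
    o <- outcomes[[oc]]
    if (is.null(o$intercept) || is.null(o$drug_effects)) {
      stop_config(paste0("outcomes$", oc), "needs intercept and drug_effects")
    }
    de <- o$drug_effects[drugs]
    if (anyNA(de)) stop_config(paste0("outcomes$", oc, "$drug_effects"),
                               "must be named by every drug")
    outcomes[[oc]]$drug_effects <- de
    outcomes[[oc]]$coefs <- o$coefs %||% numeric(0)
  }
  if (!all(c("diabetes", "death") %in% names(outcomes))) {
    stop_config("outcomes", "must define both 'diabetes' and 'death'")
  }

  em <- list(p_mono_fail = 0.02, p_other_ap = 0.02, p_excl = 0.02,
             p_cov_gap = 0.01,
             branch_probs = c(inpatient_primary = 0.2,
                              two_outpatient_12mo = 0.6,
                              outpatient_plus_antidiabetic = 0.2))
  em[names(emission)] <- emission
  for (f in c("p_mono_fail", "p_other_ap", "p_excl", "p_cov_gap")) {
    if (em[[f]] < 0 || em[[f]] > 1) stop_config(paste0("emission$", f),
                                                "must be in [0,1]")
  }
  em$branch_probs <- em$branch_probs / sum(em$branch_probs)

  structure(
    list(n_persons = as.integer(n_persons), drugs = drugs,
         confounders = confounders, assignment = assignment,
         outcomes = outcomes, emission = em, seed = as.integer(seed)),
    class = "dgp_config"
  )
}

#' Feature column names of a DGP configuration
#' @param config a `dgp_config`.
#' @return character vector of numeric feature names.
#' @export
dgp_feature_names <- function(config) {
  unlist(lapply(config$confounders, cf_feature_names), use.names = FALSE)
}

#' Sample a covariate table from the configured confounder marginals
#' @param config a `dgp_config`.
#' @param n number of rows (defaults to `config$n_persons`).
#' @return a `data.frame` with one column per confounder.
#' @keywords internal
sample_covariates <- function(config, n = config$n_persons) {
  as.data.frame(lapply(config$confounders, cf_sample, n = n),
                optional = TRUE, col.names = names(config$confounders))
}

#' Encode a covariate table as the DGP's numeric feature matrix
#' @param config a `dgp_config`.
#' @param cov covariate `data.frame` with the confounder columns.
#' @return numeric matrix with columns [dgp_feature_names()].
#' @export
dgp_features <- function(config, cov) {
  mats <- lapply(config$confounders, function(sp) cf_encode(sp, cov[[sp$name]]))
  do.call(cbind, mats)
}

# Align a possibly partial named coefficient vector / matrix onto the full
# feature set, filling absent features with 0.
align_coefs <- function(coefs, feat_names) {
  out <- setNames(rep(0, length(feat_names)), feat_names)
  if (length(coefs)) {
    bad <- setdiff(names(coefs), feat_names)
    if (length(bad)) stop_config("coefs", paste("unknown features:",
                                                paste(bad, collapse = ", ")))
    out[names(coefs)] <- coefs
  }
  out
}

#' Multinomial-logit treatment-assignment probabilities
#' @param config a `dgp_config`.
#' @param X feature matrix from [dgp_features()].
#' @return matrix of assignment probabilities, one column per drug.
#' @export
assignment_probs <- function(config, X) {
  fn <- colnames(X)
  K <- length(config$drugs)
  lp <- matrix(rep(config$assignment$intercepts, each = nrow(X)), ncol = K)
  B <- config$assignment$coefs
  if (ncol(B)) {
    use <- intersect(colnames(B), fn)
    lp <- lp + X[, use, drop = FALSE] %*% t(B[, use, drop = FALSE])
  }
  lp <- lp - apply(lp, 1, max)
  e <- exp(lp)
  p <- e / rowSums(e)
  colnames(p) <- config$drugs
  p
}

#' Conditional outcome probability under an assigned drug
#' @param config a `dgp_config`.
#' @param X feature matrix from [dgp_features()].
#' @param drug drug label (scalar or one per row).
#' @param outcome `"diabetes"` or `"death"`.
#' @return vector of outcome probabilities.
#' @export
outcome_probs <- function(config, X, drug, outcome) {
  o <- config$outcomes[[outcome]]
  if (is.null(o)) stop_config("outcome", paste("unknown outcome", outcome))
  beta <- align_coefs(o$coefs, colnames(X))
  lp <- o$intercept + drop(X %*% beta) + unname(o$drug_effects[drug])
  # optional feature-by-drug effect modification: a named list mapping a
  # feature to a per-drug vector of additional logit effects
  for (f in names(o$interactions %||% list())) {
    lp <- lp + X[, f] * unname(o$interactions[[f]][drug])
  }
  plogis(lp)
}
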