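#' Cross-validation folds
#'
#' Partitions `1:n` into `k` folds whose sizes differ by at most one.  When
#' `strata` is supplied (e.g. the treatment label for a propensity fit), units
#' are shuffled within stratum and dealt cyclically across folds with a single
#' running pointer, so folds remain globally balanced while every stratum is
#' spread as evenly as possible — protecting rare treatment arms from empty
#' training cells.
#'
#' @param n number of units.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param strata optional vector of stratum labels, length `n`.
#' @return integer vector of fold labels in `1:k`.
#' @export
make_folds <- function(n, k, seed = NULL, strata = NULL) {
  if (k < 2 || k > n) stop("need 2 <= k <= n", call. = FALSE)
  with_seed(seed, {
    folds <- integer(n)
    if (is.null(strata)) {
      folds <- sample(rep_len(seq_len(k), n))
    } else {
      stopifnot(length(strata) == n)
      ptr <- 0L
      for (s in unique(strata)) {
        idx <- sample(which(strata == s))
        folds[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
        ptr <- ptr + length(idx)
      }
    }
    folds
  })
}

# Probability each learner assigns to the observed label; the quantity the
# log-likelihood loss is computed from for both tasks.
prob_of_observed <- function(pred, y, task) {
  if (task == "binary_outcome") {
    ifelse(y == 1, pred, 1 - pred)
  } else {
    pred[cbind(seq_along(y), match(as.character(y), colnames(pred)))]
  }
}

#' Cross-validated risks for a learner library
#'
#' Fits every learner on each training split and scores all rows with the
#' model trained without their fold.  Risk is the mean held-out negative
#' log-likelihood, with predictions clipped to `[1e-6, 1 - 1e-6]` before the
#' log.  A learner that fails on any fold is dropped with a warning and
#' reported with infinite risk rather than aborting the fit.
#'
#' @param library list of [sl_learner] objects.
#' @param X numeric feature matrix.
#' @param y 0/1 vector (binary task) or factor (multiclass task).
#' @param folds fold labels from [make_folds()].
#' @param task `"binary_outcome"` or `"multiclass_treatment"`.
#' @return list with `risks` (named numeric) and `cv_obs_prob`, the n-by-J
#'   matrix of held-out probabilities of the observed label.
#' @export
cv_risks <- function(library, X, y, folds, task = "binary_outcome") {
  n <- length(y)
  J <- length(library)
  nms <- vapply(library, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("learner names must be unique", call. = FALSE)
  P <- matrix(NA_real_, n, J, dimnames = list(NULL, nms))
  for (j in seq_len(J)) {
    lrn <- library[[j]]
    ok <- TRUE
    for (f in sort(unique(folds))) {
      tr <- folds != f
      res <- tryCatch({
        m <- lrn$fit(X[tr, , drop = FALSE], y[tr], task)
        pr <- lrn$predict(m, X[!tr, , drop = FALSE], task)
        prob_of_observed(pr, y[!tr], task)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("learner '%s' failed on fold %d (%s); dropped",
                        lrn$name, f, conditionMessage(res)), call. = FALSE)
        ok <- FALSE
        break
      }
      P[!tr, j] <- res
    }
    if (!ok) P[, j] <- NA_real_
  }
  P <- clip_prob(P, 1e-6)
  risks <- colMeans(-log(P))
  risks[is.na(risks)] <- Inf
  P[is.na(P)] <- 0
  list(risks = risks, cv_obs_prob = P)
}

#' Simplex weights minimising the ensemble negative log-likelihood
#'
#' Solves `min_w -mean(log(P w)) + 1e-8 * ||w||^2` over the probability
#' simplex, where column `j` of `P` holds learner `j`'s held-out probability
#' of the observed label (a mixture likelihood, so the problem is convex).
#' Solved by the mixture EM update `w_j <- w_j * mean(P_j / (P w))` from a
#' uniform start; the tiny L2 penalty makes the solution unique when learners
#' tie (identical columns split their weight equally).  The returned ensemble
#' is never worse than the best single learner: vertex solutions are compared
#' against the EM solution and the better kept.
#'
#' @param P n-by-J matrix of held-out probabilities of the observed label.
#' @param risks optional per-learner risks; infinite-risk learners get weight
#'   zero and are excluded from the program.
#' @return numeric weight vector of length J (nonnegative, sums to 1).
#' @export
solve_weights <- function(P, risks = NULL) {
  J <- ncol(P)
  if (is.null(risks)) risks <- colMeans(-log(clip_prob(P, 1e-6)))
  live <- which(is.finite(risks))
  if (!length(live)) stop("no learner has finite risk", call. = FALSE)
  Pl <- clip_prob(P[, live, drop = FALSE], 1e-6)

  pen_obj <- function(w) -mean(log(drop(Pl %*% w))) + 1e-8 * sum(w^2)

  w <- rep(1 / length(live), length(live))
  obj <- pen_obj(w)
  for (it in seq_len(2000)) {
    mix <- drop(Pl %*% w)
    w_new <- w * colMeans(Pl / mix)
    w_new <- pmax(w_new, 0)
    w_new <- w_new / sum(w_new)
    obj_new <- pen_obj(w_new)
    delta <- max(abs(w_new - w))
    w <- w_new
    obj <- obj_new
    if (delta < 1e-12) break
  }
  # Guard: an ensemble must not lose to any of its vertices.
  for (j in seq_along(live)) {
    v <- numeric(length(live)); v[j] <- 1
    if (pen_obj(v) < obj) { w <- v; obj <- pen_obj(v) }
  }
  out <- numeric(J)
  out[live] <- w
  names(out) <- colnames(P)
  out
}

#' Fit a super learner
#'
#' Cross-validated stacking: every learner in the library is scored by K-fold
#' held-out negative log-likelihood, a simplex weight vector minimising the
#' held-out ensemble risk is solved ([solve_weights()]), and each learner is
#' refit on the full data.  With a single-learner library the CV stage is
#' skipped (the weight is 1 by construction).  Propensity fits
#' (`task = "multiclass_treatment"`) stratify folds by treatment.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 vector or factor, per task.
#' @param task `"binary_outcome"` or `"multiclass_treatment"`.
#' @param library list of [sl_learner] objects.
#' @param k number of CV folds.
#' @param seed seed for the fold draw (and any stochastic learners).
#' @return a `superlearner_fit` with elements `weights`, `risks`,
#'   `ensemble_risk`, `models`, `folds`, `levels`, `task`.
#' @export
super_learner <- function(X, y, task = "binary_outcome",
                          library = default_library(task), k = 10,
                          seed = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (task == "multiclass_treatment" && !is.factor(y)) y <- factor(y)
  nms <- vapply(library, `[[`, "", "name")

  fit <- with_seed(seed, {
    if (length(library) == 1L) {
      weights <- setNames(1, nms)
      risks <- setNames(NA_real_, nms)
      folds <- NULL
      ens_risk <- NA_real_
    } else {
      folds <- make_folds(length(y), k, seed = NULL,
                          strata = if (task == "multiclass_treatment") y)
      cv <- cv_risks(library, X, y, folds, task)
      risks <- cv$risks
      weights <- solve_weights(cv$cv_obs_prob, risks)
      keep <- weights > 0
      mix <- drop(cv$cv_obs_prob[, keep, drop = FALSE] %*% weights[keep])
      ens_risk <- mean(-log(clip_prob(mix, 1e-6)))
    }
    models <- vector("list", length(library))
    for (j in seq_along(library)) {
      if (weights[j] > 0 || length(library) == 1L) {
        models[[j]] <- library[[j]]$fit(X, y, task)
      }
    }
    list(weights = weights, risks = risks, ensemble_risk = ens_risk,
         models = models, folds = folds)
  })

  structure(
    c(fit, list(library = library, task = task,
                levels = if (is.factor(y)) levels(y),
                feature_names = colnames(X))),
    class = "superlearner_fit"
  )
}

#' Predict from a super learner fit
#'
#' @param object a `superlearner_fit`.
#' @param X numeric feature matrix with the training columns.
#' @param ... unused.
#' @return probability vector (binary task) or row-stochastic matrix over the
#'   treatment levels (multiclass task).
#' @export
predict.superlearner_fit <- function(object, X, ...) {
  stopifnot(is.matrix(X))
  if (!is.null(object$feature_names)) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  w <- object$weights
  if (object$task == "binary_outcome") {
    out <- numeric(nrow(X))
    for (j in which(w > 0)) {
      out <- out + w[j] *
        object$library[[j]]$predict(object$models[[j]], X, object$task)
    }
    pmin(pmax(out, 0), 1)
  } else {
    lv <- object$levels
    out <- matrix(0, nrow(X), length(lv), dimnames = list(NULL, lv))
    for (j in which(w > 0)) {
      p <- object$library[[j]]$predict(object$models[[j]], X, object$task)
      out <- out + w[j] * p[, lv, drop = FALSE]
    }
    out / rowSums(out)
  }
}
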