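#' Per-drug contrasts averaged over an arbitrary person subset
#'
#' The workhorse behind overall, subgroup and sensitivity effect rows.  The
#' point estimate for drug `a` in subset `S` averages the targeted predicted
#' differences over the members of `S`:
#' `mean_{i in S}(Q*(a, W_i) - Q*(c, W_i))`; the standard error is the
#' standard deviation over `S` of the per-person influence-curve contrast
#' `D*_a - D*_c`, divided by `sqrt(|S|)` (the subset is treated as fixed).
#' With `S` equal to the whole cohort this reproduces
#' [estimate_contrasts()] exactly.
#'
#' @param fit a `tmle_fit`.
#' @param comparator comparator drug label.
#' @param subset integer or logical index of cohort rows (default: all).
#' @param population label stored on the rows.
#' @return data.frame `population`, `drug`, `n`, `diff`, `se`, `lo`, `hi`.
#' @export
effect_rows <- function(fit, comparator, subset = NULL,
                        population = "overall") {
  if (!comparator %in% fit$drugs) {
    stop(sprintf("comparator '%s' not among the treatment levels",
                 comparator), call. = FALSE)
  }
  idx <- if (is.null(subset)) seq_len(fit$n) else which(
    if (is.logical(subset)) subset else seq_len(fit$n) %in% subset)
  if (!length(idx)) stop("empty subset", call. = FALSE)
  qd <- fit$qstar[idx, , drop = FALSE] - fit$qstar[idx, comparator]
  dd <- fit$eic[idx, , drop = FALSE] - fit$eic[idx, comparator]
  diff <- colMeans(qd)
  se <- apply(dd, 2, sd) / sqrt(length(idx))
  se[comparator] <- 0
  data.frame(
    population = population, drug = fit$drugs, n = length(idx),
    diff = unname(diff[fit$drugs]), se = unname(se[fit$drugs]),
    lo = unname(diff[fit$drugs] - 1.96 * se[fit$drugs]),
    hi = unname(diff[fit$drugs] + 1.96 * se[fit$drugs]),
    row.names = NULL
  )
}

#' Subgroup-averaged treatment effects
#'
#' Averages the fitted per-person predicted differences within each subgroup
#' of a partition (no refitting), the same convention the sensitivity
#' analysis uses.  Size-weighted subgroup estimates reconstruct the overall
#' estimate exactly, since averaging over a partition is an algebraic
#' identity.
#'
#' @param fit a `tmle_fit`.
#' @param labels vector partitioning the cohort (factor or character,
#'   length `fit$n`, no missing values).
#' @param comparator comparator drug label.
#' @param min_n rows from subgroups smaller than this are flagged `low_n`.
#' @return data.frame of effect rows with a `low_n` flag.
#' @export
subgroup_effects <- function(fit, labels, comparator, min_n = 50) {
  stopifnot(length(labels) == fit$n)
  if (anyNA(labels)) stop("subgroup labels must partition the cohort (no NA)",
                          call. = FALSE)
  labels <- as.factor(labels)
  out <- do.call(rbind, lapply(levels(labels), function(l) {
    rows <- effect_rows(fit, comparator, subset = labels == l,
                        population = l)
    rows$low_n <- rows$n < min_n
    rows
  }))
  rownames(out) <- NULL
  out
}

#' Sensitivity-subcohort effects
#'
#' Averages the full-cohort fit's predicted differences within the flagged
#' subcohort (persons under 45 with zero pre-period index-drug exposure) —
#' no refit is performed, mirroring how consistency against
#' confounding-by-indication is probed.
#'
#' @param fit a `tmle_fit`.
#' @param flag logical vector of length `fit$n`.
#' @param comparator comparator drug label.
#' @return data.frame of effect rows with population `"sensitivity"`.
#' @export
sensitivity_effects <- function(fit, flag, comparator) {
  stopifnot(is.logical(flag), length(flag) == fit$n)
  if (!any(flag)) stop("sensitivity subcohort is empty", call. = FALSE)
  effect_rows(fit, comparator, subset = flag, population = "sensitivity")
}

#' Render effect tables at reporting precision
#'
#' Converts probability-scale effect rows to percentage points with one
#' decimal (the reporting precision), attaches 95% CIs and the relative
#' difference scaled by the comparator's unadjusted outcome rate, and
#' suppresses the comparator's own rows.  Positive values indicate an
#' advantage for the comparator.  When `dir` is given, writes
#' `effects_<outcome>.csv` per outcome plus a combined `report.md`.
#'
#' @param effects effect-row data.frame (from [effect_rows()],
#'   [subgroup_effects()] or [sensitivity_effects()]), with an `outcome`
#'   column if several outcomes are mixed.
#' @param comparator comparator drug label.
#' @param comparator_rate_pct unadjusted comparator outcome rate(s) in
#'   percent; a named vector by outcome when `effects` spans outcomes.
#' @param dir optional output directory.
#' @return the formatted table (invisibly when writing to `dir`).
#' @export
render_tables <- function(effects, comparator, comparator_rate_pct,
                          dir = NULL) {
  eff <- effects[effects$drug != comparator, , drop = FALSE]
  if (is.null(eff$outcome)) eff$outcome <- "outcome"
  rate_of <- function(oc) {
    if (length(comparator_rate_pct) == 1L && is.null(names(comparator_rate_pct)))
      comparator_rate_pct
    else comparator_rate_pct[[oc]]
  }
  fmt <- data.frame(
    outcome = eff$outcome,
    population = eff$population,
    drug = eff$drug,
    n = eff$n,
    abs_diff_pp = sprintf("%.1f", 100 * eff$diff),
    ci_95 = sprintf("(%.1f, %.1f)", 100 * eff$lo, 100 * eff$hi),
    rel_diff_pct = sprintf("%.1f", vapply(seq_len(nrow(eff)), function(i) {
      relative_difference(100 * eff$diff[i], rate_of(eff$outcome[i]))
    }, 0)),
    row.names = NULL
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (oc in unique(fmt$outcome)) {
      utils::write.csv(fmt[fmt$outcome == oc, ],
                       file.path(dir, sprintf("effects_%s.csv", oc)),
                       row.names = FALSE)
    }
    md <- c(
      "# Average absolute outcome differences (percentage points)",
      "",
      sprintf("Comparator: %s.  Positive values indicate an advantage for %s.",
              comparator, comparator),
      "",
      paste("|", paste(names(fmt), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(fmt)), collapse = " | "), "|"),
      vapply(seq_len(nrow(fmt)), function(i) {
        paste("|", paste(unlist(fmt[i, ]), collapse = " | "), "|")
      }, "")
    )
    writeLines(md, file.path(dir, "report.md"))
    return(invisible(fmt))
  }
  fmt
}
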