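#' True counterfactual risks of a DGP configuration
#'
#' Averages the configured outcome model over the confounder distribution to
#' obtain the true risk `psi_a = E_W[ P(Y = 1 | A = a, W) ]` for each drug.
#' When every confounder has a small finite support (and `method` permits),
#' the average is computed exactly by enumerating the joint support;
#' otherwise it is approximated by Monte Carlo with a reported simulation
#' standard error.
#'
#' @param config a `dgp_config`.
#' @param outcome `"diabetes"` or `"death"`.
#' @param method `"auto"` (enumerate when possible), `"enumerate"` (error if
#'   any confounder lacks a finite enumerable support), or `"mc"`.
#' @param comparator drug label used for the contrast column.
#' @param mc_n Monte Carlo draws.
#' @param max_cells largest joint support enumerated before falling back to
#'   Monte Carlo under `method = "auto"`.
#' @param seed seed for the Monte Carlo draw.
#' @return a `truth_table`: data.frame with one row per drug (`drug`, `risk`,
#'   `contrast` = risk minus comparator risk, `mc_se`), with the method and
#'   outcome as attributes.
#' @export
true_psi <- function(config, outcome, method = c("auto", "enumerate", "mc"),
                     comparator = "aripiprazole", mc_n = 200000,
                     max_cells = 100000, seed = config$seed + 777) {
  method <- match.arg(method)
  if (!outcome %in% names(config$outcomes)) {
    stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE)
  }
  if (!comparator %in% config$drugs) {
    stop(sprintf("comparator '%s' not a study drug", comparator),
         call. = FALSE)
  }
  specs <- config$confounders
  enumerable <- all(vapply(specs, cf_enumerable, TRUE))
  n_cells <- if (enumerable) {
    prod(vapply(specs, function(s) nrow(cf_enumerate(s)), 0))
  } else {
    Inf
  }
  if (method == "enumerate" && !enumerable) {
    stop("exact enumeration unsupported: some confounders are not discrete ",
         "with finite support", call. = FALSE)
  }
  use_enum <- method == "enumerate" ||
    (method == "auto" && enumerable && n_cells <= max_cells)

  if (use_enum) {
    supports <- lapply(specs, cf_enumerate)
    grid <- do.call(expand.grid,
                    c(lapply(supports, `[[`, "value"),
                      list(KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)))
    names(grid) <- names(specs)
    probs <- Reduce(`*`, lapply(seq_along(specs), function(i) {
      supports[[i]]$prob[match(grid[[i]], supports[[i]]$value)]
    }))
    X <- dgp_features(config, grid)
    risks <- vapply(config$drugs, function(d) {
      sum(probs * outcome_probs(config, X, d, outcome))
    }, 0)
    mc_se <- setNames(rep(0, length(risks)), config$drugs)
    used <- "enumerate"
  } else {
    risks <- mc_se <- setNames(numeric(length(config$drugs)), config$drugs)
    with_seed(seed, {
      cov <- sample_covariates(config, mc_n)
      X <- dgp_features(config, cov)
      for (d in config$drugs) {
        p <- outcome_probs(config, X, d, outcome)
        risks[d] <- mean(p)
        mc_se[d] <- sd(p) / sqrt(mc_n)
      }
    })
    used <- "mc"
  }

  out <- data.frame(drug = config$drugs, risk = unname(risks),
                    contrast = unname(risks - risks[comparator]),
                    mc_se = unname(mc_se), row.names = NULL)
  structure(out, class = c("truth_table", "data.frame"),
            outcome = outcome, method = used, comparator = comparator)
}
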