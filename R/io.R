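#' Read and write claims bundles as CSV + JSON
#'
#' A bundle is persisted as `persons.csv`, `fills.csv`, `dx_claims.csv`,
#' `enrollment.csv`, with the latent ground-truth table in `latent.csv` and
#' the per-drug true counterfactual risks in `truth.json` (when a config is
#' supplied).
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @param config optional `dgp_config`; when given, `truth.json` records the
#'   true risks and contrasts for both outcomes via [true_psi()].
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in c("persons", "fills", "dx_claims", "enrollment", "latent")) {
    data.table::fwrite(bundle[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  if (!is.null(config)) {
    truth <- lapply(c("diabetes", "death"), function(oc) {
      tt <- true_psi(config, oc)
      list(risk = setNames(as.list(tt$risk), tt$drug),
           contrast = setNames(as.list(tt$contrast), tt$drug),
           comparator = attr(tt, "comparator"),
           method = attr(tt, "method"))
    })
    names(truth) <- c("diabetes", "death")
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  tabs <- lapply(c("persons", "fills", "dx_claims", "enrollment"),
                 function(tb) {
    as.data.frame(data.table::fread(file.path(dir, paste0(tb, ".csv"))))
  })
  names(tabs) <- c("persons", "fills", "dx_claims", "enrollment")
  lf <- file.path(dir, "latent.csv")
  if (file.exists(lf)) tabs$latent <- as.data.frame(data.table::fread(lf))
  structure(tabs, class = "claims_bundle")
}
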