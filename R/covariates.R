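#' Measure analytic covariates in the 183-day pre-period
#'
#' Builds the confounder vector for each indexed person strictly from records
#' dated inside `[index - 183, index)`: health-status indicators and the nine
#' utilization counts from diagnosis claims, metabolic testing, the
#' cardiometabolic pharmacy class indicators, and the summed days supply of
#' pre-period fills of the person's own index drug.  Demographics (age at
#' index, sex, race, state, payer, SMI diagnosis) come from the person table
#' and the index year from the index date.  No record on or after the index
#' date contributes to any covariate.
#'
#' @param bundle a `claims_bundle` (or any list with `persons`, `fills`,
#'   `dx_claims` in the same schema).
#' @param index_assignments data.frame with `person_id`, `drug`, `index_day`.
#' @param codes code configuration ([default_code_config()]).
#' @return data.frame with one row per indexed person, keyed by `person_id`,
#'   carrying the standard confounder columns.
#' @export
make_analytic_covariates <- function(bundle, index_assignments,
                                     codes = default_code_config()) {
  idx <- as.data.table(index_assignments)[, .(person_id, drug, index_day)]
  stopifnot(!anyDuplicated(idx$person_id))

  dx <- as.data.table(bundle$dx_claims)[idx, on = "person_id", nomatch = NULL]
  dx <- dx[day > index_day - .PRE_PERIOD_DAYS & day < index_day]
  fl <- as.data.table(bundle$fills)[idx, on = "person_id", nomatch = NULL]
  fl <- fl[day > index_day - .PRE_PERIOD_DAYS & day < index_day]

  out <- idx[as.data.table(bundle$persons), on = "person_id", nomatch = NULL]
  out[, age := as.integer(floor((index_day - birth_day) / 365.25))]
  out[, male := as.integer(sex == "male")]
  out[, payer_dual := as.integer(payer == "dual")]
  out[, index_year := format(day_to_date(index_day), "%Y")]

  ind_from_dx <- function(code_set) {
    hit <- dx[code %in% code_set, unique(person_id)]
    as.integer(out$person_id %in% hit)
  }
  for (hs in names(codes$health)) out[, (hs) := ind_from_dx(codes$health[[hs]])]
  out[, metab_test := ind_from_dx(codes$metab_test)]

  set_map <- c(inpt = "inpatient", ed = "ed", out = "outpatient")
  for (cat in names(codes$util)) {
    for (sfx in names(set_map)) {
      nm <- paste0("util_", cat, "_", sfx)
      cnt <- dx[code == codes$util[[cat]] & setting == set_map[[sfx]],
                .N, by = person_id]
      out[, (nm) := 0L]
      out[cnt, on = "person_id", (nm) := i.N]
    }
  }

  for (rx in names(codes$rx_class)) {
    hit <- fl[class == codes$rx_class[[rx]], unique(person_id)]
    out[, (rx) := as.integer(person_id %in% hit)]
  }

  # pre-period exposure to the person's own index drug: join carries the
  # index drug alongside each fill row
  fl2 <- as.data.table(bundle$fills)[
    idx[, .(person_id, index_drug = drug, index_day)],
    on = "person_id", nomatch = NULL]
  fl2 <- fl2[day > index_day - .PRE_PERIOD_DAYS & day < index_day &
               class == "antipsychotic" & drug == index_drug]
  expo <- fl2[, .(pre_expo_days = sum(days_supply)), by = person_id]
  out[, pre_expo_days := 0L]
  out[expo, on = "person_id", pre_expo_days := i.pre_expo_days]

  cols <- c("person_id", "drug", "index_day", "age", "male", "race", "smi_dx",
            "state", "payer_dual", "index_year",
            names(codes$health),
            as.vector(outer(paste0("util_", names(codes$util), "_"),
                            c("inpt", "ed", "out"), paste0)),
            "metab_test", names(codes$rx_class), "pre_expo_days")
  setorder(out, person_id)
  out <- as.data.frame(out[, ..cols])
  for (cl in c("race", "smi_dx", "state", "index_year")) {
    out[[cl]] <- factor(out[[cl]])
  }
  out
}
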