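#' Stylized claim-code configuration
#'
#' Small configurable label sets stand in for the ICD-9 / NDC code lists a
#' production claims pipeline would carry.  The defaults name one type-2
#' diabetes code, the pre-period exclusion conditions (type-2 diabetes,
#' dyslipidemia, hypertension, cardiovascular disease, and
#' antidiabetic-managed conditions such as polycystic ovary syndrome), the
#' three health-status code families (chronic medical conditions including
#' type 1 diabetes — which is a confounder, never an exclusion —
#' cardiometabolic risk factors, and psychiatric comorbidity), the metabolic
#' testing code, the utilization category codes, and the pharmacy class flags
#' with cardiometabolic relevance.
#'
#' @return a named list of code sets.
#' @export
default_code_config <- function() {
  list(
    t2d = "T2D",
    exclusions = c("T2D", "DYSLIPIDEMIA", "HYPERTENSION", "CVD", "PCOS"),
    health = list(
      hs_chronic = c("CHRONIC_MED", "T1D", "HIV", "MALIGNANCY"),
      hs_cardio_risk = c("OBESITY", "PREDIABETES"),
      hs_psych = c("PSYCH_COMORBID", "PTSD")
    ),
    metab_test = "METAB_TEST",
    util = list(psy = "UTIL_PSY", inj = "UTIL_INJ", oth = "UTIL_OTH"),
    rx_class = list(
      rx_antidiabetic = "oral_antidiabetic",
      rx_antihtn = "antihypertensive",
      rx_othercm = "other_cardiometabolic"
    )
  )
}

known_codes <- function(codes) {
  unique(c(codes$t2d, codes$exclusions, unlist(codes$health),
           codes$metab_test, unlist(codes$util)))
}
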