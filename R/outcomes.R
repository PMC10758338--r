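#' Ascertain incident type 2 diabetes from claim patterns
#'
#' A person is called diabetic when, inside follow-up (`start <= day <= end`),
#' any of three branches fires:
#'
#' * `inpatient_primary` — at least one inpatient claim with the type-2
#'   diabetes code in primary position;
#' * `two_outpatient_12mo` — at least two outpatient claims (primary or
#'   secondary position) within any 365-day window;
#' * `outpatient_plus_antidiabetic` — one outpatient claim accompanied by an
#'   oral-antidiabetic fill within 365 days of the claim.
#'
#' The evidence day is the earliest day on which any branch completes (for
#' the two-claim branch, the second claim of the earliest qualifying pair;
#' for the claim-plus-fill branch, the later of the pair).  Ties between
#' branches resolve in the order listed.
#'
#' @param dx_claims diagnosis claims table.
#' @param fills fills table (for oral-antidiabetic fills).
#' @param followup data.frame from [resolve_followup()] (`person_id`,
#'   `start`, `end`).
#' @param codes code configuration.
#' @return data.frame `person_id`, `indicator`, `evidence_day`, `branch`.
#' @export
ascertain_diabetes <- function(dx_claims, fills, followup,
                               codes = default_code_config()) {
  t2d <- dx_claims[dx_claims$code %in% codes$t2d, , drop = FALSE]
  oad <- fills[fills$class == "oral_antidiabetic", , drop = FALSE]
  W <- .DX_PAIR_WINDOW_DAYS

  res <- lapply(seq_len(nrow(followup)), function(i) {
    pid <- followup$person_id[i]
    s <- followup$start[i]; e <- followup$end[i]
    cl <- t2d[t2d$person_id == pid & t2d$day >= s & t2d$day <= e, ,
              drop = FALSE]
    best_day <- Inf; best_branch <- NA_character_

    inp <- cl$day[cl$setting == "inpatient" & cl$position == "primary"]
    if (length(inp)) { best_day <- min(inp); best_branch <- "inpatient_primary" }

    outp <- sort(cl$day[cl$setting == "outpatient"])
    if (length(outp) >= 2) {
      gaps <- diff(outp)
      j <- which(gaps < W)
      if (length(j)) {
        d <- outp[min(j) + 1L]
        if (d < best_day) { best_day <- d; best_branch <- "two_outpatient_12mo" }
      }
    }

    if (length(outp)) {
      fd <- oad$day[oad$person_id == pid & oad$day >= s & oad$day <= e]
      if (length(fd)) {
        comp <- outer(outp, fd, function(a, b) ifelse(abs(a - b) < W,
                                                      pmax(a, b), Inf))
        d <- min(comp)
        if (d < best_day) {
          best_day <- d; best_branch <- "outpatient_plus_antidiabetic"
        }
      }
    }

    data.frame(person_id = pid,
               indicator = as.integer(is.finite(best_day)),
               evidence_day = if (is.finite(best_day)) as.integer(best_day)
                              else NA_integer_,
               branch = best_branch)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ascertain all-cause death within follow-up
#'
#' @param death_day integer vector of death days aligned with the follow-up
#'   rows (NA if alive).
#' @param followup data.frame from [resolve_followup()].
#' @return data.frame `person_id`, `indicator`, `evidence_day`, `branch`.
#' @export
ascertain_death <- function(death_day, followup) {
  stopifnot(length(death_day) == nrow(followup))
  if (any(!is.na(death_day) & death_day < followup$start)) {
    stop("death date before index day: upstream cohort construction bug",
         call. = FALSE)
  }
  ind <- !is.na(death_day) & death_day >= followup$start &
    death_day <= followup$end
  data.frame(
    person_id = followup$person_id,
    indicator = as.integer(ind),
    evidence_day = ifelse(ind, death_day, NA_integer_),
    branch = ifelse(ind, "death_record", NA_character_)
  )
}
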