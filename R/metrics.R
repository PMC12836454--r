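#' Control baselines: mean host emergence in unparasitized vials
#'
#' For every host x temperature cell, `Hc` is the arithmetic mean of adult
#' host emergence `H` across the control vials of that cell. `Hc` is the
#' denominator of both per-vial interaction indices.
#'
#' @param vials A vial-record data frame (see [simulate_experiment()]).
#' @return Data frame with columns `host, temperature, Hc, n_control`.
#' @export
control_baselines <- function(vials) {
  vials <- validate_vials(vials)
  ctl <- vials[vials$parasitoid == "CONTROL", ]
  trt <- unique(vials[vials$parasitoid != "CONTROL", c("host", "temperature")])
  have <- unique(ctl[, c("host", "temperature")])
  key <- function(d) paste(d$host, d$temperature)
  miss <- trt[!key(trt) %in% key(have), , drop = FALSE]
  if (nrow(miss)) {
    stop("no control vials for cell(s): ",
         paste(paste0(miss$host, " x ", miss$temperature, "C"), collapse = "; "),
         call. = FALSE)
  }
  agg <- stats::aggregate(H ~ host + temperature, data = ctl, FUN = mean)
  n <- stats::aggregate(H ~ host + temperature, data = ctl, FUN = length)
  names(agg)[3] <- "Hc"
  agg$n_control <- n$H[match(key(agg), key(n))]
  agg[order(agg$host, agg$temperature), ]
}

#' Per-vial baseline adjustment
#'
#' `Hc` can fall below a vial's own `H` or `P`; the adjusted baseline is the
#' best estimate of how many flies could have hatched in that vial, namely
#' `max(Hc, H, P)`. Vectorized.
#'
#' @param P,H Counts of emerged parasitoids and hosts in the vial.
#' @param Hc Control baseline for the vial's host x temperature cell.
#' @return Data frame with columns `Hc_adj` and logical `adjusted`
#'   (`TRUE` where `Hc_adj > Hc`).
#' @export
adjust_baseline <- function(P, H, Hc) {
  stopifnot(all(P >= 0), all(H >= 0), all(Hc >= 0))
  Hc_adj <- pmax(Hc, H, P)
  data.frame(Hc_adj = Hc_adj, adjusted = Hc_adj > Hc)
}

#' Per-vial interaction indices
#'
#' Parasitism success `P / Hc_adj` (parasitoid developmental success) and
#' degree of infestation `1 - H / Hc_adj` (host suppression). Both lie in
#' \[0, 1\] by construction of the adjusted baseline. With `Hc_adj = 0` both
#' are undefined (`NA`); such vials are excluded downstream.
#'
#' @param P,H Vial counts.
#' @param Hc_adj Adjusted baseline, `>= max(P, H)` elementwise.
#' @return Data frame with columns `parasitism_success` and
#'   `degree_of_infestation`.
#' @export
outcome_indices <- function(P, H, Hc_adj) {
  if (any(Hc_adj < pmax(P, H) - 1e-9)) {
    stop("internal error: Hc_adj below max(P, H); adjustment not applied",
         call. = FALSE)
  }
  ps <- ifelse(Hc_adj > 0, P / Hc_adj, NA_real_)
  di <- ifelse(Hc_adj > 0, 1 - H / Hc_adj, NA_real_)
  data.frame(parasitism_success = ps, degree_of_infestation = di)
}

#' Treatment outcomes for all parasitized vials
#'
#' Joins each parasitized vial to its control baseline, applies the
#' adjustment rule and computes both indices. Vials whose adjusted baseline
#' is zero are flagged `excluded` (indices undefined).
#'
#' @param vials A vial-record data frame containing control vials for every
#'   treated host x temperature cell.
#' @return Data frame of class `"treatment_outcomes"`: one row per
#'   parasitized vial with columns
#'   `host, parasitoid, temperature, replicate, eggs, P, H, Hc, Hc_adj,
#'   adjusted, parasitism_success, degree_of_infestation, excluded`.
#' @export
treatment_outcomes <- function(vials) {
  vials <- validate_vials(vials)
  base <- control_baselines(vials)
  trt <- vials[vials$parasitoid != "CONTROL", ]
  i <- match(paste(trt$host, trt$temperature), paste(base$host, base$temperature))
  trt$Hc <- base$Hc[i]
  adj <- adjust_baseline(trt$P, trt$H, trt$Hc)
  trt$Hc_adj <- adj$Hc_adj
  trt$adjusted <- adj$adjusted
  idx <- outcome_indices(trt$P, trt$H, trt$Hc_adj)
  trt$parasitism_success <- idx$parasitism_success
  trt$degree_of_infestation <- idx$degree_of_infestation
  trt$excluded <- trt$Hc_adj == 0
  rownames(trt) <- NULL
  class(trt) <- c("treatment_outcomes", "data.frame")
  trt
}

#' Host developmental success observations
#'
#' One `(successes, trials)` observation per control vial: emerged adults out
#' of the eggs placed in the vial, grouped by host and temperature.
#'
#' @param vials A vial-record data frame.
#' @return Data frame `host, temperature, replicate, successes, trials`.
#' @export
host_dev_success <- function(vials) {
  vials <- validate_vials(vials)
  ctl <- vials[vials$parasitoid == "CONTROL", ]
  out <- data.frame(host = ctl$host, temperature = ctl$temperature,
                    replicate = ctl$replicate,
                    successes = ctl$H, trials = ctl$eggs)
  rownames(out) <- NULL
  out
}

# round-half-up; base round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' Binomial observations for the Bayesian models
#'
#' The adjusted baseline is the number of trials (rounded half-up once, at
#' model entry; the indices themselves stay exact). The outcome is `P` for
#' parasitism success and `round(Hc_adj) - H` for degree of infestation.
#' Excluded vials (`Hc_adj = 0`) are dropped, with their count attached as
#' attribute `n_excluded`.
#'
#' @param outcomes A [treatment_outcomes()] table.
#' @param kind `"parasitism"` or `"infestation"`.
#' @return Data frame `host, parasitoid, temperature, replicate, successes,
#'   trials` with attribute `n_excluded`.
#' @export
model_observations <- function(outcomes, kind = c("parasitism", "infestation")) {
  kind <- match.arg(kind)
  n_excl <- sum(outcomes$excluded)
  keep <- outcomes[!outcomes$excluded, ]
  trials <- round_half_up(keep$Hc_adj)
  successes <- if (kind == "parasitism") keep$P else trials - keep$H
  if (any(successes < 0) || any(successes > trials)) {
    stop("successes outside [0, trials] after rounding; baseline adjustment ",
         "was not applied upstream", call. = FALSE)
  }
  out <- data.frame(host = keep$host, parasitoid = keep$parasitoid,
                    temperature = keep$temperature, replicate = keep$replicate,
                    successes = successes, trials = trials)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excl
  out
}

#' Summary of baseline adjustments and exclusions per temperature
#' @param outcomes A [treatment_outcomes()] table.
#' @return Data frame `temperature, n_vials, n_adjusted, n_excluded`.
#' @export
adjustment_summary <- function(outcomes) {
  temps <- sort(unique(outcomes$temperature))
  data.frame(
    temperature = temps,
    n_vials = vapply(temps, function(t) sum(outcomes$temperature == t), 0L),
    n_adjusted = vapply(temps, function(t)
      sum(outcomes$adjusted & outcomes$temperature == t), 0L),
    n_excluded = vapply(temps, function(t)
      sum(outcomes$excluded & outcomes$temperature == t), 0L)
  )
}
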