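# Growth, feed-utilization and body indices of a feeding trial, computed
# from cage-level bookkeeping records and individual-fish morphometrics.
#
# The unit of analysis is the cage: ibw/fbw are cage-mean body weights and
# feed_dm, dead_weight, protein_intake, body_protein_gain are cage totals.
# Ratio indices (feeding rate, feed efficiency, PER, PRE) require weights and
# intakes on the same basis; the `basis` flag records whether a record is
# kept per fish or per cage so mixed-basis arithmetic can be caught early.

#' Construct a cage record
#'
#' One cage's growth and feed bookkeeping over the trial. Weight fields must
#' be on a single consistent basis: with `basis = "cage"` (default), `ibw`
#' and `fbw` are total cage biomass and `feed_dm` the cage's total dry feed
#' intake; with `basis = "fish"` everything is per fish.
#'
#' @param diet Diet name.
#' @param n_initial,n_final Fish counts at stocking and at the end.
#' @param ibw,fbw Initial and final body weight (g), > 0.
#' @param feed_dm Total dry feed intake (g), >= 0.
#' @param days Trial duration (days), > 0; the packaged trial ran 56 d.
#' @param dead_weight Total weight of fish that died during the trial (g).
#' @param protein_intake Protein intake (g), for PER/PRE.
#' @param body_protein_gain Body protein deposited (g), for PRE.
#' @param basis `"cage"` or `"fish"`; bookkeeping basis shared by weights and
#'   intakes.
#' @return A list of class `cage_record`.
#' @export
cage_record <- function(diet, n_initial, n_final, ibw, fbw, feed_dm,
                        days = 56, dead_weight = 0, protein_intake = NA_real_,
                        body_protein_gain = NA_real_,
                        basis = c("cage", "fish")) {
  basis <- match.arg(basis)
  if (n_final > n_initial) {
    stop("n_final exceeds n_initial for diet ", diet, call. = FALSE)
  }
  if (n_initial <= 0) stop("n_initial must be > 0", call. = FALSE)
  if (!is.finite(ibw) || !is.finite(fbw) || ibw <= 0 || fbw <= 0) {
    stop("body weights must be > 0", call. = FALSE)
  }
  if (days <= 0) stop("days must be > 0", call. = FALSE)
  if (feed_dm < 0 || dead_weight < 0) {
    stop("feed_dm and dead_weight must be >= 0", call. = FALSE)
  }
  structure(list(diet = diet, n_initial = n_initial, n_final = n_final,
                 ibw = ibw, fbw = fbw, feed_dm = feed_dm, days = days,
                 dead_weight = dead_weight, protein_intake = protein_intake,
                 body_protein_gain = body_protein_gain, basis = basis),
            class = "cage_record")
}

#' Survival rate
#'
#' `100 * n_final / n_initial`.
#'
#' @param rec A [cage_record()].
#' @return Percentage in \[0, 100\].
#' @export
survival_rate <- function(rec) 100 * rec$n_final / rec$n_initial

#' Specific growth rate
#'
#' `100 * (ln fbw - ln ibw) / days`, in %/day. Invariant to rescaling both
#' weights by a common factor, so per-fish and per-cage weights give the same
#' SGR when fish counts are constant.
#'
#' @param rec A [cage_record()].
#' @return SGR in %/day; sign matches the sign of `fbw - ibw`.
#' @export
specific_growth_rate <- function(rec) {
  100 * (log(rec$fbw) - log(rec$ibw)) / rec$days
}

#' Feeding rate
#'
#' `100 * feed_dm / (days * (fbw + ibw) / 2)`, in % of body weight per day.
#' Weights and feed intake must be on the same basis (both per cage or both
#' per fish).
#'
#' @param rec A [cage_record()].
#' @return Feeding rate, %BW/d.
#' @export
feeding_rate <- function(rec) {
  denom <- rec$days * (rec$fbw + rec$ibw) / 2
  if (denom <= 0) stop("zero denominator in feeding rate", call. = FALSE)
  100 * rec$feed_dm / denom
}

#' Feed efficiency
#'
#' `100 * (weight gain + dead fish weight) / feed_dm`. Dead-fish weight is
#' credited as produced biomass, matching standard trial bookkeeping.
#'
#' @param rec A [cage_record()].
#' @return Feed efficiency, %.
#' @export
feed_efficiency <- function(rec) {
  if (rec$feed_dm <= 0) stop("feed_dm must be > 0", call. = FALSE)
  100 * ((rec$fbw - rec$ibw) + rec$dead_weight) / rec$feed_dm
}

#' Protein efficiency ratio
#'
#' `(fbw - ibw) / protein_intake` (dimensionless).
#'
#' @param rec A [cage_record()].
#' @return PER.
#' @export
protein_efficiency_ratio <- function(rec) {
  if (!is.finite(rec$protein_intake) || rec$protein_intake <= 0) {
    stop("protein_intake must be > 0", call. = FALSE)
  }
  (rec$fbw - rec$ibw) / rec$protein_intake
}

#' Protein retention efficiency
#'
#' `100 * body_protein_gain / protein_intake`, %.
#'
#' @param rec A [cage_record()].
#' @return PRE, %.
#' @export
protein_retention <- function(rec) {
  if (!is.finite(rec$protein_intake) || rec$protein_intake <= 0) {
    stop("protein_intake must be > 0", call. = FALSE)
  }
  100 * rec$body_protein_gain / rec$protein_intake
}

#' Construct a fish morphometrics record
#'
#' @param body_weight Whole-body weight (g), > 0.
#' @param total_length Total length (cm), > 0.
#' @param visceral_weight Visceral weight (g), in (0, body_weight).
#' @param liver_weight Liver weight (g), in (0, visceral_weight).
#' @return A list of class `fish_morphometrics`.
#' @export
fish_morphometrics <- function(body_weight, total_length,
                               visceral_weight = NA_real_,
                               liver_weight = NA_real_) {
  if (!is.finite(body_weight) || body_weight <= 0 ||
      !is.finite(total_length) || total_length <= 0) {
    stop("body_weight and total_length must be > 0", call. = FALSE)
  }
  if (is.finite(visceral_weight)) {
    if (visceral_weight <= 0 || visceral_weight >= body_weight) {
      stop("visceral_weight must be in (0, body_weight)", call. = FALSE)
    }
    if (is.finite(liver_weight) &&
        (liver_weight <= 0 || liver_weight >= visceral_weight)) {
      stop("liver_weight must be in (0, visceral_weight)", call. = FALSE)
    }
  }
  structure(list(body_weight = body_weight, total_length = total_length,
                 visceral_weight = visceral_weight,
                 liver_weight = liver_weight),
            class = "fish_morphometrics")
}

#' Condition factor
#'
#' `100 * body_weight / total_length^3`, g/cm^3.
#'
#' @param m A [fish_morphometrics()].
#' @return Condition factor.
#' @export
condition_factor <- function(m) 100 * m$body_weight / m$total_length^3

#' Viscerosomatic index
#'
#' `100 * visceral_weight / body_weight`, %.
#'
#' @param m A [fish_morphometrics()].
#' @return VSI, %.
#' @export
viscerosomatic_index <- function(m) {
  if (!is.finite(m$visceral_weight)) {
    stop("visceral_weight missing", call. = FALSE)
  }
  100 * m$visceral_weight / m$body_weight
}

#' Hepatosomatic index
#'
#' `100 * liver_weight / body_weight`, %.
#'
#' @param m A [fish_morphometrics()].
#' @return HSI, %.
#' @export
hepatosomatic_index <- function(m) {
  if (!is.finite(m$liver_weight)) stop("liver_weight missing", call. = FALSE)
  100 * m$liver_weight / m$body_weight
}

#' Per-diet performance summary of a set of cage records
#'
#' Computes every index available on each record and summarizes by diet as
#' mean and standard error over cages.
#'
#' @param records List of [cage_record()]s.
#' @return Data frame with one row per (diet, index): columns `diet`,
#'   `index`, `mean`, `se`, `n`.
#' @export
summarize_performance <- function(records) {
  per_cage <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      diet = r$diet,
      sr = survival_rate(r),
      sgr = specific_growth_rate(r),
      fr = feeding_rate(r),
      fe = feed_efficiency(r),
      per = if (is.finite(r$protein_intake)) protein_efficiency_ratio(r)
            else NA_real_,
      pre = if (is.finite(r$protein_intake) &&
                is.finite(r$body_protein_gain)) protein_retention(r)
            else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  idx <- setdiff(names(per_cage), "diet")
  out <- do.call(rbind, lapply(idx, function(v) {
    agg_m <- tapply(per_cage[[v]], per_cage$diet, mean)
    agg_se <- tapply(per_cage[[v]], per_cage$diet,
                     function(x) stats::sd(x) / sqrt(length(x)))
    agg_n <- tapply(per_cage[[v]], per_cage$diet, length)
    data.frame(diet = names(agg_m), index = v, mean = as.numeric(agg_m),
               se = as.numeric(agg_se), n = as.integer(agg_n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
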