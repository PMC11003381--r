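# Geometric-mean protein-quality indices.
#
# EAAI scores a dietary protein by how its nine essential amino acids match a
# requirement pattern: 100 times the geometric mean of the content/requirement
# ratios. DEAAI applies the same score to digestible contents
# (content * ADC/100), so it reflects both composition and availability.
# Ratios above 1 are NOT capped (the classic Oser formulation caps at 1; this
# index does not, and the uncapped form is what reproduces published values).
# The geometric mean is evaluated in log space for numerical stability.

.quality_index <- function(ratios, basis) {
  value <- 100 * exp(mean(log(ratios)))
  structure(list(value = value, per_aa_ratios = ratios, basis = basis),
            class = "quality_index")
}

#' @export
print.quality_index <- function(x, ...) {
  cat(sprintf("%s index: %.2f%%\n",
              if (x$basis == "digestible") "Digestible EAA (DEAAI)"
              else "EAA (EAAI)", x$value))
  invisible(x)
}

.eaa_ratios <- function(diet_aa, req) {
  stopifnot(inherits(req, "requirement_set"))
  v <- aa_vector(diet_aa)
  missing <- setdiff(eaa_names(), names(v))
  if (length(missing) > 0) {
    stop("diet composition is missing EAA(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contents <- unclass(v)[eaa_names()]
  if (any(contents <= 0)) {
    stop("zero EAA content for: ",
         paste(eaa_names()[contents <= 0], collapse = ", "), call. = FALSE)
  }
  contents / req$requirements
}

#' Essential amino acid index (EAAI)
#'
#' `100 * (prod_i content_i / requirement_i)^(1/9)` over the nine canonical
#' EAAs. Scale-invariant: multiplying all contents and all requirements by a
#' common factor leaves the index unchanged.
#'
#' @param diet_aa An [aa_vector()] containing all nine EAAs with content > 0
#'   (NEAA entries are ignored).
#' @param req A [requirement_set()]; defaults to the packaged gibel carp set.
#' @return A `quality_index`: list with `value` (%), `per_aa_ratios` (named
#'   ratios content/requirement) and `basis = "chemical"`.
#' @export
#' @examples
#' fx <- paper_fixture()
#' eaai(fx$aa$Control)$value  # 95.83
eaai <- function(diet_aa, req = gibel_requirements()) {
  .quality_index(.eaa_ratios(diet_aa, req), "chemical")
}

#' Digestible essential amino acid index (DEAAI)
#'
#' EAAI computed on digestible contents: each EAA content is first multiplied
#' by its apparent digestibility coefficient over 100, then divided by the
#' requirement; the index is 100 times the geometric mean of the nine
#' ratios. With all ADCs at 100% the DEAAI equals the EAAI, and with all
#' ADCs <= 100% it never exceeds it.
#'
#' @param diet_aa An [aa_vector()] with all nine EAAs > 0.
#' @param adc_per_aa Named numeric vector of per-EAA ADCs (%); must cover all
#'   nine EAAs (aliases accepted).
#' @param req A [requirement_set()].
#' @return A `quality_index` with `basis = "digestible"`.
#' @export
#' @examples
#' fx <- paper_fixture()
#' deaai(fx$aa$Control, fx$adc[eaa_names(), "Control"])$value  # 79.07
deaai <- function(diet_aa, adc_per_aa, req = gibel_requirements()) {
  if (is.null(names(adc_per_aa))) {
    stop("adc_per_aa must be named by amino acid", call. = FALSE)
  }
  nm <- canonical_aa(names(adc_per_aa))
  adc <- stats::setNames(as.numeric(adc_per_aa), nm)
  missing <- setdiff(eaa_names(), nm)
  if (length(missing) > 0) {
    stop("no ADC supplied for EAA(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chem <- .eaa_ratios(diet_aa, req)
  ratios <- chem * adc[eaa_names()] / 100
  if (any(ratios <= 0)) {
    stop("nonpositive digestible ratio; check ADC signs", call. = FALSE)
  }
  .quality_index(ratios, "digestible")
}

#' Digestible-EAA ratio profile against a reference pattern
#'
#' For each EAA, the ratio of its digestible dietary content
#' (`content * ADC/100`) to a reference content — typically the muscle EAA
#' composition of the target species, or the requirement pattern. With the
#' requirement pattern as reference, 100 times the geometric mean of the
#' profile equals the DEAAI.
#'
#' @param diet_aa An [aa_vector()] with all nine EAAs > 0.
#' @param adc_per_aa Named per-EAA ADCs (%), covering the nine EAAs.
#' @param reference An [aa_vector()] (or named numeric) with all nine EAAs
#'   strictly positive.
#' @return Named numeric vector of nine ratios (canonical EAA order).
#' @export
deaa_ratio_profile <- function(diet_aa, adc_per_aa, reference) {
  refv <- aa_vector(reference)
  missing <- setdiff(eaa_names(), names(refv))
  if (length(missing) > 0) {
    stop("reference is missing EAA(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- unclass(refv)[eaa_names()]
  if (any(ref <= 0)) stop("reference entries must be > 0", call. = FALSE)
  nm <- canonical_aa(names(adc_per_aa))
  adc <- stats::setNames(as.numeric(adc_per_aa), nm)
  if (length(setdiff(eaa_names(), nm)) > 0) {
    stop("no ADC supplied for every EAA", call. = FALSE)
  }
  v <- aa_vector(diet_aa)
  if (length(setdiff(eaa_names(), names(v))) > 0) {
    stop("diet composition is missing EAAs", call. = FALSE)
  }
  dig <- digestible_content(unclass(v)[eaa_names()], adc[eaa_names()])
  dig / ref
}

#' Quality-index table for a whole trial
#'
#' Computes EAAI and DEAAI for every diet of a trial from its amino-acid
#' compositions and per-EAA ADC matrix.
#'
#' @param aa Named list of [aa_vector()]s, one per diet.
#' @param adc Substance x diet numeric matrix containing at least the nine
#'   EAA rows.
#' @param req A [requirement_set()].
#' @return Data frame with columns `diet`, `eaai`, `deaai`.
#' @export
quality_index_table <- function(aa, adc, req = gibel_requirements()) {
  diets <- names(aa)
  out <- data.frame(
    diet = diets,
    eaai = vapply(diets, function(d) eaai(aa[[d]], req)$value, numeric(1)),
    deaai = vapply(diets, function(d)
      deaai(aa[[d]], adc[eaa_names(), d], req)$value, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
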