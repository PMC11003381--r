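# Marker-based apparent digestibility: an indigestible indicator (yttrium
# trioxide) is mixed into the diet; because the marker passes through
# unabsorbed, the ratio of marker concentrations in diet and feces scales the
# fecal nutrient concentration back to the ingested mass, giving
#   ADC(%) = 100 * [1 - (fecal conc / dietary conc) * (marker diet / marker feces)].

#' Construct an ADC assay
#'
#' Paired diet/feces concentrations of one substance together with the inert
#' marker concentrations in the same diet and feces samples. Diet and feces
#' concentrations must share units (% DM for nutrients, MJ/kg for energy);
#' the marker is % DM.
#'
#' @param substance Substance name (e.g. `"crude_protein"`, `"lysine"`,
#'   `"dry_matter"`).
#' @param diet_conc Substance concentration in the diet (> 0).
#' @param feces_conc Substance concentration in feces (>= 0), same units.
#' @param marker_diet,marker_feces Marker (Y2O3) concentration in diet and
#'   feces (% DM, both > 0).
#' @return A list of class `adc_assay`.
#' @export
adc_assay <- function(substance, diet_conc, feces_conc, marker_diet,
                      marker_feces) {
  if (!is.finite(marker_diet) || marker_diet <= 0 ||
      !is.finite(marker_feces) || marker_feces <= 0) {
    stop("marker concentrations must be > 0", call. = FALSE)
  }
  if (!is.finite(diet_conc) || diet_conc <= 0) {
    stop("diet_conc must be > 0 for ", substance, call. = FALSE)
  }
  if (!is.finite(feces_conc) || feces_conc < 0) {
    stop("feces_conc must be >= 0 for ", substance, call. = FALSE)
  }
  structure(list(substance = substance, diet_conc = diet_conc,
                 feces_conc = feces_conc, marker_diet = marker_diet,
                 marker_feces = marker_feces),
            class = "adc_assay")
}

#' Apparent digestibility coefficient
#'
#' `100 * (1 - (feces_conc/diet_conc) * (marker_diet/marker_feces))`. For dry
#' matter itself both substance concentrations are 100, so the formula
#' reduces to `100 * (1 - marker_diet/marker_feces)`. The value is at most
#' 100 and may be negative under assay noise; negative values are kept as-is
#' but raised as a warning rather than clamped.
#'
#' @param a An [adc_assay()].
#' @return ADC, %.
#' @export
#' @examples
#' adc(adc_assay("crude_protein", 34, 30, 0.10, 0.22))
adc <- function(a) {
  stopifnot(inherits(a, "adc_assay"))
  value <- 100 * (1 - (a$feces_conc / a$diet_conc) *
                    (a$marker_diet / a$marker_feces))
  if (value < 0) {
    warning(sprintf("negative ADC (%.2f%%) for %s; kept unclamped",
                    value, a$substance), call. = FALSE)
  }
  value
}

#' Dry-matter ADC from marker concentrations alone
#'
#' @param marker_diet,marker_feces Marker concentrations (% DM, > 0).
#' @return ADC of dry matter, %.
#' @export
adc_dry_matter <- function(marker_diet, marker_feces) {
  adc(adc_assay("dry_matter", 100, 100, marker_diet, marker_feces))
}

#' Digestible content of a nutrient
#'
#' `content * adc / 100`: the portion of a dietary content (e.g. lysine, %
#' DM) that is apparently absorbed.
#'
#' @param content Dietary content (>= 0).
#' @param adc Apparent digestibility coefficient, %.
#' @return Digestible content, same units as `content`.
#' @export
digestible_content <- function(content, adc) {
  if (any(content < 0)) stop("content must be >= 0", call. = FALSE)
  content * adc / 100
}

#' Pooled ADC of several substances sharing marker data
#'
#' The ADC of a pooled fraction ("total essential amino acids", "total
#' nonessential amino acids") is the marker-ratio formula applied to the
#' summed diet and feces concentrations — not the mean of the individual
#' ADCs, which would weight trace and abundant substances equally.
#'
#' @param assays List of [adc_assay()]s with identical `marker_diet` and
#'   `marker_feces`.
#' @return Pooled ADC, %.
#' @export
pooled_adc <- function(assays) {
  stopifnot(length(assays) >= 1,
            all(vapply(assays, inherits, logical(1), "adc_assay")))
  md <- vapply(assays, function(a) a$marker_diet, numeric(1))
  mf <- vapply(assays, function(a) a$marker_feces, numeric(1))
  if (length(unique(md)) != 1 || length(unique(mf)) != 1) {
    stop("pooled_adc requires assays sharing marker concentrations",
         call. = FALSE)
  }
  adc(adc_assay(
    substance = paste0("pooled(", paste(vapply(assays, function(a)
      a$substance, character(1)), collapse = "+"), ")"),
    diet_conc = sum(vapply(assays, function(a) a$diet_conc, numeric(1))),
    feces_conc = sum(vapply(assays, function(a) a$feces_conc, numeric(1))),
    marker_diet = md[1], marker_feces = mf[1]
  ))
}

#' Read an ADC assay table
#'
#' Delimited table with columns `substance`, `diet_conc`, `feces_conc`,
#' `marker_diet`, `marker_feces`; one row per assay.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @return List of [adc_assay()]s.
#' @export
read_adc_assays <- function(path) {
  tab <- .read_delim_table(path)
  need <- c("substance", "diet_conc", "feces_conc", "marker_diet",
            "marker_feces")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("assay table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    adc_assay(tab$substance[i],
              as.numeric(tab$diet_conc[i]), as.numeric(tab$feces_conc[i]),
              as.numeric(tab$marker_diet[i]), as.numeric(tab$marker_feces[i]))
  })
}
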