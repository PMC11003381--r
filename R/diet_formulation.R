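# Diet formulation: replacing fishmeal with a blended protein source on a
# protein-equivalent (isonitrogenous) basis, computing the resulting dietary
# amino-acid composition, and closing formulations with a filler.

#' Construct an ingredient profile
#'
#' @param name Ingredient name.
#' @param crude_protein Crude protein, % of dry matter, in (0, 100].
#' @param crude_lipid Crude lipid, % of dry matter (>= 0).
#' @param aa An [aa_vector()] of amino-acid contents (% DM); their sum must
#'   not exceed 100.
#' @param marker Optional inert-marker content (% DM).
#' @return A list of class `ingredient_profile`.
#' @export
ingredient_profile <- function(name, crude_protein, crude_lipid = 0,
                               aa = aa_vector(numeric(0)), marker = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(crude_protein) || crude_protein <= 0 || crude_protein > 100) {
    stop("crude_protein must be in (0, 100] for ", name, call. = FALSE)
  }
  aa <- aa_vector(aa)
  if (sum(aa) > 100 + 1e-9) {
    stop("amino-acid contents of ", name, " sum above 100% DM", call. = FALSE)
  }
  structure(list(name = name, crude_protein = crude_protein,
                 crude_lipid = crude_lipid, aa = aa, marker = marker),
            class = "ingredient_profile")
}

#' Construct a blend specification
#'
#' A blend is an ordered set of ingredients with positive ratio parts, e.g.
#' parts 1:1:8:2 over four protein sources. Parts need not sum to anything in
#' particular; only their proportions matter.
#'
#' @param parts Named numeric vector of positive ratio parts.
#' @return A list of class `blend_spec` with `ingredients` and `parts`.
#' @export
#' @examples
#' blend_spec(c(t_molitor_meal = 1, chlorella_meal = 1, cap = 8, cpc = 2))
blend_spec <- function(parts) {
  if (length(parts) < 1 || is.null(names(parts)) || any(names(parts) == "")) {
    stop("blend_spec needs a named vector with at least one part",
         call. = FALSE)
  }
  nm <- names(parts)
  parts <- as.numeric(parts)
  names(parts) <- nm
  if (any(!is.finite(parts)) || any(parts <= 0)) {
    stop("all blend parts must be positive", call. = FALSE)
  }
  structure(list(ingredients = names(parts), parts = parts),
            class = "blend_spec")
}

#' Protein-equivalence factor of a blend against fishmeal
#'
#' The mass of blend that carries the same crude protein as unit mass of
#' fishmeal: `fm$crude_protein / (ratio-weighted mean crude protein of the
#' blend components)`. Multiplying the replaced fishmeal mass by this factor
#' keeps the diet isonitrogenous.
#'
#' @param fm Fishmeal [ingredient_profile()].
#' @param blend A [blend_spec()].
#' @param ingredients Named list of [ingredient_profile()]s covering every
#'   blend component.
#' @return Positive dimensionless factor.
#' @export
equivalence_factor <- function(fm, blend, ingredients) {
  stopifnot(inherits(blend, "blend_spec"))
  missing <- setdiff(blend$ingredients, names(ingredients))
  if (length(missing) > 0) {
    stop("no ingredient profile for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cp <- vapply(ingredients[blend$ingredients],
               function(p) p$crude_protein, numeric(1))
  if (any(cp <= 0) || fm$crude_protein <= 0) {
    stop("crude protein must be > 0 for all components", call. = FALSE)
  }
  w <- blend$parts / sum(blend$parts)
  fm$crude_protein / sum(w * cp)
}

#' Blend inclusions replacing a fraction of dietary fishmeal
#'
#' Total blend mass is `fm_base * replacement_fraction * factor` (% of diet
#' dry matter), split across the blend components proportionally to their
#' ratio parts; the residual fishmeal inclusion is
#' `fm_base * (1 - replacement_fraction)`.
#'
#' @param fm_base Fishmeal inclusion of the control diet (% DM, > 0).
#' @param replacement_fraction Fraction of fishmeal replaced, in \[0, 1\].
#' @param blend A [blend_spec()].
#' @param factor Protein-equivalence factor (see [equivalence_factor()] and
#'   [trial_blend_factors()]).
#' @return Named numeric vector of inclusions (% DM): the blend components
#'   plus `fish_meal`.
#' @export
#' @examples
#' b <- trial_blends()$A
#' blend_inclusions(15, 1, b, 0.912)["cap"]  # 9.12% DM
blend_inclusions <- function(fm_base, replacement_fraction, blend, factor) {
  stopifnot(inherits(blend, "blend_spec"))
  if (!is.finite(fm_base) || fm_base <= 0) {
    stop("fm_base must be > 0", call. = FALSE)
  }
  if (!is.finite(replacement_fraction) || replacement_fraction < 0 ||
      replacement_fraction > 1) {
    stop("replacement_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(factor) || factor <= 0) {
    stop("equivalence factor must be > 0", call. = FALSE)
  }
  total <- fm_base * replacement_fraction * factor
  shares <- total * blend$parts / sum(blend$parts)
  c(shares, fish_meal = fm_base * (1 - replacement_fraction))
}

#' Dietary amino-acid composition from inclusions
#'
#' Linear mixing: each amino-acid content of the diet is the inclusion-
#' weighted sum `sum_i inclusion_i/100 * content_i` over all ingredients with
#' a nonzero inclusion. Ingredients included at zero need no profile.
#'
#' @param inclusions Named numeric vector of inclusions (% DM).
#' @param ingredients Named list of [ingredient_profile()]s covering every
#'   ingredient with a nonzero inclusion.
#' @return An [aa_vector()] over the union of amino acids present in the
#'   contributing profiles (canonical order).
#' @export
diet_aa <- function(inclusions, ingredients) {
  stopifnot(!is.null(names(inclusions)))
  if (any(inclusions < 0)) stop("negative inclusion", call. = FALSE)
  active <- names(inclusions)[inclusions > 0]
  missing <- setdiff(active, names(ingredients))
  if (length(missing) > 0) {
    stop("no ingredient profile for nonzero inclusion(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  acc <- stats::setNames(numeric(length(aa_names())), aa_names())
  seen <- stats::setNames(logical(length(aa_names())), aa_names())
  for (ing in active) {
    aa <- ingredients[[ing]]$aa
    if (length(aa) > 0) {
      acc[names(aa)] <- acc[names(aa)] + inclusions[[ing]] / 100 * unclass(aa)
      seen[names(aa)] <- TRUE
    }
  }
  aa_vector(acc[seen])
}

#' Close a formulation with a filler ingredient
#'
#' Sets the filler inclusion so all inclusions sum to exactly 100% of dry
#' matter (microcrystalline cellulose in the packaged trial).
#'
#' @param inclusions Named numeric vector of inclusions (% DM); may or may
#'   not already contain the filler.
#' @param filler Name of the filler ingredient.
#' @return Inclusions with the filler set; sums to 100 exactly.
#' @export
close_formulation <- function(inclusions, filler = "microcrystalline_cellulose") {
  stopifnot(!is.null(names(inclusions)))
  others <- inclusions[setdiff(names(inclusions), filler)]
  if (any(others < 0)) stop("negative inclusion", call. = FALSE)
  rest <- 100 - sum(others)
  if (rest < -1e-9) {
    stop(sprintf("infeasible formulation: non-filler inclusions sum to %.4f > 100",
                 sum(others)), call. = FALSE)
  }
  out <- c(others, stats::setNames(max(rest, 0), filler))
  out
}

#' Formulate the blend-ingredient inclusions of a whole trial
#'
#' Reconstructs, for every combination of blend and replacement level, the
#' inclusions of the four blend components and the residual fishmeal. With
#' the packaged blends, factors and a 15% DM fishmeal base this reproduces
#' the blend-ingredient cells of the printed formulation table.
#'
#' @param fm_base Fishmeal inclusion of the control diet (% DM).
#' @param blends Named list of [blend_spec()]s (default [trial_blends()]).
#' @param factors Named numeric vector of equivalence factors, same names as
#'   `blends` (default [trial_blend_factors()]).
#' @param fractions Named numeric vector of replacement fractions (default
#'   33% and 67% read as exactly 1/3 and 2/3, plus 1).
#' @return Matrix of inclusions (% DM), rows = ingredients (blend components
#'   and `fish_meal`), columns = diet names (`Control`, `A33`, ...).
#' @export
formulate_trial_diets <- function(fm_base = 15,
                                  blends = trial_blends(),
                                  factors = trial_blend_factors(),
                                  fractions = c(`33` = 1 / 3, `67` = 2 / 3,
                                                `100` = 1)) {
  stopifnot(identical(sort(names(blends)), sort(names(factors))))
  comp <- unique(unlist(lapply(blends, function(b) b$ingredients)))
  rows <- c(comp, "fish_meal")
  diets <- c("Control",
             unlist(lapply(names(blends), function(b) {
               paste0(b, names(fractions))
             })))
  out <- matrix(0, nrow = length(rows), ncol = length(diets),
                dimnames = list(rows, diets))
  out["fish_meal", "Control"] <- fm_base
  for (b in names(blends)) {
    for (f in names(fractions)) {
      inc <- blend_inclusions(fm_base, fractions[[f]], blends[[b]],
                              factors[[b]])
      out[names(inc), paste0(b, f)] <- inc
    }
  }
  out
}
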