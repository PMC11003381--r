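# Packaged fixtures: the ten experimental diets of the gibel carp
# fishmeal-replacement trial (ingredient inclusions, amino-acid compositions,
# EAA requirements, growth summaries, apparent digestibility coefficients),
# plus a synthetic set of ingredient amino-acid profiles for the formulation
# engine and the trial simulator. All fixtures are plain TSV under extdata.

.at_extdata <- function(file) {
  path <- system.file("extdata", file, package = "aquatrial")
  if (!nzchar(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

.read_numeric_matrix <- function(path, key_col) {
  tab <- .read_delim_table(path)
  keys <- tab[[key_col]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "character"
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  if (any(is.na(num))) stop("non-numeric cell in fixture ", path, call. = FALSE)
  rownames(num) <- keys
  num
}

#' Diet names of the packaged feeding trial
#'
#' The ten diets: a 15% fishmeal control and three blends (A, B, C, differing
#' in the ratio of the four alternative protein sources) each replacing 33%,
#' 67% or 100% of the fishmeal on a protein-equivalent basis.
#'
#' @return Character vector of length 10.
#' @export
trial_diet_names <- function() {
  c("Control", "A33", "A67", "A100", "B33", "B67", "B100",
    "C33", "C67", "C100")
}

#' Default EAA requirement set for gibel carp
#'
#' The nine EAA requirement levels (% of dry matter) used as denominators of
#' the protein-quality indices: lysine 3.30, methionine 0.89, threonine 1.70,
#' arginine 1.50, leucine 1.80, isoleucine 1.30, valine 1.70, phenylalanine
#' 1.10, histidine 0.80, each with its literature source tag.
#'
#' @return A [requirement_set()].
#' @export
gibel_requirements <- function() {
  read_requirements(.at_extdata("requirements.tsv"))
}

#' Complete packaged dataset of the ten printed diets
#'
#' Loads every packaged fixture of the trial and returns them keyed by diet
#' name: ingredient inclusions, proximate composition, amino-acid
#' compositions, the published protein-quality indices, the EAA requirement
#' set, per-substance apparent digestibility coefficients, and the growth /
#' feed-utilization summary. Basic integrity checks (diet count, inclusion
#' closure to 100%) guard against corrupted fixtures.
#'
#' @return A list with elements `inclusions` (ingredient x diet matrix, % DM),
#'   `proximate` (component x diet matrix), `aa` (named list of
#'   [aa_vector()]s), `indices` (published EAAI/DEAAI matrix),
#'   `requirements` ([requirement_set()]), `adc` (substance x diet matrix, %),
#'   `growth` (data frame, one row per diet), and `diets` (diet names).
#' @export
paper_fixture <- function() {
  inclusions <- .read_numeric_matrix(.at_extdata("table1_ingredients.tsv"),
                                     "ingredient")
  proximate <- .read_numeric_matrix(.at_extdata("table1_proximate.tsv"),
                                    "component")
  aa <- read_aa_table(.at_extdata("table2_amino_acids.tsv"))
  indices <- .read_numeric_matrix(.at_extdata("table2_indices.tsv"), "index")
  adc <- .read_numeric_matrix(.at_extdata("table7_adc.tsv"), "substance")
  growth <- utils::read.table(.at_extdata("table4_growth.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  diets <- trial_diet_names()
  ok <- identical(colnames(inclusions), diets) &&
    identical(names(aa), diets) &&
    identical(colnames(adc), diets) &&
    identical(growth$diet, diets) &&
    all(abs(colSums(inclusions) - 100) < 1e-8)
  if (!ok) stop("packaged trial fixtures failed integrity checks",
                call. = FALSE)
  list(inclusions = inclusions, proximate = proximate, aa = aa,
       indices = indices, requirements = gibel_requirements(), adc = adc,
       growth = growth, diets = diets)
}

#' Synthetic ingredient profiles
#'
#' Amino-acid and proximate profiles for the seven protein ingredients of the
#' trial (fishmeal, *Tenebrio molitor* meal, *Chlorella* meal, *Clostridium
#' autoethanogenum* protein, cottonseed protein concentrate, rapeseed meal,
#' soybean meal). The trial publication does not print per-ingredient
#' amino-acid compositions, so these are synthetic profiles assembled from
#' typical feed-table values; they drive the formulation engine and the
#' trial simulator, not the reproduction of printed diet compositions.
#'
#' @return Named list of ingredient profiles, each a list with `name`,
#'   `crude_protein`, `crude_lipid` (% DM) and `aa` (an [aa_vector()]).
#' @export
synthetic_ingredients <- function() {
  tab <- .read_delim_table(.at_extdata("synthetic_ingredients.tsv"))
  out <- vector("list", nrow(tab))
  names(out) <- tab$name
  aa_cols <- setdiff(names(tab), c("name", "crude_protein", "crude_lipid"))
  for (i in seq_len(nrow(tab))) {
    aa <- suppressWarnings(as.numeric(tab[i, aa_cols]))
    names(aa) <- aa_cols
    out[[i]] <- ingredient_profile(
      name = tab$name[i],
      crude_protein = as.numeric(tab$crude_protein[i]),
      crude_lipid = as.numeric(tab$crude_lipid[i]),
      aa = aa_vector(aa)
    )
  }
  out
}

#' Blend specifications of the packaged trial
#'
#' The three blends of *T. molitor* meal : *Chlorella* meal : *C.
#' autoethanogenum* protein : cottonseed protein concentrate, at ratio parts
#' 1:1:8:2 (blend A), 1:1:6:4 (blend B) and 1:1:4:6 (blend C).
#'
#' @return Named list of three [blend_spec()]s (`A`, `B`, `C`).
#' @export
trial_blends <- function() {
  list(
    A = blend_spec(c(t_molitor_meal = 1, chlorella_meal = 1, cap = 8, cpc = 2)),
    B = blend_spec(c(t_molitor_meal = 1, chlorella_meal = 1, cap = 6, cpc = 4)),
    C = blend_spec(c(t_molitor_meal = 1, chlorella_meal = 1, cap = 4, cpc = 6))
  )
}

#' Protein-equivalence factors of the packaged trial
#'
#' The mass of each blend that replaces unit mass of fishmeal so the diet
#' stays isonitrogenous. The publication does not print these factors; they
#' are back-derived from the printed ingredient-inclusion columns (e.g. blend
#' A at 100% replacement sums to 13.68% DM against a 15% fishmeal base, so
#' 13.68/15 = 0.912) and shipped as constants. Use [equivalence_factor()] to
#' derive factors from ingredient crude-protein values instead.
#'
#' @return Named numeric vector (`A`, `B`, `C`).
#' @export
trial_blend_factors <- function() c(A = 0.912, B = 0.96, C = 1.008)
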