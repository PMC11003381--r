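# Canonical amino-acid naming, composition vectors, and requirement sets.
#
# The canonical set has 17 names: 9 essential amino acids (EAA) and 8
# nonessential (NEAA). Tryptophan is deliberately absent: the protein-quality
# indices computed downstream use exactly these nine EAAs (n = 9), so the
# partition is fixed here once and queried everywhere else. The asparagine
# entry is pooled Asx (asparagine + aspartate), as acid hydrolysis reports it.

#' Canonical essential amino acids
#'
#' The nine essential amino acids (EAA) used throughout the package, in the
#' conventional reporting order. Tryptophan is excluded: all quality indices
#' in this package are geometric means over exactly these nine EAAs, matching
#' the requirement sets available for cyprinid fish (tryptophan is destroyed
#' by acid hydrolysis and is rarely reported alongside the others).
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' eaa_names()
eaa_names <- function() {
  c("lysine", "methionine", "threonine", "arginine", "leucine",
    "isoleucine", "valine", "phenylalanine", "histidine")
}

#' Canonical nonessential amino acids
#'
#' The eight nonessential amino acids (NEAA) tracked by the package. The
#' `asparagine` entry is pooled Asx (asparagine + aspartate) as produced by
#' acid hydrolysis; no attempt is made to split it.
#'
#' @return Character vector of length 8.
#' @export
neaa_names <- function() {
  c("asparagine", "serine", "glutamic_acid", "glycine", "alanine",
    "tyrosine", "proline", "cysteine")
}

#' All canonical amino-acid names
#'
#' @return Character vector of length 17 (EAA first, then NEAA).
#' @export
aa_names <- function() c(eaa_names(), neaa_names())

# fixed alias map: common 3-letter codes and spelling variants -> canonical
.aa_aliases <- c(
  lys = "lysine", met = "methionine", thr = "threonine", arg = "arginine",
  leu = "leucine", ile = "isoleucine", val = "valine", phe = "phenylalanine",
  his = "histidine", asn = "asparagine", asx = "asparagine",
  asp = "asparagine", ser = "serine", glu = "glutamic_acid",
  glx = "glutamic_acid", gly = "glycine", ala = "alanine", tyr = "tyrosine",
  pro = "proline", cys = "cysteine",
  "glutamic acid" = "glutamic_acid", glutamate = "glutamic_acid",
  aspartate = "asparagine"
)

#' Resolve amino-acid names to canonical form
#'
#' Accepts canonical lower-case full names, common 3-letter abbreviations
#' (`"Lys"`, `"glu"`, ...) and a few spelling variants, case-insensitively.
#'
#' @param x Character vector of amino-acid names.
#' @return Character vector of canonical names.
#' @export
#' @examples
#' canonical_aa(c("Lys", "glutamic acid", "histidine"))
canonical_aa <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- ifelse(key %in% aa_names(), key, unname(.aa_aliases[key]))
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown amino-acid name(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct an amino-acid composition vector
#'
#' A named numeric vector of amino-acid contents in % of dry matter, with
#' names restricted to the canonical 17-name set (see [aa_names()]). Names
#' are resolved through the alias map, so 3-letter codes are accepted.
#'
#' @param x Named numeric vector of contents (% DM); all values must be
#'   finite and non-negative.
#' @return A named numeric vector of class `aa_vector`.
#' @export
#' @examples
#' aa_vector(c(lysine = 2.16, met = 0.56))
aa_vector <- function(x) {
  if (length(x) == 0) {
    out <- numeric(0)
    names(out) <- character(0)
    class(out) <- c("aa_vector", "numeric")
    return(out)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("aa_vector requires a fully named numeric vector", call. = FALSE)
  }
  nm <- canonical_aa(names(x))
  if (anyDuplicated(nm)) {
    stop("duplicated amino-acid entries: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  v <- as.numeric(x)
  if (any(!is.finite(v))) stop("non-finite amino-acid content", call. = FALSE)
  if (any(v < 0)) {
    stop("negative amino-acid content for: ",
         paste(nm[v < 0], collapse = ", "), call. = FALSE)
  }
  names(v) <- nm
  class(v) <- c("aa_vector", "numeric")
  v
}

#' Extract the essential amino acids from a composition vector
#'
#' Returns the subset of the nine canonical EAAs present in `v`, in the
#' canonical order. NEAA entries are dropped.
#'
#' @param v An [aa_vector()] (or coercible named numeric vector).
#' @return An `aa_vector` with at most 9 entries.
#' @export
eaa_subset <- function(v) {
  v <- aa_vector(v)
  keep <- intersect(eaa_names(), names(v))
  aa_vector(v[keep])
}

#' Extract the nonessential amino acids from a composition vector
#'
#' @param v An [aa_vector()].
#' @return An `aa_vector` with at most 8 entries.
#' @export
neaa_subset <- function(v) {
  v <- aa_vector(v)
  keep <- intersect(neaa_names(), names(v))
  aa_vector(v[keep])
}

#' Is an amino acid essential?
#'
#' @param x Character vector of amino-acid names (aliases accepted).
#' @return Logical vector.
#' @export
is_eaa <- function(x) canonical_aa(x) %in% eaa_names()

#' Construct a requirement set
#'
#' An EAA requirement set holds the dietary requirement level (% of dry
#' matter) for each of the nine canonical EAAs; these are the denominators of
#' the protein-quality indices. Exactly nine strictly positive entries are
#' required.
#'
#' @param requirements Named numeric vector covering all nine EAAs (% DM,
#'   all > 0). Aliases accepted.
#' @param source_labels Optional character vector (same names) of free-text
#'   citation tags for each entry.
#' @return A list of class `requirement_set` with elements `requirements`
#'   (named numeric, canonical EAA order) and `source_labels`.
#' @export
requirement_set <- function(requirements, source_labels = NULL) {
  v <- aa_vector(requirements)
  missing <- setdiff(eaa_names(), names(v))
  if (length(missing) > 0) {
    stop("requirement set is missing EAA(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(v), eaa_names())
  if (length(extra) > 0) {
    stop("requirement set may contain only the 9 EAAs; got also: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  v <- v[eaa_names()]
  if (any(v <= 0)) stop("all requirements must be > 0", call. = FALSE)
  labels <- rep(NA_character_, 9)
  names(labels) <- eaa_names()
  if (!is.null(source_labels)) {
    nm <- canonical_aa(names(source_labels))
    labels[nm] <- as.character(source_labels)
  }
  structure(list(requirements = unclass(v)[eaa_names()],
                 source_labels = labels),
            class = "requirement_set")
}

#' @export
print.requirement_set <- function(x, ...) {
  cat("EAA requirement set (% of dry matter):\n")
  print(round(x$requirements, 2))
  invisible(x)
}

# ---- delimited-table I/O ----------------------------------------------------

.read_delim_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' Read a table of amino-acid compositions
#'
#' Reads a delimited table (tab- or comma-separated, chosen by file
#' extension) whose first column holds amino-acid names and whose remaining
#' header columns are diet (or ingredient) names, one column per diet.
#' Every cell must be a finite, non-negative number; unknown amino-acid
#' names are rejected.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file with a
#'   header row.
#' @return Named list mapping each diet name to an [aa_vector()].
#' @export
read_aa_table <- function(path) {
  tab <- .read_delim_table(path)
  if (ncol(tab) < 1) stop("table has no columns: ", path, call. = FALSE)
  aa <- canonical_aa(tab[[1]])
  diets <- names(tab)[-1]
  out <- vector("list", length(diets))
  names(out) <- diets
  for (d in diets) {
    raw <- tab[[d]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                   raw[bad[1]], aa[bad[1]], d, path), call. = FALSE)
    }
    neg <- which(val < 0)
    if (length(neg) > 0) {
      stop(sprintf("negative content at row '%s', column '%s' in %s",
                   aa[neg[1]], d, path), call. = FALSE)
    }
    names(val) <- aa
    out[[d]] <- aa_vector(val)
  }
  out
}

#' Write amino-acid compositions to a delimited table
#'
#' Inverse of [read_aa_table()]: writes a header of diet names and one row
#' per amino acid, at full stored precision (up to 15 significant digits),
#' so a write/read round trip reproduces the contents exactly.
#'
#' @param x Named list of [aa_vector()]s (one per diet), all sharing the same
#'   amino acids.
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @return `path`, invisibly.
#' @export
write_aa_table <- function(x, path) {
  stopifnot(is.list(x), length(x) > 0, !is.null(names(x)))
  rows <- names(x[[1]])
  for (v in x) {
    if (!identical(names(v), rows)) {
      stop("all diets must list the same amino acids in the same order",
           call. = FALSE)
    }
  }
  mat <- vapply(x, function(v) sprintf("%.17g", unclass(v)),
                character(length(rows)))
  df <- data.frame(amino_acid = rows, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a requirement set from a delimited table
#'
#' Expects columns `amino_acid`, `requirement` and optionally `source`.
#'
#' @param path Path to the table.
#' @return A [requirement_set()].
#' @export
read_requirements <- function(path) {
  tab <- .read_delim_table(path)
  req <- suppressWarnings(as.numeric(tab$requirement))
  if (any(is.na(req))) stop("non-numeric requirement in ", path, call. = FALSE)
  names(req) <- tab$amino_acid
  labels <- if ("source" %in% names(tab)) {
    stats::setNames(tab$source, tab$amino_acid)
  } else NULL
  requirement_set(req, labels)
}
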