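# End-to-end analysis driver: formulation check, protein-quality indices,
# digestibility, performance summary with Duncan letters, and dose-response
# fits, from either the packaged trial tables or a generated dataset.

#' Run the full feeding-trial analysis
#'
#' Sequences every analysis stage over a trial dataset:
#' 1. quality indices — EAAI and DEAAI per diet from the amino-acid
#'    compositions and per-EAA ADCs;
#' 2. digestibility — per-substance ADCs recomputed from assay tables when
#'    present, otherwise the supplied ADC matrix is passed through;
#' 3. performance — per-diet mean +/- SE of every growth index with Duncan
#'    letters when cage-level records are present; skipped with a warning
#'    when they are absent or empty (printed summary tables cannot be
#'    re-lettered without replicates);
#' 4. dose response — linear-plateau fit of SGR (and FE, PRE when available)
#'    against DEAAI, and an ordinary linear fit of SGR against the
#'    crude-protein ADC.
#'
#' Given identical inputs the report is identical: every stage is
#' deterministic.
#'
#' @param trial A list like [paper_fixture()] or [generate_trial()] output:
#'   must contain `aa`; optionally `adc` (substance x diet matrix),
#'   `adc_assays` (long assay table), `cage_records`, `growth` (per-diet
#'   summary with columns `diet`, `ibw`, `fbw`, `sgr`, ...).
#' @param requirements A [requirement_set()].
#' @param alpha Significance level for the letter display.
#' @param outdir Optional directory; when given, each report table is written
#'   there as a TSV (2-dp rounding happens only here, at render time).
#' @return List of class `trial_report`: `quality`, `adc`, `performance`
#'   (or `NULL`), `letters` (or `NULL`), `fits`.
#' @export
run_full_analysis <- function(trial, requirements = gibel_requirements(),
                              alpha = 0.05, outdir = NULL) {
  if (is.null(trial$aa)) stop("trial$aa is required", call. = FALSE)

  # digestibility stage
  adc_tab <- if (!is.null(trial$adc_assays) && nrow(trial$adc_assays) > 0) {
    recover_adc(trial$adc_assays)
  } else if (!is.null(trial$adc)) {
    trial$adc
  } else {
    stop("need either adc_assays or an adc matrix", call. = FALSE)
  }

  # quality stage
  quality <- quality_index_table(trial$aa, adc_tab, requirements)

  # performance stage
  performance <- NULL
  letters_tab <- NULL
  if (!is.null(trial$cage_records) && length(trial$cage_records) > 0) {
    performance <- summarize_performance(trial$cage_records)
    per_cage <- data.frame(
      diet = vapply(trial$cage_records, function(r) r$diet, character(1)),
      sgr = vapply(trial$cage_records, specific_growth_rate, numeric(1)),
      fe = vapply(trial$cage_records, feed_efficiency, numeric(1))
    )
    letters_tab <- lapply(c(sgr = "sgr", fe = "fe"), function(v) {
      duncan_mrt(per_cage[[v]], per_cage$diet, alpha = alpha)
    })
  } else if (!is.null(trial$growth) && nrow(trial$growth) > 0) {
    g <- trial$growth
    g$sgr_recomputed <- 100 * (log(g$fbw) - log(g$ibw)) / 56
    performance <- g
  } else {
    warning("no cage records or growth summary; performance stage skipped",
            call. = FALSE)
  }

  # dose-response stage
  sgr_by_diet <- NULL
  fe_by_diet <- NULL
  pre_by_diet <- NULL
  if (!is.null(trial$cage_records) && length(trial$cage_records) > 0) {
    agg <- performance
    pick <- function(ix) {
      v <- agg[agg$index == ix, ]
      stats::setNames(v$mean, v$diet)[quality$diet]
    }
    sgr_by_diet <- pick("sgr")
    fe_by_diet <- pick("fe")
    pre_by_diet <- tryCatch(pick("pre"), error = function(e) NULL)
  } else if (!is.null(trial$growth) && nrow(trial$growth) > 0) {
    g <- trial$growth
    sgr_by_diet <- stats::setNames(g$sgr, g$diet)[quality$diet]
    if ("fe" %in% names(g)) fe_by_diet <- stats::setNames(g$fe, g$diet)[quality$diet]
    if ("pre" %in% names(g)) pre_by_diet <- stats::setNames(g$pre, g$diet)[quality$diet]
  }
  fits <- list()
  if (!is.null(sgr_by_diet) && all(is.finite(sgr_by_diet))) {
    fits$sgr_vs_deaai <- fit_linear_plateau(quality$deaai, sgr_by_diet)
    if ("crude_protein" %in% rownames(adc_tab)) {
      fits$sgr_vs_adc_cp <- fit_linear(adc_tab["crude_protein",
                                               quality$diet], sgr_by_diet)
    }
    if (!is.null(fe_by_diet) && all(is.finite(fe_by_diet))) {
      fits$fe_vs_deaai <- fit_linear_plateau(quality$deaai, fe_by_diet)
    }
    if (!is.null(pre_by_diet) && all(is.finite(pre_by_diet))) {
      fits$pre_vs_deaai <- fit_linear_plateau(quality$deaai, pre_by_diet)
    }
    if (all(c("dry_matter", "crude_protein") %in% rownames(adc_tab))) {
      fits$adc_cp_vs_adc_dm <- fit_linear_plateau(
        adc_tab["dry_matter", quality$diet],
        adc_tab["crude_protein", quality$diet])
    }
  }

  report <- structure(list(quality = quality, adc = adc_tab,
                           performance = performance,
                           letters = letters_tab, fits = fits),
                      class = "trial_report")
  if (!is.null(outdir)) write_trial_report(report, outdir)
  report
}

#' Write a trial report to delimited files
#'
#' Renders each report table as a TSV under `outdir` (created if needed),
#' rounding to 2 decimals at render time only, plus a plain-text summary of
#' the regression fits. Timestamp-free, so re-running on identical inputs
#' yields byte-identical files.
#'
#' @param report A `trial_report` from [run_full_analysis()].
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_trial_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = 2)
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(report$quality, "quality_indices.tsv")
  adc_df <- data.frame(substance = rownames(report$adc),
                       round(report$adc, 2), check.names = FALSE)
  utils::write.table(adc_df, file.path(outdir, "adc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$performance)) wr(report$performance, "performance.tsv")
  if (!is.null(report$letters)) {
    let_df <- do.call(rbind, lapply(names(report$letters), function(v) {
      d <- report$letters[[v]]
      data.frame(index = v, diet = names(d$means),
                 mean = round(d$means, 2), letters = d$letters,
                 row.names = NULL)
    }))
    utils::write.table(let_df, file.path(outdir, "duncan_letters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  lines <- unlist(lapply(names(report$fits), function(nm) {
    f <- report$fits[[nm]]
    if (inherits(f, "broken_line_fit")) {
      sprintf("%s: breakpoint=%.3f slope=%.4f plateau=%.4f rss=%.6g r2=%.4f",
              nm, f$breakpoint, f$slope, f$plateau, f$rss, f$r2)
    } else {
      sprintf("%s: slope=%.4f intercept=%.4f r2=%.4f p=%.4g",
              nm, f$slope, f$intercept, f$r2, f$p_slope)
    }
  }))
  writeLines(lines, file.path(outdir, "fits.txt"))
  invisible(outdir)
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Trial report\n============\n\nQuality indices:\n")
  q <- x$quality
  q$eaai <- round(q$eaai, 2)
  q$deaai <- round(q$deaai, 2)
  print(q)
  if (length(x$fits) > 0) {
    cat("\nDose-response fits:\n")
    for (nm in names(x$fits)) {
      cat(" ", nm, ": ", sep = "")
      print(x$fits[[nm]])
    }
  }
  invisible(x)
}
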