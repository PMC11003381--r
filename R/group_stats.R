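# Group statistics: one-way ANOVA, Duncan's multiple range test with a
# compact letter display (the superscript letters of trial summary tables),
# Levene's homogeneity test, and reference-gene-normalized qPCR relative
# expression.

.check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups lengths differ", call. = FALSE)
  }
  groups <- as.character(groups)
  keep <- is.finite(values)
  values <- values[keep]
  groups <- groups[keep]
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs >= 2 observations; too few in: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  list(values = values, groups = groups)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via [stats::aov()]. If all
#' observations are identical the F statistic is undefined and the result is
#' flagged degenerate instead of erroring.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length.
#' @return List: `f` (F statistic), `p` (p-value), `mse` (pooled within-group
#'   variance), `df_error`, `df_between`, `means` (named group means),
#'   `n` (named group sizes), `degenerate` (flag).
#' @export
one_way_anova <- function(values, groups) {
  g <- .check_groups(values, groups)
  means <- tapply(g$values, g$groups, mean)
  n <- table(g$groups)
  df_error <- length(g$values) - length(means)
  df_between <- length(means) - 1L
  if (diff(range(g$values)) == 0) {
    return(list(f = NA_real_, p = NA_real_, mse = 0, df_error = df_error,
                df_between = df_between, means = means,
                n = stats::setNames(as.integer(n), names(n)),
                degenerate = TRUE))
  }
  tab <- stats::anova(stats::lm(g$values ~ factor(g$groups)))
  mse <- tab$`Mean Sq`[2]
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  degenerate <- !is.finite(f) || mse == 0
  list(f = if (degenerate) NA_real_ else f,
       p = if (degenerate) NA_real_ else p,
       mse = mse, df_error = df_error, df_between = df_between,
       means = means, n = stats::setNames(as.integer(n), names(n)),
       degenerate = degenerate)
}

#' Levene's test of homogeneity of variances (median-centered)
#'
#' Brown–Forsythe variant via [car::leveneTest()]. Reported alongside the
#' ANOVA but not used as a gate.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @return List with `f`, `p`, `df`.
#' @export
levene_test <- function(values, groups) {
  g <- .check_groups(values, groups)
  lt <- car::leveneTest(g$values, factor(g$groups), center = stats::median)
  list(f = lt[1, "F value"], p = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]))
}

# compact letter display from a symmetric non-significance relation over
# means sorted ascending: maximal runs of mutually non-different groups get
# one letter each. Duncan's step-down procedure only ever declares contiguous
# spans (in the sorted order) non-significant, so runs suffice.
.letters_from_spans <- function(k, nonsig) {
  spans <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    spans[[length(spans) + 1]] <- c(i, j)
  }
  spans <- unique(spans)
  # drop spans contained in another
  keep <- vapply(seq_along(spans), function(a) {
    !any(vapply(seq_along(spans), function(b) {
      b != a && spans[[b]][1] <= spans[[a]][1] && spans[[a]][2] <= spans[[b]][2]
    }, logical(1)))
  }, logical(1))
  spans <- spans[keep]
  ord <- order(vapply(spans, `[`, numeric(1), 1))
  spans <- spans[ord]
  letters_out <- rep("", k)
  for (s in seq_along(spans)) {
    idx <- spans[[s]][1]:spans[[s]][2]
    letters_out[idx] <- paste0(letters_out[idx], letters[s])
  }
  letters_out
}

#' Duncan's multiple range test with compact letter display
#'
#' Step-down range procedure on the sorted group means: a span of `p`
#' adjacent means is declared non-significant when its range does not exceed
#' the critical range `R_p = q(1 - alpha_p, p, df_error) * sqrt(mse / n_h)`,
#' where `q` is the studentized-range quantile, `alpha_p = 1 - (1 - alpha)^(p-1)`
#' is Duncan's protection level, and `n_h` is the harmonic mean group size
#' (Kramer adjustment for unequal sizes). Spans are tested from the widest
#' down; all comparisons inside a non-significant span are shielded. Groups
#' that are not significantly different share a letter. With two groups the
#' procedure is exactly the pooled two-sample t-test at level `alpha`.
#'
#' Letters are assigned over means sorted in decreasing order ("a" = highest
#' mean), matching the usual trial-table convention.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @param alpha Significance level in (0, 0.5); default 0.05.
#' @return A list of class `duncan_result`: `means` (sorted decreasing),
#'   `letters` (map group -> letter string), `significant` (logical matrix of
#'   pairwise decisions), `critical_ranges`, `mse`, `df_error`, `alpha`,
#'   `degenerate`.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 0.5) {
    stop("alpha must be in (0, 0.5)", call. = FALSE)
  }
  av <- one_way_anova(values, groups)
  means_sorted <- sort(av$means, decreasing = FALSE)  # ascending for spans
  k <- length(means_sorted)
  nm <- names(means_sorted)
  nonsig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  diag(nonsig) <- TRUE
  n_h <- length(av$n) / sum(1 / av$n)
  crit <- rep(NA_real_, k)
  if (av$degenerate) {
    nonsig[, ] <- TRUE
  } else {
    se <- sqrt(av$mse / n_h)
    for (p in 2:k) {
      alpha_p <- 1 - (1 - alpha)^(p - 1)
      crit[p] <- stats::qtukey(1 - alpha_p, p, av$df_error) * se
    }
    for (p in k:2) {
      for (i in 1:(k - p + 1)) {
        j <- i + p - 1
        if (nonsig[i, j]) next  # shielded by a wider non-significant span
        if (means_sorted[j] - means_sorted[i] <= crit[p]) {
          nonsig[i:j, i:j] <- TRUE
        }
      }
    }
  }
  letters_asc <- .letters_from_spans(k, nonsig)
  # report decreasing (highest mean = "a"): reverse order, relabel letters
  ord_desc <- k:1
  lab <- letters_asc[ord_desc]
  seen <- unique(unlist(strsplit(lab, "")))
  relabel <- stats::setNames(letters[seq_along(seen)], seen)
  lab <- vapply(strsplit(lab, ""), function(ch)
    paste(sort(relabel[ch]), collapse = ""), character(1))
  means_desc <- means_sorted[ord_desc]
  structure(list(means = means_desc,
                 letters = stats::setNames(lab, names(means_desc)),
                 significant = !nonsig[ord_desc, ord_desc],
                 critical_ranges = crit,
                 mse = av$mse, df_error = av$df_error, n_harmonic = n_h,
                 alpha = alpha, degenerate = av$degenerate),
            class = "duncan_result")
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %.2f):\n", x$alpha))
  print(data.frame(mean = round(x$means, 4), letters = x$letters))
  invisible(x)
}

#' Reference-gene-normalized qPCR relative expression
#'
#' For each sample, the raw relative quantity of the target is
#' `efficiency^(-ct_target)` divided by the geometric mean over the reference
#' genes of `efficiency^(-ct_ref)` (multi-reference normalization in the
#' geNorm manner). Quantities are then rescaled so the mean of the calibrator
#' group equals 1.
#'
#' @param ct_target Numeric vector of target-gene Ct values, one per sample.
#' @param ct_refs Numeric matrix (samples x reference genes) — or a vector if
#'   a single reference gene — of reference Ct values.
#' @param group Group labels, one per sample.
#' @param calibrator Label of the calibrator group (default the first).
#' @param efficiency Amplification factor per cycle, in (1, 2.2]; default 2
#'   (perfect doubling).
#' @return Numeric vector of normalized relative quantities, one per sample;
#'   mean over the calibrator group is 1.
#' @export
relative_expression <- function(ct_target, ct_refs, group,
                                calibrator = NULL, efficiency = 2) {
  if (!is.finite(efficiency) || efficiency <= 1 || efficiency > 2.2) {
    stop("efficiency must be in (1, 2.2]", call. = FALSE)
  }
  if (is.vector(ct_refs)) ct_refs <- matrix(ct_refs, ncol = 1)
  if (ncol(ct_refs) < 1) stop("need at least one reference gene", call. = FALSE)
  if (nrow(ct_refs) != length(ct_target)) {
    stop("ct_refs rows must match ct_target length", call. = FALSE)
  }
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_refs))) {
    stop("non-finite Ct value", call. = FALSE)
  }
  if (any(c(ct_target, ct_refs) <= 0) || any(c(ct_target, ct_refs) >= 45)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  group <- as.character(group)
  if (is.null(calibrator)) calibrator <- group[1]
  if (!calibrator %in% group) {
    stop("calibrator group not present: ", calibrator, call. = FALSE)
  }
  # log-scale arithmetic: log_E(raw RQ) = mean(ct_refs) - ct_target
  rq <- efficiency^(rowMeans(ct_refs) - ct_target)
  rq / mean(rq[group == calibrator])
}
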