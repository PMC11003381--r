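# Synthetic feeding-trial generator with known ground truth.
#
# The generator emulates the structure of the packaged trial — ten diets
# (one fishmeal control, three blends x three replacement levels), three
# cages of 70 fish per diet, 56 days — so that every pipeline stage can be
# exercised end to end and checked against the truth used to simulate:
#
#   * diets are formulated through the formulation engine;
#   * each diet's true DEAAI is computed from its true amino-acid contents
#     and true per-AA ADCs;
#   * cage mean SGR is drawn from a linear-plateau response to true DEAAI
#     plus normal noise;
#   * feces compositions follow marker mass balance — the indigestible
#     marker concentrates in feces exactly as dry matter disappears — with
#     multiplicative lognormal assay noise, so the marker-ratio ADC
#     recomputed by the pipeline returns the true ADC exactly in noiseless
#     mode;
#   * qPCR Ct values carry additive normal noise around group means with a
#     constant reference gene.
#
# One seed fixes everything; each table type draws from its own derived
# substream so adding a table never perturbs the draws of another.

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 2039 + 101 * k) %% 2147483647L
}

#' Configuration of a synthetic feeding trial
#'
#' Defaults mirror the packaged study: 10 diets, 3 cages of 70 fish, 56
#' days, true amino-acid compositions and per-AA ADCs taken from the
#' packaged diet tables, growth responding to DEAAI through a linear-plateau
#' curve with breakpoint 79.5% DEAAI, plateau SGR 2.46 %/d and rising slope
#' 0.25 (%/d per DEAAI unit), cage-mean SGR noise sd 0.03 %/d, 2% lognormal
#' CV on fecal assay concentrations, 0.2-cycle Ct noise.
#'
#' @param n_cages Cages per diet.
#' @param n_fish Fish per cage at stocking.
#' @param days Trial duration (d).
#' @param fm_base Fishmeal inclusion of the control diet (% DM).
#' @param blends,factors,fractions Passed to [formulate_trial_diets()].
#' @param ingredients Named list of [ingredient_profile()]s.
#' @param true_aa Named list of [aa_vector()]s: true diet compositions.
#' @param true_adc Substance x diet matrix of true ADCs (%); must contain the
#'   nine EAA rows plus `dry_matter` and `crude_protein`.
#' @param requirements A [requirement_set()].
#' @param target_deaai Optional named numeric vector of per-diet DEAAI values;
#'   when given, each diet's EAA ADCs are rescaled by a common factor so its
#'   true DEAAI equals the target exactly (composition unchanged).
#' @param breakpoint,plateau_sgr,rise_slope Growth model: cage-mean SGR is
#'   `plateau_sgr - rise_slope * max(0, breakpoint - DEAAI)` plus noise.
#' @param sgr_sd SD of cage-mean SGR noise (%/d); 0 gives noiseless growth.
#' @param ibw_mean,ibw_sd Cage-mean initial body weight (g) and its SD.
#' @param feeding_rate True feeding rate (%BW/d).
#' @param survival_prob Per-fish survival probability.
#' @param crude_protein Dietary crude protein (% DM) used for protein intake.
#' @param body_protein_frac Protein fraction of wet weight gain.
#' @param marker_diet Marker (Y2O3) inclusion (% DM).
#' @param assay_cv Lognormal CV of fecal concentration assays; 0 = noiseless.
#' @param ct_sd SD of Ct noise (cycles); 0 = noiseless.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(n_cages = 3, n_fish = 70, days = 56, fm_base = 15,
                         blends = trial_blends(),
                         factors = trial_blend_factors(),
                         fractions = c(`33` = 1 / 3, `67` = 2 / 3, `100` = 1),
                         ingredients = synthetic_ingredients(),
                         true_aa = NULL, true_adc = NULL,
                         requirements = gibel_requirements(),
                         target_deaai = NULL,
                         breakpoint = 79.5, plateau_sgr = 2.46,
                         rise_slope = 0.25, sgr_sd = 0.03,
                         ibw_mean = 15.18, ibw_sd = 0.10,
                         feeding_rate = 3.0, survival_prob = 0.96,
                         crude_protein = 34.2, body_protein_frac = 0.169,
                         marker_diet = 0.10, assay_cv = 0.02, ct_sd = 0.2) {
  fx <- paper_fixture()
  if (is.null(true_aa)) true_aa <- fx$aa
  if (is.null(true_adc)) true_adc <- fx$adc
  stopifnot(n_cages >= 1, n_fish >= 1, days > 0, fm_base > 0,
            sgr_sd >= 0, assay_cv >= 0, ct_sd >= 0,
            survival_prob > 0, survival_prob <= 1,
            all(eaa_names() %in% rownames(true_adc)),
            all(c("dry_matter", "crude_protein") %in% rownames(true_adc)))
  diets <- names(true_aa)
  if (!is.null(target_deaai)) {
    if (is.null(names(target_deaai))) {
      stop("target_deaai must be named by diet", call. = FALSE)
    }
    for (d in names(target_deaai)) {
      cur <- deaai(true_aa[[d]], true_adc[eaa_names(), d], requirements)$value
      true_adc[eaa_names(), d] <- true_adc[eaa_names(), d] *
        (target_deaai[[d]] / cur)
    }
  }
  cfg <- list(n_cages = n_cages, n_fish = n_fish, days = days,
              fm_base = fm_base, blends = blends, factors = factors,
              fractions = fractions, ingredients = ingredients,
              true_aa = true_aa, true_adc = true_adc,
              requirements = requirements, diets = diets,
              breakpoint = breakpoint, plateau_sgr = plateau_sgr,
              rise_slope = rise_slope, sgr_sd = sgr_sd,
              ibw_mean = ibw_mean, ibw_sd = ibw_sd,
              feeding_rate = feeding_rate, survival_prob = survival_prob,
              crude_protein = crude_protein,
              body_protein_frac = body_protein_frac,
              marker_diet = marker_diet, assay_cv = assay_cv, ct_sd = ct_sd)
  class(cfg) <- "trial_config"
  # breakpoint must lie inside the generated DEAAI range for the growth
  # model to be identifiable
  truth <- vapply(cfg$diets, function(d)
    deaai(true_aa[[d]], true_adc[eaa_names(), d], requirements)$value,
    numeric(1))
  if (breakpoint < min(truth) || breakpoint > max(truth)) {
    stop(sprintf("breakpoint %.2f outside generated DEAAI range [%.2f, %.2f]",
                 breakpoint, min(truth), max(truth)), call. = FALSE)
  }
  cfg$true_deaai <- truth
  cfg
}

#' Generate a complete synthetic feeding-trial dataset
#'
#' Produces every table the analysis stages consume — diet formulation,
#' amino-acid compositions, cage growth records, fecal digestibility assays,
#' morphometrics, qPCR Ct values — together with the ground truth that
#' generated them. Identical seeds give bit-identical datasets.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return List: `inclusions` (blend-ingredient matrix), `aa` (list of
#'   [aa_vector()]s), `cage_records` (list of [cage_record()]s),
#'   `adc_assays` (long data frame: diet, cage, substance, diet_conc,
#'   feces_conc, marker_diet, marker_feces), `morphometrics` (data frame),
#'   `ct` (data frame: diet, cage, gene, ct, plus reference column),
#'   `truth` (list: per-diet `deaai`, `eaai`, `adc` matrix, `sgr_expected`,
#'   and the growth-model parameters).
#' @export
generate_trial <- function(config, seed = 1) {
  stopifnot(inherits(config, "trial_config"))
  cfg <- config
  diets <- cfg$diets
  n_diets <- length(diets)

  inclusions <- formulate_trial_diets(cfg$fm_base, cfg$blends, cfg$factors,
                                      cfg$fractions)
  inclusions <- inclusions[, intersect(colnames(inclusions), diets),
                           drop = FALSE]

  truth_deaai <- cfg$true_deaai
  truth_eaai <- vapply(diets, function(d)
    eaai(cfg$true_aa[[d]], cfg$requirements)$value, numeric(1))
  sgr_expected <- cfg$plateau_sgr -
    cfg$rise_slope * pmax(0, cfg$breakpoint - truth_deaai)

  # --- cage growth records (substream 1) ---
  set.seed(.derive_seed(seed, 1))
  cage_records <- list()
  for (di in seq_along(diets)) {
    for (cg in seq_len(cfg$n_cages)) {
      sgr <- sgr_expected[di] + if (cfg$sgr_sd > 0)
        stats::rnorm(1, 0, cfg$sgr_sd) else 0
      ibw <- cfg$ibw_mean + if (cfg$ibw_sd > 0)
        stats::rnorm(1, 0, cfg$ibw_sd) else 0
      fbw <- ibw * exp(sgr * cfg$days / 100)
      n_final <- if (cfg$survival_prob < 1) {
        stats::rbinom(1, cfg$n_fish, cfg$survival_prob)
      } else cfg$n_fish
      feed <- cfg$feeding_rate / 100 * cfg$days * (ibw + fbw) / 2
      gain <- fbw - ibw
      cage_records[[length(cage_records) + 1]] <- cage_record(
        diet = diets[di], n_initial = cfg$n_fish, n_final = n_final,
        ibw = ibw, fbw = fbw, feed_dm = feed, days = cfg$days,
        dead_weight = 0,
        protein_intake = feed * cfg$crude_protein / 100,
        body_protein_gain = cfg$body_protein_frac * gain,
        basis = "fish"
      )
    }
  }

  # --- fecal digestibility assays (substream 2) ---
  set.seed(.derive_seed(seed, 2))
  substances <- rownames(cfg$true_adc)
  assay_rows <- vector("list", n_diets * cfg$n_cages)
  r <- 0
  sdlog <- if (cfg$assay_cv > 0) sqrt(log(1 + cfg$assay_cv^2)) else 0
  for (di in seq_along(diets)) {
    d <- diets[di]
    adc_dm <- cfg$true_adc["dry_matter", d]
    indig <- 1 - adc_dm / 100          # fraction of ingested DM excreted
    marker_feces_true <- cfg$marker_diet / indig  # marker fully recovered
    diet_conc <- vapply(substances, function(s) {
      if (s == "dry_matter") 100
      else if (s == "crude_protein") cfg$crude_protein
      else if (s %in% names(cfg$true_aa[[d]])) unclass(cfg$true_aa[[d]])[s]
      else NA_real_
    }, numeric(1))
    feces_true <- diet_conc * (1 - cfg$true_adc[, d] / 100) / indig
    feces_true["dry_matter"] <- 100
    for (cg in seq_len(cfg$n_cages)) {
      noise <- if (sdlog > 0) {
        exp(stats::rnorm(length(substances), -sdlog^2 / 2, sdlog))
      } else rep(1, length(substances))
      mnoise <- if (sdlog > 0) exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)) else 1
      keep <- !is.na(diet_conc)
      r <- r + 1
      assay_rows[[r]] <- data.frame(
        diet = d, cage = cg, substance = substances[keep],
        diet_conc = diet_conc[keep],
        feces_conc = ifelse(substances[keep] == "dry_matter", 100,
                            feces_true[keep] * noise[keep]),
        marker_diet = cfg$marker_diet,
        marker_feces = marker_feces_true * mnoise,
        stringsAsFactors = FALSE
      )
    }
  }
  adc_assays <- do.call(rbind, assay_rows)
  rownames(adc_assays) <- NULL

  # --- morphometrics (substream 3) ---
  set.seed(.derive_seed(seed, 3))
  morpho_rows <- list()
  for (di in seq_along(diets)) {
    fbw_mean <- cfg$ibw_mean * exp(sgr_expected[di] * cfg$days / 100)
    for (f in seq_len(3 * cfg$n_cages)) {
      bw <- fbw_mean * exp(stats::rnorm(1, 0, 0.08))
      cf <- 3.2 * exp(stats::rnorm(1, 0, 0.03))
      len <- (100 * bw / cf)^(1 / 3)
      vw <- bw * 0.12 * exp(stats::rnorm(1, 0, 0.05))
      lw <- vw * 0.26 * exp(stats::rnorm(1, 0, 0.08))
      morpho_rows[[length(morpho_rows) + 1]] <- data.frame(
        diet = diets[di], fish = f, body_weight = bw, total_length = len,
        visceral_weight = vw, liver_weight = lw, stringsAsFactors = FALSE)
    }
  }
  morphometrics <- do.call(rbind, morpho_rows)
  rownames(morphometrics) <- NULL

  # --- qPCR Ct table (substream 4) ---
  set.seed(.derive_seed(seed, 4))
  # one illustrative target with a DEAAI-linked expression shift
  log2fc <- (truth_deaai - mean(truth_deaai)) * 0.3
  ct_rows <- list()
  for (di in seq_along(diets)) {
    for (cg in seq_len(2 * cfg$n_cages)) {
      ct_ref <- 18 + if (cfg$ct_sd > 0) stats::rnorm(1, 0, cfg$ct_sd) else 0
      ct_t <- 25 - log2fc[di] +
        if (cfg$ct_sd > 0) stats::rnorm(1, 0, cfg$ct_sd) else 0
      ct_rows[[length(ct_rows) + 1]] <- data.frame(
        diet = diets[di], sample = cg, gene = "pept1",
        ct_target = ct_t, ct_reference = ct_ref, stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, ct_rows)
  rownames(ct) <- NULL

  list(inclusions = inclusions, aa = cfg$true_aa,
       cage_records = cage_records, adc_assays = adc_assays,
       morphometrics = morphometrics, ct = ct,
       truth = list(deaai = truth_deaai, eaai = truth_eaai,
                    adc = cfg$true_adc, sgr_expected = sgr_expected,
                    breakpoint = cfg$breakpoint,
                    plateau_sgr = cfg$plateau_sgr,
                    rise_slope = cfg$rise_slope,
                    log2fc = stats::setNames(log2fc, diets)))
}

#' Recompute per-substance ADCs from a generated assay table
#'
#' Runs the marker-ratio ADC on every (diet, cage, substance) row and
#' averages over cages, i.e. exactly what the digestibility stage of the
#' analysis does on real assay tables.
#'
#' @param adc_assays Long assay data frame as produced by [generate_trial()].
#' @return Substance x diet matrix of mean recomputed ADCs (%).
#' @export
recover_adc <- function(adc_assays) {
  adc_assays$value <- vapply(seq_len(nrow(adc_assays)), function(i) {
    with(adc_assays[i, ], adc(adc_assay(substance, diet_conc, feces_conc,
                                        marker_diet, marker_feces)))
  }, numeric(1))
  tab <- tapply(adc_assays$value,
                list(adc_assays$substance, adc_assays$diet), mean)
  tab[unique(adc_assays$substance), unique(adc_assays$diet), drop = FALSE]
}
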