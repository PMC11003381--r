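#!/usr/bin/env Rscript
# Step 3 — marker-based digestibility on a synthetic trial.
#
# The published feces compositions are not available, so this stage
# demonstrates the digestibility machinery end to end on a simulated trial
# whose true ADCs are the published ones: feces are generated by marker mass
# balance with 2% assay noise, the marker-ratio ADC is recomputed per cage,
# and the recovered values are compared with the generating truth.

library(aquatrial)

dir.create("results", showWarnings = FALSE)

cfg <- trial_config()            # study conditions; assay CV 2%
tr <- generate_trial(cfg, seed = 20240325 %% 1000000)
rec <- recover_adc(tr$adc_assays)
rows <- intersect(rownames(rec), rownames(cfg$true_adc))
err <- rec[rows, cfg$diets] - cfg$true_adc[rows, cfg$diets]

cat(sprintf("Recovered ADCs for %d substances x %d diets (3 cages each).\n",
            length(rows), length(cfg$diets)))
cat(sprintf("Mean absolute recovery error: %.3f ADC points (assay CV %.0f%%)\n",
            mean(abs(err)), 100 * cfg$assay_cv))
cat(sprintf("Largest error: %.3f points\n", max(abs(err))))

# pooled total-EAA ADC per diet from summed concentrations, not mean of ADCs
pooled <- vapply(cfg$diets, function(d) {
  sub <- tr$adc_assays[tr$adc_assays$diet == d & tr$adc_assays$cage == 1 &
                         tr$adc_assays$substance %in% eaa_names(), ]
  pooled_adc(lapply(seq_len(nrow(sub)), function(i)
    adc_assay(sub$substance[i], sub$diet_conc[i], sub$feces_conc[i],
              sub$marker_diet[i], sub$marker_feces[i])))
}, numeric(1))
cat("\nPooled total-EAA ADC per diet (cage 1):\n")
print(round(pooled, 2))

out <- data.frame(substance = rows, round(rec[rows, cfg$diets], 2),
                  check.names = FALSE)
write.table(out, "results/03_recovered_adc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nWrote results/03_recovered_adc.tsv\n")
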