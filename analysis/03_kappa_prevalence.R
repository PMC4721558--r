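#!/usr/bin/env Rscript
# Demonstrate the kappa-prevalence paradox on simulated studies: holding the
# per-core noise fixed and sweeping the latent prevalence of one binary
# marker, raw concordance stays high while Cohen's kappa collapses as the
# positive category becomes rare (chance agreement p_e rises toward 1).

suppressPackageStartupMessages(library(tmaretest))
dir.create("results", showWarnings = FALSE)

sw <- kappa_prevalence_sweep(sim_config(), marker = "er",
                             prevalences = c(0.5, 0.3, 0.15, 0.05),
                             n_reps = 40, seed = 4242)
write.csv(sw, "results/kappa_prevalence_sweep.csv", row.names = FALSE)

cat("Kappa-prevalence sweep (ER marker, fixed core noise, 40 studies per row):\n")
print(sw, digits = 3, row.names = FALSE)
cat(sprintf("\nConcordance moves only %.1f points across the sweep while kappa falls from %.2f to %.2f:\n",
            max(sw$mean_concordance) - min(sw$mean_concordance),
            sw$mean_kappa[1], sw$mean_kappa[nrow(sw)]))
cat("the same mechanism that leaves dichotomized Ki67 (about one case in ten\n")
cat("above the 14% cutoff) with 90% concordance but kappa 0.346.\n")
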