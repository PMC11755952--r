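#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis: 1,000 Monte Carlo iterations over the
# parameter distributions, cost-effectiveness plane points and the
# acceptability curve written under results/.

suppressPackageStartupMessages(library(epiwait))

dir.create("results", showWarnings = FALSE)
seed <- 1

params <- default_parameters()
lt <- bundled_life_table()

psa <- run_psa(params, lt, n = 1000, seed = seed)
cat(sprintf("PSA (%d iterations, seed %d)\n", psa$n, psa$seed))
cat(sprintf("  mean incremental cost:  $%.0f\n", psa$mean_delta_cost))
cat(sprintf("  mean incremental QALYs: %.4g\n", psa$mean_delta_qaly))
cat(sprintf("  ICER of means: $%s/QALY\n",
            format(round(psa$icer), big.mark = ",")))
cat(sprintf("  INMB at WTP $%s: $%.0f\n",
            format(psa$wtp, big.mark = ","), psa$inmb))
cat(sprintf("  iterations cost-effective at WTP: %.1f%%\n",
            100 * psa$frac_cost_effective))

plane <- psa$iterations[, c("iteration", "delta_cost", "delta_qaly")]
utils::write.csv(plane, "results/psa_ce_plane.csv", row.names = FALSE)

curve <- ceac(psa, seq(0, 150000, by = 5000))
utils::write.csv(curve, "results/psa_ceac.csv", row.names = FALSE)
cat(sprintf("  acceptability over WTP $0-$150,000: min %.3f, max %.3f\n",
            min(curve$p_cost_effective), max(curve$p_cost_effective)))
cat("wrote results/psa_ce_plane.csv, results/psa_ceac.csv\n")
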