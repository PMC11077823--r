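#!/usr/bin/env Rscript
# Build the synthetic study that the rest of the analysis consumes: a
# drug-target style exposure (10 instruments on the biomarker-lowering
# scale), one true mediator and nine null mediators (each with 20
# instruments of its own), and an outcome, under the mediation model
# a = -0.4, b = 1.0, c' = -0.9. The total effect is therefore c = -1.3
# and the true mediated proportion a*b/c = 30.8%.

library(mrmediate)

cfg <- sim_config(a = -0.4, b = 1.0, c_prime = -0.9, n_null_mediators = 9,
                  palindromic_rate = 0.1, seed = 20240507)
study <- simulate_study(cfg)

out <- "results/study"
write_study(study, out)

cat("wrote", length(list.files(out)), "files under", out, "\n")
cat(sprintf("true total effect %.2f, true mediated proportion %.1f%%\n",
            study$truth$theta, 100 * study$truth$proportion))
cat(sprintf("SNP universe: %d SNPs (%d palindromic), %d invalid\n",
            nrow(study$panels$exposure$data),
            length(study$truth$palindromic_snps),
            length(study$truth$invalid_snps)))
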