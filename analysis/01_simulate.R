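#!/usr/bin/env Rscript
# Stage 1: build the synthetic proteome-wide MR study.
#
# One protein panel (each protein with a cis locus of large-effect pQTLs),
# an independent outcome cohort (quantitative pain-site-count proxy), a
# small replication pQTL panel covering only part of the proteome, two
# polygenic risk factors (one acting on the outcome partly through a causal
# protein), and a bank of phenome-wide outcomes with case counts.

library(pwmr)

SEED <- 2026L
dir.create("results", showWarnings = FALSE)

study <- simulate_study(seed = SEED)

cat("Simulated study (seed ", SEED, "):\n", sep = "")
cat("  proteins measured:       ", length(study$proteins), "\n")
cat("  causal proteins:         ", paste(study$truth$causal_proteins,
                                         collapse = ", "), "\n")
cat("  replication panel:       ", length(study$replication), "proteins\n")
cat("  risk factors:            ", paste(names(study$riskfactors),
                                         collapse = ", "), "\n")
cat("  true mediation chain:    ", study$truth$mediation$risk_factor, "->",
    study$truth$mediation$mediator, "-> outcome; proportion mediated",
    sprintf("%.0f%%", 100 * study$truth$mediation$proportion), "\n")
cat("  phenome-wide outcomes:   ", length(study$phewas), "\n")

saveRDS(study, "results/study.rds")
cat("study bundle saved to results/study.rds\n")
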