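#!/usr/bin/env Rscript
# Stage 3: validation of the discovery hits.
#
# Reverse MR (outcome instruments, no cis restriction) with per-instrument
# Steiger filtering, the SMR test at the top cis-QTL with the HEIDI
# linkage-heterogeneity test, Bayesian colocalization at each cis locus,
# and the evidence-tier classification.

library(pwmr)

study <- readRDS("results/study.rds")
stage2 <- readRDS("results/discovery.rds")
cfg <- run_config(seed = 2026L)
disc <- stage2$disc
repl <- stage2$repl
sig <- disc$results$exposure_id[disc$results$significant]

rev <- run_reverse(study$outcome, study$proteins, disc$pairs, study$ld, cfg,
                   protein_ids = sig)
cat("Reverse MR on", length(sig), "proteins:",
    sum(rev$reverse_null, na.rm = TRUE), "with null reverse effect;",
    sum(rev$steiger_pass), "pass Steiger filtering\n")

smr <- run_smr_heidi(study$proteins, study$outcome, study$genes, study$ld,
                     cfg, protein_ids = sig)
cat("SMR:", sum(smr$smr_pass, na.rm = TRUE), "pass; HEIDI:",
    sum(smr$heidi_pass, na.rm = TRUE), "pass,",
    sum(is.na(smr$heidi_p)), "not performable (too few linked SNPs)\n")

col <- run_coloc(study$proteins, study$outcome, disc$pairs, cfg,
                 protein_ids = sig)
cat("Colocalization: PPH4 >", cfg$pph4_strong, "for",
    sum(col$coloc_strong), "loci; tier-rule pass (PPH4 >",
    cfg$coloc_pass_threshold, ") for", sum(col$coloc_pass), "\n")

flags <- data.frame(
  protein_id = sig,
  replicated = repl$replicated[match(sig, repl$protein_id)],
  smr_pass = smr$smr_pass[match(sig, smr$probe_id)],
  heidi_pass = smr$heidi_pass[match(sig, smr$probe_id)],
  coloc_pass = col$coloc_pass[match(sig, col$locus_id)],
  reverse_null = rev$reverse_null[match(sig, rev$protein_id)],
  steiger_pass = rev$steiger_pass[match(sig, rev$protein_id)]
)
flags$tier <- vapply(seq_len(nrow(flags)), function(i) {
  classify_tier(flags$replicated[i], flags$smr_pass[i], flags$heidi_pass[i],
                flags$coloc_pass[i], flags$reverse_null[i],
                flags$steiger_pass[i])
}, integer(1))
cat("Evidence tiers: ",
    sum(flags$tier == 1), "Tier 1 /",
    sum(flags$tier == 2), "Tier 2 /",
    sum(flags$tier == 3), "Tier 3\n")

for (d in list(list(rev, "reverse.tsv"), list(smr, "smr_heidi.tsv"),
               list(col, "coloc.tsv"), list(flags, "tiers.tsv"))) {
  write.table(d[[1]], file.path("results/reports", d[[2]]), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
saveRDS(flags, "results/tiers.rds")
cat("wrote reverse.tsv, smr_heidi.tsv, coloc.tsv, tiers.tsv\n")
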