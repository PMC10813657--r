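#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates the plasma design of the study this pipeline targets: 12
# wild-type vs 11 knockout samples, ~300 circles per sample with a
# nucleosomal length profile, and 20 effect genes whose excision rate is
# elevated 8-fold in the knockout group. Writes the cohort as the same
# plain-text tables a circle caller would hand us, plus the ground truth.

suppressPackageStartupMessages(library(difcir))
suppressPackageStartupMessages(library(jsonlite))

out_dir <- "results/synthetic_cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20240801L)
genome <- simulate_genome(cfg)
sim <- simulate_cohort(cfg, genome)

write_gene_models(genome$genes, file.path(out_dir, "genes.bed"))
write.table(genome$cfs, file.path(out_dir, "cfs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (s in names(sim$cohort))
  write_eccdna_table(sim$cohort[[s]], file.path(out_dir, paste0(s, ".ecc.tsv")))
manifest <- data.frame(sample_id = sim$manifest$sample_id,
                       path = paste0(sim$manifest$sample_id, ".ecc.tsv"),
                       group = sim$manifest$group,
                       tissue = sim$manifest$tissue,
                       protocol = sim$manifest$protocol)
write.table(manifest, file.path(out_dir, "manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_json(list(effect_gene_symbols = sim$truth$effect_gene_symbols,
                provenance = sim$truth$provenance),
           file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d genes on %d chromosomes (genome %.1f Mb).\n",
            nrow(genome$genes), cfg$n_chroms,
            sum(genome$chrom_lengths) / 1e6))
cat(sprintf("Cohort: %d samples (%s), %.0f circles/sample on average.\n",
            length(sim$cohort),
            paste(sprintf("%s n=%d", names(cfg$n_samples_per_group),
                          cfg$n_samples_per_group), collapse = ", "),
            mean(sapply(sim$cohort, nrow))))
cat(sprintf("Planted %d effect genes at %.0f-fold excision in KO; %d fragile-site genes labeled.\n",
            cfg$effect_genes, cfg$effect_multiplier, nrow(genome$cfs)))
cat("Wrote", out_dir, "\n")
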