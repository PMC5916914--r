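#!/usr/bin/env Rscript
# Simulate a study-sized longitudinal cohort (14 converters vs 25
# non-converters, two timepoints) with known planted signal: 4 group-level
# VMP shifts, 6 private epimutations, and light QC corruption. Writes the
# cohort tables under results/sim/ for the downstream steps.

suppressPackageStartupMessages(library(methvar))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_probes = 20000,
                  n_vmp = 4, vmp_shift = 0.15,
                  n_epimutation = 6, epimutation_offset = 0.25,
                  detp_fail_rate = 0.0005, low_beadcount_rate = 0.001,
                  seed = 20180426)
sim <- simulate_cohort(cfg)

write_beta_matrix(sim$betas_m0, file.path(out, "betas_M0.tsv"))
write_beta_matrix(sim$betas_mf, file.path(out, "betas_MF.tsv"))
write.table(sim$sheet, file.path(out, "sheet.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (tp in c("m0", "mf")) {
  write_beta_matrix(sim$detection_p[[tp]],
                    file.path(out, sprintf("detp_%s.tsv", toupper(tp))))
  write.table(data.frame(probe_id = rownames(sim$beadcount[[tp]]),
                         sim$beadcount[[tp]], check.names = FALSE),
              file.path(out, sprintf("beadcount_%s.tsv", toupper(tp))),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# synthetic probe annotation: hg19-style coordinates, a few percent of
# probes on sex chromosomes or carrying exclusion flags
set.seed(cfg$seed + 1)
n <- cfg$n_probes
ann <- data.frame(
  probe_id = rownames(sim$betas_m0),
  chrom = sample(c(paste0("chr", 1:22), "chrX", "chrY"), n, replace = TRUE,
                 prob = c(rep(0.96 / 22, 22), 0.03, 0.01)),
  pos = sample.int(2.4e8, n, replace = TRUE),
  gene = ifelse(runif(n) < 0.6, sprintf("GENE%04d", sample.int(3000, n, TRUE)), ""),
  snp_probe = runif(n) < 0.01,
  snp_at_cpg = runif(n) < 0.01,
  cross_reactive = runif(n) < 0.01)
ann$sex_chromosome <- ann$chrom %in% c("chrX", "chrY")
write.table(ann, file.path(out, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

message(sprintf("simulated %d probes x %d samples; planted %d VMPs and %d epimutations",
                n, nrow(sim$sheet), nrow(sim$truth$vmp),
                nrow(sim$truth$epimutation)))
message("wrote cohort tables to ", out)
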