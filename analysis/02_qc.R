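#!/usr/bin/env Rscript
# Array QC on the simulated cohort: sample filter (detection p-value
# failures), then probe filter (detection p, beadcount, annotation flags),
# keeping a common probe set across the two timepoints. Writes the
# filtered matrices and per-reason exclusion counts under results/qc/.

suppressPackageStartupMessages(library(methvar))

sim_dir <- "results/sim"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

betas <- list(M0 = read_beta_matrix(file.path(sim_dir, "betas_M0.tsv")),
              MF = read_beta_matrix(file.path(sim_dir, "betas_MF.tsv")))
detp <- list(M0 = read_qc_matrix(file.path(sim_dir, "detp_M0.tsv")),
             MF = read_qc_matrix(file.path(sim_dir, "detp_MF.tsv")))
bead <- list(M0 = read_qc_matrix(file.path(sim_dir, "beadcount_M0.tsv")),
             MF = read_qc_matrix(file.path(sim_dir, "beadcount_MF.tsv")))
ann <- read_probe_annotation(file.path(sim_dir, "annotation.tsv"))

reports <- list()
for (tp in c("M0", "MF")) {
  fs <- filter_samples(betas[[tp]], detp[[tp]])
  message(sprintf("%s: %d/%d samples retained", tp,
                  fs$report$n_samples_retained, fs$report$n_samples_in))
  fp <- filter_probes(fs$betas, fs$detection_p,
                      bead[[tp]][rownames(fs$betas), colnames(fs$betas)],
                      ann)
  reports[[tp]] <- list(samples = fs$report, probes = fp$report)
  betas[[tp]] <- fp$betas
}

keep <- intersect(rownames(betas$M0), rownames(betas$MF))
message(sprintf("common retained probe set: %d probes", length(keep)))
write_beta_matrix(betas$M0[keep, ], file.path(out, "betas_M0_filtered.tsv"))
write_beta_matrix(betas$MF[keep, ], file.path(out, "betas_MF_filtered.tsv"))

counts <- do.call(rbind, lapply(names(reports), function(tp) {
  ex <- reports[[tp]]$probes$excluded_probes
  if (nrow(ex) == 0) return(NULL)
  data.frame(timepoint = tp, as.data.frame(table(reason = ex$reason)))
}))
write.table(counts, file.path(out, "exclusion_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(counts)
message("wrote filtered matrices to ", out)
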