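#!/usr/bin/env Rscript
# Stage 1 -- simulate the study's inputs with known ground truth:
#  (a) a standard-scale synthetic parcellation (41 homologous pairs),
#  (b) raw 70 s referential icEEG recordings for three demo subjects,
#      written as EDF, with contact coordinate and clinical-flag tables,
#  (c) a full-scale multi-hospital normative cohort (15 hospitals,
#      ~500 subjects) drawn from the generative random-intercept model,
#      with its ground-truth parameter sidecar.

suppressPackageStartupMessages(library(iceegnorm))
dir.create("results/raw", recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

## (a) parcellation -----------------------------------------------------------
parc <- simulate_parcellation(41, voxel_spacing = 2, seed = seed)
utils::write.table(
  merge(parc$voxels, parc$regions[, c("region_id", "name")]),
  "results/parcellation_voxels.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message(sprintf("parcellation: %d regions (%d homologous pairs), %d voxels",
                nrow(parc$regions), nrow(parc$pairs), nrow(parc$voxels)))

## (b) demo subjects: raw signals + contacts + clinical flags -----------------
set.seed(seed)
contacts <- list(); flags <- list()
for (k in 1:3) {
  sid <- sprintf("demo%02d", k)
  seg <- simulate_recording(planted_spectrum(), n_channels = 12, fs = 512,
                            duration = 70, seed = seed + k, subject = sid)
  write_edf(seg, sprintf("results/raw/%s.edf", sid))
  # place contacts on (or near) grey-matter voxels; two stray contacts
  # fall farther than the 5 mm assignment limit
  vox <- parc$voxels[sample(nrow(parc$voxels), 12), ]
  jitter <- matrix(stats::runif(36, -1.5, 1.5), 12)
  xyz <- as.matrix(vox[, c("x", "y", "z")]) + jitter
  xyz[11, ] <- xyz[11, ] + c(0, 0, 40)   # stray
  xyz[12, ] <- xyz[12, ] + c(0, 40, 0)   # stray
  contacts[[k]] <- data.frame(subject = sid, contact = seg$labels,
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              space = "template")
  # one seizure-onset-zone contact per subject
  flags[[k]] <- data.frame(subject = sid, contact = seg$labels[1],
                           flag = "soz")
}
utils::write.table(do.call(rbind, contacts), "results/raw/contacts.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(do.call(rbind, flags), "results/raw/clinical_flags.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(subject = sprintf("demo%02d", 1:3),
             hospital = c("hospA", "hospA", "hospB"),
             age = c(23.5, 41.0, 33.0),
             sex = c("female", "male", "male")),
  "results/raw/metadata.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote 3 demo subjects (EDF + contacts + flags + metadata)")

## (c) full-scale normative cohort -------------------------------------------
params <- simulation_params(seed = seed)
sim <- simulate_cohort(params)
write_normative_table(sim$table, "results/cohort_mirrored.tsv",
                      atlas = "synthetic-38")
truth <- list(
  beta0 = as.list(params$beta0), b_age = as.list(params$b_age),
  b_sex = as.list(params$b_sex), sigma_u = as.list(params$sigma_u),
  sigma_e = as.list(params$sigma_e),
  n_hospitals = params$n_hospitals,
  hospital_intercepts = apply(sim$truth$u, 2, as.list),
  seed = seed)
jsonlite::write_json(truth, "results/cohort_ground_truth.json",
                     auto_unbox = TRUE, digits = NA)
message(sprintf(
  "cohort: %d subjects, %d hospitals, %d subject-x-region rows",
  length(unique(sim$table$subject)), params$n_hospitals, nrow(sim$table)))
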