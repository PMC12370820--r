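#!/usr/bin/env Rscript
# Stage 5 -- clinical-style deviation scoring: compare an out-of-sample
# subject's regional RBP to the regional age-model lines, standardise by
# the model residual SD and rank the extreme deviations.

suppressPackageStartupMessages(library(iceegnorm))
stopifnot(file.exists("results/regional_map.tsv"))  # run 04 first

map <- tibble::as_tibble(
  utils::read.table("results/regional_map.tsv", header = TRUE, sep = "\t"))
class(map) <- c("regional_map", class(map))

truth <- jsonlite::read_json("results/cohort_ground_truth.json",
                             simplifyVector = TRUE)
age <- 33
rois <- c("middle_temporal", "hippocampus", "superior_temporal", "insula")
# a subject on the normative line everywhere except the hippocampus,
# planted 2.5 residual SDs high in the alpha band there
subj <- tibble::tibble(roi = rois)
for (b in band_names())
  subj[[b]] <- truth$beta0[[b]] + truth$b_age[[b]] * age
subj$alpha[subj$roi == "hippocampus"] <-
  subj$alpha[subj$roi == "hippocampus"] + 2.5 * truth$sigma_e$alpha

scores <- score_subject(map, subj, age = age,
                        threshold = pipeline_config()$deviation_threshold)
utils::write.table(as.data.frame(scores), "results/deviation_scores.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("top deviations (|z| ranked):")
print(as.data.frame(scores[1:5, ]), row.names = FALSE, digits = 3)
message(sprintf("flagged (|z| > 2): %d of %d region-band scores",
                sum(scores$flagged, na.rm = TRUE), nrow(scores)))
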