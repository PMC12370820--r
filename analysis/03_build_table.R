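#!/usr/bin/env Rscript
# Stage 3 -- localise demo contacts to the parcellation (nearest grey
# matter within 5 mm), drop clinically flagged contacts (SOZ / lesion /
# resected), average contact RBP within subject and region, build the
# normative table (subcortical exclusions: 82 -> 76 regions) and mirror
# homologous regions (76 -> 38).

suppressPackageStartupMessages(library(iceegnorm))
stopifnot(file.exists("results/rbp_contacts.tsv"))  # run 02 first

vox <- utils::read.table("results/parcellation_voxels.tsv", header = TRUE,
                         sep = "\t")
regions <- unique(vox[, c("region_id", "name")])
parc <- structure(list(
  regions = tibble::tibble(
    region_id = regions$region_id, name = regions$name,
    base = sub("^(left|right)_", "", regions$name),
    hemisphere = ifelse(grepl("^left_", regions$name), "left", "right"),
    subcortical = sub("^(left|right)_", "", regions$name) %in%
      c("hippocampus", "amygdala", "caudate", "putamen", "thalamus",
        "pallidum", "accumbens")),
  voxels = tibble::as_tibble(vox[, c("region_id", "voxel_idx",
                                     "x", "y", "z")])),
  class = "parcellation")

contacts <- utils::read.table("results/raw/contacts.tsv", header = TRUE,
                              sep = "\t")
flags <- utils::read.table("results/raw/clinical_flags.tsv", header = TRUE,
                           sep = "\t")
meta <- utils::read.table("results/raw/metadata.tsv", header = TRUE,
                          sep = "\t")
rbp <- tibble::as_tibble(
  utils::read.table("results/rbp_contacts.tsv", header = TRUE, sep = "\t"))

asn <- assign_contacts(contacts, parc, max_dist = 5)
message(sprintf("assigned %d/%d contacts (%d beyond 5 mm)",
                sum(!asn$excluded), nrow(asn),
                sum(vapply(asn$reasons, function(r)
                  "too_far" %in% r, TRUE))))
asn <- apply_channel_exclusions(asn, flags)
message(sprintf("%d contacts excluded after clinical flags",
                sum(asn$excluded)))

agg <- aggregate_contacts(asn, rbp)
tab <- build_normative_table(agg, meta)
mir <- mirror_table(tab)
write_normative_table(tab, "results/demo_table_original.tsv",
                      atlas = "synthetic-82")
write_normative_table(mir, "results/demo_table_mirrored.tsv",
                      atlas = "synthetic-38")

universe <- sum(!(parc$regions$name %in% default_subcortical_exclusions()))
message(sprintf(
  "region universe: %d atlas regions -> %d after subcortical exclusion -> %d mirrored",
  nrow(parc$regions), universe, universe / 2))
message(sprintf("demo table: %d subject-x-region rows (%d mirrored)",
                nrow(tab), nrow(mir)))
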