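#' Tag a data frame as a normative table
#'
#' The normative table is a long-format tibble with one row per subject
#' per sampled region: `subject`, `hospital`, `age` (years), `sex`
#' (`"female"`/`"male"`), `roi`, and one column per frequency band
#' holding that subject's relative band power in the region. The
#' `mirrored` attribute records whether homologous left/right regions
#' have been collapsed.
#'
#' @param x Data frame with the columns above.
#' @param mirrored Logical: are regions homologous-collapsed?
#' @return `x` as a tibble of class `normative_table`.
#' @export
as_normative_table <- function(x, mirrored = FALSE) {
  x <- tibble::as_tibble(x)
  need <- c("subject", "hospital", "age", "sex", "roi", band_names())
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("normative table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(x$age <= 0)) stop("ages must be positive")
  if (!all(x$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (anyDuplicated(paste(x$subject, x$roi)))
    stop("at most one row per subject x ROI")
  bp <- as.matrix(x[, band_names()])
  if (!all(is.finite(bp))) stop("band values must be finite")
  class(x) <- c("normative_table", class(x))
  attr(x, "mirrored") <- isTRUE(mirrored)
  x
}

#' Is a normative table mirrored?
#' @param x A `normative_table`.
#' @return Logical.
#' @export
is_mirrored <- function(x) isTRUE(attr(x, "mirrored"))

#' Average contact-level RBP within subject and region
#'
#' When several of a subject's contacts are assigned to the same region,
#' their relative band power values are averaged per band to give a
#' single value per region per subject; single-contact regions pass
#' through unchanged. Excluded contacts are dropped first. Because the
#' mean is linear, averaged unit-sum RBP vectors still sum to one.
#'
#' @param assignments Output of [assign_contacts()] (after
#'   [apply_channel_exclusions()]), keyed by `subject`, `contact`.
#' @param rbp Contact-level RBP as returned by [extract_rbp()]: columns
#'   `subject`, `channel` and the five band columns (`channel` matches
#'   `contact` in `assignments`).
#' @return Tibble with columns `subject`, `roi`, `n_contacts` and the
#'   five band columns; empty (with a warning) when nothing is assigned.
#' @export
aggregate_contacts <- function(assignments, rbp) {
  keep <- assignments[!assignments$excluded, ]
  key_r <- paste(rbp$subject, rbp$channel, sep = "\r")
  key_k <- paste(keep$subject, keep$contact, sep = "\r")
  m <- match(key_k, key_r)
  if (nrow(keep) == 0L || all(is.na(m))) {
    warning("no assigned contacts with RBP values; empty result")
    out <- tibble::tibble(subject = character(0), roi = character(0),
                          n_contacts = integer(0))
    for (b in band_names()) out[[b]] <- numeric(0)
    return(out)
  }
  keep <- keep[!is.na(m), ]; m <- m[!is.na(m)]
  grp <- paste(keep$subject, keep$region, sep = "\r")
  ug <- !duplicated(grp)
  out <- tibble::tibble(subject = keep$subject[ug], roi = keep$region[ug])
  gi <- match(grp, grp[ug])
  out$n_contacts <- as.integer(tabulate(gi, nbins = sum(ug)))
  for (b in band_names())
    out[[b]] <- as.numeric(rowsum(rbp[[b]][m], gi)) / out$n_contacts
  out
}

#' Build the normative data table
#'
#' Joins per-subject per-region RBP values with subject metadata and
#' drops the excluded subcortical regions (pallidum, thalamus and
#' accumbens area in both hemispheres by default), reducing the standard
#' 82-region universe to 76.
#'
#' @param roi_rbp Tibble from [aggregate_contacts()]: `subject`, `roi`
#'   and the five band columns.
#' @param metadata Data frame with one row per subject: `subject`,
#'   `hospital`, `age`, `sex`. Must cover every subject in `roi_rbp`.
#' @param exclusions Character vector of region names to drop (default
#'   [default_subcortical_exclusions()]).
#' @return An unmirrored [as_normative_table()].
#' @export
build_normative_table <- function(roi_rbp, metadata,
                                  exclusions =
                                    default_subcortical_exclusions()) {
  stopifnot(all(c("subject", "hospital", "age", "sex") %in% names(metadata)))
  missing <- setdiff(unique(roi_rbp$subject), metadata$subject)
  if (length(missing))
    stop("metadata missing for subject(s): ", paste(missing, collapse = ", "))
  kept <- roi_rbp[!(roi_rbp$roi %in% exclusions), ]
  m <- match(kept$subject, metadata$subject)
  tab <- tibble::tibble(subject = kept$subject,
                        hospital = metadata$hospital[m],
                        age = metadata$age[m], sex = metadata$sex[m],
                        roi = kept$roi)
  for (b in band_names()) tab[[b]] <- kept[[b]]
  as_normative_table(tab, mirrored = FALSE)
}

#' Collapse homologous left/right regions ("mirroring")
#'
#' Relies on the reported hemispheric symmetry of relative band power to
#' combine homologous regions and so roughly double the subjects per
#' region: region labels lose their hemisphere prefix, and a subject
#' implanted bilaterally in a symmetric pair contributes exactly one row
#' per mirrored region, collapsed by the configured rule (per-band mean
#' by default; left- or right-priority selection as alternatives). A
#' 76-region table becomes a 38-region mirrored table. Re-mirroring a
#' mirrored table is an error rather than a silent double collapse.
#'
#' @param table An unmirrored [as_normative_table()].
#' @param homologous_map Optional data frame with columns `region` and
#'   `mirrored` overriding the default `left_`/`right_` prefix pairing.
#' @param rule Bilateral collapse rule: `"mean"`, `"left"` or `"right"`.
#' @return A mirrored `normative_table`.
#' @export
mirror_table <- function(table, homologous_map = NULL,
                         rule = c("mean", "left", "right")) {
  rule <- match.arg(rule)
  if (is_mirrored(table)) stop("table is already mirrored")
  if (is.null(homologous_map)) {
    has_prefix <- grepl("^(left|right)_", table$roi)
    if (!all(has_prefix))
      stop("region(s) without a left_/right_ hemisphere prefix and no ",
           "override map: ",
           paste(unique(table$roi[!has_prefix]), collapse = ", "))
    mirrored <- sub("^(left|right)_", "", table$roi)
  } else {
    m <- match(table$roi, homologous_map$region)
    if (anyNA(m))
      stop("region(s) missing from the homologous map: ",
           paste(unique(table$roi[is.na(m)]), collapse = ", "))
    mirrored <- homologous_map$mirrored[m]
  }
  hemi <- ifelse(grepl("^right_", table$roi), "right", "left")
  grp <- paste(table$subject, mirrored, sep = "\r")
  ug <- !duplicated(grp)
  gi <- match(grp, grp[ug])
  out <- tibble::tibble(subject = table$subject[ug],
                        hospital = table$hospital[ug],
                        age = table$age[ug], sex = table$sex[ug],
                        roi = mirrored[ug])
  cnt <- tabulate(gi, nbins = sum(ug))
  for (b in band_names()) {
    if (rule == "mean") {
      out[[b]] <- as.numeric(rowsum(table[[b]], gi)) / cnt
    } else {
      pref <- hemi == rule
      v <- rep(NA_real_, sum(ug))
      v[gi[!pref]] <- table[[b]][!pref]   # non-preferred first,
      v[gi[pref]] <- table[[b]][pref]     # preferred overwrites
      out[[b]] <- v
    }
  }
  as_normative_table(out, mirrored = TRUE)
}

#' Write a normative table as TSV with a provenance header
#'
#' Serialises the table with a fixed column order and `#`-prefixed
#' header comments recording the mirrored state, atlas name, number of
#' regions and package version, so downstream stages can validate what
#' they are reading.
#'
#' @param table A `normative_table`.
#' @param path Output path.
#' @param atlas Atlas name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_normative_table <- function(table, path, atlas = "synthetic") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# normative_table\tmirrored=", is_mirrored(table)),
    paste0("# atlas=", atlas, "\tregions=", length(unique(table$roi))),
    paste0("# iceegnorm_version=",
           as.character(utils::packageVersion("iceegnorm")))), con)
  cols <- c("subject", "hospital", "age", "sex", "roi", band_names())
  utils::write.table(as.data.frame(table)[, cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a normative table written by [write_normative_table()]
#' @param path Path to the TSV file.
#' @return A `normative_table` with its mirrored state restored.
#' @export
read_normative_table <- function(path) {
  hdr <- readLines(path, n = 3)
  mirrored <- grepl("mirrored=TRUE", hdr[1])
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  as_normative_table(x, mirrored = mirrored)
}
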