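#' Assign electrode contacts to parcellation regions
#'
#' Each contact is mapped to the region owning its nearest grey-matter
#' voxel centre (Euclidean distance in mm). Contacts whose nearest voxel
#' lies farther than `max_dist` are excluded with reason `"too_far"`.
#' Ties are broken deterministically: lowest region id, then lowest voxel
#' index. Contacts and parcellation must share one coordinate space; the
#' `space` column, if present, is carried through untouched (no
#' registration is performed).
#'
#' @param contacts Data frame with columns `subject`, `contact`, `x`,
#'   `y`, `z` (mm) and optionally `space`.
#' @param parcellation A `parcellation` (see [simulate_parcellation()]).
#' @param max_dist Maximum assignment distance, mm (default 5).
#' @return A tibble with one row per contact: `subject`, `contact`,
#'   `region_id`, `region` (NA when excluded), `distance` (mm),
#'   `excluded` (logical), `reasons` (list of character vectors).
#' @export
assign_contacts <- function(contacts, parcellation, max_dist = 5) {
  stopifnot(all(c("subject", "contact", "x", "y", "z") %in% names(contacts)))
  vox <- parcellation$voxels
  if (is.null(vox) || nrow(vox) == 0L) stop("parcellation has no voxels")
  if (!all(is.finite(as.matrix(contacts[, c("x", "y", "z")]))))
    stop("contact coordinates must be finite")
  V <- as.matrix(vox[, c("x", "y", "z")])
  vn2 <- rowSums(V^2)
  n <- nrow(contacts)
  region_id <- integer(n); distance <- numeric(n)
  for (i in seq_len(n)) {
    p <- c(contacts$x[i], contacts$y[i], contacts$z[i])
    d2 <- pmax(vn2 - 2 * (V %*% p)[, 1] + sum(p^2), 0)
    # deterministic tie-break: distance, then region id, then voxel index
    j <- order(d2, vox$region_id, vox$voxel_idx)[1]
    region_id[i] <- vox$region_id[j]
    distance[i] <- sqrt(d2[j])
  }
  too_far <- distance > max_dist
  name <- parcellation$regions$name[match(region_id,
                                          parcellation$regions$region_id)]
  tibble::tibble(
    subject = contacts$subject, contact = contacts$contact,
    region_id = ifelse(too_far, NA_integer_, region_id),
    region = ifelse(too_far, NA_character_, name),
    distance = distance, excluded = too_far,
    reasons = lapply(too_far, function(tf) if (tf) "too_far" else character(0)))
}

#' Exclude clinically flagged contacts
#'
#' Marks contacts lying within known lesions, within the seizure onset
#' zone, or subsequently resected as excluded, so only channels thought
#' to be non-pathological enter the normative table. A contact carrying
#' several flags is excluded once with all reasons retained (set union).
#'
#' @param assignments Output of [assign_contacts()].
#' @param clinical_flags Data frame with columns `subject`, `contact`,
#'   `flag` (one of `"lesion"`, `"soz"`, `"resected"`, `"pathological"`);
#'   one row per flag. May be empty.
#' @return `assignments` with flagged contacts marked excluded and their
#'   reasons appended.
#' @export
apply_channel_exclusions <- function(assignments, clinical_flags) {
  if (is.null(clinical_flags) || nrow(clinical_flags) == 0L)
    return(assignments)
  stopifnot(all(c("subject", "contact", "flag") %in% names(clinical_flags)))
  ok_flags <- c("lesion", "soz", "resected", "pathological")
  bad <- setdiff(unique(clinical_flags$flag), ok_flags)
  if (length(bad)) stop("unknown clinical flag(s): ",
                        paste(bad, collapse = ", "))
  key_a <- paste(assignments$subject, assignments$contact, sep = "\r")
  key_f <- paste(clinical_flags$subject, clinical_flags$contact, sep = "\r")
  missing <- !(key_f %in% key_a)
  if (any(missing))
    stop("clinical flags reference unknown contact(s): ",
         paste(unique(paste(clinical_flags$subject[missing],
                            clinical_flags$contact[missing])),
               collapse = ", "))
  for (i in which(key_a %in% key_f)) {
    fl <- sort(unique(clinical_flags$flag[key_f == key_a[i]]))
    assignments$reasons[[i]] <- union(assignments$reasons[[i]], fl)
    assignments$excluded[i] <- TRUE
  }
  assignments
}
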