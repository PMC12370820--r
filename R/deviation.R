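#' Score a new subject against the regional normative model
#'
#' For each region and band the subject's observed RBP is compared with
#' the regional age-model prediction at the subject's age. The
#' prediction is population-level: an out-of-sample subject has no
#' hospital of their own in the model, so the hospital offset enters at
#' its prior mean of zero. The raw residual is standardised by the
#' model's residual SD (optionally inflated to
#' `sqrt(sigma2_u + sigma2_e)` to acknowledge the unknown hospital
#' offset), and deviations beyond the configured threshold are flagged.
#' Regions whose fit is singular are scored with the raw residual only
#' (the standardised score is `NA`) and flagged; regions absent from the
#' map or unfitted are marked unscorable. Results are ranked by absolute
#' standardised score so extreme deviations lead.
#'
#' @param map A `regional_map` from [fit_regional()].
#' @param subject_rbp Tibble in normative-table row format: `roi` plus
#'   one column per band with the subject's RBP.
#' @param age Subject age, years.
#' @param denominator `"residual"` (default) or `"total"`
#'   (`sqrt(sigma2_u + sigma2_e)`).
#' @param threshold |score| above which a deviation is flagged.
#' @return Tibble, one row per scoreable ROI x band: `roi`, `band`,
#'   `observed`, `predicted`, `residual`, `score`, `flagged`, `note`.
#' @export
score_subject <- function(map, subject_rbp, age,
                          denominator = c("residual", "total"),
                          threshold = 2) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(map, "regional_map"), "roi" %in% names(subject_rbp),
            is.numeric(age), age > 0)
  bands <- intersect(band_names(), names(subject_rbp))
  if (!length(bands)) stop("subject_rbp has no band columns")
  rows <- list()
  for (i in seq_len(nrow(subject_rbp))) {
    r <- subject_rbp$roi[i]
    for (b in bands) {
      obs <- subject_rbp[[b]][i]
      m <- map[map$roi == r & map$band == b, ]
      if (nrow(m) == 0L || !isTRUE(m$fitted)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          roi = r, band = b, observed = obs, predicted = NA_real_,
          residual = NA_real_, score = NA_real_, flagged = NA,
          note = if (nrow(m) == 0L) "roi_absent_from_map" else "unfitted")
        next
      }
      pred <- m$intercept + m$b_age * age
      res <- obs - pred
      if (isTRUE(m$singular)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          roi = r, band = b, observed = obs, predicted = pred,
          residual = res, score = NA_real_, flagged = NA,
          note = "singular_fit_raw_residual_only")
        next
      }
      denom <- if (denominator == "total")
        sqrt(m$sigma2_u + m$sigma2_e) else sqrt(m$sigma2_e)
      sc <- res / denom
      rows[[length(rows) + 1L]] <- tibble::tibble(
        roi = r, band = b, observed = obs, predicted = pred,
        residual = res, score = sc, flagged = abs(sc) > threshold,
        note = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-abs(ifelse(is.na(out$score), -Inf, out$score))), ]
}
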