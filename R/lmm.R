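#' @importFrom stats qchisq pchisq qnorm uniroot optimise sd setNames
NULL

# ---------------------------------------------------------------------------
# Core engine: random-intercept LMM by closed-form GLS profiling.
#
# Model: y = X beta + Z u + e, one random intercept per group,
# u ~ N(0, sigma_u^2 I_H), e ~ N(0, sigma_e^2 I_n). Writing
# lambda = sigma_u^2 / sigma_e^2, the marginal covariance is
# sigma_e^2 (I + lambda J) block-diagonal over groups (J = ones).
# For fixed lambda, beta and sigma_e^2 have closed GLS forms, leaving a
# one-dimensional profiled ML/REML criterion in lambda which is
# minimised by golden-section search after a coarse log-spaced bracket.
# This keeps every fit cheap and makes dense grid-search oracles viable.
# ---------------------------------------------------------------------------

# Precompute the sufficient statistics that do not depend on lambda.
lmm_prepare <- function(y, X, g) {
  g <- factor(g)
  gi <- as.integer(g)
  n_h <- tabulate(gi)
  list(y = y, X = X, gi = gi, n_h = n_h, levels = levels(g),
       n = length(y), p = ncol(X),
       Sx = rowsum(X, gi), Sy = as.numeric(rowsum(y, gi)),
       XtX = crossprod(X), Xty = crossprod(X, y)[, 1], yty = sum(y^2))
}

# Profiled -2 log-likelihood (ML) or -2 restricted log-likelihood (REML)
# at a given variance ratio lambda, with the profiling by-products.
lmm_eval <- function(prep, lambda, REML) {
  c_h <- lambda / (1 + lambda * prep$n_h)
  XtWX <- prep$XtX - crossprod(prep$Sx, prep$Sx * c_h)
  XtWy <- prep$Xty - colSums(prep$Sx * (c_h * prep$Sy))
  yWy <- prep$yty - sum(c_h * prep$Sy^2)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(list(crit = Inf))
  beta <- backsolve(R, forwardsolve(t(R), XtWy))
  rss <- max(yWy - sum(beta * XtWy), 1e-300)
  logdetR <- sum(log1p(lambda * prep$n_h))
  n <- prep$n; p <- prep$p
  if (REML) {
    sigma2 <- rss / (n - p)
    crit <- (n - p) * log(2 * pi * sigma2) + logdetR +
      2 * sum(log(diag(R))) + (n - p)
  } else {
    sigma2 <- rss / n
    crit <- n * log(2 * pi * sigma2) + logdetR + n
  }
  list(crit = crit, beta = beta, sigma2 = sigma2, XtWX = XtWX, chol = R)
}

# Minimise the profiled criterion over lambda >= 0.
lmm_optimise <- function(prep, REML) {
  grid <- c(0, 10^seq(-6, 4, by = 0.5))
  crit <- vapply(grid, function(l) lmm_eval(prep, l, REML)$crit, 0)
  i <- which.min(crit)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimise(function(l) lmm_eval(prep, l, REML)$crit,
                         interval = c(lo, hi), tol = 1e-9)
  if (crit[1] <= opt$objective) list(lambda = 0, crit = crit[1])
  else list(lambda = opt$minimum, crit = opt$objective)
}

#' Fit a random-intercept linear mixed model for one frequency band
#'
#' Fits `RBP(band) ~ fixed effects + (1 | hospital)` by REML (default,
#' for reported coefficients and variance components) or ML (for
#' information criteria and likelihood ratio tests), using closed-form
#' GLS profiling over the hospital/residual variance ratio. Handles
#' unequal hospital sizes. The fit is flagged singular when the
#' estimated variance ratio falls below `singular_tol` (boundary
#' collapse of the hospital variance), which with a single hospital is
#' inevitable and additionally warned about. Columns aliased with others
#' (zero or collinear covariates) receive `NA` coefficients with a
#' warning, matching `lm()` conventions, so degenerate nested
#' comparisons remain well defined.
#'
#' @param table A [as_normative_table()] (or any data frame with
#'   `hospital`, `age`, `sex` and the band column).
#' @param band Band name, e.g. `"alpha"`.
#' @param fixed Character subset of `c("age", "sex")`.
#' @param method `"REML"` or `"ML"`.
#' @param singular_tol Variance-ratio threshold for the singular flag.
#' @return An `lmm_fit`: coefficients and their SEs, `sigma2_u`,
#'   `sigma2_e`, `lambda`, per-hospital predicted offsets `u` (BLUPs),
#'   `logLik`, `AIC`, `BIC` (from this fit's own likelihood and
#'   parameter count `k`), `icc`, `r2m`, `singular`, `n`, `method`.
#' @export
fit_lmm <- function(table, band, fixed = character(0),
                    method = c("REML", "ML"), singular_tol = 1e-4) {
  method <- match.arg(method)
  stopifnot(band %in% names(table), all(fixed %in% c("age", "sex")))
  y <- table[[band]]
  if (anyNA(y) || anyNA(table$age) || anyNA(table$sex))
    stop("missing values in response or covariates")
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if ("age" %in% fixed) X <- cbind(X, age = table$age)
  if ("sex" %in% fixed) X <- cbind(X, sexmale = as.numeric(table$sex == "male"))
  qx <- qr(X)
  aliased <- character(0)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    aliased <- colnames(X)[-keep]
    warning("dropping aliased column(s): ", paste(aliased, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  g <- factor(table$hospital)
  prep <- lmm_prepare(y, X, g)
  if (nlevels(g) < 2L) {
    # one group: the intercept absorbs the hospital offset, so the
    # variance split is unidentifiable; pin the ratio at the boundary
    warning("single hospital: variance components unidentifiable; ",
            "fit is singular")
    opt <- list(lambda = 0, crit = lmm_eval(prep, 0,
                                            REML = method == "REML")$crit)
  } else {
    opt <- lmm_optimise(prep, REML = method == "REML")
  }
  ev <- lmm_eval(prep, opt$lambda, REML = method == "REML")
  beta <- setNames(as.numeric(ev$beta), colnames(X))
  vcov_beta <- ev$sigma2 * chol2inv(ev$chol)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  if (length(aliased)) {
    beta[aliased] <- NA_real_
    se[aliased] <- NA_real_
  }
  sigma2_e <- ev$sigma2
  sigma2_u <- opt$lambda * sigma2_e
  # BLUPs: shrunk per-hospital mean residuals
  resid <- y - X %*% ev$beta
  rbar <- as.numeric(rowsum(resid, prep$gi)) / prep$n_h
  u <- setNames(opt$lambda * prep$n_h / (1 + opt$lambda * prep$n_h) * rbar,
                prep$levels)
  eta <- as.numeric(X %*% ev$beta)
  var_fixed <- if (ncol(X) > 1L) mean((eta - mean(eta))^2) else 0
  k <- prep$p + 2L  # fixed effects + sigma_u^2 + sigma_e^2
  ll <- -opt$crit / 2
  singular <- opt$lambda < singular_tol
  structure(list(
    coefficients = beta, se = se, vcov = vcov_beta,
    sigma2_u = sigma2_u, sigma2_e = sigma2_e, lambda = opt$lambda,
    u = u, logLik = ll, AIC = -2 * ll + 2 * k,
    BIC = -2 * ll + k * log(prep$n), k = k,
    icc = opt$lambda / (1 + opt$lambda),
    var_fixed = var_fixed,
    r2m = var_fixed / (var_fixed + sigma2_u + sigma2_e),
    singular = singular, n = prep$n, n_hospitals = nlevels(g),
    method = method, fixed = fixed, band = band, aliased = aliased,
    y = y, X = X, g = g),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> RBP(%s) ~ %s + (1|hospital)  [%s, n=%d, H=%d]\n",
              x$band,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$method, x$n, x$n_hospitals))
  print(round(rbind(estimate = x$coefficients, se = x$se), 6))
  cat(sprintf("sigma2_u=%.3g sigma2_e=%.3g ICC=%.3f R2m=%.3f logLik=%.2f%s\n",
              x$sigma2_u, x$sigma2_e, x$icc, x$r2m, x$logLik,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Intraclass correlation of a fitted model
#'
#' The proportion of (hospital + residual) variance attributable to the
#' hospital grouping: `sigma2_u / (sigma2_u + sigma2_e)`.
#'
#' @param fit An `lmm_fit`.
#' @return Proportion in `[0, 1]`.
#' @export
icc <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e)
}

#' Marginal R-squared of a fitted model
#'
#' The proportion of the total modelled variance explained by the fixed
#' effects: the population variance of the fixed-effect linear predictor
#' divided by (that variance + hospital variance + residual variance).
#' The denominator includes the residual variance and therefore changes
#' between models, so marginal R-squared values of nested models are not
#' additive. The null model returns 0.
#'
#' @param fit An `lmm_fit`.
#' @return Proportion in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$var_fixed / (fit$var_fixed + fit$sigma2_u + fit$sigma2_e)
}

#' Profile likelihood confidence interval for a fixed effect
#'
#' Profiles the ML deviance over one fixed-effect coefficient: for each
#' trial value t the coefficient's column is moved into the offset and
#' the remaining fixed effects and both variance components are
#' re-optimised. The interval ends where the profiled deviance rises by
#' the chi-squared(1) quantile, located by root finding within +-10 Wald
#' SEs (tolerance 1e-6). If the deviance fails to cross the cutoff in
#' that range the Wald limit is returned for that side and the attached
#' `method` attribute says so.
#'
#' @param fit An `lmm_fit`.
#' @param parameter Name of a fixed effect of the fit (e.g. `"age"`).
#' @param level Confidence level (default 0.95).
#' @return `c(lower, upper)` with attribute `method` per side
#'   (`"profile"` or `"wald"`).
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!(parameter %in% colnames(fit$X)))
    stop("'", parameter, "' is not a fixed effect of this fit")
  j <- match(parameter, colnames(fit$X))
  est <- fit$coefficients[parameter]
  se <- fit$se[parameter]
  if (!is.finite(est) || !is.finite(se))
    stop("cannot profile an aliased coefficient")
  Xr <- fit$X[, -j, drop = FALSE]
  xj <- fit$X[, j]
  base_crit <- function(t) {
    prep <- lmm_prepare(fit$y - xj * t, Xr, fit$g)
    lmm_optimise(prep, REML = FALSE)$crit
  }
  # ML criterion with the parameter free (deviance reference point)
  prep_full <- lmm_prepare(fit$y, fit$X, fit$g)
  full <- lmm_optimise(prep_full, REML = FALSE)
  est_ml <- lmm_eval(prep_full, full$lambda, REML = FALSE)$beta[j]
  cutoff <- stats::qchisq(level, df = 1)
  zse <- stats::qnorm(1 - (1 - level) / 2) * se
  dev <- function(t) base_crit(t) - full$crit
  side <- function(dir) {
    far <- est_ml + dir * 10 * se
    fd <- dev(far) - cutoff
    if (!is.finite(fd) || fd < 0)
      return(list(value = est + dir * zse, method = "wald"))
    r <- stats::uniroot(function(t) dev(t) - cutoff,
                        lower = min(est_ml, far), upper = max(est_ml, far),
                        tol = 1e-6 * max(se, 1e-12))
    list(value = r$root, method = "profile")
  }
  lo <- side(-1); hi <- side(+1)
  out <- c(lower = lo$value, upper = hi$value)
  attr(out, "method") <- c(lower = lo$method, upper = hi$method)
  attr(out, "level") <- level
  out
}

#' Likelihood ratio test between two nested ML fits
#'
#' Compares two ML fits on the same rows whose fixed-effect sets differ
#' by exactly one term; the statistic `2 * (logLik_alt - logLik_null)`
#' is referred to a chi-squared distribution with 1 degree of freedom.
#' REML fits are refused: REML likelihoods of models with different
#' fixed effects are not comparable.
#'
#' @param fit_null,fit_alt Nested `lmm_fit`s estimated by ML.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
lrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "lmm_fit"), inherits(fit_alt, "lmm_fit"))
  if (fit_null$method != "ML" || fit_alt$method != "ML")
    stop("LRT on fixed effects requires ML fits (got ",
         fit_null$method, "/", fit_alt$method, ")")
  if (fit_null$n != fit_alt$n || fit_null$band != fit_alt$band)
    stop("fits must use identical rows and response")
  extra <- setdiff(fit_alt$fixed, fit_null$fixed)
  if (length(extra) != 1L || !all(fit_null$fixed %in% fit_alt$fixed))
    stop("models must be nested and differ by exactly one fixed effect")
  stat <- max(0, 2 * (fit_alt$logLik - fit_null$logLik))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, term = extra)
}

#' Select the fixed-effect structure for one band
#'
#' Fits the four candidate models (null, age, sex, full) by ML for
#' information criteria and likelihood ratio tests and by REML for
#' reported coefficients, then applies the agreement rule: the metrics
#' agree when the AIC-best and BIC-best model coincide and equal the
#' unique model all of whose terms have a confidence interval excluding
#' zero and an LRT p-value below `alpha` (with no further term reaching
#' significance). When the metrics split, the simplest of the top
#' contenders is retained.
#'
#' @param table A normative table (rows for one analysis level).
#' @param band Band name.
#' @param config A [pipeline_config()] supplying the candidate set,
#'   `selection_alpha` and `conf_level`.
#' @param ci_method `"profile"` (default) or `"wald"` intervals for the
#'   CI-excludes-zero indicator.
#' @return List: `fixed` (chosen fixed-effect set), `spec` (its label),
#'   `fits_ml`, `fits_reml` (named lists of `lmm_fit`s), `trace` (tibble
#'   of per-model metrics), `lrt_table`, `agreement`, `note`.
#' @export
select_model <- function(table, band, config = pipeline_config(),
                         ci_method = c("profile", "wald")) {
  ci_method <- match.arg(ci_method)
  cands <- config$candidate_models
  label <- function(fx) if (length(fx)) paste(sort(fx), collapse = "+")
  else "null"
  labels <- vapply(cands, label, "")
  fits_ml <- lapply(cands, function(fx)
    fit_lmm(table, band, fx, method = "ML",
            singular_tol = config$singular_tol))
  fits_reml <- lapply(cands, function(fx)
    fit_lmm(table, band, fx, method = "REML",
            singular_tol = config$singular_tol))
  names(fits_ml) <- names(fits_reml) <- labels

  # every nested pair differing by one term
  lrt_rows <- list()
  for (i in seq_along(cands)) for (j in seq_along(cands)) {
    extra <- setdiff(cands[[j]], cands[[i]])
    if (length(extra) == 1L && all(cands[[i]] %in% cands[[j]])) {
      t <- lrt(fits_ml[[i]], fits_ml[[j]])
      lrt_rows[[length(lrt_rows) + 1L]] <-
        tibble::tibble(null = labels[i], alt = labels[j], term = t$term,
                       statistic = t$statistic, p_value = t$p_value)
    }
  }
  lrt_table <- do.call(rbind, lrt_rows)

  # per-model: do all included terms have CI excluding zero?
  term_col <- c(age = "age", sex = "sexmale")
  ci_excl <- vapply(seq_along(cands), function(i) {
    fx <- cands[[i]]
    if (!length(fx)) return(TRUE)
    all(vapply(fx, function(tm) {
      f <- fits_reml[[i]]
      if (ci_method == "profile") {
        ci <- profile_ci(f, term_col[[tm]], level = config$conf_level)
      } else {
        z <- stats::qnorm(1 - (1 - config$conf_level) / 2)
        ci <- f$coefficients[term_col[[tm]]] + c(-1, 1) * z * f$se[term_col[[tm]]]
      }
      ci[1] > 0 || ci[2] < 0
    }, TRUE))
  }, TRUE)

  # LRT support: every included term significant when added last; no
  # excluded term significant when added to this model
  lrt_ok <- vapply(seq_along(cands), function(i) {
    fx <- cands[[i]]
    inc <- all(vapply(fx, function(tm) {
      r <- lrt_table[lrt_table$alt == labels[i] & lrt_table$term == tm, ]
      nrow(r) > 0 && all(r$p_value < config$selection_alpha)
    }, TRUE))
    exc <- all(vapply(setdiff(c("age", "sex"), fx), function(tm) {
      r <- lrt_table[lrt_table$null == labels[i] & lrt_table$term == tm, ]
      nrow(r) == 0 || all(r$p_value >= config$selection_alpha)
    }, TRUE))
    inc && exc
  }, TRUE)

  aic <- vapply(fits_ml, function(f) f$AIC, 0)
  bic <- vapply(fits_ml, function(f) f$BIC, 0)
  aic_best <- labels[which.min(aic)]
  bic_best <- labels[which.min(bic)]
  supported <- labels[ci_excl & lrt_ok]
  test_best <- if (length(supported) == 1L) supported else NA_character_

  nterms <- vapply(cands, length, 0L)
  if (!is.na(test_best) && aic_best == bic_best && aic_best == test_best) {
    chosen <- aic_best
    agreement <- TRUE
    note <- "all metrics agree"
  } else {
    contenders <- unique(c(aic_best, bic_best,
                           if (!is.na(test_best)) test_best,
                           supported))
    ord <- order(nterms[match(contenders, labels)],
                 match(contenders, labels))
    chosen <- contenders[ord][1]
    agreement <- FALSE
    note <- paste0("metrics split (AIC: ", aic_best, ", BIC: ", bic_best,
                   ", CI/LRT: ",
                   if (is.na(test_best)) paste(supported, collapse = "|")
                   else test_best,
                   "); simpler contender '", chosen, "' retained")
  }
  trace <- tibble::tibble(
    model = labels, n_terms = nterms, AIC = aic, BIC = bic,
    logLik_ml = vapply(fits_ml, function(f) f$logLik, 0),
    ci_excludes_zero = ci_excl, lrt_supported = lrt_ok,
    singular = vapply(fits_reml, function(f) f$singular, TRUE))
  list(fixed = cands[[match(chosen, labels)]], spec = chosen,
       fits_ml = fits_ml, fits_reml = fits_reml, trace = trace,
       lrt_table = lrt_table, agreement = agreement, note = note)
}

#' Regional normative map: per-ROI age-model fits
#'
#' Fits the age model `RBP(band) ~ age + (1|hospital)` by REML in every
#' region of a mirrored normative table, extracting the age coefficient,
#' its standard error and confidence interval, a CI-contains-zero flag
#' and the singular-fit flag. All fits are retained, including singular
#' ones; regions with fewer than `config$min_roi_n` rows are returned
#' unfitted with a reason. Regions are ordered by decreasing sample
#' size.
#'
#' @param table A mirrored [as_normative_table()].
#' @param bands Character vector of bands to map (default all five).
#' @param config A [pipeline_config()].
#' @param ci_method `"profile"` (default, with Wald fallback) or
#'   `"wald"`.
#' @return A tibble of class `regional_map`, one row per ROI x band:
#'   `roi`, `band`, `n`, `n_hospitals`, `fitted`, `reason`, `intercept`,
#'   `b_age`, `se_b_age`, `ci_lo`, `ci_hi`, `ci_contains_zero`,
#'   `singular`, `sigma2_u`, `sigma2_e`.
#' @export
fit_regional <- function(table, bands = band_names(),
                         config = pipeline_config(),
                         ci_method = c("profile", "wald")) {
  ci_method <- match.arg(ci_method)
  if (!is_mirrored(table))
    stop("regional mapping expects a mirrored table; see mirror_table()")
  rois <- names(sort(table(table$roi), decreasing = TRUE))
  rows <- list()
  z <- stats::qnorm(1 - (1 - config$conf_level) / 2)
  for (r in rois) {
    sub <- table[table$roi == r, ]
    n <- nrow(sub)
    nh <- length(unique(sub$hospital))
    for (b in bands) {
      if (n < config$min_roi_n) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          roi = r, band = b, n = n, n_hospitals = nh, fitted = FALSE,
          reason = sprintf("n=%d below minimum %d", n, config$min_roi_n),
          intercept = NA_real_, b_age = NA_real_, se_b_age = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, ci_contains_zero = NA,
          singular = NA, sigma2_u = NA_real_, sigma2_e = NA_real_)
        next
      }
      fit <- suppressWarnings(
        fit_lmm(sub, b, fixed = "age", method = "REML",
                singular_tol = config$singular_tol))
      ci <- if (ci_method == "profile")
        tryCatch(suppressWarnings(
          profile_ci(fit, "age", level = config$conf_level)),
          error = function(e) fit$coefficients["age"] +
            c(-1, 1) * z * fit$se["age"])
      else fit$coefficients["age"] + c(-1, 1) * z * fit$se["age"]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        roi = r, band = b, n = n, n_hospitals = nh, fitted = TRUE,
        reason = NA_character_,
        intercept = fit$coefficients[["(Intercept)"]],
        b_age = fit$coefficients[["age"]],
        se_b_age = fit$se[["age"]],
        ci_lo = ci[[1]], ci_hi = ci[[2]],
        ci_contains_zero = ci[[1]] <= 0 && ci[[2]] >= 0,
        singular = fit$singular,
        sigma2_u = fit$sigma2_u, sigma2_e = fit$sigma2_e)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("regional_map", class(out))
  attr(out, "conf_level") <- config$conf_level
  out
}
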