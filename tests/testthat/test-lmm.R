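# Small fixed cohort for oracle comparisons.
small_cohort <- function(seed = 31, H = 4, n_h = 10) {
  simulate_cohort(wb_params(n_hospitals = H, n_per_hospital = n_h,
                            seed = seed))$table
}

test_that("REML and ML optima beat a dense grid-search oracle", {
  tab <- small_cohort()          # 40 rows
  y <- tab$alpha
  X <- cbind(1, tab$age)
  g <- tab$hospital
  fml <- fit_lmm(tab, "alpha", "age", method = "ML")
  frm <- fit_lmm(tab, "alpha", "age", method = "REML")
  # ML: grid over (beta0, b_age, sigma2_u, sigma2_e) around the estimate
  b0 <- seq(fml$coefficients[1] - 0.02, fml$coefficients[1] + 0.02,
            length.out = 7)
  b1 <- seq(fml$coefficients[2] - 4e-4, fml$coefficients[2] + 4e-4,
            length.out = 7)
  s2u <- c(0, 1e-5, 1e-4, 5e-4, 1e-3, 5e-3)
  s2e <- seq(fml$sigma2_e * 0.5, fml$sigma2_e * 2, length.out = 8)
  best <- -Inf
  for (a in b0) for (b in b1) for (u in s2u) for (e in s2e)
    best <- max(best, oracle_loglik_ml(y, X, g, c(a, b), u, e))
  expect_gte(fml$logLik + 1e-6, best)
  # the grid point at the fitted parameters matches the stored logLik
  expect_equal(oracle_loglik_ml(y, X, g, unname(fml$coefficients),
                                fml$sigma2_u, fml$sigma2_e),
               fml$logLik, tolerance = 1e-8)
  # REML: grid over the variance components with beta profiled
  best_r <- -Inf
  for (u in c(s2u, frm$sigma2_u)) for (e in s2e)
    best_r <- max(best_r, oracle_loglik_reml(y, X, g, u, e))
  expect_gte(frm$logLik + 1e-6, best_r)
  expect_equal(oracle_loglik_reml(y, X, g, frm$sigma2_u, frm$sigma2_e),
               frm$logLik, tolerance = 1e-8)
})

test_that("fits agree with lme4 on coefficients, variances and likelihoods", {
  skip_if_not_installed("lme4")
  tab <- small_cohort(seed = 7, H = 6, n_h = 15)
  d <- as.data.frame(tab)
  for (method in c("REML", "ML")) {
    f <- fit_lmm(tab, "delta", c("age", "sex"), method = method)
    m <- lme4::lmer(delta ~ age + sex + (1 | hospital), data = d,
                    REML = method == "REML")
    expect_equal(unname(f$coefficients), unname(lme4::fixef(m)),
                 tolerance = 1e-6)
    expect_equal(f$sigma2_u,
                 as.numeric(lme4::VarCorr(m)$hospital), tolerance = 1e-5)
    expect_equal(f$sigma2_e, stats::sigma(m)^2, tolerance = 1e-6)
    expect_equal(f$logLik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
    expect_equal(unname(f$se),
                 unname(sqrt(diag(as.matrix(stats::vcov(m))))),
                 tolerance = 1e-4)
    # BLUPs
    expect_equal(unname(f$u), lme4::ranef(m)$hospital[, 1],
                 tolerance = 1e-5)
  }
})

test_that("with the ratio pinned at zero the fit reduces to OLS", {
  # a single hospital forces lambda = 0 (variance split unidentifiable):
  # the GLS solution collapses to ordinary least squares
  tab <- small_cohort(seed = 13, H = 1, n_h = 40)
  expect_warning(f <- fit_lmm(tab, "beta", "age", method = "ML"),
                 "single hospital")
  expect_true(f$singular)
  expect_equal(f$sigma2_u, 0)
  ols <- stats::lm(beta ~ age, data = as.data.frame(tab))
  expect_equal(unname(f$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-9)
  # with one row per hospital u and e are confounded but the balanced
  # design still makes the GLS coefficients equal OLS at any ratio
  tab1 <- small_cohort(seed = 13, H = 30, n_h = 1)
  f1 <- fit_lmm(tab1, "beta", "age", method = "ML")
  ols1 <- stats::lm(beta ~ age, data = as.data.frame(tab1))
  expect_equal(unname(f1$coefficients), unname(stats::coef(ols1)),
               tolerance = 1e-6)
})

test_that("information criteria recompute from logLik and k", {
  tab <- small_cohort(seed = 3)
  f <- fit_lmm(tab, "alpha", "age", method = "ML")
  expect_identical(f$k, 4L)  # intercept, age, sigma2_u, sigma2_e
  expect_equal(f$AIC, -2 * f$logLik + 2 * f$k)
  expect_equal(f$BIC, -2 * f$logLik + f$k * log(f$n))
})

test_that("boundary-truth fits collapse to zero hospital variance", {
  # under sigma_u^2 = 0 the REML estimate sits on the boundary with
  # probability ~1/2 (Self-Liang mixture); the singular flag should fire
  # at about that rate and agree with lme4's isSingular on every fit
  skip_if_not_installed("lme4")
  ours <- l4 <- logical(100)
  su2 <- numeric(100)
  for (i in 1:100) {
    tab <- simulate_cohort(wb_params(sigma_u = 0, n_hospitals = 8,
                                     n_per_hospital = 8,
                                     seed = 4000L + i))$table
    f <- fit_lmm(tab, "theta", "age")
    ours[i] <- f$singular
    su2[i] <- f$sigma2_u
    m <- suppressMessages(lme4::lmer(
      theta ~ age + (1 | hospital), data = as.data.frame(tab),
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    l4[i] <- lme4::isSingular(m)
  }
  expect_equal(ours, l4)
  expect_gte(mean(ours), 0.3)
  expect_lte(mean(ours), 0.7)
  # and the estimated hospital variance stays near zero on average
  expect_lt(mean(su2), 0.1 * 0.024^2)
})

test_that("ICC and marginal R2 recover their generative values", {
  # sigma_u^2 = 1, sigma_e^2 = 3 -> ICC 0.25, on a 20 x 50 design
  iccs <- vapply(1:20, function(i) {
    tab <- simulate_cohort(wb_params(sigma_u = 1, sigma_e = sqrt(3),
                                     b_age = 0, b_sex = 0,
                                     n_hospitals = 20, n_per_hospital = 50,
                                     seed = 5000L + i))$table
    icc(fit_lmm(tab, "alpha"))
  }, 0)
  # Monte-Carlo SE of the mean ICC over 20 reps of 20 hospitals ~ 0.018
  expect_lt(abs(mean(iccs) - 0.25), 0.055)
  # closed-form cases
  tab <- small_cohort(seed = 19)
  f0 <- fit_lmm(tab, "alpha")
  expect_equal(marginal_r2(f0), 0)
  expect_equal(icc(f0), f0$sigma2_u / (f0$sigma2_u + f0$sigma2_e))
  # R2m near its plug-in truth: var_fixed 1, sigma2_u 1, sigma2_e 2
  age_sd <- sqrt(stats::var(stats::runif(1e6, 4, 66)))
  slope <- 1 / age_sd
  r2 <- vapply(1:20, function(i) {
    tab <- simulate_cohort(wb_params(b_age = slope, b_sex = 0, sigma_u = 1,
                                     sigma_e = sqrt(2), n_hospitals = 15,
                                     n_per_hospital = 40,
                                     seed = 6000L + i))$table
    marginal_r2(fit_lmm(tab, "gamma", "age"))
  }, 0)
  expect_equal(mean(r2), 0.25, tolerance = 0.03)
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("profile intervals contain the estimate and match Wald at scale", {
  tab <- simulate_cohort(wb_params(n_hospitals = 15, n_per_hospital = 60,
                                   seed = 77))$table
  f <- fit_lmm(tab, "alpha", "age")
  ci <- profile_ci(f, "age")
  expect_lt(ci[1], f$coefficients["age"])
  expect_gt(ci[2], f$coefficients["age"])
  # large balanced data: profile and Wald half-widths agree within 10%
  wald_half <- stats::qnorm(0.975) * f$se["age"]
  prof_half <- (ci[2] - ci[1]) / 2
  expect_equal(unname(prof_half / wald_half), 1, tolerance = 0.1)
  expect_error(profile_ci(f, "sexmale"), "not a fixed effect")
})

test_that("profile intervals match lme4's likelihood profiling", {
  skip_if_not_installed("lme4")
  tab <- small_cohort(seed = 41, H = 6, n_h = 12)
  f <- fit_lmm(tab, "alpha", "age")
  ci <- profile_ci(f, "age")
  m <- lme4::lmer(alpha ~ age + (1 | hospital), data = as.data.frame(tab))
  ci4 <- suppressWarnings(
    suppressMessages(stats::confint(m, parm = "age", quiet = TRUE)))
  expect_equal(as.numeric(ci), as.numeric(ci4[1, ]), tolerance = 1e-4)
})

test_that("the likelihood ratio test is valid and guards its preconditions", {
  tab <- small_cohort(seed = 53, H = 6, n_h = 15)
  f0 <- fit_lmm(tab, "delta", method = "ML")
  f1 <- fit_lmm(tab, "delta", "age", method = "ML")
  f2 <- fit_lmm(tab, "delta", c("age", "sex"), method = "ML")
  t1 <- lrt(f0, f1)
  expect_gte(t1$statistic, 0)
  expect_equal(t1$p_value,
               stats::pchisq(t1$statistic, 1, lower.tail = FALSE))
  # REML fits refused; non-nested pairs refused
  expect_error(lrt(fit_lmm(tab, "delta"), f1), "ML")
  expect_error(lrt(f0, f2), "exactly one")
  expect_error(lrt(fit_lmm(tab, "delta", "sex", method = "ML"), f1),
               "nested|exactly one")
  # degenerate added column: all-female cohort makes sex an aliased zero
  # column, the alt collapses onto the null and the statistic is 0
  tabf <- tab; tabf$sex <- "female"
  g0 <- fit_lmm(tabf, "delta", method = "ML")
  g1 <- suppressWarnings(fit_lmm(tabf, "delta", "sex", method = "ML"))
  tz <- lrt(g0, g1)
  expect_equal(tz$statistic, 0, tolerance = 1e-8)
  expect_equal(tz$p_value, 1, tolerance = 1e-8)
})

test_that("a strongly planted age effect is detected decisively", {
  tab <- simulate_cohort(wb_params(b_age = 2e-3, seed = 61))$table
  f0 <- fit_lmm(tab, "alpha", method = "ML")
  f1 <- fit_lmm(tab, "alpha", "age", method = "ML")
  expect_lt(lrt(f0, f1)$p_value, 1e-3)
})

test_that("model selection returns a full decision trace", {
  tab <- simulate_cohort(wb_params(seed = 71))$table
  sel <- select_model(tab, "alpha", ci_method = "wald")
  expect_true(sel$spec %in% c("null", "age", "sex", "age+sex"))
  expect_equal(nrow(sel$trace), 4L)
  expect_setequal(sel$lrt_table$term, c("age", "sex"))
  expect_equal(nrow(sel$lrt_table), 4L)
  expect_true(is.character(sel$note))
})

test_that("regional maps report per-ROI age fits ordered by sample size", {
  sim <- simulate_cohort(regional_params(seed = 83))
  map <- fit_regional(sim$table, bands = c("delta", "alpha"),
                      ci_method = "wald")
  expect_s3_class(map, "regional_map")
  expect_equal(nrow(map), 6L)
  ns <- map$n[map$band == "delta"]
  expect_true(all(diff(ns) <= 0))
  fitted <- map[map$fitted, ]
  expect_equal(fitted$ci_contains_zero,
               fitted$ci_lo <= 0 & fitted$ci_hi >= 0)
  # unmirrored tables are refused
  tab_un <- as_normative_table(as.data.frame(sim$table), mirrored = FALSE)
  expect_error(fit_regional(tab_un), "mirrored")
})

test_that("an ROI sampled by a single hospital yields a singular fit", {
  sim <- simulate_cohort(regional_params(seed = 91))
  tab <- sim$table[sim$table$hospital == "hosp01" |
                     sim$table$roi != "hippocampus", ]
  tab <- as_normative_table(as.data.frame(tab), mirrored = TRUE)
  map <- suppressWarnings(fit_regional(tab, bands = "alpha",
                                       ci_method = "wald"))
  hip <- map[map$roi == "hippocampus", ]
  expect_equal(hip$n_hospitals, 1L)
  expect_true(hip$singular)
  # small ROIs are reported unfitted with a reason
  cfg <- pipeline_config(min_roi_n = 1e6)
  map2 <- fit_regional(tab, bands = "alpha", config = cfg)
  expect_true(all(!map2$fitted))
  expect_match(map2$reason[1], "below minimum")
})
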