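# Contraction detection, rate modelling, respirometry and coupling.

test_that("constant traces yield no events; all-missing yields empty", {
  t <- seq(0, 4 * 3600, 30)
  flat <- data.frame(timestamp_s = t, area = 5000)
  expect_equal(nrow(detect_contractions(flat)), 0L)
  miss <- data.frame(timestamp_s = t, area = NA_real_)
  expect_equal(nrow(detect_contractions(miss)), 0L)
  short <- data.frame(timestamp_s = c(0, 30), area = c(1, 1))
  expect_error(detect_contractions(short), "baseline")
})

test_that("planted noise-free events are recovered at the planted times", {
  et <- experiment_truth(schedule = data.frame(t_start_s = 0,
                                               percent_as = 100),
                         duration_s = 86400, lambda_per_day = 3,
                         noise_sd = 0, o2_noise_uM = 0, seed = 2)
  sim <- simulate_experiment(et)
  ev <- detect_contractions(sim$area)
  expect_equal(nrow(ev), nrow(sim$events))
  expect_true(all(ev$class == "full_body"))
  # onsets recovered within a couple of samples: the detector fires
  # when the dip crosses theta_sub, slightly after the true onset
  expect_true(all(abs(ev$trough_s - sim$events$trough_s) <= 60))
})

test_that("amplitude classes follow the thresholds", {
  t <- seq(0, 6 * 3600, 30)
  area <- rep(1000, length(t))
  dip <- t >= 3 * 3600 & t <= 3.5 * 3600
  area[dip] <- 1000 * (1 - 0.2 * sin(pi * (t[dip] - 3 * 3600) / 1800)^2)
  ev <- detect_contractions(data.frame(timestamp_s = t, area = area))
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$class, "sub")
  expect_lt(abs(ev$amplitude - 0.2), 0.03)

  area2 <- rep(1000, length(t))
  area2[dip] <- 1000 * (1 - 0.6 * sin(pi * (t[dip] - 3 * 3600) / 1800)^2)
  ev2 <- detect_contractions(data.frame(timestamp_s = t, area = area2))
  expect_identical(ev2$class, "full_body")
})

test_that("contraction rate is count over interval in days", {
  ev <- data.frame(start_s = seq(0, 11 * 3600, 2 * 3600),
                   trough_s = 0, end_s = 0, amplitude = 0.6,
                   class = "full_body")
  expect_equal(contraction_rate(ev, c(0, 12 * 3600)), 12)
  expect_equal(contraction_rate(ev[0, ], c(0, 86400)), 0)
  expect_equal(contraction_rate(ev, c(0, 12 * 3600), "sub"), 0)
  expect_error(contraction_rate(ev, c(5, 5)), "positive")
})

test_that("identical-rate groups give LRT 0 and matched MLEs", {
  d <- data.frame(individual = "a", level = c("x", "y"),
                  count = c(5, 5), exposure_days = 1)
  f <- fit_rate_model(d)
  expect_equal(f$lrt$statistic, 0, tolerance = 1e-8)
  expect_equal(f$lrt$p_value, 1, tolerance = 1e-6)
  expect_gte(f$loglik_fit, f$loglik_null - 1e-10)
})

test_that("the IRLS fit matches glm() on nontrivial data", {
  set.seed(31)
  d <- expand.grid(individual = paste0("s", 1:6),
                   level = c("hi", "mid", "lo"),
                   stringsAsFactors = FALSE)
  d$exposure_days <- runif(nrow(d), 0.5, 2)
  d$count <- rpois(nrow(d), c(hi = 10, mid = 8, lo = 2)[d$level] *
                     d$exposure_days)
  f <- fit_rate_model(d)
  g <- stats::glm(count ~ 0 + individual + level +
                    offset(log(exposure_days)),
                  family = stats::poisson,
                  data = transform(d, level = factor(level,
                                                     levels = c("hi", "mid",
                                                                "lo"))))
  expect_equal(f$loglik_fit, as.numeric(stats::logLik(g)),
               tolerance = 1e-6)
  expect_equal(unname(f$coefficients["level:lo"]),
               unname(stats::coef(g)["levello"]), tolerance = 1e-6)
  # LRT statistic is twice the log-likelihood gap and non-negative
  expect_equal(f$lrt$statistic,
               2 * (f$loglik_fit - f$loglik_null), tolerance = 1e-10)
  expect_gte(f$lrt$statistic, 0)
})

test_that("all-zero groups are reported at the boundary, not an error", {
  d <- data.frame(individual = rep(c("a", "b"), 2),
                  level = rep(c("norm", "anoxic"), each = 2),
                  count = c(6, 8, 0, 0), exposure_days = 1)
  f <- fit_rate_model(d)
  expect_identical(unname(f$coefficients["level:anoxic"]), -Inf)
  expect_true(is.finite(f$lrt$statistic))
  expect_equal(unname(f$rate_ratios["anoxic"]), 0)
})

test_that("rate-ratio recovery is accurate over replicates", {
  set.seed(17)
  ratios <- vapply(1:60, function(i) {
    d <- expand.grid(individual = paste0("s", 1:8),
                     level = c("hi", "lo"), stringsAsFactors = FALSE)
    d$exposure_days <- 1
    d$count <- rpois(nrow(d), c(hi = 10, lo = 2)[d$level])
    fit_rate_model(d)$rate_ratios["lo"]
  }, numeric(1))
  expect_lt(abs(median(ratios) - 0.2), 0.05 * 0.2 + 0.02)
})

test_that("respiration slopes are exact on linear and piecewise traces", {
  t <- seq(0, 3600, 30)
  lin <- data.frame(timestamp_s = t,
                    o2_uM = 211 - 11 * t / 3600)
  r <- respiration_rate(lin, 9)
  mid <- !is.na(r$uptake_uM_per_hr)
  expect_true(all(abs(r$uptake_uM_per_hr[mid] - 11) < 1e-9))
  flat <- data.frame(timestamp_s = t, o2_uM = 200)
  rf <- respiration_rate(flat, 9)
  expect_true(all(abs(rf$uptake_uM_per_hr[!is.na(rf$uptake_uM_per_hr)])
                  < 1e-12))
  # piecewise slopes away from the breakpoint
  t2 <- seq(0, 7200, 30)
  pw <- data.frame(timestamp_s = t2,
                   o2_uM = ifelse(t2 <= 3600, 211 - 5 * t2 / 3600,
                                  206 - 20 * (t2 - 3600) / 3600))
  rp <- respiration_rate(pw, 9)
  early <- which(t2 < 3000)
  late <- which(t2 > 4200 & t2 < 6800)
  expect_true(all(abs(rp$uptake_uM_per_hr[early][-(1:4)] - 5) < 1e-9))
  expect_true(all(abs(rp$uptake_uM_per_hr[late] - 20) < 1e-9))
  expect_error(respiration_rate(lin, 999), "larger")
  expect_error(respiration_rate(lin, 2), "at least 3")
})

test_that("phase-coupled uptake recovers a planted contrast exactly", {
  t <- seq(0, 12 * 3600, 30)
  ev <- data.frame(start_s = c(2, 6, 10) * 3600,
                   trough_s = c(2.25, 6.25, 10.25) * 3600,
                   end_s = c(2.5, 6.5, 10.5) * 3600,
                   amplitude = 0.6, class = "full_body")
  inside <- rep(FALSE, length(t))
  for (k in 1:3) inside <- inside | (t >= ev$start_s[k] &
                                       t <= ev$end_s[k])
  rates <- data.frame(timestamp_s = t,
                      uptake_uM_per_hr = ifelse(inside, 10, 5))
  r <- phase_coupled_uptake(rates, ev, n_shuffles = 199, seed = 6)
  expect_equal(r$difference, 5)
  expect_equal(r$mean_contracting, 10)
  expect_lt(r$p_value, 0.05)
  r2 <- phase_coupled_uptake(rates, ev, n_shuffles = 199, seed = 6)
  expect_identical(r, r2)
  # identical phases -> difference 0, p 1
  same <- data.frame(timestamp_s = t, uptake_uM_per_hr = 7)
  rs <- phase_coupled_uptake(same, ev, n_shuffles = 99, seed = 1)
  expect_equal(rs$difference, 0)
  expect_equal(rs$p_value, 1)
  expect_error(phase_coupled_uptake(rates, ev[0, ], 99, 1), "no contraction")
})
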