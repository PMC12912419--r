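# Statistical pipeline: endpoint coding, categorization, KM/log-rank, Cox,
# concordance, nested LRT, reclassification, stratified analyses.

make_surv <- function(n, seed, event_p = 0.5) {
  set.seed(seed)
  data.frame(time_y = runif(n, 0.1, 8),
             event = ifelse(runif(n) < event_p, "cvd_death", "censored"),
             stringsAsFactors = FALSE)
}

test_that("cardiovascular death codes are recognized (57-code list)", {
  expect_true(is_cvd_death_code("I250"))
  expect_true(is_cvd_death_code("i25.0"))   # case and dots are normalized
  expect_true(is_cvd_death_code("I10"))
  expect_true(is_cvd_death_code("I770"))
  expect_false(is_cvd_death_code("C349"))
  expect_false(is_cvd_death_code("I999"))
  expect_length(aortaflow:::CVD_DEATH_CODES, 57L)
  expect_false(anyDuplicated(aortaflow:::CVD_DEATH_CODES) > 0)
  expect_error(is_cvd_death_code(""), "non-empty")
})

test_that("categorization reproduces split sizes and boundary semantics", {
  n <- 24770
  set.seed(8)
  co <- data.frame(max_diameter_cm = rnorm(n, 3.6, 0.4),
                   aortic_volume_ml = rnorm(n, 215, 52),
                   aortic_calcium_mm3 = exp(rnorm(n, 6.5, 1.1)),
                   time_y = runif(n, 6, 6.9), event = "censored")
  cfg <- analysis_config(calcium_cutoffs_mm3 = "data_tertiles")
  cc <- categorize_features(co, cfg)
  expect_equal(as.vector(table(cc$volume_group)), c(12385, 12385))
  expect_equal(as.vector(table(cc$calcium_tertile)), c(8257, 8257, 8256))
  # fixed cutoffs: < 270 is T1, [270, 1050) is T2, >= 1050 is T3
  co3 <- data.frame(max_diameter_cm = c(3, 4.5, 5),
                    aortic_volume_ml = c(100, 200, 300),
                    aortic_calcium_mm3 = c(0, 270, 1050),
                    time_y = 1, event = "censored")
  cc3 <- categorize_features(co3, analysis_config())
  expect_equal(as.character(cc3$calcium_tertile), c("T1", "T2", "T3"))
  expect_equal(as.character(cc3$diameter_group),
               c("<4.5cm", ">=4.5cm", ">=4.5cm"))
  # missing features are excluded with a message and kept in the attribute
  co3$aortic_volume_ml[2] <- NA
  expect_message(cc4 <- categorize_features(co3, analysis_config()),
                 "excluding 1")
  expect_equal(nrow(cc4), 2L)
  expect_equal(nrow(attr(cc4, "excluded")), 1L)
})

test_that("median split and tertile sizes differ by at most one", {
  for (n in c(101, 1000, 24770)) {
    co <- data.frame(max_diameter_cm = 3.6, aortic_volume_ml = runif(n),
                     aortic_calcium_mm3 = runif(n), time_y = 1,
                     event = "censored")
    cc <- categorize_features(co,
                              analysis_config(calcium_cutoffs_mm3 = "data_tertiles"))
    expect_lte(diff(range(table(cc$volume_group))), 1)
    expect_lte(diff(range(table(cc$calcium_tertile))), 1)
  }
})

test_that("log-rank matches a hand-computed statistic and handles duplicates", {
  # 4 subjects, all events: hand O-E/V computation
  d4 <- data.frame(time_y = c(1, 2, 3, 4), event = "cvd_death",
                   grp = factor(c("A", "A", "B", "B")))
  lr <- km_logrank(d4, "grp")
  v <- function(n1, n2, dd) {
    n <- n1 + n2
    if (n < 2) return(0)
    n1 * n2 * dd * (n - dd) / (n^2 * (n - 1))
  }
  V <- v(2, 2, 1) + v(1, 2, 1) + v(0, 2, 1) + v(0, 1, 1)
  OE <- 2 - (2 / 4 + 1 / 3 + 0 + 0)
  expect_equal(lr$pairwise$statistic, OE^2 / V, tolerance = 1e-10)
  # identical survival in both groups: statistic 0, p 1
  base <- make_surv(40, 1)
  dup <- rbind(cbind(base, grp = "A"), cbind(base, grp = "B"))
  lr2 <- km_logrank(dup, "grp")
  expect_lt(lr2$pairwise$statistic, 1e-10)
  expect_equal(lr2$pairwise$p, 1, tolerance = 1e-6)
  # three groups: exactly 3 pairwise tests, Holm-adjusted >= raw, monotone
  d3 <- cbind(make_surv(90, 2), grp = rep(c("A", "B", "C"), each = 30))
  lr3 <- km_logrank(d3, "grp")
  expect_equal(nrow(lr3$pairwise), 3L)
  expect_true(all(lr3$pairwise$p_adjusted >= lr3$pairwise$p - 1e-12))
  ord <- order(lr3$pairwise$p)
  expect_true(all(diff(lr3$pairwise$p_adjusted[ord]) >= -1e-12))
  expect_error(km_logrank(cbind(base, grp = "A"), "grp"), "two groups")
})

test_that("Cox coefficient matches a 1-D grid-search partial-likelihood oracle", {
  d <- data.frame(time_y = c(1, 2, 3), event = "cvd_death", x = c(0, 1, 0))
  # no ties: log PL(b) = -log(e^b + 2) + b - log(e^b + 1)
  grid <- seq(-5, 5, by = 1e-4)
  lpl <- -log(exp(grid) + 2) + grid - log(exp(grid) + 1)
  b_oracle <- grid[which.max(lpl)]
  f <- cox_fit(d, "x")
  expect_equal(unname(f$coefficients[1]), b_oracle, tolerance = 1e-3)
  expect_equal(f$n_events, 3)
  # loglik at the maximum matches the oracle value
  expect_equal(f$log_likelihood, max(lpl), tolerance = 1e-6)
})

test_that("Cox fits are invariant to affine covariate rescaling", {
  d <- simulate_group_cohort(c(400, 400), 2.5, 0.4, "overall", seed = 21)
  d$x <- as.integer(d$group == "g2")
  d$x_scaled <- 10 * d$x + 3
  f1 <- cox_fit(d, "x")
  f2 <- cox_fit(d, "x_scaled")
  expect_equal(unname(f1$coefficients[1]), 10 * unname(f2$coefficients[1]),
               tolerance = 1e-6)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-8)
  expect_error(cox_fit(within(d, const <- 1), "const"), "constant")
})

test_that("Cox recovery under the published two-group geometry", {
  hrs <- sapply(1:10, function(s) {
    d <- simulate_group_cohort(c(24490, 280), 3.68, 423 / 24490, "reference",
                               seed = 600 + s)
    cox_fit(d, "group")$hazard_ratios[[1]]
  })
  expect_equal(pool_hazard_ratios(hrs), 3.68, tolerance = 0.17)
})

test_that("c-index equals brute-force pair enumeration on random censored data", {
  set.seed(1234)
  for (k in 1:100) {
    n <- sample(10:50, 1)
    d <- data.frame(time_y = runif(n, 0.1, 8),
                    event = ifelse(runif(n) < 0.6, "cvd_death", "censored"))
    score <- round(rnorm(n), 1)  # rounded so tied scores occur
    if (!any(d$event == "cvd_death")) next
    h <- harrell_c(d, score)
    b <- brute_force_cindex(d$time_y, as.integer(d$event == "cvd_death"), score)
    expect_equal(h$c, b, tolerance = 1e-12)
  }
})

test_that("c-index endpoints: perfect ranking gives 1, pure noise gives ~0.5", {
  n <- 200
  d <- data.frame(time_y = sort(runif(n, 0.1, 8)), event = "cvd_death")
  expect_equal(harrell_c(d, rev(seq_len(n)))$c, 1.0)
  set.seed(2)
  d2 <- make_surv(2000, 3)
  expect_lt(abs(harrell_c(d2, rnorm(2000))$c - 0.5), 0.03)
  d3 <- data.frame(time_y = c(1, 2), event = "censored")
  expect_error(harrell_c(d3, c(1, 2)), "usable")
  expect_error(harrell_c(d2, rep(NA_real_, 2000)), "finite")
})

test_that("concordance comparison is rank-invariant and detects a better marker", {
  d <- make_surv(500, 11)
  s <- rnorm(500)
  cc <- compare_c(d, s, exp(s))  # monotone transform: identical ranks
  expect_equal(cc$delta, 0, tolerance = 1e-12)
  expect_equal(compare_c(d, s, s)$p, 1)
  wins <- sapply(1:10, function(k) {
    set.seed(100 + k)
    n <- 10000
    lp <- rnorm(n)
    noise <- rnorm(n)
    marker_a <- lp + noise          # diluted version of the linear predictor
    marker_b <- lp + 0.3 * noise    # twice the signal-to-noise on the log-hazard
    t_ev <- rexp(n, 0.05 * exp(0.8 * lp))
    cen <- runif(n, 6, 6.9)
    dd <- data.frame(time_y = pmin(t_ev, cen),
                     event = ifelse(t_ev <= cen, "cvd_death", "censored"))
    r <- compare_c(dd, marker_b, marker_a)
    r$delta > 0 && r$p < 0.05
  })
  expect_gte(mean(wins), 0.9)
})

test_that("nested LRT is zero on itself and chi-square(1) under the null", {
  d <- simulate_group_cohort(c(100, 100), 2, 0.4, "overall", seed = 5)
  f <- cox_fit(d, "group")
  same <- nested_lrt(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  stats_null <- sapply(1:400, function(s) {
    dd <- simulate_group_cohort(c(60, 60), 2.0, 0.5, "overall", seed = 7000 + s)
    set.seed(s)
    dd$noise <- rnorm(nrow(dd))
    nested_lrt(cox_fit(dd, "group"), cox_fit(dd, c("group", "noise")))$statistic
  })
  ks <- suppressWarnings(stats::ks.test(stats_null, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
  f2 <- cox_fit(within(d, z <- seq_len(nrow(d))), "z")
  expect_error(nested_lrt(f, f2), "not nested")
})

test_that("nested LRT power agrees with a Monte-Carlo Wald rejection oracle", {
  res <- t(sapply(1:60, function(s) {
    set.seed(9000 + s)
    n <- 300
    dd <- data.frame(x1 = rep(0:1, each = n / 2), x2 = rnorm(n))
    t_ev <- rexp(n, 0.08 * exp(log(2) * dd$x1 + 0.45 * dd$x2))
    cen <- runif(n, 6, 6.9)
    dd$time_y <- pmin(t_ev, cen)
    dd$event <- ifelse(t_ev <= cen, "cvd_death", "censored")
    base <- cox_fit(dd, "x1")
    ext <- cox_fit(dd, c("x1", "x2"))
    lrt <- nested_lrt(base, ext)
    wald <- ext$p_values[["x2"]]
    c(lrt = lrt$p < 0.05, wald = wald < 0.05)
  }))
  # the two tests are asymptotically equivalent: rejection rates agree within
  # binomial error, and power against this real effect is high
  expect_lt(abs(mean(res[, "lrt"]) - mean(res[, "wald"])),
            3 * sqrt(0.25 / nrow(res)))
  expect_gt(mean(res[, "lrt"]), 0.8)
})

test_that("reclassification table counts, rates and monotone structure", {
  d <- data.frame(time_y = c(1, 2, 3), event = c("cvd_death", "censored",
                                                 "cvd_death"),
                  calcium_tertile = factor("T1", levels = c("T1", "T2", "T3")),
                  cac_category = factor("0", levels = c("0", "1-99", "100-399",
                                                        ">=400")))
  rt <- reclassification_table(d)
  expect_equal(sum(rt$n), 3L)
  one <- rt[rt$n > 0, ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$event_rate, 2 / 3)
  expect_true(all(is.na(rt$event_rate[rt$n == 0])))
  # perfectly aligned categories: off-diagonal cells stay empty
  d2 <- data.frame(time_y = runif(300, 1, 8),
                   event = sample(c("cvd_death", "censored"), 300, TRUE),
                   calcium_tertile = factor(rep(c("T1", "T2", "T3"), 100)),
                   cac_category = factor(rep(c("0", "1-99", "100-399"), 100),
                                         levels = c("0", "1-99", "100-399",
                                                    ">=400")))
  rt2 <- reclassification_table(d2)
  off <- rt2[!(as.integer(factor(rt2$calcium_tertile)) ==
                 as.integer(factor(rt2$cac_category,
                                   levels = c("0", "1-99", "100-399")))), ]
  expect_true(all(off$n == 0, na.rm = TRUE))
  # calcium effect independent of CAC: within-column rates rise across tertiles
  mono <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 6000
    tert <- sample(1:3, n, TRUE)
    cacc <- sample(1:4, n, TRUE)
    h <- 0.02 * exp(0.8 * (tert - 1))
    t_ev <- rexp(n, h); cen <- runif(n, 6, 6.9)
    dd <- data.frame(time_y = pmin(t_ev, cen),
                     event = ifelse(t_ev <= cen, "cvd_death", "censored"),
                     calcium_tertile = factor(paste0("T", tert)),
                     cac_category = factor(cacc))
    rr <- reclassification_table(dd)
    all(sapply(levels(dd$cac_category), function(cc) {
      rates <- rr$event_rate[rr$cac_category == cc]
      mean(diff(rates) > 0) >= 0.5
    }))
  })
  expect_gte(mean(mono), 0.9)
})

test_that("stratified sensitivity analysis respects strata and event minima", {
  d <- simulate_confounded_tertile_cohort(6000, c(1.2, 2.5),
                                          target_event_fraction = 0.05,
                                          seed = 13)
  d$max_diameter_cm <- 3.6 + 0.2 * rnorm(nrow(d))
  d$aortic_volume_ml <- 215 + 50 * rnorm(nrow(d))
  d$aortic_calcium_mm3 <- exp(rnorm(nrow(d), 6.5, 1.1))
  cc <- categorize_features(d, analysis_config(calcium_cutoffs_mm3 = "data_tertiles"))
  res <- run_stratified_sensitivity(cc, min_events = 25)
  expect_named(res, c("sex", "age_group", "hypertension", "no_prior_cvd"))
  expect_true(all(c("female", "male") %in% names(res$sex)))
  for (lv in names(res$sex)) {
    fits <- res$sex[[lv]]
    if (!identical(fits, "skipped"))
      expect_s3_class(fits$calcium_tertile, "survival_fit")
  }
  # a constant stratification reproduces the full-cohort fit
  cc$all <- "everyone"
  full <- cox_fit(cc, "calcium_tertile")
  by_const <- cox_fit(cc[cc$all == "everyone", ], "calcium_tertile")
  expect_equal(full$coefficients, by_const$coefficients)
  # tight event floor: small strata are skipped and logged
  res2 <- run_stratified_sensitivity(cc[1:200, ], min_events = 1e6)
  expect_true(all(unlist(lapply(res2, function(x) lapply(x, identical,
                                                         "skipped")))))
  expect_gt(length(attr(res2, "log")), 0)
})
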