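# Simulated lung-screening cohorts with known survival parameters.
#
# Covariate marginals emulate a heavy-smoker screening population (ages
# 55-74, >= 30 pack-years); aortic features are drawn with realistic
# location/scale and mild age/sex structure; death times follow two
# independent exponential cause-specific hazards (cardiovascular and
# other-cause) with administrative censoring.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

default_covariate_params <- function() {
  list(age = list(mean = 61.4, sd = 5.0, lo = 55, hi = 74),
       p_female = 0.408,
       bmi = list(mean = 27.9, sd = 5.0, lo = 15, hi = 60),
       p_race = c(white = 0.914, african_american = 0.042, other = 0.044),
       p_current_smoker = 0.479,
       packyears = list(mean = 56, sd = 24, lo = 30, hi = Inf),
       p_diabetes = 0.097, p_hypertension = 0.351,
       p_heart_disease = 0.129, p_stroke = 0.028)
}

default_feature_params <- function() {
  # diameter: mean 3.6 cm, sd ~0.4 cm, mild age/sex structure
  # volume: linear in diameter, targets mean 215 ml, sd ~52 ml
  # calcium: log-normal targeting mean 1326 mm^3, sd 2208 mm^3, age effect
  list(diameter = list(intercept = 3.45, b_age = 0.02, b_male = 0.25, sd = 0.36),
       volume = list(intercept = -145, b_diameter = 100, sd = 34, floor = 10),
       calcium = list(mu = log(1326) - 1.327 / 2, b_age = 0.06,
                      sigma = sqrt(1.327 - 0.06^2 * 25)))
}

default_beta_cvd <- function() {
  c(age_c = 0.09, male = 0.55, bmi_c = 0.010, current_smoker = 0.28,
    packyears_c = 0.004, diabetes = 0.35, hypertension = 0.30,
    heart_disease = 0.45, stroke = 0.35, race_african_american = 0,
    race_other = 0, diameter_c = 0.35, volume_c = 0.003, log_calcium_c = 0.60)
}

default_beta_other <- function() {
  c(age_c = 0.09, male = 0.30, bmi_c = -0.010, current_smoker = 0.45,
    packyears_c = 0.005, diabetes = 0.30, hypertension = 0.15,
    heart_disease = 0.30, stroke = 0.25, race_african_american = 0,
    race_other = 0, diameter_c = 0.10, volume_c = 0.001, log_calcium_c = 0.25)
}

#' Specify a synthetic screening cohort
#'
#' Defaults emulate a 24,770-subject heavy-smoker lung-screening cohort:
#' covariate marginals (age truncated normal 61.4 +/- 5.0 on 55-74 y, 40.8%
#' female, BMI 27.9 +/- 5.0, race 91.4/4.2/4.4%, 47.9% current smokers,
#' pack-years 56 +/- 24 truncated at 30, diabetes 9.7%, hypertension 35.1%,
#' heart disease 12.9%, stroke 2.8%), aortic features (diameter ~ N(3.6,
#' 0.4) cm with additive age/sex effects, volume linear in diameter targeting
#' N(215, 52) ml, calcium log-normal targeting mean 1326 / sd 2208 mm^3 with
#' an age effect), cause-specific exponential hazards, and administrative
#' censoring Uniform(6.0, 6.9) years capped at 8.
#'
#' @param n_subjects cohort size.
#' @param covariate_params,feature_params parameter lists; see
#'   `aortaflow:::default_covariate_params()` and
#'   `aortaflow:::default_feature_params()` for the structure.
#' @param beta_cvd,beta_other named log-hazard coefficient vectors on the
#'   centered design columns (see [cohort_design_matrix()]).
#' @param baseline_hazard_cvd,baseline_hazard_other baseline rates per year
#'   at the covariate reference; calibrate with
#'   [calibrate_baseline_hazards()].
#' @param censor_window_years administrative censoring window (uniform);
#'   must lie inside (0, 8].
#' @param cac_missing_fraction fraction of subjects without a coronary
#'   calcium score.
#' @param seed integer seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 24770,
                        covariate_params = default_covariate_params(),
                        feature_params = default_feature_params(),
                        beta_cvd = default_beta_cvd(),
                        beta_other = default_beta_other(),
                        baseline_hazard_cvd = 0.0020,
                        baseline_hazard_other = 0.0105,
                        censor_window_years = c(6.0, 6.9),
                        cac_missing_fraction = 1 - 13898 / 24770,
                        seed = 20240101L) {
  probs <- c(covariate_params$p_female, covariate_params$p_race,
             covariate_params$p_current_smoker, covariate_params$p_diabetes,
             covariate_params$p_hypertension, covariate_params$p_heart_disease,
             covariate_params$p_stroke, cac_missing_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (baseline_hazard_cvd <= 0 || baseline_hazard_other <= 0)
    stop("parameter error: baseline hazards must be positive")
  cw <- as.numeric(censor_window_years)
  if (length(cw) != 2L || cw[1] <= 0 || cw[2] > 8 || cw[1] > cw[2])
    stop("censoring window must lie inside (0, 8]")
  structure(list(n_subjects = as.integer(n_subjects),
                 covariate_params = covariate_params,
                 feature_params = feature_params,
                 beta_cvd = beta_cvd, beta_other = beta_other,
                 baseline_hazard_cvd = baseline_hazard_cvd,
                 baseline_hazard_other = baseline_hazard_other,
                 censor_window_years = cw,
                 cac_missing_fraction = cac_missing_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw cohort covariates
#'
#' @param n number of subjects.
#' @param params covariate parameter list (see [cohort_spec()]).
#' @return data.frame with demographic and risk-factor columns.
#' @export
draw_covariates <- function(n, params = default_covariate_params()) {
  age <- rtruncnorm(n, params$age$mean, params$age$sd, params$age$lo, params$age$hi)
  sex <- ifelse(stats::runif(n) < params$p_female, "female", "male")
  bmi <- rtruncnorm(n, params$bmi$mean, params$bmi$sd, params$bmi$lo, params$bmi$hi)
  race <- sample(names(params$p_race), n, replace = TRUE, prob = params$p_race)
  smoking <- ifelse(stats::runif(n) < params$p_current_smoker, "current", "former")
  packyears <- rtruncnorm(n, params$packyears$mean, params$packyears$sd,
                          params$packyears$lo, params$packyears$hi)
  data.frame(age_y = age, sex = sex, race = race, bmi = bmi,
             smoking_status = smoking, packyears = packyears,
             diabetes = as.integer(stats::runif(n) < params$p_diabetes),
             hypertension = as.integer(stats::runif(n) < params$p_hypertension),
             history_heart_disease = as.integer(stats::runif(n) < params$p_heart_disease),
             history_stroke = as.integer(stats::runif(n) < params$p_stroke),
             stringsAsFactors = FALSE)
}

draw_features <- function(cov, params = default_feature_params()) {
  n <- nrow(cov)
  male <- as.integer(cov$sex == "male")
  dpar <- params$diameter
  d <- dpar$intercept + dpar$b_age * (cov$age_y - 61.4) + dpar$b_male * male +
    stats::rnorm(n, 0, dpar$sd)
  vpar <- params$volume
  v <- pmax(vpar$floor, vpar$intercept + vpar$b_diameter * d +
              stats::rnorm(n, 0, vpar$sd))
  cpar <- params$calcium
  calc <- exp(cpar$mu + cpar$b_age * (cov$age_y - 61.4) +
                stats::rnorm(n, 0, cpar$sigma))
  data.frame(max_diameter_cm = d, aortic_volume_ml = v, aortic_calcium_mm3 = calc)
}

#' Centered design matrix for the cohort hazard model
#'
#' Columns (and the names expected in `beta_cvd`/`beta_other`): `age_c`
#' (years - 61.4), `male`, `bmi_c` (- 27.9), `current_smoker`,
#' `packyears_c` (- 56), `diabetes`, `hypertension`, `heart_disease`,
#' `stroke`, `race_african_american`, `race_other`, `diameter_c` (cm - 3.6),
#' `volume_c` (ml - 215), `log_calcium_c` (log(mm^3 + 1) - log(1326)).
#'
#' @param df a cohort data.frame with covariate and feature columns.
#' @return numeric matrix with one row per subject.
#' @export
cohort_design_matrix <- function(df) {
  cbind(age_c = df$age_y - 61.4,
        male = as.integer(df$sex == "male"),
        bmi_c = df$bmi - 27.9,
        current_smoker = as.integer(df$smoking_status == "current"),
        packyears_c = df$packyears - 56,
        diabetes = df$diabetes,
        hypertension = df$hypertension,
        heart_disease = df$history_heart_disease,
        stroke = df$history_stroke,
        race_african_american = as.integer(df$race == "african_american"),
        race_other = as.integer(df$race == "other"),
        diameter_c = df$max_diameter_cm - 3.6,
        volume_c = df$aortic_volume_ml - 215,
        log_calcium_c = log(df$aortic_calcium_mm3 + 1) - log(1326))
}

simulate_event_times <- function(X, spec) {
  n <- nrow(X)
  lp_cvd <- drop(X[, names(spec$beta_cvd), drop = FALSE] %*% spec$beta_cvd)
  lp_oth <- drop(X[, names(spec$beta_other), drop = FALSE] %*% spec$beta_other)
  t_cvd <- stats::rexp(n, spec$baseline_hazard_cvd * exp(lp_cvd))
  t_oth <- stats::rexp(n, spec$baseline_hazard_other * exp(lp_oth))
  cens <- pmin(stats::runif(n, spec$censor_window_years[1],
                            spec$censor_window_years[2]), 8)
  time <- pmin(t_cvd, t_oth, cens)
  event <- ifelse(time == t_cvd, "cvd_death",
                  ifelse(time == t_oth, "other_death", "censored"))
  data.frame(time_y = time, event = event, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort table
#'
#' Draws covariates and aortic features, simulates cause-specific exponential
#' death times, applies administrative censoring, and attaches a
#' zero-inflated coronary-calcium (Agatston-like) score for the non-missing
#' subset. Bit-reproducible for a fixed spec and seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return data.frame with one row per subject: identifiers, covariates,
#'   aortic features, `cac_agatston` (NA where unavailable), `time_y`, and
#'   `event` (`"censored"`, `"cvd_death"`, `"other_death"`).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    cov <- draw_covariates(n, spec$covariate_params)
    feat <- draw_features(cov, spec$feature_params)
    df <- cbind(subject_id = sprintf("S%06d", seq_len(n)), cov, feat)
    X <- cohort_design_matrix(df)
    surv <- simulate_event_times(X, spec)
    # Agatston-like CAC correlated with aortic calcium; missing by design
    zc <- scale(log(df$aortic_calcium_mm3 + 1))[, 1]
    latent <- 0.75 * zc + 0.66 * stats::rnorm(n)
    cac <- ifelse(latent < stats::qnorm(0.30), 0, exp(3.5 + 1.6 * latent))
    cac[stats::runif(n) < spec$cac_missing_fraction] <- NA
    out <- cbind(df, cac_agatston = cac, surv)
    rownames(out) <- NULL
    out
  })
}

# P(event before censoring) for an exponential time with rate h and
# administrative censoring Uniform(a, b): 1 - E[exp(-hC)].
exp_event_fraction <- function(h, a, b) {
  ifelse(h <= 0, 0, 1 - (exp(-a * h) - exp(-b * h)) / ((b - a) * h))
}

#' Calibrate baseline hazards to target mortality fractions
#'
#' Adjusts `baseline_hazard_cvd` and `baseline_hazard_other` by bisection on
#' Monte-Carlo event fractions (fixed internal seed, at least 20,000
#' subjects) so the simulated CVD and all-cause death fractions land within
#' `tol` of the targets. The two hazards are calibrated alternately (the
#' competing-risk coupling is weak at these event rates), with a fresh
#' Monte-Carlo evaluation per candidate.
#'
#' @param spec a [cohort_spec()].
#' @param target_cvd_fraction,target_allcause_fraction target death
#'   fractions, both in (0, 1), CVD <= all-cause.
#' @param tol convergence tolerance on the fractions (default 0.001, i.e.
#'   0.1 percentage points).
#' @param n_mc Monte-Carlo cohort size (>= 20,000).
#' @return the spec with calibrated baseline hazards.
#' @export
calibrate_baseline_hazards <- function(spec, target_cvd_fraction = 0.018,
                                       target_allcause_fraction = 0.070,
                                       tol = 0.001, n_mc = 80000L) {
  if (target_cvd_fraction <= 0 || target_cvd_fraction >= 1 ||
      target_allcause_fraction <= 0 || target_allcause_fraction >= 1)
    stop("targets must lie in the open interval (0, 1)")
  if (target_cvd_fraction > target_allcause_fraction)
    stop("CVD fraction cannot exceed the all-cause fraction")
  n_mc <- max(20000L, as.integer(n_mc))

  # fixed covariate/uniform draws so the fractions are smooth monotone
  # functions of the hazards and bisection is well-behaved
  mc <- with_seed(spec$seed + 7919L, {
    cov <- draw_covariates(n_mc, spec$covariate_params)
    feat <- draw_features(cov, spec$feature_params)
    df <- cbind(cov, feat)
    list(X = cohort_design_matrix(df),
         u_cvd = stats::runif(n_mc), u_oth = stats::runif(n_mc),
         cens = pmin(stats::runif(n_mc, spec$censor_window_years[1],
                                  spec$censor_window_years[2]), 8))
  })
  lp_cvd <- drop(mc$X[, names(spec$beta_cvd)] %*% spec$beta_cvd)
  lp_oth <- drop(mc$X[, names(spec$beta_other)] %*% spec$beta_other)

  fracs <- function(h_cvd, h_oth) {
    t_cvd <- -log(mc$u_cvd) / (h_cvd * exp(lp_cvd))
    t_oth <- -log(mc$u_oth) / (h_oth * exp(lp_oth))
    tm <- pmin(t_cvd, t_oth, mc$cens)
    c(cvd = mean(tm == t_cvd), all = mean(tm < mc$cens))
  }

  bisect <- function(f, target, lo = 1e-7, hi = 1) {
    if (f(lo) > target || f(hi) < target)
      stop("calibration error: target fraction not bracketed in [1e-7, 1] per year")
    for (it in 1:60) {
      mid <- sqrt(lo * hi)
      v <- f(mid)
      if (abs(v - target) < tol / 4) return(mid)
      if (v < target) lo <- mid else hi <- mid
    }
    mid
  }

  h_cvd <- spec$baseline_hazard_cvd
  h_oth <- spec$baseline_hazard_other
  for (round in 1:3) {
    h_cvd <- bisect(function(h) fracs(h, h_oth)["cvd"], target_cvd_fraction)
    h_oth <- bisect(function(h) fracs(h_cvd, h)["all"], target_allcause_fraction)
  }
  got <- fracs(h_cvd, h_oth)
  if (abs(got["cvd"] - target_cvd_fraction) > tol ||
      abs(got["all"] - target_allcause_fraction) > tol)
    stop(sprintf("calibration error: reached cvd=%.4f all=%.4f (targets %.4f/%.4f)",
                 got["cvd"], got["all"], target_cvd_fraction,
                 target_allcause_fraction))
  spec$baseline_hazard_cvd <- h_cvd
  spec$baseline_hazard_other <- h_oth
  spec
}

#' Pool hazard-ratio estimates across simulation replicates
#'
#' Hazard ratios are averaged on the log scale (geometric mean), the natural
#' scale of the Cox model on which the estimator is asymptotically unbiased;
#' arithmetic averaging of exponentiated coefficients would carry a
#' systematic upward bias of order exp(se^2/2).
#'
#' @param hrs vector of hazard-ratio estimates.
#' @return the pooled hazard ratio.
#' @export
pool_hazard_ratios <- function(hrs) exp(mean(log(hrs)))

# Solve the baseline yearly rate giving a target event fraction for a
# population with per-subject relative hazards `rel` under Uniform(a, b)
# administrative censoring.
solve_baseline_rate <- function(target, rel, a, b) {
  f <- function(h) mean(exp_event_fraction(h * rel, a, b)) - target
  stats::uniroot(f, c(1e-8, 5), tol = 1e-12)$root
}

#' Simulate a grouped two-arm or multi-arm survival cohort
#'
#' Subjects are split into fixed-size groups with known group hazard ratios;
#' event times are exponential with a baseline rate solved in closed form so
#' the expected event fraction matches `target_event_fraction` (computed over
#' the whole cohort, or over the reference group only).
#'
#' @param group_sizes integer vector of group sizes (first group is the
#'   reference).
#' @param hazard_ratios hazard ratio per non-reference group (length =
#'   `length(group_sizes) - 1`).
#' @param target_event_fraction expected fraction of subjects with an event.
#' @param target_scope `"overall"` or `"reference"`: population over which
#'   the target fraction is defined.
#' @param censor_window_years administrative censoring window.
#' @param seed integer seed.
#' @return data.frame with `group` (factor `g1`, `g2`, ...), `time_y`,
#'   `event` (`"cvd_death"` or `"censored"`).
#' @export
simulate_group_cohort <- function(group_sizes, hazard_ratios,
                                  target_event_fraction,
                                  target_scope = c("overall", "reference"),
                                  censor_window_years = c(6.0, 6.9),
                                  seed = 1L) {
  target_scope <- match.arg(target_scope)
  stopifnot(length(hazard_ratios) == length(group_sizes) - 1L,
            all(hazard_ratios > 0))
  hr <- c(1, hazard_ratios)
  rel <- rep(hr, group_sizes)
  a <- censor_window_years[1]; b <- censor_window_years[2]
  h0 <- if (target_scope == "reference")
    solve_baseline_rate(target_event_fraction, rep(1, group_sizes[1]), a, b)
  else solve_baseline_rate(target_event_fraction, rel, a, b)
  with_seed(seed, {
    n <- sum(group_sizes)
    t_ev <- stats::rexp(n, h0 * rel)
    cens <- stats::runif(n, a, b)
    time <- pmin(t_ev, cens)
    data.frame(group = factor(rep(paste0("g", seq_along(group_sizes)), group_sizes)),
               time_y = time,
               event = ifelse(t_ev <= cens, "cvd_death", "censored"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a confounded tertile cohort
#'
#' Confounders (age, sex, smoking status, plus the remaining demographic and
#' risk-factor columns at null effect) influence both tertile membership and
#' the cause-specific hazard, so the marginal tertile association exceeds the
#' generating conditional hazard ratios. Tertiles are assigned by ranking a
#' confounder-driven propensity score into fixed tertile sizes.
#'
#' @param n cohort size.
#' @param hazard_ratios length-2 vector: conditional HR of tertiles 2 and 3
#'   vs tertile 1.
#' @param confounder_betas named log-HR vector for `age_c`, `male`,
#'   `current_smoker`.
#' @param assignment_strength scale of the confounder effect on the tertile
#'   propensity (in sd units of the propensity noise).
#' @param target_event_fraction overall expected event fraction.
#' @param censor_window_years administrative censoring window.
#' @param seed integer seed.
#' @return data.frame with covariates, `calcium_tertile` (factor T1/T2/T3),
#'   `time_y`, `event`.
#' @export
simulate_confounded_tertile_cohort <- function(n, hazard_ratios,
                                               confounder_betas = c(age_c = 0.08,
                                                                    male = 0.5,
                                                                    current_smoker = 0.3),
                                               assignment_strength = 1.0,
                                               target_event_fraction = 0.018,
                                               censor_window_years = c(6.0, 6.9),
                                               seed = 1L) {
  stopifnot(length(hazard_ratios) == 2L, all(hazard_ratios > 0))
  with_seed(seed, {
    cov <- draw_covariates(n)
    conf <- cbind(age_c = (cov$age_y - 61.4) / 5,
                  male = as.integer(cov$sex == "male"),
                  current_smoker = as.integer(cov$smoking_status == "current"))
    prop <- assignment_strength * drop(conf %*% c(1, 0.6, 0.4)) + stats::rnorm(n)
    sizes <- rep(n %/% 3L, 3L) + c(rep(1L, n %% 3L), rep(0L, 3L - n %% 3L))
    tert <- integer(n)
    tert[order(prop)] <- rep(1:3, sizes)
    tert <- factor(paste0("T", tert), levels = c("T1", "T2", "T3"))
    lp <- (cov$age_y - 61.4) * confounder_betas["age_c"] +
      (cov$sex == "male") * confounder_betas["male"] +
      (cov$smoking_status == "current") * confounder_betas["current_smoker"] +
      log(c(1, hazard_ratios))[as.integer(tert)]
    rel <- exp(lp)
    a <- censor_window_years[1]; b <- censor_window_years[2]
    h0 <- solve_baseline_rate(target_event_fraction, rel, a, b)
    t_ev <- stats::rexp(n, h0 * rel)
    cens <- stats::runif(n, a, b)
    data.frame(cov, calcium_tertile = tert,
               time_y = pmin(t_ev, cens),
               event = ifelse(t_ev <= cens, "cvd_death", "censored"),
               stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort table as CSV
#'
#' Plain-text serialization of the cohort schema. On reading, if an `event`
#' column is absent but a `death` indicator and an ICD `cause_code` column
#' are present, the event is derived via [is_cvd_death_code()].
#'
#' @param cohort a cohort data.frame.
#' @param path CSV path.
#' @return `write_cohort_csv`: the path, invisibly; `read_cohort_csv`: the
#'   cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"event" %in% names(df) && all(c("death", "cause_code") %in% names(df))) {
    df$event <- "censored"
    died <- df$death != 0
    df$event[died] <- ifelse(vapply(as.character(df$cause_code[died]),
                                    is_cvd_death_code, logical(1)),
                             "cvd_death", "other_death")
  }
  df
}
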