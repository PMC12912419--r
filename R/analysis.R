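# Prognostic analysis of aortic features: categorization, Kaplan-Meier and
# log-rank tests, cause-specific Cox models, concordance comparison, nested
# likelihood-ratio tests, reclassification tables and stratified sensitivity
# analyses. Model fitting is delegated to the survival package; other-cause
# death is treated as censoring for the cardiovascular endpoint throughout.

#' Analysis configuration
#'
#' @param diameter_threshold_cm aneurysm threshold for the diameter group
#'   (4.5 cm clinical default; 4.0 cm for the dilatation sensitivity
#'   analysis).
#' @param volume_split `"median"` (rank-based median split) or
#'   `"fixed_210_ml"`.
#' @param calcium_cutoffs_mm3 numeric pair of fixed tertile cutoffs (default
#'   270 and 1050 mm^3, both lower-inclusive for the upper group) or the
#'   string `"data_tertiles"` for empirical rank tertiles.
#' @param cac_cutpoints Agatston category cutpoints: score 0, 1-99, 100-399,
#'   >= 400.
#' @param covariates covariate columns for multivariable adjustment.
#' @param alpha two-sided significance level.
#' @param holm apply Holm adjustment to pairwise log-rank tests.
#' @return an `analysis_config` object.
#' @export
analysis_config <- function(diameter_threshold_cm = 4.5,
                            volume_split = c("median", "fixed_210_ml"),
                            calcium_cutoffs_mm3 = c(270, 1050),
                            cac_cutpoints = c(0, 100, 400),
                            covariates = c("race", "age_y", "sex", "bmi",
                                           "smoking_status", "diabetes",
                                           "hypertension",
                                           "history_heart_disease",
                                           "history_stroke"),
                            alpha = 0.05, holm = TRUE) {
  volume_split <- match.arg(volume_split)
  if (!diameter_threshold_cm %in% c(4.5, 4.0))
    stop("diameter threshold must be 4.5 or 4.0 cm")
  if (!identical(calcium_cutoffs_mm3, "data_tertiles")) {
    calcium_cutoffs_mm3 <- as.numeric(calcium_cutoffs_mm3)
    if (length(calcium_cutoffs_mm3) != 2L || diff(calcium_cutoffs_mm3) <= 0)
      stop("calcium cutoffs must be a strictly increasing pair")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(diameter_threshold_cm = diameter_threshold_cm,
                 volume_split = volume_split,
                 calcium_cutoffs_mm3 = calcium_cutoffs_mm3,
                 cac_cutpoints = cac_cutpoints, covariates = covariates,
                 alpha = alpha, holm = holm),
            class = "analysis_config")
}

event_indicator <- function(cohort, endpoint = c("cvd", "all_cause")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "cvd") as.integer(cohort$event == "cvd_death")
  else as.integer(cohort$event != "censored")
}

#' Categorize aortic features into analysis groups
#'
#' Adds `diameter_group` (indicator of the diameter threshold),
#' `volume_group` (rank-based median split, lowest floor(n/2) ranks in the
#' low group with ties broken by stable subject order, or the fixed 210 ml
#' cut), `calcium_tertile` (fixed cutoffs: `< c1` is T1, `[c1, c2)` is T2,
#' `>= c2` is T3; or empirical rank tertiles with remainder subjects
#' allocated to the lowest-index groups), and `cac_category` when an
#' Agatston score column is present. Subjects with a missing feature are
#' excluded with a message; the excluded rows are attached as the
#' `"excluded"` attribute.
#'
#' @param cohort cohort data.frame with feature columns.
#' @param cfg an [analysis_config()].
#' @return the cohort with group columns added.
#' @export
categorize_features <- function(cohort, cfg = analysis_config()) {
  feat_cols <- c("max_diameter_cm", "aortic_volume_ml", "aortic_calcium_mm3")
  miss <- !stats::complete.cases(cohort[, feat_cols])
  excluded <- cohort[miss, , drop = FALSE]
  if (any(miss)) {
    message(sprintf("categorize_features: excluding %d subjects with missing features",
                    sum(miss)))
    cohort <- cohort[!miss, , drop = FALSE]
  }
  n <- nrow(cohort)
  thr <- cfg$diameter_threshold_cm
  cohort$diameter_group <- factor(
    ifelse(cohort$max_diameter_cm >= thr, sprintf(">=%.1fcm", thr),
           sprintf("<%.1fcm", thr)),
    levels = c(sprintf("<%.1fcm", thr), sprintf(">=%.1fcm", thr)))
  if (cfg$volume_split == "median") {
    ord <- order(cohort$aortic_volume_ml)  # stable for ties
    low <- logical(n); low[ord[seq_len(n %/% 2L)]] <- TRUE
    cohort$volume_group <- factor(ifelse(low, "low", "high"),
                                  levels = c("low", "high"))
  } else {
    cohort$volume_group <- factor(ifelse(cohort$aortic_volume_ml >= 210,
                                         "high", "low"),
                                  levels = c("low", "high"))
  }
  if (identical(cfg$calcium_cutoffs_mm3, "data_tertiles")) {
    sizes <- rep(n %/% 3L, 3L)
    rem <- n %% 3L
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    tert <- integer(n)
    tert[order(cohort$aortic_calcium_mm3)] <- rep(1:3, sizes)
  } else {
    cc <- cfg$calcium_cutoffs_mm3
    tert <- 1L + (cohort$aortic_calcium_mm3 >= cc[1]) +
      (cohort$aortic_calcium_mm3 >= cc[2])
  }
  cohort$calcium_tertile <- factor(paste0("T", tert), levels = c("T1", "T2", "T3"))
  if ("cac_agatston" %in% names(cohort)) {
    cp <- cfg$cac_cutpoints
    cohort$cac_category <- cut(cohort$cac_agatston,
                               breaks = c(-Inf, cp[1], cp[2] - 1e-9,
                                          cp[3] - 1e-9, Inf),
                               labels = c("0", "1-99", "100-399", ">=400"))
  }
  attr(cohort, "excluded") <- excluded
  cohort
}

#' Kaplan-Meier curves with pairwise log-rank tests
#'
#' Product-limit survival estimates per group plus all pairwise two-sided
#' log-rank tests, Holm-adjusted across the pairs.
#'
#' @param cohort cohort data.frame with `time_y` and `event`.
#' @param group_col name of the grouping factor column.
#' @param endpoint `"cvd"` or `"all_cause"` (competing deaths censored).
#' @param holm apply the Holm adjustment.
#' @return list with `curves` (data.frame: group, time, n_risk, n_event,
#'   survival) and `pairwise` (data.frame: group1, group2, statistic, df, p,
#'   p_adjusted).
#' @export
km_logrank <- function(cohort, group_col, endpoint = c("cvd", "all_cause"),
                       holm = TRUE) {
  endpoint <- match.arg(endpoint)
  grp <- droplevels(factor(cohort[[group_col]]))
  if (nlevels(grp) < 2L) stop("need at least two groups")
  if (any(table(grp) == 0L)) stop("empty group")
  status <- event_indicator(cohort, endpoint)
  d <- data.frame(time = cohort$time_y, status = status, group = grp)
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = d)
  strata_grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(group = strata_grp, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       survival = fit$surv)
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = NA_real_, df = 1L, p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    sub <- d[d$group %in% pairs[, j], ]
    sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = sub)
    res$statistic[j] <- sd$chisq
    res$p[j] <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  res$p_adjusted <- if (holm) stats::p.adjust(res$p, method = "holm") else res$p
  list(curves = curves, pairwise = res)
}

#' Fit a cause-specific Cox proportional hazards model
#'
#' Maximizes the partial likelihood (Efron tie correction by default) for
#' the chosen endpoint, treating competing deaths as censoring. Subjects
#' with missing values in any term are excluded listwise. Wald 95% CIs are
#' `exp(coef +/- 1.96 se)`.
#'
#' @param cohort cohort data.frame.
#' @param terms character vector of column names entering the linear
#'   predictor.
#' @param endpoint `"cvd"` or `"all_cause"`.
#' @param ties `"efron"` or `"breslow"`.
#' @return a `survival_fit` object: `terms`, `coefficients`, `se`,
#'   `hazard_ratios`, `ci95` (matrix), `p_values`, `log_likelihood`,
#'   `null_log_likelihood`, `n`, `n_events`, `ties`, and `flags` (fitter
#'   diagnostics such as monotone-likelihood/separation messages).
#' @export
cox_fit <- function(cohort, terms, endpoint = c("cvd", "all_cause"),
                    ties = c("efron", "breslow")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  status <- event_indicator(cohort, endpoint)
  d <- cbind(data.frame(.time = cohort$time_y, .status = status),
             cohort[, terms, drop = FALSE])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  for (tm in terms) {
    v <- d[[tm]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop(sprintf("term `%s` is constant", tm))
  }
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                 paste(sprintf("`%s`", terms), collapse = " + ")))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      # monotone-likelihood / separation diagnostics are kept on the fit
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (sum(d$.status) < length(stats::coef(fit)))
    stop("fewer events than model terms")
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(terms = terms,
                 coefficients = co, se = se,
                 hazard_ratios = exp(co),
                 ci95 = cbind(lower = exp(co - 1.96 * se),
                              upper = exp(co + 1.96 * se)),
                 p_values = 2 * stats::pnorm(-abs(co / se)),
                 log_likelihood = fit$loglik[2],
                 null_log_likelihood = fit$loglik[1],
                 n = fit$n, n_events = fit$nevent,
                 ties = ties, endpoint = endpoint, flags = flags),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> endpoint=%s, n=%d, events=%d, ties=%s\n",
              x$endpoint, x$n, x$n_events, x$ties))
  tab <- data.frame(HR = x$hazard_ratios, lower = x$ci95[, "lower"],
                    upper = x$ci95[, "upper"], p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Harrell's concordance index for a risk score
#'
#' `c = (concordant + 0.5 * tied-score) / usable pairs`, where a pair is
#' usable when the ordering of failure times is determinable under
#' censoring; higher scores are treated as higher risk (earlier failure).
#' The CI uses the asymptotic U-statistic variance.
#'
#' @param cohort cohort data.frame.
#' @param score numeric risk score (finite for all subjects) or the name of
#'   a column.
#' @param endpoint `"cvd"` or `"all_cause"`.
#' @return a `cindex_result`: `c`, `ci95`, `se`, `n_usable_pairs`.
#' @export
harrell_c <- function(cohort, score, endpoint = c("cvd", "all_cause")) {
  endpoint <- match.arg(endpoint)
  if (is.character(score) && length(score) == 1L) score <- cohort[[score]]
  if (any(!is.finite(score))) stop("risk score must be finite for all subjects")
  status <- event_indicator(cohort, endpoint)
  d <- data.frame(time = cohort$time_y, status = status, score = score)
  cf <- survival::concordance(survival::Surv(time, status) ~ score, data = d,
                              reverse = TRUE)
  counts <- cf$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no usable pairs")
  se <- sqrt(cf$var)
  structure(list(c = unname(cf$concordance),
                 ci95 = c(lower = unname(cf$concordance - 1.96 * se),
                          upper = unname(cf$concordance + 1.96 * se)),
                 se = unname(se), n_usable_pairs = unname(usable)),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("<cindex> c=%.4f [%.4f, %.4f], usable pairs %g\n",
              x$c, x$ci95[1], x$ci95[2], x$n_usable_pairs))
  invisible(x)
}

#' Compare two concordance indices on the same subjects
#'
#' Two-sided test of `c_a - c_b` using the correlated U-statistic variance
#' of the paired concordance estimates (the covariance of the two
#' concordances on the shared subjects).
#'
#' @param cohort cohort data.frame.
#' @param score_a,score_b numeric risk scores or column names.
#' @param endpoint `"cvd"` or `"all_cause"`.
#' @return list with `c_a`, `c_b`, `delta`, `se`, `z`, `p`.
#' @export
compare_c <- function(cohort, score_a, score_b, endpoint = c("cvd", "all_cause")) {
  endpoint <- match.arg(endpoint)
  if (is.character(score_a)) score_a <- cohort[[score_a]]
  if (is.character(score_b)) score_b <- cohort[[score_b]]
  status <- event_indicator(cohort, endpoint)
  d <- data.frame(time = cohort$time_y, status = status, a = score_a, b = score_b)
  cf <- survival::concordance(survival::Surv(time, status) ~ a + b, data = d,
                              reverse = TRUE)
  ca <- cf$concordance[1]; cb <- cf$concordance[2]
  v <- cf$var  # 2x2 covariance of (c_a, c_b)
  se <- sqrt(max(v[1, 1] + v[2, 2] - 2 * v[1, 2], 0))
  delta <- unname(ca - cb)
  if (se < 1e-12) {
    z <- 0; p <- 1
  } else {
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(c_a = unname(ca), c_b = unname(cb), delta = delta, se = unname(se),
       z = z, p = p)
}

#' Likelihood-ratio test between nested Cox models
#'
#' @param base,extended [cox_fit()] results on the same subjects; the
#'   extended model's terms must be a superset of the base model's.
#' @return list with `statistic`, `df`, `p`.
#' @export
nested_lrt <- function(base, extended) {
  if (!all(base$terms %in% extended$terms))
    stop("models are not nested: base terms are not a subset of extended terms")
  if (base$n != extended$n)
    stop("models were fitted on different subjects")
  df <- length(extended$coefficients) - length(base$coefficients)
  if (df < 0) stop("extended model has fewer parameters than base")
  stat <- max(0, 2 * (extended$log_likelihood - base$log_likelihood))
  list(statistic = stat, df = df,
       p = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Risk reclassification table: calcium tertiles vs coronary calcium
#'
#' Cross-tabulates aortic calcium tertiles against Agatston categories with
#' per-cell subject counts, cardiovascular death counts and event rates
#' (rate `NA` for empty cells). Rows without a coronary calcium category are
#' dropped.
#'
#' @param cohort a categorized cohort (see [categorize_features()]) with
#'   `calcium_tertile` and `cac_category`.
#' @return data.frame with columns `calcium_tertile`, `cac_category`, `n`,
#'   `n_cvd_events`, `event_rate`.
#' @export
reclassification_table <- function(cohort) {
  stopifnot(all(c("calcium_tertile", "cac_category") %in% names(cohort)))
  d <- cohort[!is.na(cohort$cac_category), , drop = FALSE]
  ev <- event_indicator(d, "cvd")
  out <- expand.grid(calcium_tertile = levels(d$calcium_tertile),
                     cac_category = levels(d$cac_category),
                     stringsAsFactors = FALSE)
  out$n <- 0L; out$n_cvd_events <- 0L; out$event_rate <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- d$calcium_tertile == out$calcium_tertile[i] &
      d$cac_category == out$cac_category[i]
    out$n[i] <- sum(sel)
    out$n_cvd_events[i] <- sum(ev[sel])
    if (out$n[i] > 0) out$event_rate[i] <- out$n_cvd_events[i] / out$n[i]
  }
  out
}

#' Stratified sensitivity analyses
#'
#' Repeats the feature-group Cox fits within strata defined by sex, age
#' (< 65 vs >= 65), hypertension, and the subgroup without prior
#' cardiovascular disease (no history of heart disease or stroke). Group
#' cutoffs are taken cohort-wide (the cohort must already be categorized).
#' Strata with fewer than `min_events` endpoint events are skipped with a
#' log entry.
#'
#' @param cohort a categorized cohort data.frame.
#' @param cfg an [analysis_config()].
#' @param min_events minimum endpoint events per stratum.
#' @param endpoint `"cvd"` or `"all_cause"`.
#' @param multivariable also fit covariate-adjusted models.
#' @return nested list: stratum -> level -> feature -> `survival_fit` (or a
#'   `"skipped"` marker), plus a `log` character vector.
#' @export
run_stratified_sensitivity <- function(cohort, cfg = analysis_config(),
                                       min_events = 25L,
                                       endpoint = c("cvd", "all_cause"),
                                       multivariable = FALSE) {
  endpoint <- match.arg(endpoint)
  strata <- list(
    sex = split(seq_len(nrow(cohort)), cohort$sex),
    age_group = split(seq_len(nrow(cohort)),
                      ifelse(cohort$age_y < 65, "<65", ">=65")),
    hypertension = split(seq_len(nrow(cohort)),
                         ifelse(cohort$hypertension == 1, "yes", "no")),
    no_prior_cvd = list(yes = which(cohort$history_heart_disease == 0 &
                                      cohort$history_stroke == 0)))
  groups <- c("diameter_group", "volume_group", "calcium_tertile")
  log <- character(0)
  out <- list()
  for (snm in names(strata)) {
    out[[snm]] <- list()
    for (lv in names(strata[[snm]])) {
      idx <- strata[[snm]][[lv]]
      sub <- cohort[idx, , drop = FALSE]
      nev <- sum(event_indicator(sub, endpoint))
      if (nev < min_events) {
        out[[snm]][[lv]] <- "skipped"
        log <- c(log, sprintf("%s=%s skipped (%d events < %d)", snm, lv, nev,
                              min_events))
        next
      }
      fits <- list()
      for (gc in groups) {
        terms <- if (multivariable) c(gc, cfg$covariates) else gc
        fits[[gc]] <- tryCatch(cox_fit(sub, terms, endpoint = endpoint),
                               error = function(e) conditionMessage(e))
      }
      out[[snm]][[lv]] <- fits
    }
  }
  attr(out, "log") <- log
  out
}
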