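# Validation statistics for density measures against screening outcomes:
# weighted population percentiles and quintile-decile grouping, adjusted
# logistic odds-ratio models, programme-sensitivity prediction, ROC/AUC,
# non-parametric trend and rank tests, and between-measure agreement.

#' Weighted empirical percentiles
#'
#' Percentile of each value within the weighted empirical distribution,
#' using the mid-rank convention for ties:
#' \deqn{p(v) = 100 \, (W_{<v} + W_{=v}/2) / W,}
#' where `W` sums the weights. Weighting controls by their inverse sampling
#' fraction reproduces whole-screened-population percentiles from a
#' case-control sample. A record duplicated with weight 2 scores exactly as
#' two unit-weight copies would.
#'
#' @param values Numeric vector (e.g. dense areas in pixels).
#' @param weights Non-negative weights, not all zero (default: equal).
#' @return Numeric vector of percentiles in `[0, 100]`, one per value; tied
#'   values share the same percentile.
#' @export
weighted_percentiles <- function(values, weights = rep(1, length(values))) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  if (length(weights) != length(values))
    stop("`values` and `weights` lengths differ")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  W <- sum(weights)
  u <- sort(unique(values))
  w_eq <- vapply(split(weights, match(values, u)), sum, numeric(1))
  w_less <- c(0, cumsum(w_eq))[seq_along(u)]
  pct <- 100 * (w_less + w_eq / 2) / W
  unname(pct[match(values, u)])
}

#' Assign quintile-decile density groups
#'
#' Density percentiles are grouped into the four lowest quintiles and the
#' two upper deciles: Q1 `[0,20)`, Q2 `[20,40)`, Q3 `[40,60)`, Q4 `[60,80)`,
#' D9 `[80,90)`, D10 `[90,100]`. Boundaries are left-closed, so a percentile
#' exactly on a cut point joins the upper group.
#'
#' @param percentile Numeric vector of percentiles in `[0, 100]`.
#' @return Ordered factor with levels `Q1, Q2, Q3, Q4, D9, D10`.
#' @export
assign_density_group <- function(percentile) {
  if (any(is.na(percentile)) || any(percentile < 0 | percentile > 100))
    stop("percentiles must lie in [0, 100]")
  idx <- findInterval(percentile, c(0, 20, 40, 60, 80, 90),
                      rightmost.closed = FALSE)
  factor(.group_levels[idx], levels = .group_levels, ordered = TRUE)
}

#' Classify tumour size
#'
#' Microinvasive tumours are assigned a size of 0.1 mm; screen-detected
#' cancers are small when `<= 15` mm and large when `> 15` mm.
#'
#' @param size_code Numeric sizes in mm, or the string `"microinvasive"`
#'   (vectors may mix both if given as character).
#' @return Data frame with `size_mm` and `category` (`"small"`/`"large"`).
#' @export
classify_tumour <- function(size_code) {
  micro <- is.character(size_code) & FALSE
  if (is.character(size_code)) {
    micro <- size_code == "microinvasive"
    size <- suppressWarnings(as.numeric(size_code))
    size[micro] <- 0.1
    if (anyNA(size)) stop("unrecognised tumour size code")
  } else {
    size <- as.numeric(size_code)
  }
  if (anyNA(size) || any(size <= 0))
    stop("tumour sizes must be positive (or 'microinvasive')")
  data.frame(size_mm = size,
             category = ifelse(size <= 15, "small", "large"),
             stringsAsFactors = FALSE)
}

# --- logistic fitting core --------------------------------------------------

# Prepare analysis columns: density group from weighted population
# percentiles of the chosen measure, covariates as factors with their
# reference levels first.
.prepare_records <- function(records, measure = c("a", "b"),
                             group_col = NULL) {
  .check_cohort(records)
  measure <- match.arg(measure)
  d <- records
  if (is.null(group_col)) {
    col <- paste0("dense_area_px_", measure)
    pct <- weighted_percentiles(d[[col]], d$weight)
    d$density_group <- assign_density_group(pct)
  } else {
    d$density_group <- factor(d[[group_col]], levels = .group_levels,
                              ordered = TRUE)
  }
  d$age_group <- factor(d$age_group, levels = .age_levels)
  d$ht_use <- factor(d$ht_use, levels = c("no", "yes"))
  d$family_history <- factor(d$family_history, levels = c("no", "yes"))
  d$symptoms <- factor(d$symptoms, levels = c("none", "no-significant"))
  d$screening_round <- factor(d$screening_round,
                              levels = c("first", "subsequent"))
  d
}

# Maximum-likelihood logistic fit shared by the odds-ratio models and the
# programme-sensitivity model. Errors out explicitly on (near-)separation.
.fit_logistic <- function(formula, data) {
  fit <- suppressWarnings(glm(formula, family = binomial(), data = data,
                              control = stats::glm.control(epsilon = 1e-10)))
  cf <- coef(fit)
  cf <- cf[!is.na(cf)]                   # aliased terms (empty cells) dropped
  se <- sqrt(diag(vcov(fit)))[names(cf)]
  bad <- which(abs(cf) > 15 | se > 15)
  if (length(bad))
    stop("logistic model did not converge (possible complete separation) ",
         "for term(s): ", paste(names(cf)[bad], collapse = ", "))
  fit
}

.default_covariates <- c("age_group", "ht_use", "family_history",
                         "symptoms", "screening_round")

#' Fit a covariate-adjusted logistic odds-ratio model
#'
#' Unconditional logistic regression of a case outcome versus controls with
#' the quintile-decile density group as categorical exposure (Q1 reference),
#' adjusted for the listed categorical covariates. Confidence intervals are
#' Wald intervals on the log-odds scale.
#'
#' @param records Cohort data frame (see [generate_cohort] for the schema).
#' @param cases Outcome level(s) counted as cases, e.g. `"interval"` or
#'   `c("small_screen_detected", "large_screen_detected", "interval")`.
#' @param controls Outcome level(s) counted as controls (default
#'   `"control"`).
#' @param covariates Adjustment covariates (default: age group, hormone
#'   therapy use, family history, symptoms, screening round). Use
#'   `character(0)` for an unadjusted model.
#' @param measure Which density measure drives the exposure: `"a"` or
#'   `"b"`.
#' @param group_col Optional column already holding quintile-decile group
#'   labels; when given, percentile computation is skipped.
#' @param interaction Add a screening-round-by-density-group interaction
#'   (for tests of whether rounds need separate analysis).
#' @param conf_level Confidence level (default 0.95).
#' @return An `or_table`: data frame with one row per density group
#'   (`group`, `or`, `ci_low`, `ci_high`, `n_cases`, `n_controls`), Q1
#'   fixed at OR 1. The fitted `glm` object is attached as attribute
#'   `"model"`.
#' @export
fit_outcome_model <- function(records, cases,
                              controls = "control",
                              covariates = .default_covariates,
                              measure = "a", group_col = NULL,
                              interaction = FALSE,
                              conf_level = 0.95) {
  d <- .prepare_records(records, measure, group_col)
  d <- d[d$outcome %in% c(cases, controls), , drop = FALSE]
  if (!any(d$outcome %in% cases) || !any(d$outcome %in% controls))
    stop("both case and control records are required")
  if (!any(d$outcome %in% controls & d$density_group == "Q1"))
    stop("reference group Q1 has no control records")
  d$case <- as.integer(d$outcome %in% cases)
  d$density_group <- factor(as.character(d$density_group),
                            levels = .group_levels)  # treatment contrasts
  rhs <- c("density_group", covariates,
           if (interaction) "screening_round:density_group")
  fml <- stats::reformulate(rhs, response = "case")
  fit <- .fit_logistic(fml, d)
  cf <- coef(fit)
  se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  se[rownames(vcov(fit))] <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  terms <- paste0("density_group", .group_levels[-1])
  out <- data.frame(
    group = factor(.group_levels, levels = .group_levels),
    or = c(1, exp(unname(cf[terms]))),
    ci_low = c(NA, exp(unname(cf[terms] - z * se[terms]))),
    ci_high = c(NA, exp(unname(cf[terms] + z * se[terms]))),
    n_cases = as.integer(table(d$density_group[d$case == 1])[.group_levels]),
    n_controls = as.integer(table(d$density_group[d$case == 0])[.group_levels]),
    row.names = NULL
  )
  structure(out, class = c("or_table", "data.frame"), model = fit)
}

#' Predict screening programme sensitivity by density group
#'
#' Programme sensitivity is the proportion of cancers that are
#' screen-detected. It is estimated from a case-only logistic model of
#' interval (versus screen-detected) cancer on density group plus
#' covariates: if `odds` is the predicted odds of an interval cancer for a
#' covariate profile, sensitivity is `100 / (1 + odds)` percent. Confidence
#' limits transform the Wald interval of the linear predictor, so they stay
#' inside `[0, 100]`.
#'
#' @param records Cohort data frame; only cancer records are used.
#' @param profile Named list fixing the covariate profile, e.g.
#'   `list(age_group = "50-54", ht_use = "no", family_history = "no",
#'   symptoms = "none", screening_round = "first")`. Defaults to the
#'   reference level of every covariate.
#' @param covariates Adjustment covariates (as [fit_outcome_model]).
#' @param measure Density measure `"a"` or `"b"`.
#' @param group_col Optional column already holding group labels (as
#'   [fit_outcome_model]).
#' @param conf_level Confidence level (default 0.95).
#' @return A `sensitivity_table`: data frame with one row per density group
#'   (`group`, `interval_odds`, `sensitivity`, `ci_low`, `ci_high`),
#'   sensitivities in percent; fitted model attached as attribute
#'   `"model"`, the profile as `"profile"`.
#' @export
predict_sensitivity <- function(records, profile = list(),
                                covariates = .default_covariates,
                                measure = "a", group_col = NULL,
                                conf_level = 0.95) {
  d <- .prepare_records(records, measure, group_col)
  d <- d[d$outcome != "control", , drop = FALSE]
  if (!nrow(d)) stop("no cancer records available")
  d$interval_case <- as.integer(d$outcome == "interval")
  if (!any(d$interval_case == 1) || !any(d$interval_case == 0))
    stop("both interval and screen-detected cancers are required")
  d$density_group <- factor(as.character(d$density_group),
                            levels = .group_levels)
  fml <- stats::reformulate(c("density_group", covariates),
                            response = "interval_case")
  fit <- .fit_logistic(fml, d)
  newdata <- data.frame(density_group = factor(.group_levels,
                                               levels = .group_levels))
  for (cv in covariates) {
    lev <- levels(d[[cv]])
    val <- if (!is.null(profile[[cv]])) profile[[cv]] else lev[1]
    if (!val %in% lev) stop("profile value '", val, "' not a level of ", cv)
    newdata[[cv]] <- factor(val, levels = lev)
  }
  pr <- stats::predict(fit, newdata = newdata, type = "link", se.fit = TRUE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  odds <- exp(pr$fit)
  out <- data.frame(
    group = newdata$density_group,
    interval_odds = odds,
    sensitivity = sensitivity_from_odds(odds),
    ci_low = sensitivity_from_odds(exp(pr$fit + z * pr$se.fit)),
    ci_high = sensitivity_from_odds(exp(pr$fit - z * pr$se.fit)),
    row.names = NULL
  )
  structure(out, class = c("sensitivity_table", "data.frame"),
            model = fit, profile = profile)
}

#' Convert interval-cancer odds to programme sensitivity
#'
#' @param odds Odds of an interval (versus screen-detected) cancer.
#' @return Sensitivity in percent: `100 / (1 + odds)`.
#' @export
sensitivity_from_odds <- function(odds) {
  if (any(odds < 0, na.rm = TRUE)) stop("odds must be non-negative")
  100 / (1 + odds)
}

# --- discrimination and non-parametric tests --------------------------------

#' ROC curve and area under the curve
#'
#' AUC via the Mann-Whitney statistic: the proportion of case-control pairs
#' in which the case has the higher value, ties counted one half. Curve
#' points are given at every distinct threshold (classification rule: value
#' `>=` threshold is called positive).
#'
#' @param case_values,control_values Numeric vectors, both non-empty.
#' @return List with `auc` and `curve` (data frame `threshold`, `tpr`,
#'   `fpr`, descending thresholds, ending at the (1,1) corner).
#' @export
roc_auc <- function(case_values, control_values) {
  n1 <- length(case_values); n0 <- length(control_values)
  if (n1 == 0L || n0 == 0L) stop("both groups must be non-empty")
  r <- rank(c(case_values, control_values))       # mid-ranks for ties
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(c(case_values, control_values)), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(thr, -Inf),
    tpr = c(vapply(thr, function(t) mean(case_values >= t), numeric(1)), 1),
    fpr = c(vapply(thr, function(t) mean(control_values >= t), numeric(1)), 1)
  )
  list(auc = auc, curve = curve)
}

#' Cuzick non-parametric test for trend across ordered groups
#'
#' Wilcoxon-type rank test for a monotone trend across ordinal categories:
#' the statistic correlates overall mid-ranks with ordinal group scores; the
#' z value uses the exact permutation mean and variance with the usual tie
#' correction.
#'
#' @param values Numeric outcome vector.
#' @param groups Factor (or coercible) of ordered group membership; every
#'   group must be non-empty.
#' @param scores Ordinal score per group level (default `1..k`).
#' @return List with `z`, `p_value` (two-sided normal), `statistic` (the
#'   weighted rank sum `T`) and `scores`.
#' @export
cuzick_trend_test <- function(values, groups, scores = NULL) {
  groups <- as.factor(groups)
  if (any(tabulate(groups, nbins = nlevels(groups)) == 0L))
    stop("every group must have at least one member")
  k <- nlevels(groups)
  if (k < 2L) stop("at least two groups are required")
  if (is.null(scores)) scores <- seq_len(k)
  if (length(scores) != k) stop("`scores` must give one score per level")
  n <- length(values)
  r <- rank(values)
  l <- scores[as.integer(groups)]
  T_stat <- sum(l * r)
  nj <- tabulate(groups, nbins = k)
  L1 <- sum(nj * scores)
  L2 <- sum(nj * scores^2)
  ET <- (n + 1) / 2 * L1
  VT <- (n + 1) / 12 * (n * L2 - L1^2)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  VT <- VT * tie_corr
  z <- if (VT > 0) (T_stat - ET) / sqrt(VT) else 0
  list(z = z, p_value = 2 * pnorm(-abs(z)), statistic = T_stat,
       scores = scores)
}

#' Trend and rank tests across density-related groups
#'
#' Runs the Cuzick trend test (for ordinal groupings) and the
#' Kruskal-Wallis rank test with tie correction (for nominal groupings) on
#' the same data. Degenerate input with all values identical yields zero
#' statistics and p = 1.
#'
#' @inheritParams cuzick_trend_test
#' @return List with `cuzick` (see [cuzick_trend_test]) and
#'   `kruskal_wallis` (`h`, `df`, `p_value`).
#' @export
trend_and_rank_tests <- function(values, groups, scores = NULL) {
  groups <- as.factor(groups)
  cz <- cuzick_trend_test(values, groups, scores)
  if (length(unique(values)) == 1L) {
    kw <- list(h = 0, df = nlevels(groups) - 1L, p_value = 1)
  } else {
    kt <- kruskal.test(values, groups)
    kw <- list(h = unname(kt$statistic), df = unname(kt$parameter),
               p_value = kt$p.value)
  }
  list(cuzick = cz, kruskal_wallis = kw)
}

# --- agreement between two measures -----------------------------------------

# Weighted Pearson correlation.
.weighted_cor <- function(x, y, w) {
  W <- sum(w)
  mx <- sum(w * x) / W; my <- sum(w * y) / W
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx <= 0 || syy <= 0)
    stop("correlation undefined for zero-variance input")
  sxy / sqrt(sxx * syy)
}

#' Agreement between two density measures
#'
#' Compares paired measurements of the same mammograms: Pearson correlation
#' of weighted population percentiles, a Bland-Altman analysis of
#' log-transformed dense areas (mean difference and 1.96-SD limits of
#' agreement), and the 6x6 cross-classification of quintile-decile groups
#' with percent perfect agreement (matrix trace) and percent agreement
#' within one neighbouring category. All components use the supplied
#' analysis weights.
#'
#' @param measure_a,measure_b Paired positive dense-area values.
#' @param weights Analysis weights (default equal). Pairs with a
#'   non-positive value are dropped from the Bland-Altman component only.
#' @return An `agreement_report` list: `r` and `r_p_value` (normal
#'   approximation on the Fisher transform with the effective sample size),
#'   `bland_altman` (`mean_diff`, `loa_low`, `loa_high`, `n_used`; natural
#'   log scale), `cross_classification` (6x6 percentage matrix summing to
#'   100), `perfect_agreement_pct`, `within_one_pct`, and the percentile
#'   vectors `percentile_a`, `percentile_b`.
#' @export
compare_measures <- function(measure_a, measure_b,
                             weights = rep(1, length(measure_a))) {
  if (length(measure_a) != length(measure_b))
    stop("`measure_a` and `measure_b` must be paired (equal length)")
  if (length(measure_a) < 3L) stop("at least three pairs are required")
  pa <- weighted_percentiles(measure_a, weights)
  pb <- weighted_percentiles(measure_b, weights)
  r <- .weighted_cor(pa, pb, weights)
  n_eff <- sum(weights)^2 / sum(weights^2)
  z_r <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12)) * sqrt(max(n_eff - 3, 1))
  r_p <- 2 * pnorm(-abs(z_r))

  ok <- measure_a > 0 & measure_b > 0
  if (sum(ok) < 3L) stop("too few positive pairs for Bland-Altman")
  dl <- log(measure_a[ok]) - log(measure_b[ok])
  wk <- weights[ok]
  md <- sum(wk * dl) / sum(wk)
  sdd <- sqrt(sum(wk * (dl - md)^2) / sum(wk) * sum(ok) / (sum(ok) - 1))
  ba <- list(mean_diff = md, loa_low = md - 1.96 * sdd,
             loa_high = md + 1.96 * sdd, n_used = sum(ok))

  ga <- assign_density_group(pa)
  gb <- assign_density_group(pb)
  xt <- matrix(0, 6, 6, dimnames = list(a = .group_levels, b = .group_levels))
  for (i in seq_along(ga))
    xt[as.integer(ga[i]), as.integer(gb[i])] <-
      xt[as.integer(ga[i]), as.integer(gb[i])] + weights[i]
  xt <- 100 * xt / sum(xt)
  perfect <- sum(diag(xt))
  within1 <- sum(xt[abs(row(xt) - col(xt)) <= 1])

  structure(list(r = r, r_p_value = r_p, bland_altman = ba,
                 cross_classification = xt,
                 perfect_agreement_pct = perfect,
                 within_one_pct = within1,
                 percentile_a = pa, percentile_b = pb),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report: r = %.3f, perfect %.1f%%, within-one %.1f%%>\n",
              x$r, x$perfect_agreement_pct, x$within_one_pct))
  invisible(x)
}
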