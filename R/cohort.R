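# Simulated screening cohorts. Each woman receives a latent density
# percentile (uniform in the screened population), a dense-area value on the
# pixel scale via a lognormal quantile transform, screening covariates, and
# a clinical outcome drawn from a multinomial logistic model whose
# coefficients are the designed log-odds. Controls carry the
# inverse-sampling-fraction analysis weight of their screening round.

.age_levels <- c("40-49", "50-54", "55-59", "60-64", "65-69", "70-79")
.outcome_levels <- c("control", "small_screen_detected",
                     "large_screen_detected", "interval")
.group_levels <- c("Q1", "Q2", "Q3", "Q4", "D9", "D10")

# Interpolate a D10 log-OR across quintile-decile groups linearly on the
# percentile midpoints (10, 30, 50, 70, 85, 95), anchored at 0 for Q1.
.density_coef_vector <- function(logor_d10) {
  mids <- c(10, 30, 50, 70, 85, 95)
  logor_d10 * (mids - mids[1]) / (mids[6] - mids[1])
}

#' Specify a simulated screening cohort
#'
#' Defaults emulate a film-screening case-control study: control sampling
#' fractions of 1.55% (first round) and 3.25% (subsequent rounds), the
#' standard screening age mix, and outcome log-odds that rise with density
#' group, anchored at highest-decile odds ratios of 2.2 (small
#' screen-detected), 6.4 (large screen-detected) and 4.7 (interval cancer)
#' versus the lowest quintile.
#'
#' @param n_women Number of women to simulate.
#' @param sampling_fraction_round1,sampling_fraction_subsequent Control
#'   sampling fractions by screening round; controls get analysis weight
#'   `1/fraction`.
#' @param p_first_round Probability a woman is at her first screening round.
#' @param age_probs Length-6 probabilities over age groups 40-49, 50-54,
#'   55-59, 60-64, 65-69, 70-79.
#' @param p_ht,p_family_history,p_symptoms Covariate prevalences (current
#'   hormone-therapy use; first-degree family history; non-significant
#'   breast symptoms).
#' @param density_meanlog,density_sdlog Lognormal parameters of the
#'   dense-area (pixel) distribution for measure A.
#' @param measure_b_rho,measure_b_meanlog,measure_b_sdlog Second density
#'   measure: normal-copula correlation with measure A and its lognormal
#'   marginal (set `measure_b_rho = 1` and equal marginals for identical
#'   measures).
#' @param intercepts Named log-odds (vs control) of `small`, `large`,
#'   `interval` at the reference profile (Q1, youngest age group, no HT, no
#'   family history, no symptoms, first round).
#' @param density_logor Named list of length-6 log-OR vectors
#'   (Q1..D10, first element 0) per outcome, or scalars giving the D10
#'   log-OR to interpolate across groups.
#' @param covariate_logor Named list per outcome of named vectors with
#'   elements `ht`, `family_history`, `symptoms`, `subsequent_round`,
#'   `age_step` (per age-category step).
#' @param case_control_sampling If `TRUE`, controls are retained with their
#'   round's sampling probability (emulating the case-control design);
#'   `n_women` is then the screened-population size before sampling.
#' @param seed RNG seed (required).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_women = 50000L,
                        sampling_fraction_round1 = 0.0155,
                        sampling_fraction_subsequent = 0.0325,
                        p_first_round = 0.45,
                        age_probs = c(0.25, 0.15, 0.17, 0.17, 0.15, 0.11),
                        p_ht = 0.20, p_family_history = 0.10,
                        p_symptoms = 0.15,
                        density_meanlog = log(20000), density_sdlog = 0.8,
                        measure_b_rho = 0.63,
                        measure_b_meanlog = log(18000),
                        measure_b_sdlog = 0.8,
                        intercepts = c(small = log(0.010 / 0.976),
                                       large = log(0.006 / 0.976),
                                       interval = log(0.008 / 0.976)),
                        density_logor = list(small = log(2.2),
                                             large = log(6.4),
                                             interval = log(4.7)),
                        covariate_logor = NULL,
                        case_control_sampling = FALSE, seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(length(age_probs) == 6L, abs(sum(age_probs) - 1) < 1e-8)
  for (p in c(sampling_fraction_round1, sampling_fraction_subsequent,
              p_first_round, p_ht, p_family_history, p_symptoms))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  dl <- lapply(density_logor, function(v) {
    if (length(v) == 1L) v <- .density_coef_vector(v)
    if (length(v) != 6L || v[1] != 0)
      stop("density log-OR vectors must have length 6 with first element 0")
    v
  })
  if (!setequal(names(dl), c("small", "large", "interval")))
    stop("`density_logor` needs elements small, large, interval")
  default_cov <- c(ht = log(1.3), family_history = log(1.8),
                   symptoms = log(1.5), subsequent_round = log(0.8),
                   age_step = log(1.05))
  if (is.null(covariate_logor))
    covariate_logor <- list(small = default_cov, large = default_cov,
                            interval = default_cov)
  structure(list(
    n_women = as.integer(n_women),
    sampling_fraction_round1 = sampling_fraction_round1,
    sampling_fraction_subsequent = sampling_fraction_subsequent,
    p_first_round = p_first_round, age_probs = age_probs,
    p_ht = p_ht, p_family_history = p_family_history,
    p_symptoms = p_symptoms,
    density_meanlog = density_meanlog, density_sdlog = density_sdlog,
    measure_b_rho = measure_b_rho,
    measure_b_meanlog = measure_b_meanlog,
    measure_b_sdlog = measure_b_sdlog,
    intercepts = intercepts, density_logor = dl,
    covariate_logor = covariate_logor,
    case_control_sampling = isTRUE(case_control_sampling),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a simulated screening cohort
#'
#' @param spec A [cohort_spec].
#' @return Data frame with columns `woman_id`, `age_group`, `ht_use`,
#'   `family_history`, `symptoms`, `screening_round`, `outcome`,
#'   `tumour_size_mm` (cancers only, `NA` for controls), `dense_area_px_a`,
#'   `dense_area_px_b`, `weight`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, .generate_cohort_impl(spec))
}

.generate_cohort_impl <- function(spec) {
  n <- spec$n_women
  round1 <- runif(n) < spec$p_first_round
  age_idx <- sample.int(6L, n, replace = TRUE, prob = spec$age_probs)
  ht <- runif(n) < spec$p_ht
  fh <- runif(n) < spec$p_family_history
  sym <- runif(n) < spec$p_symptoms

  u <- runif(n) * 100                       # latent population percentile
  dense_a <- qlnorm(u / 100, spec$density_meanlog, spec$density_sdlog)
  z_a <- qnorm(u / 100)
  rho <- spec$measure_b_rho
  z_b <- rho * z_a + sqrt(1 - rho^2) * rnorm(n)
  dense_b <- qlnorm(pnorm(z_b), spec$measure_b_meanlog, spec$measure_b_sdlog)

  grp_idx <- as.integer(assign_density_group(u))

  eta <- sapply(c("small", "large", "interval"), function(k) {
    cv <- spec$covariate_logor[[k]]
    spec$intercepts[[k]] + spec$density_logor[[k]][grp_idx] +
      cv[["ht"]] * ht + cv[["family_history"]] * fh +
      cv[["symptoms"]] * sym + cv[["subsequent_round"]] * !round1 +
      cv[["age_step"]] * (age_idx - 1L)
  })
  expeta <- exp(eta)
  denom <- 1 + rowSums(expeta)
  # outcome draw from the multinomial logit (control is the baseline)
  p_cum <- cbind(1, 1 + expeta[, 1], 1 + expeta[, 1] + expeta[, 2]) / denom
  r <- runif(n)
  out_idx <- 1L + (r > p_cum[, 1]) + (r > p_cum[, 2]) + (r > p_cum[, 3])
  outcome <- .outcome_levels[out_idx]

  size <- rep(NA_real_, n)
  is_small <- outcome == "small_screen_detected"
  is_large <- outcome == "large_screen_detected"
  is_int <- outcome == "interval"
  micro <- is_small & runif(n) < 0.05       # occasional microinvasive tumours
  size[is_small] <- round(runif(sum(is_small), 1, 15), 1)
  size[micro] <- 0.1
  size[is_large] <- round(runif(sum(is_large), 15.1, 45), 1)
  size[is_int] <- round(runif(sum(is_int), 1, 45), 1)

  weight <- ifelse(outcome == "control",
                   ifelse(round1, 1 / spec$sampling_fraction_round1,
                          1 / spec$sampling_fraction_subsequent), 1)

  keep <- rep(TRUE, n)
  if (spec$case_control_sampling) {
    f <- ifelse(round1, spec$sampling_fraction_round1,
                spec$sampling_fraction_subsequent)
    keep <- outcome != "control" | runif(n) < f
  }

  data.frame(
    woman_id = sprintf("W%07d", seq_len(n)),
    age_group = .age_levels[age_idx],
    ht_use = ifelse(ht, "yes", "no"),
    family_history = ifelse(fh, "yes", "no"),
    symptoms = ifelse(sym, "no-significant", "none"),
    screening_round = ifelse(round1, "first", "subsequent"),
    outcome = outcome,
    tumour_size_mm = size,
    dense_area_px_a = dense_a,
    dense_area_px_b = dense_b,
    weight = weight,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
}

#' Write / read a cohort table
#'
#' The CSV schema consumed by the validation statistics: columns
#' `woman_id, age_group, ht_use, family_history, symptoms, screening_round,
#' outcome, tumour_size_mm, dense_area_px_a, dense_area_px_b, weight`.
#'
#' @param cohort Data frame from [generate_cohort].
#' @param path CSV path.
#' @return Invisibly `path` (write) or the validated data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  .check_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(woman_id = "character"))
  .check_cohort(tab)
  tab
}

.cohort_columns <- c("woman_id", "age_group", "ht_use", "family_history",
                     "symptoms", "screening_round", "outcome",
                     "tumour_size_mm", "dense_area_px_a", "dense_area_px_b",
                     "weight")

.check_cohort <- function(tab) {
  missing <- setdiff(.cohort_columns, names(tab))
  if (length(missing))
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "))
  invisible(tab)
}
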