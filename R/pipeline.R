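# Batch drivers tying image processing and statistics together. Every run
# writes a resolved-config snapshot next to its outputs so it can be
# reproduced bit-identically.

#' Measure breast density for a batch of mammograms
#'
#' Processes each image independently (per-image thresholds do not depend
#' on the rest of the batch), logging one status line per image. Failures
#' are recorded as data rows, not raised as errors.
#'
#' @param inputs Character vector of image paths, or a single directory
#'   (every `.png`/`.tif`/`.tiff`/`.pgm` file in it).
#' @param output_dir Output directory; created if missing. Receives
#'   `results.csv`, `config.yaml` and, on request, per-image overlay and
#'   mask images.
#' @param config Pipeline configuration from [density_config].
#' @param save_masks,save_overlays Write a dense-mask image / an outline
#'   overlay image per successful mammogram.
#' @param quiet Suppress per-image log messages.
#' @return Invisibly, the results data frame (see [results_table]).
#' @export
run_measure <- function(inputs, output_dir, config = density_config(),
                        save_masks = FALSE, save_overlays = FALSE,
                        quiet = FALSE) {
  if (length(inputs) == 1L && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.(png|tif|tiff|pgm)$",
                         full.names = TRUE, ignore.case = TRUE)
  if (length(inputs) == 0L) stop("no readable images supplied")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (!quiet) message(sprintf(...))
  results <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    t0 <- proc.time()[["elapsed"]]
    img <- read_image(inputs[i])
    keep <- save_masks || save_overlays
    res <- process_image(img, config, keep_masks = keep)
    dt <- proc.time()[["elapsed"]] - t0
    if (identical(res$status, "success")) {
      log_line("[%s] OK  PD=%.2f%% t=%g (%.2fs)", res$source_id,
               res$percent_density, res$threshold, dt)
      ext <- if (img$bit_depth == 8L) "png" else "pgm"
      if (save_overlays || save_masks)
        write_overlay(img, res$breast, res$dense,
                      file.path(output_dir,
                                sprintf("%s_outline.%s", res$source_id, ext)),
                      file.path(output_dir,
                                sprintf("%s_dense_mask.png", res$source_id)))
      res$breast <- NULL
      res$dense <- NULL
    } else {
      log_line("[%s] %s (%.2fs)", res$source_id, res$reason, dt)
    }
    results[[i]] <- res
  }
  tab <- results_table(results)
  write_results(tab, file.path(output_dir, "results.csv"))
  yaml::write_yaml(config, file.path(output_dir, "config.yaml"))
  n_ok <- sum(tab$status == "OK")
  log_line("processed %d image(s): %d success, %d failure",
           nrow(tab), n_ok, nrow(tab) - n_ok)
  invisible(tab)
}

#' Run the validation analyses on a cohort
#'
#' Joins per-image density measurements (optional) onto a cohort table and
#' emits the analysis reports: covariate-adjusted odds-ratio tables per
#' outcome, the programme-sensitivity table, AUCs for each outcome
#' contrast, trend/rank tests, and the between-measure agreement report.
#'
#' @param cohort Cohort data frame or CSV path (schema of
#'   [generate_cohort]).
#' @param results Optional results data frame or CSV path from
#'   [run_measure]; successful rows replace `dense_area_px_a` by matching
#'   `source_id` to `woman_id` (every cohort id must resolve).
#' @param output_dir Output directory for the CSV reports (created if
#'   missing); `NULL` to skip writing.
#' @param profile Covariate profile for the sensitivity table (see
#'   [predict_sensitivity]).
#' @param make_plots Also write `roc.png` and `bland_altman.png`.
#' @return Invisibly, a list with `or_tables`, `sensitivity`, `auc`,
#'   `trend`, `agreement` (components `NULL` when skipped for lack of
#'   cases).
#' @export
run_analysis <- function(cohort, results = NULL, output_dir = NULL,
                         profile = list(), make_plots = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  .check_cohort(cohort)
  if (!is.null(results)) {
    if (is.character(results)) results <- read_results(results)
    ok <- results[results$status == "OK", , drop = FALSE]
    idx <- match(cohort$woman_id, ok$source_id)
    if (anyNA(idx))
      stop("cohort ids not found in results: ",
           paste(head(cohort$woman_id[is.na(idx)], 5L), collapse = ", "))
    cohort$dense_area_px_a <- ok$dense_area_px[idx]
  }
  has_cases <- any(cohort$outcome != "control")
  has_controls <- any(cohort$outcome == "control")
  case_sets <- list(
    all_cancers = c("small_screen_detected", "large_screen_detected",
                    "interval"),
    small_screen_detected = "small_screen_detected",
    large_screen_detected = "large_screen_detected",
    interval = "interval"
  )
  or_tables <- NULL
  auc_tab <- NULL
  sens <- NULL
  if (has_cases && has_controls) {
    or_tables <- lapply(case_sets, function(cs) {
      if (!any(cohort$outcome %in% cs)) return(NULL)
      tryCatch(fit_outcome_model(cohort, cases = cs),
               error = function(e) {
                 message("odds-ratio model skipped (", conditionMessage(e),
                         ")")
                 NULL
               })
    })
    d <- .prepare_records(cohort, "a")
    pct <- weighted_percentiles(d$dense_area_px_a, d$weight)
    auc_rows <- lapply(names(case_sets), function(nm) {
      cs <- case_sets[[nm]]
      if (!any(d$outcome %in% cs)) return(NULL)
      a <- roc_auc(pct[d$outcome %in% cs], pct[d$outcome == "control"])
      data.frame(contrast = paste0(nm, "_vs_controls"), auc = a$auc)
    })
    sd_set <- c("small_screen_detected", "large_screen_detected")
    if (any(d$outcome == "interval") && any(d$outcome %in% sd_set)) {
      a <- roc_auc(pct[d$outcome == "interval"], pct[d$outcome %in% sd_set])
      auc_rows <- c(auc_rows, list(data.frame(
        contrast = "interval_vs_screen_detected", auc = a$auc)))
      sens <- tryCatch(predict_sensitivity(cohort, profile = profile),
                       error = function(e) {
                         message("sensitivity model skipped (",
                                 conditionMessage(e), ")")
                         NULL
                       })
    }
    auc_tab <- do.call(rbind, auc_rows)
  } else {
    message("no cases (or no controls) in cohort: ",
            "odds-ratio, AUC and sensitivity analyses skipped")
  }
  dd <- .prepare_records(cohort, "a")
  trend <- trend_and_rank_tests(dd$dense_area_px_a,
                                dd$density_group)
  agreement <- compare_measures(cohort$dense_area_px_a,
                                cohort$dense_area_px_b, cohort$weight)
  out <- list(or_tables = or_tables, sensitivity = sens, auc = auc_tab,
              trend = trend, agreement = agreement)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(or_tables))
      for (nm in names(or_tables))
        if (!is.null(or_tables[[nm]]))
          write.csv(or_tables[[nm]],
                    file.path(output_dir, paste0("or_", nm, ".csv")),
                    row.names = FALSE)
    if (!is.null(sens))
      write.csv(sens, file.path(output_dir, "sensitivity.csv"),
                row.names = FALSE)
    if (!is.null(auc_tab))
      write.csv(auc_tab, file.path(output_dir, "auc.csv"), row.names = FALSE)
    write.csv(data.frame(test = c("cuzick_z", "cuzick_p", "kruskal_h",
                                  "kruskal_p"),
                         value = c(trend$cuzick$z, trend$cuzick$p_value,
                                   trend$kruskal_wallis$h,
                                   trend$kruskal_wallis$p_value)),
              file.path(output_dir, "trend_tests.csv"), row.names = FALSE)
    write.csv(as.data.frame(agreement$cross_classification),
              file.path(output_dir, "cross_classification.csv"))
    write.csv(data.frame(
      statistic = c("pearson_r", "r_p_value", "ba_mean_diff_log",
                    "ba_loa_low", "ba_loa_high", "perfect_agreement_pct",
                    "within_one_pct"),
      value = c(agreement$r, agreement$r_p_value,
                agreement$bland_altman$mean_diff,
                agreement$bland_altman$loa_low,
                agreement$bland_altman$loa_high,
                agreement$perfect_agreement_pct,
                agreement$within_one_pct)),
      file.path(output_dir, "agreement.csv"), row.names = FALSE)
    if (make_plots) {
      if (has_cases && has_controls) {
        d <- .prepare_records(cohort, "a")
        pct <- weighted_percentiles(d$dense_area_px_a, d$weight)
        roc <- roc_auc(pct[d$outcome != "control"],
                       pct[d$outcome == "control"])
        grDevices::png(file.path(output_dir, "roc.png"), 600, 600)
        plot_roc(roc)
        grDevices::dev.off()
      }
      grDevices::png(file.path(output_dir, "bland_altman.png"), 600, 600)
      plot_bland_altman(cohort$dense_area_px_a, cohort$dense_area_px_b)
      grDevices::dev.off()
    }
  }
  invisible(out)
}

#' Plot an ROC curve
#' @param roc Result of [roc_auc].
#' @param ... Passed to [graphics::plot].
#' @export
plot_roc <- function(roc, ...) {
  graphics::plot(roc$curve$fpr, roc$curve$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", roc$auc), ...)
  graphics::abline(0, 1, lty = 2)
}

#' Bland-Altman plot of two dense-area measures (log scale)
#' @param measure_a,measure_b Paired positive dense areas.
#' @export
plot_bland_altman <- function(measure_a, measure_b) {
  ok <- measure_a > 0 & measure_b > 0
  d <- log(measure_a[ok]) - log(measure_b[ok])
  m <- (log(measure_a[ok]) + log(measure_b[ok])) / 2
  md <- mean(d); s <- sd(d)
  graphics::plot(m, d, xlab = "Mean of log dense areas",
                 ylab = "Difference of log dense areas",
                 main = "Bland-Altman agreement")
  graphics::abline(h = c(md, md - 1.96 * s, md + 1.96 * s),
                   lty = c(1, 2, 2))
}
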