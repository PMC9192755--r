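## CLIA-style validation statistics: per-sample cell-level sensitivity and
## specificity, treatment-bin accuracy concordance, ICC precision from
## two-way variance components with a parametric-simulation 95% CI, Pearson
## concordance with Bonferroni correction, average percent error, and the
## four-parameter validation report.

#' Default validation criteria
#'
#' @param identification_min minimum fraction of true cells identified.
#' @param fpr_max maximum false positive rate (negative cells called
#'   positive).
#' @param fnr_max maximum false negative rate (positive cells called
#'   negative).
#' @param cohort_pass_min minimum fraction of samples meeting all criteria.
#' @param bin_concordance_min minimum treatment-bin concordance fraction.
#' @param icc_min minimum ICC (point estimate and CI lower bound).
#' @export
criteria_config <- function(identification_min = 0.90, fpr_max = 0.10,
                            fnr_max = 0.20, cohort_pass_min = 0.90,
                            bin_concordance_min = 0.90, icc_min = 0.60) {
  list(identification_min = identification_min, fpr_max = fpr_max,
       fnr_max = fnr_max, cohort_pass_min = cohort_pass_min,
       bin_concordance_min = bin_concordance_min, icc_min = icc_min)
}

#' Cell-level identification and staining-classification metrics
#'
#' Matches predicted to true cells by mutual nearest neighbour within
#' `match_dist`, then computes per sample: the identification rate (matched
#' true cells / true cells), the false positive rate (matched truly
#' PD-L1-negative cells classified positive) and the false negative rate
#' (matched truly positive cells classified negative). Samples with zero
#' true cells are excluded with a warning.
#'
#' @param samples list; each element is `list(pred = <cell table with
#'   pdl1_bin>, truth = <ground-truth table>)`.
#' @param match_dist matching radius in pixels.
#' @param criteria a [criteria_config()].
#' @return list with `per_sample` (data frame) and `pass_fraction`s per
#'   criterion plus `cohort_pass_fraction` (all criteria jointly).
#' @export
cell_level_metrics <- function(samples, match_dist = 5,
                               criteria = criteria_config()) {
  rows <- lapply(seq_along(samples), function(i) {
    pred <- samples[[i]]$pred; truth <- samples[[i]]$truth
    if (nrow(truth) == 0) {
      warning("sample ", i, " has zero true cells; excluded")
      return(NULL)
    }
    m <- match_points(as.matrix(truth[, c("x", "y")]),
                      as.matrix(pred[, c("x", "y")]), match_dist)
    ident <- nrow(m$pairs) / nrow(truth)
    fpr <- fnr <- NA_real_
    if (nrow(m$pairs) > 0) {
      tpos <- truth$pdl1_intensity[m$pairs[, 1]] >= 1
      ppos <- pred$pdl1_bin[m$pairs[, 2]] >= 1
      if (any(!tpos)) fpr <- mean(ppos[!tpos])
      if (any(tpos)) fnr <- mean(!ppos[tpos])
    }
    data.frame(sample = i, n_true = nrow(truth), n_pred = nrow(pred),
               identification_rate = ident,
               false_positive_rate = fpr, false_negative_rate = fnr)
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) == 0) stop("no scorable samples")
  ok_id <- per$identification_rate >= criteria$identification_min
  ok_fp <- is.na(per$false_positive_rate) |
    per$false_positive_rate <= criteria$fpr_max
  ok_fn <- is.na(per$false_negative_rate) |
    per$false_negative_rate <= criteria$fnr_max
  list(per_sample = per,
       identification_pass_fraction = mean(ok_id),
       fpr_pass_fraction = mean(ok_fp),
       fnr_pass_fraction = mean(ok_fn),
       cohort_pass_fraction = mean(ok_id & ok_fp & ok_fn))
}

#' Treatment-bin accuracy concordance
#'
#' Fraction of samples where digital and manual TPS fall on the same side
#' of the treatment cut-off (default 1%).
#'
#' @param digital,manual numeric TPS vectors of equal length.
#' @param cutoff treatment decision cut-off in percent.
#' @param pass_min minimum concordant fraction to pass.
#' @return list `(bin_concordance_fraction, pass, n)`.
#' @export
accuracy_concordance <- function(digital, manual, cutoff = 1,
                                 pass_min = 0.90) {
  if (length(digital) != length(manual))
    stop("digital and manual score lists differ in length")
  conc <- mean((digital >= cutoff) == (manual >= cutoff))
  list(bin_concordance_fraction = conc, pass = conc >= pass_min,
       n = length(digital))
}

reliability_category <- function(icc) {
  if (icc < 0.5) "poor"
  else if (icc <= 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
}

## Method-of-moments variance components from the two-way (sample x repeat)
## ANOVA table; negative estimates truncated at zero.
variance_components <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  long <- data.frame(y = as.numeric(tab),
                     s = factor(rep(seq_len(n), k)),
                     r = factor(rep(seq_len(k), each = n)))
  ## perfect-fit F-statistic warnings are irrelevant here: only the
  ## mean squares are consumed
  an <- suppressWarnings(stats::anova(stats::aov(y ~ s + r, data = long)))
  ms_s <- an["s", "Mean Sq"]; ms_r <- an["r", "Mean Sq"]
  ms_e <- an["Residuals", "Mean Sq"]
  c(sample = max((ms_s - ms_e) / k, 0),
    repeat_ = max((ms_r - ms_e) / n, 0),
    residual = ms_e)
}

#' ICC precision analysis of a sample-by-repeat score table
#'
#' Fits the random two-way decomposition (sample + repeat day + residual)
#' by method of moments from the ANOVA table, truncating negative
#' components at zero, and computes `ICC = 1 - (proportion of variance due
#' to repeated scoring + proportion of residual variance)` — i.e. the
#' inter-sample variance proportion. Reliability is categorized as poor
#' (< 0.5), moderate (0.5-0.75), good (0.75-0.9) or excellent (> 0.9).
#'
#' A table with zero total variance is degenerate: ICC is 1 by convention
#' and the result is flagged. When `n_sim > 0` a parametric-simulation 95%
#' CI is attached via [icc_simulation_ci()].
#'
#' @param tab numeric matrix (samples x repeats).
#' @param n_sim number of CI simulations (0 = no CI).
#' @param seed RNG seed for the CI simulation.
#' @param icc_min pass threshold for point estimate and CI lower bound.
#' @param variant `"printed"` (default) scores ICC = 1 - (repeat + residual
#'   proportions), the inter-sample share; `"prose"` scores the looser
#'   reading 1 - repeat proportion. Both values are always reported
#'   (`icc`, `icc_prose`); the variant selects which one drives
#'   `pass`/`reliability` and the CI.
#' @return object of class `precision_result`: variance `proportions`
#'   (sample/repeat/residual, summing to 1), `icc`, `ci95`, `n_simulations`,
#'   `reliability`, `pass`, `degenerate`.
#' @export
icc_precision <- function(tab, n_sim = 0, seed = 1L, icc_min = 0.60,
                          variant = c("printed", "prose")) {
  variant <- match.arg(variant)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need >= 2 samples and >= 2 repeats")
  if (anyNA(tab)) stop("score table contains missing values")
  degenerate <- FALSE
  if (stats::var(as.numeric(tab)) == 0) {
    ## all scores identical: no variance to attribute anywhere
    comps <- c(sample = 0, repeat_ = 0, residual = 0)
    props <- c(sample = 1, repeat_ = 0, residual = 0)
    degenerate <- TRUE
  } else {
    comps <- variance_components(tab)
    props <- comps / sum(comps)
  }
  icc_printed <- unname(1 - (props["repeat_"] + props["residual"]))
  icc_prose <- unname(1 - props["repeat_"])
  icc <- if (variant == "printed") icc_printed else icc_prose
  res <- structure(list(
    variance_components = comps,
    proportions = stats::setNames(as.numeric(props),
                                  c("sample", "repeat", "residual")),
    icc = as.numeric(icc), icc_printed = as.numeric(icc_printed),
    icc_prose = as.numeric(icc_prose), variant = variant,
    ci95 = c(NA_real_, NA_real_),
    n_simulations = 0L, reliability = reliability_category(icc),
    n_samples = nrow(tab), n_repeats = ncol(tab),
    pass = as.numeric(icc) >= icc_min, degenerate = degenerate,
    icc_min = icc_min), class = "precision_result")
  if (n_sim > 0) res <- icc_simulation_ci(res, n_sim = n_sim, seed = seed)
  res
}

#' Parametric-simulation 95% CI for an ICC estimate
#'
#' Simulates score tables at the observed design (same number of samples
#' and repeats) from the fitted Gaussian variance components, refits the
#' decomposition per replicate and takes the percentile 2.5/97.5 interval.
#' Deterministic given the seed. With zero repeat and residual variance the
#' interval is exactly (1, 1).
#'
#' @param result a `precision_result` from [icc_precision()].
#' @param n_sim number of simulations (>= 1000 by convention).
#' @param seed RNG seed.
#' @return the updated `precision_result` (with `ci95`, `n_simulations`,
#'   and `pass` now requiring the CI lower bound to clear the threshold).
#' @export
icc_simulation_ci <- function(result, n_sim = 1000, seed = 1L) {
  stopifnot(inherits(result, "precision_result"))
  comps <- result$variance_components
  if (sum(comps) == 0 && !result$degenerate)
    stop("degenerate variance components: all zero")
  if (comps["repeat_"] == 0 && comps["residual"] == 0) {
    result$ci95 <- c(1, 1)
    result$n_simulations <- as.integer(n_sim)
    result$pass <- result$icc >= result$icc_min
    return(result)
  }
  n <- result$n_samples; k <- result$n_repeats
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      s <- stats::rnorm(n, 0, sqrt(comps["sample"]))
      r <- stats::rnorm(k, 0, sqrt(comps["repeat_"]))
      e <- matrix(stats::rnorm(n * k, 0, sqrt(comps["residual"])), n, k)
      tab <- outer(s, r, "+") + e
      cc <- variance_components(tab)
      if (result$variant == "prose") 1 - as.numeric(cc["repeat_"] / sum(cc))
      else as.numeric(cc["sample"] / sum(cc))
    }, numeric(1))
  })
  result$ci95 <- as.numeric(stats::quantile(sims, c(0.025, 0.975),
                                            names = FALSE))
  result$n_simulations <- as.integer(n_sim)
  result$pass <- result$icc >= result$icc_min &&
    result$ci95[1] >= result$icc_min
  result
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf(paste0("ICC = %.3f (%s reliability)%s\n",
                     "variance proportions: sample %.3f, repeat %.3f, ",
                     "residual %.3f\n"),
              x$icc, x$reliability,
              if (x$n_simulations > 0)
                sprintf(", 95%% CI [%.3f, %.3f] from %d simulations",
                        x$ci95[1], x$ci95[2], x$n_simulations) else "",
              x$proportions["sample"], x$proportions["repeat"],
              x$proportions["residual"]))
  if (x$degenerate) cat("note: degenerate (zero-variance) score table\n")
  invisible(x)
}

#' Pearson concordance with Bonferroni correction
#'
#' Computes Pearson's r and two-sided p for each named score pair;
#' significance is tested against `family_alpha / n_comparisons` (the
#' reported threshold is rounded to 3 decimals, e.g. 0.05/3 -> 0.017, but
#' decisions use the exact value).
#'
#' @param pairs named list of `list(x = , y = )` numeric vectors.
#' @param n_comparisons size of the comparison family (default: number of
#'   pairs).
#' @param family_alpha family-wise alpha.
#' @return object of class `concordance_result`.
#' @export
pearson_concordance <- function(pairs, n_comparisons = length(pairs),
                                family_alpha = 0.05) {
  alpha <- family_alpha / n_comparisons
  rows <- lapply(names(pairs), function(nm) {
    x <- pairs[[nm]]$x; y <- pairs[[nm]]$y
    if (length(x) < 3 || length(y) < 3)
      stop("pair '", nm, "' needs >= 3 observations")
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(name = nm, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, significant = ct$p.value < alpha)
  })
  structure(list(pairs = do.call(rbind, rows),
                 alpha_corrected = alpha,
                 alpha_reported = round(alpha, 3),
                 family_alpha = family_alpha,
                 n_comparisons = n_comparisons),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Pearson concordance (Bonferroni-corrected alpha %.3f):\n",
              x$alpha_reported))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Average percent error of predicted vs truth counts
#'
#' `mean(100 * (predicted - truth) / truth)` over samples; negative values
#' mean under-prediction. Samples with zero truth are excluded with a
#' warning.
#'
#' @param predicted,truth numeric count vectors of equal length.
#' @return percent (scalar).
#' @export
average_percent_error <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  keep <- truth != 0
  if (!any(keep)) stop("all truth counts are zero")
  if (any(!keep))
    warning(sum(!keep), " sample(s) with zero truth count excluded")
  mean(100 * (predicted[keep] - truth[keep]) / truth[keep])
}

#' Assemble the four-parameter validation report
#'
#' One row per validation parameter (Specificity, Sensitivity, Accuracy,
#' Precision) with its definition, observed value, criterion and pass/fail.
#' Missing inputs are listed and the report is still emitted as partial.
#'
#' @param cell_metrics output of [cell_level_metrics()] (specificity /
#'   sensitivity), or NULL.
#' @param accuracy output of [accuracy_concordance()], or NULL.
#' @param precision a `precision_result`, or NULL.
#' @param criteria a [criteria_config()].
#' @return object of class `validation_report` (data frame `rows` +
#'   `missing_inputs`).
#' @export
validation_report <- function(cell_metrics = NULL, accuracy = NULL,
                              precision = NULL,
                              criteria = criteria_config()) {
  rows <- list(); missing <- character()
  if (!is.null(cell_metrics)) {
    rows$specificity <- data.frame(
      parameter = "Analytical Specificity",
      definition = "cells identified only when true; FPR <= 10% per sample",
      observed = cell_metrics$fpr_pass_fraction,
      criterion = sprintf(">= %.0f%% of samples", 100 * criteria$cohort_pass_min),
      pass = cell_metrics$fpr_pass_fraction >= criteria$cohort_pass_min)
    rows$sensitivity <- data.frame(
      parameter = "Analytical Sensitivity",
      definition = "cells identified when present; FNR <= 20% per sample",
      observed = min(cell_metrics$identification_pass_fraction,
                     cell_metrics$fnr_pass_fraction),
      criterion = sprintf(">= %.0f%% of samples", 100 * criteria$cohort_pass_min),
      pass = cell_metrics$identification_pass_fraction >=
        criteria$cohort_pass_min &&
        cell_metrics$fnr_pass_fraction >= criteria$cohort_pass_min)
  } else missing <- c(missing, "cell_metrics")
  if (!is.null(accuracy)) {
    rows$accuracy <- data.frame(
      parameter = "Accuracy",
      definition = "digital vs manual treatment-bin concordance",
      observed = accuracy$bin_concordance_fraction,
      criterion = sprintf(">= %.0f%% concordant",
                          100 * criteria$bin_concordance_min),
      pass = accuracy$bin_concordance_fraction >= criteria$bin_concordance_min)
  } else missing <- c(missing, "accuracy")
  if (!is.null(precision)) {
    rows$precision <- data.frame(
      parameter = "Precision",
      definition = "inter-day ICC of repeated scoring",
      observed = precision$icc,
      criterion = sprintf("ICC and CI lower bound >= %.1f", criteria$icc_min),
      pass = isTRUE(precision$pass))
  } else missing <- c(missing, "precision")
  structure(list(rows = do.call(rbind, unname(rows)),
                 missing_inputs = missing),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  print(x$rows, row.names = FALSE)
  if (length(x$missing_inputs) > 0)
    cat("partial report; missing inputs:",
        paste(x$missing_inputs, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a validation report as JSON
#' @param report a `validation_report`.
#' @param path .json path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(list(rows = report$rows,
                            missing_inputs = report$missing_inputs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(rows = obj$rows,
                 missing_inputs = as.character(obj$missing_inputs)),
            class = "validation_report")
}
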