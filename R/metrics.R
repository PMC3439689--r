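# Per-colony CFC metrics and group-level statistical summaries.

#' Compute per-colony proliferation and differentiation metrics
#'
#' From the assigned nucleus records and MHC region table of one image:
#' `total_nuclei` is the sum of all nuclear quantities (proliferative
#' potential); `df`, the coefficient of differentiation, is
#' `1 - stain_negative / total` — the fraction of the colony's nuclei lying
#' within MHC+ cytoplasm; `ui`, the fusion index, is the fraction of nuclei
#' inside MULTI-classified fibers (more than two nuclei), the definitive
#' fusion products. Both run from 0 to 1 and `ui <= df` always. A
#' zero-nucleus image yields `df = ui = 0` with a warning so batch output
#' stays rectangular.
#'
#' @param nuclei,mhc the two tibbles returned by [assign_nuclei_to_mhc()].
#' @param image_id image identifier for the output row.
#' @return a one-row tibble: `image_id`, `total_nuclei`,
#'   `stain_negative_nuclei`, `mhc_positive_nuclei`, `df`, `ui`,
#'   `mono_count`, `bi_count`, `multi_count`, `anucleate_count`.
#' @export
compute_colony_metrics <- function(nuclei, mhc, image_id) {
  stopifnot(is.data.frame(nuclei), is.data.frame(mhc),
            is.character(image_id), length(image_id) == 1L)
  total <- sum(nuclei$nuclear_quantity)
  unassigned <- is.na(nuclei$assigned_mhc_label)
  stain_negative <- sum(nuclei$nuclear_quantity[unassigned])
  mhc_positive <- total - stain_negative
  if (total > 0) {
    df <- 1 - stain_negative / total
    multi <- mhc$fiber_class == "MULTI"
    ui <- sum(mhc$nuclei_total[multi]) / total
  } else {
    warning("image '", image_id, "' has no nuclei; df and ui set to 0",
            call. = FALSE)
    df <- 0; ui <- 0
  }
  cls <- table(factor(mhc$fiber_class,
                      levels = c("ANUCLEATE", "MONO", "BI", "MULTI")))
  quick_tibble(list(
    image_id = image_id,
    total_nuclei = total,
    stain_negative_nuclei = stain_negative,
    mhc_positive_nuclei = mhc_positive,
    df = df,
    ui = ui,
    mono_count = as.integer(cls[["MONO"]]),
    bi_count = as.integer(cls[["BI"]]),
    multi_count = as.integer(cls[["MULTI"]]),
    anucleate_count = as.integer(cls[["ANUCLEATE"]])))
}

metric_columns <- c(TOTAL = "total_nuclei", DF = "df", UI = "ui")

resolve_metric <- function(metric) {
  if (metric %in% names(metric_columns)) metric_columns[[metric]]
  else if (metric %in% metric_columns) metric
  else stop_cfc("unknown metric '", metric, "'", class = "cfc_param_error")
}

#' Summarize a group of colonies
#'
#' Mean and two-sided 95% confidence interval (Student t, `n - 1` degrees
#' of freedom) of a colony metric over a group, as drawn as the blue
#' mean/CI bars of a CFC group plot. With a single colony the interval is
#' degenerate at the mean, with a warning.
#'
#' @param colonies tibble of per-colony metrics
#'   (rows from [compute_colony_metrics()]).
#' @param metric `"TOTAL"`, `"DF"` or `"UI"` (or the corresponding column
#'   name).
#' @param conf_level confidence level (default 0.95).
#' @return a one-row tibble: `metric`, `n`, `mean`, `ci_lower`, `ci_upper`.
#' @export
summarize_group <- function(colonies, metric = c("TOTAL", "DF", "UI"),
                            conf_level = 0.95) {
  stopifnot(is.data.frame(colonies))
  if (nrow(colonies) == 0L)
    stop_cfc("no colonies to summarize", class = "cfc_value_error")
  metric <- resolve_metric(match.arg(metric))
  x <- colonies[[metric]]
  n <- length(x)
  m <- mean(x)
  if (n == 1L) {
    warning("single colony: confidence interval degenerate at the mean",
            call. = FALSE)
    half <- 0
  } else {
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(x) / sqrt(n)
  }
  quick_tibble(list(metric = metric, n = n, mean = m,
                    ci_lower = m - half, ci_upper = m + half))
}

#' Compare a colony metric between two groups
#'
#' Welch's unequal-variance two-sample t test on the per-colony values of
#' the chosen metric, reporting the difference of means (group a minus
#' group b) with its confidence interval.
#'
#' @param a,b tibbles of per-colony metrics, each with at least 2 rows.
#' @param metric `"TOTAL"`, `"DF"` or `"UI"` (or a column name).
#' @param conf_level confidence level (default 0.95).
#' @return a one-row tibble: `metric`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `difference`, `ci_lower`, `ci_upper`, `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(a, b, metric = c("TOTAL", "DF", "UI"),
                           conf_level = 0.95) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  metric <- resolve_metric(match.arg(metric))
  x <- a[[metric]]; y <- b[[metric]]
  if (length(x) < 2L || length(y) < 2L)
    stop_cfc("each group needs at least 2 colonies", class = "cfc_value_error")
  ht <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  quick_tibble(list(metric = metric,
                    n_a = length(x), n_b = length(y),
                    mean_a = mean(x), mean_b = mean(y),
                    difference = mean(x) - mean(y),
                    ci_lower = ht$conf.int[1], ci_upper = ht$conf.int[2],
                    statistic = unname(ht$statistic),
                    df = unname(ht$parameter),
                    p_value = ht$p.value))
}
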