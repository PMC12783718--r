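#' Two-sided Mann-Whitney U test
#'
#' U computed by rank summation with midranks for ties. The p-value is exact
#' (by enumeration) for small tie-free samples (combined n <= 16), otherwise
#' a normal approximation with tie and continuity corrections is used.
#' Delegates to [stats::wilcox.test()] for the computation; identical
#' degenerate samples are flagged and reported with p = 1.
#'
#' @param x,y numeric samples.
#' @param alternative only `"two_sided"` is offered.
#' @param method `"auto"` (exact for tie-free combined n <= 16, else the
#'   normal approximation), or force `"exact"` / `"normal_approx"`.
#' @return a `u_test_result` list: `u_statistic` (U for `x`), `p_value`,
#'   `n_x`, `n_y`, `method` (`"exact"` or `"normal_approx"`),
#'   `zero_variance` flag.
#' @export
mann_whitney_u <- function(x, y, alternative = "two_sided",
                           method = c("auto", "exact", "normal_approx")) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  method <- match.arg(method)
  ranks <- rank(c(x, y))
  rx <- sum(ranks[seq_along(x)])
  u <- rx - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    res <- list(u_statistic = u, p_value = 1, n_x = length(x),
                n_y = length(y), method = "normal_approx",
                zero_variance = TRUE)
    class(res) <- "u_test_result"
    return(res)
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(method,
                  auto = !has_ties && (length(x) + length(y)) <= 16,
                  exact = TRUE,
                  normal_approx = FALSE)
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  res <- list(u_statistic = unname(wt$statistic), p_value = wt$p.value,
              n_x = length(x), n_y = length(y),
              method = if (exact) "exact" else "normal_approx",
              zero_variance = FALSE)
  class(res) <- "u_test_result"
  res
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction; p from the chi-squared distribution
#' with (number of groups - 1) degrees of freedom (via
#' [stats::kruskal.test()]). All-identical observations give H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list with `h_statistic`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  if (length(unique(unlist(groups))) == 1L) {
    return(list(h_statistic = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- kruskal.test(groups)
  list(h_statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Percentile bootstrap confidence interval of the median
#'
#' @param values numeric vector (>= 2 values).
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return named vector `c(lower, upper)`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 1000L, level = 0.95,
                                seed = NULL) {
  stopifnot(length(values) >= 2)
  with_seed(seed, {
    meds <- vapply(seq_len(n_boot), function(i) {
      median(sample(values, length(values), replace = TRUE))
    }, numeric(1))
    q <- quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    c(lower = q[1], upper = q[2])
  })
}

#' Per-metric clade comparison of the five shape descriptors
#'
#' One two-sided Mann-Whitney test per descriptor between the two levels of
#' the group column, with per-group medians, unadjusted p-values and a
#' Bonferroni-adjusted column.
#'
#' @param metrics tibble from [metrics_for_dataset()] (or any table with the
#'   five metric columns).
#' @param group_col name of the two-level grouping column (default
#'   `"clade"`).
#' @return tibble: metric, median per group, u_statistic, p_value,
#'   p_bonferroni, method.
#' @export
compare_clade_metrics <- function(metrics, group_col = "clade") {
  metric_cols <- c("circularity", "eccentricity", "solidity", "extent",
                   "minor_axis_length")
  missing <- setdiff(c(metric_cols, group_col), names(metrics))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  gl <- sort(unique(metrics[[group_col]]))
  if (length(gl) != 2) stop("group column must have exactly two levels", call. = FALSE)
  rows <- lapply(metric_cols, function(mc) {
    x <- metrics[[mc]][metrics[[group_col]] == gl[1]]
    y <- metrics[[mc]][metrics[[group_col]] == gl[2]]
    ut <- mann_whitney_u(x, y)
    out <- tibble::tibble(metric = mc, u_statistic = ut$u_statistic,
                          p_value = ut$p_value, method = ut$method)
    out[[paste0("median_", gl[1])]] <- median(x)
    out[[paste0("median_", gl[2])]] <- median(y)
    out
  })
  res <- dplyr::bind_rows(rows)
  res$p_bonferroni <- p.adjust(res$p_value, method = "bonferroni")
  res
}

#' Summaries and box plot of iteration F1 results
#'
#' Median/max/min/IQR of macro-F1 per configuration (mixed flag x test
#' kind), a bootstrap CI of the median, and the clade-based versus
#' mixed-group Mann-Whitney comparison per test kind when both are present.
#'
#' @param results an `iteration_results` tibble from [run_iterations()] (or
#'   several row-bound together).
#' @param n_boot bootstrap replicates for the median CI.
#' @param seed seed for the bootstrap.
#' @return list: `summary` (tibble), `comparisons` (tibble or NULL),
#'   `plot` (ggplot box plot).
#' @export
summarize_runs <- function(results, n_boot = 1000L, seed = 1L) {
  per_iter <- dplyr::distinct(results, .data$iteration, .data$mixed,
                              .data$test_kind, .data$macro_f1)
  summary <- per_iter |>
    dplyr::group_by(.data$mixed, .data$test_kind) |>
    dplyr::summarise(n = dplyr::n(), median = median(.data$macro_f1),
                     max = max(.data$macro_f1), min = min(.data$macro_f1),
                     iqr = stats::IQR(.data$macro_f1), .groups = "drop")
  cis <- lapply(seq_len(nrow(summary)), function(i) {
    v <- per_iter$macro_f1[per_iter$mixed == summary$mixed[i] &
                             per_iter$test_kind == summary$test_kind[i]]
    if (length(v) >= 2) bootstrap_median_ci(v, n_boot, seed = seed + i)
    else c(lower = v, upper = v)
  })
  summary$ci_lower <- vapply(cis, `[[`, numeric(1), "lower")
  summary$ci_upper <- vapply(cis, `[[`, numeric(1), "upper")
  comparisons <- NULL
  if (length(unique(per_iter$mixed)) == 2) {
    comparisons <- dplyr::bind_rows(lapply(unique(per_iter$test_kind), function(tk) {
      cb <- per_iter$macro_f1[!per_iter$mixed & per_iter$test_kind == tk]
      mx <- per_iter$macro_f1[per_iter$mixed & per_iter$test_kind == tk]
      ut <- mann_whitney_u(cb, mx)
      tibble::tibble(test_kind = tk, median_clade = median(cb),
                     median_mixed = median(mx), u_statistic = ut$u_statistic,
                     p_value = ut$p_value)
    }))
  }
  plot_df <- dplyr::mutate(per_iter,
                           model = ifelse(.data$mixed, "mixed-group control",
                                          "clade-based"))
  plt <- ggplot2::ggplot(plot_df,
                         ggplot2::aes(x = .data$test_kind, y = .data$macro_f1,
                                      fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::scale_fill_manual(values = c("clade-based" = "#4477AA",
                                          "mixed-group control" = "#CC6677")) +
    ggplot2::labs(x = "test set", y = "macro-F1", fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  list(summary = summary, comparisons = comparisons, plot = plt)
}
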