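#' Two-group comparison of a per-cell metric
#'
#' Two-sided test of a numeric metric between two independent groups of
#' cells. \code{"t_independent"} is Student's two-sample t with pooled
#' variance (the scientific-computing default for an independent-samples
#' t-test; set \code{welch = TRUE} for the unequal-variance form).
#' \code{"mann_whitney"} uses the exact null distribution when the smaller
#' group has at most 8 observations and no ties are present, and the
#' normal approximation with tie correction otherwise; completely tied
#' data return p = 1 rather than failing.
#'
#' @param a,b numeric vectors (each at least 2 finite values).
#' @param test \code{"t_independent"} or \code{"mann_whitney"}.
#' @param metricName label for the output row.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return One-row data.frame with columns \code{metric_name}, \code{n_a},
#'   \code{n_b}, \code{mean_a}, \code{mean_b}, \code{median_a},
#'   \code{median_b}, \code{test}, \code{statistic}, \code{p_value}.
#' @examples
#' compareGroups(c(1, 2, 3), c(10, 11, 12), "mann_whitney")$p_value  # 0.1
#' @export
compareGroups <- function(a, b, test = c("t_independent", "mann_whitney"),
                          metricName = "metric", welch = FALSE) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite values in input groups")
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")

  if (test == "t_independent") {
    if (stats::sd(c(a, b)) == 0) {
      statistic <- 0; p <- 1
    } else {
      ht <- stats::t.test(a, b, var.equal = !welch)
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    allTied <- length(unique(c(a, b))) == 1L
    if (allTied) {
      statistic <- length(a) * length(b) / 2; p <- 1
    } else {
      ties <- any(duplicated(c(a, b)))
      exact <- min(length(a), length(b)) <= 8L && !ties
      ht <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = !exact))
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  }
  data.frame(metric_name = metricName,
             n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             median_a = stats::median(a), median_b = stats::median(b),
             test = test, statistic = statistic,
             p_value = min(max(p, 0), 1),
             stringsAsFactors = FALSE)
}

#' Compare all metrics between two groups and draw box plots
#'
#' Consumes long-format per-cell measurements (columns \code{cell_id},
#' \code{group}, \code{metric}, \code{value}) — either a data.frame or one
#' or more CSV paths that are concatenated — and produces one
#' [compareGroups()] row per metric plus a box-whisker figure per metric.
#' Exactly two groups must be present. Whiskers extend to 1.5x the
#' interquartile range (\code{whiskers = "iqr"}, the per-cell convention)
#' or to the extremes (\code{whiskers = "minmax"}, the per-subject-summary
#' convention).
#'
#' No multiple-testing correction is applied by default (discovery-phase
#' reporting); \code{adjust = "BH"} switches on Benjamini-Hochberg.
#'
#' @param data long-format data.frame, or character vector of CSV paths.
#' @param test test passed to [compareGroups()].
#' @param welch use Welch's t (when \code{test = "t_independent"}).
#' @param whiskers \code{"iqr"} or \code{"minmax"}.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return List with \code{table} (one row per metric, plus
#'   \code{p_adjusted} when requested) and \code{plots} (named list of
#'   ggplot objects).
#' @importFrom ggplot2 .data
#' @export
batchReport <- function(data, test = c("t_independent", "mann_whitney"),
                        welch = FALSE, whiskers = c("iqr", "minmax"),
                        adjust = c("none", "BH")) {
  test <- match.arg(test)
  whiskers <- match.arg(whiskers)
  adjust <- match.arg(adjust)
  if (is.character(data)) {
    data <- do.call(rbind, lapply(data, utils::read.csv,
                                  stringsAsFactors = FALSE))
  }
  need <- c("cell_id", "group", "metric", "value")
  if (is.null(data) || !nrow(data))
    stop("empty input: no per-cell measurements")
  if (!all(need %in% names(data)))
    stop("input must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(data$group)))
    stop("missing group labels")
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) < 2L)
    stop("at least 2 groups required, found ", length(groups))
  if (length(groups) > 2L)
    stop("exactly 2 groups supported, found ", length(groups))

  metrics <- unique(data$metric)
  tab <- do.call(rbind, lapply(metrics, function(m) {
    sub <- data[data$metric == m, ]
    a <- sub$value[sub$group == groups[1L]]
    b <- sub$value[sub$group == groups[2L]]
    out <- compareGroups(a, b, test = test, metricName = m, welch = welch)
    out$group_a <- groups[1L]; out$group_b <- groups[2L]
    out
  }))
  if (adjust == "BH") tab$p_adjusted <- stats::p.adjust(tab$p_value, "BH")

  coef <- if (whiskers == "iqr") 1.5 else Inf
  plots <- lapply(metrics, function(m) {
    sub <- data[data$metric == m, ]
    ggplot2::ggplot(sub, ggplot2::aes(x = .data$group, y = .data$value)) +
      ggplot2::geom_boxplot(coef = coef, outlier.shape = 1) +
      ggplot2::labs(title = m, x = NULL, y = m) +
      ggplot2::theme_classic()
  })
  names(plots) <- metrics
  list(table = tab, plots = plots)
}
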