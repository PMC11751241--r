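#' G-test of prey use versus availability
#'
#' Goodness-of-fit test of observed prey occurrence counts against expected
#' counts under proportional use of availability:
#' G = 2 * sum_i O_i * log(O_i / E_i) over categories with O_i > 0, with
#' E_i = n * pi_i, df = k - 1 (availability proportions treated as fixed,
#' not estimated), and the p-value from the upper chi-square tail.
#'
#' @param observed a `frequency_table`, or a named vector of observed
#'   counts.
#' @param availability an `availability_table` (or named vector of
#'   availability proportions summing to 1). Categories are taken from the
#'   availability support.
#' @return object of class `gof_result`: list with `g_statistic`, `df`,
#'   `p_value`, `n`.
#' @export
g_test <- function(observed, availability) {
  if (inherits(observed, "frequency_table")) observed <- observed$counts
  if (inherits(availability, "availability_table"))
    pi_i <- availability$proportions
  else {
    pi_i <- availability
    if (abs(sum(pi_i) - 1) > 1e-9)
      stop("availability proportions must sum to 1")
  }
  used <- names(observed)[observed > 0]
  off_support <- setdiff(used, names(pi_i)[pi_i > 0])
  if (length(off_support) > 0L)
    stop("observed use of prey with zero availability: ",
         paste(off_support, collapse = ", "))
  o <- stats::setNames(numeric(length(pi_i)), names(pi_i))
  o[intersect(names(observed), names(o))] <-
    observed[intersect(names(observed), names(o))]
  n <- sum(o)
  if (n <= 0) stop("no observed occurrences")
  keep <- pi_i > 0
  e <- n * pi_i[keep]
  o <- o[keep]
  pos <- o > 0
  g <- 2 * sum(o[pos] * log(o[pos] / e[pos]))
  df <- sum(keep) - 1L
  structure(list(g_statistic = g, df = df,
                 p_value = stats::pchisq(g, df, lower.tail = FALSE),
                 n = n),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("G-test of use vs availability: G = %.2f, df = %d, p = %.4g\n",
              x$g_statistic, x$df, x$p_value))
  invisible(x)
}

#' Manly selection ratios with Bonferroni-adjusted simultaneous CIs
#'
#' For each prey i, w_i = o_i / pi_i with o_i the used proportion
#' (O_i / n) and pi_i the available proportion (treated as known,
#' census-style availability). The standard error is
#' sqrt(o_i (1 - o_i) / (n pi_i^2)) and the simultaneous confidence
#' intervals use z at level 1 - alpha/(2k) (Bonferroni over the k prey
#' types), truncated below at 0. A prey is classified `preference` when its
#' lower limit exceeds 1, `avoidance` when its upper limit is below 1, and
#' `neutral` otherwise. Prey with zero observed use get w = 0 with a
#' degenerate [0, 0] interval and a small-count warning.
#'
#' @param observed a `frequency_table` or named vector of observed counts.
#' @param availability an `availability_table` (or named proportions vector).
#' @param alpha familywise type-I error rate (default 0.05).
#' @return object of class `selection_result`: data.frame with one row per
#'   prey (`prey`, `used`, `available`, `ratio`, `se`, `ci_low`, `ci_high`,
#'   `classification`) and attributes `alpha`, `z`, `n`.
#' @export
selection_ratios <- function(observed, availability, alpha = 0.05) {
  if (inherits(observed, "frequency_table")) observed <- observed$counts
  if (inherits(availability, "availability_table"))
    pi_i <- availability$proportions
  else {
    pi_i <- availability
    if (abs(sum(pi_i) - 1) > 1e-9)
      stop("availability proportions must sum to 1")
  }
  pi_i <- pi_i[pi_i > 0]
  k <- length(pi_i)
  if (k < 2L) stop("selection requires at least 2 prey categories")
  off_support <- setdiff(names(observed)[observed > 0], names(pi_i))
  if (length(off_support) > 0L)
    stop("observed use of prey with zero availability: ",
         paste(off_support, collapse = ", "))
  o_counts <- stats::setNames(numeric(k), names(pi_i))
  o_counts[intersect(names(observed), names(pi_i))] <-
    observed[intersect(names(observed), names(pi_i))]
  n <- sum(o_counts)
  if (n <= 0) stop("no observed occurrences")
  if (any(o_counts == 0))
    warning("prey with zero observed occurrences get degenerate [0,0] ",
            "intervals: ", paste(names(o_counts)[o_counts == 0],
                                 collapse = ", "))
  o <- o_counts / n
  w <- o / pi_i
  se <- sqrt(o * (1 - o) / (n * pi_i^2))
  z <- stats::qnorm(1 - alpha / (2 * k))
  lo <- pmax(0, w - z * se)
  hi <- pmax(0, w + z * se)
  cls <- ifelse(lo > 1, "preference", ifelse(hi < 1, "avoidance", "neutral"))
  out <- data.frame(prey = names(pi_i), used = o, available = pi_i,
                    ratio = w, se = se, ci_low = lo, ci_high = hi,
                    classification = cls, row.names = NULL)
  structure(out, alpha = alpha, z = z, n = n,
            class = c("selection_result", "data.frame"))
}

#' Selection-ratio report: table and forest-style plot
#'
#' Returns the result sorted by decreasing ratio, with wide intervals that
#' cross 1 flagged `inconclusive`, and (optionally) draws horizontal
#' confidence bars per prey with a dashed reference line at 1 (neutral
#' selection).
#'
#' @param result a `selection_result`.
#' @param file optional path for a PDF of the plot; when `NULL` and `plot`
#'   is TRUE, draws on the current device.
#' @param plot whether to draw the plot (default TRUE).
#' @param wide_ci_factor intervals wider than this multiple of the median
#'   width are annotated `inconclusive` when they cross 1 (default 2).
#' @return the sorted table (invisibly when plotting), with an extra
#'   `note` column.
#' @export
selection_report <- function(result, file = NULL, plot = TRUE,
                             wide_ci_factor = 2) {
  stopifnot(inherits(result, "selection_result"), nrow(result) > 0L)
  tab <- result[order(-result$ratio), , drop = FALSE]
  width <- tab$ci_high - tab$ci_low
  wide <- width > wide_ci_factor * stats::median(width) &
    tab$classification == "neutral"
  tab$note <- ifelse(wide, "inconclusive", "")
  rownames(tab) <- NULL
  if (plot) {
    if (!is.null(file)) grDevices::pdf(file, width = 7, height = 5)
    y <- rev(seq_len(nrow(tab)))
    xmax <- max(tab$ci_high, 1.2)
    graphics::plot(NULL, xlim = c(0, xmax * 1.05),
                   ylim = c(0.5, nrow(tab) + 0.5),
                   yaxt = "n", xlab = "Selection ratio (used / available)",
                   ylab = "")
    graphics::abline(v = 1, lty = 2, col = "grey40")
    graphics::segments(tab$ci_low, y, tab$ci_high, y)
    graphics::points(tab$ratio, y, pch = 16)
    graphics::axis(2, at = y, labels = tab$prey, las = 1, cex.axis = 0.8)
    if (!is.null(file)) grDevices::dev.off()
  }
  if (plot) invisible(tab) else tab
}
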