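#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample skewness and kurtosis into the K-squared statistic:
#' each moment is transformed to an approximately standard-normal z-score
#' (skewness via the Johnson SU transformation of D'Agostino 1970, kurtosis
#' via the Anscombe-Glynn 1983 cube-root transformation), and
#' K2 = z_skew^2 + z_kurt^2 is referred to a chi-square distribution with 2
#' degrees of freedom. Requires n >= 20 for the approximations to hold.
#'
#' @param x Numeric sample, n >= 20, finite, non-constant.
#' @return An object of class `htest` with `statistic` (K-squared),
#'   `p.value`, and the component z-scores in `estimate`.
#' @export
dagostino_test <- function(x) {
  dname <- deparse(substitute(x))
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (n < 20L) stop("insufficient sample: the omnibus test requires n >= 20")
  if (stats::var(x) == 0) stop("degenerate variance: sample is constant")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5           # sample skewness g1
  b2 <- m4 / m2^2             # sample kurtosis g2 (not excess)

  # skewness z-score (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z-score (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  structure(list(statistic = c("K-squared" = k2), parameter = c(df = 2),
                 p.value = p,
                 estimate = c(z_skewness = z1, z_kurtosis = z2,
                              skewness = b1, kurtosis = b2 - 3),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = dname),
            class = "htest")
}

#' Kruskal-Wallis comparison of per-cell measurements across groups
#'
#' Rank-based H test (tie-corrected, chi-square reference with k - 1
#' degrees of freedom, via [stats::kruskal.test()]) with per-group summary
#' statistics and a significance label. Each group must have at least
#' `min_n` observations. If all values across all groups are identical the
#' boundary case is handled as H = 0, p = 1.
#'
#' @param values Numeric vector of measurements.
#' @param groups Group labels (factor or character), >= 2 levels.
#' @param metric Name of the measured quantity (for reporting).
#' @param min_n Minimum per-group sample size (default 5).
#' @param thresholds Significance thresholds, see [significance_label()].
#' @return Object of class `group_comparison`: `metric`, `groups`,
#'   `H_statistic`, `df`, `p_value`, `significance`, `summary` (per-group
#'   n/mean/sd/median), and the raw data.
#' @export
kruskal_compare <- function(values, groups, metric = "value", min_n = 5L,
                            thresholds = significance_thresholds()) {
  groups <- as.factor(as.character(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups with finite values")
  ns <- table(groups)
  if (any(ns < min_n)) {
    stop(sprintf("insufficient sample: group(s) %s below n = %d",
                 paste(names(ns)[ns < min_n], collapse = ", "), min_n))
  }
  if (length(unique(values)) == 1L) {
    h <- 0; p <- 1; df <- nlevels(groups) - 1L
  } else {
    kt <- stats::kruskal.test(values, groups)
    h <- unname(kt$statistic); p <- kt$p.value; df <- unname(kt$parameter)
  }
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               median = stats::median(v), stringsAsFactors = FALSE)
  }))
  structure(list(metric = metric, groups = levels(groups),
                 H_statistic = h, df = df, p_value = p,
                 significance = significance_label(p, thresholds),
                 summary = summ, values = values, group_labels = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis comparison of %s across %d groups\n",
              x$metric, length(x$groups)))
  cat(sprintf("  H = %.4f, df = %d, p = %.4g  [%s]\n",
              x$H_statistic, x$df, x$p_value, x$significance))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Compare measurement groups with optional pairwise follow-up
#'
#' Overall Kruskal-Wallis test across all groups; for more than two groups,
#' all pairwise two-group Kruskal-Wallis tests (rank-equivalent to
#' Mann-Whitney) with Bonferroni correction are appended. The pairwise
#' procedure is a pragmatic follow-up choice, not part of the core score.
#'
#' @param df Long-format data frame with columns `group` and `value` (or
#'   names given by `group_col` / `value_col`).
#' @param metric Metric name for reporting.
#' @param group_col,value_col Column names.
#' @inheritParams kruskal_compare
#' @return A `group_comparison`, with a `pairwise` data frame when > 2
#'   groups.
#' @export
compare_groups <- function(df, metric = "d_h", group_col = "group",
                           value_col = "value", min_n = 5L,
                           thresholds = significance_thresholds()) {
  values <- df[[value_col]]; groups <- df[[group_col]]
  res <- kruskal_compare(values, groups, metric, min_n, thresholds)
  if (length(res$groups) > 2L) {
    prs <- utils::combn(res$groups, 2, simplify = FALSE)
    m <- length(prs)
    res$pairwise <- do.call(rbind, lapply(prs, function(pr) {
      sel <- res$group_labels %in% pr
      kt <- kruskal_compare(res$values[sel], res$group_labels[sel], metric,
                            min_n, thresholds)
      p_adj <- min(1, kt$p_value * m)
      data.frame(group1 = pr[1], group2 = pr[2], H = kt$H_statistic,
                 p_raw = kt$p_value, p_adj = p_adj,
                 significance = significance_label(p_adj, thresholds),
                 stringsAsFactors = FALSE)
    }))
  }
  res
}

#' Significance labels at fixed p-value thresholds
#'
#' Returns the label of the first threshold bounding `p` from above, with
#' the defaults `****` below 1e-4, `***` below 1e-3, `**` below 0.01, `*`
#' below 0.1, and `n.s.` otherwise.
#'
#' @param p P-value in \[0, 1\].
#' @param thresholds Named numeric vector of strictly increasing upper
#'   bounds; names are the labels.
#' @return Character label.
#' @export
significance_label <- function(p, thresholds = significance_thresholds()) {
  if (is.na(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("configuration error: thresholds must be strictly increasing")
  }
  hit <- which(p < thresholds)
  if (length(hit)) names(thresholds)[hit[1]] else "n.s."
}

#' @rdname significance_label
#' @export
significance_thresholds <- function() {
  c("****" = 1e-4, "***" = 1e-3, "**" = 1e-2, "*" = 0.1)
}

#' Swarm-style plot of per-cell measurements by group
#'
#' Jittered per-cell points with a light grey circle at the group mean and
#' a vertical bar spanning mean +/- one standard deviation.
#'
#' @param x A `group_comparison`.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.group_comparison <- function(x, ...) {
  g <- as.integer(x$group_labels)
  set.seed(1L)  # deterministic jitter
  graphics::plot(g + stats::runif(length(g), -0.18, 0.18), x$values,
                 xaxt = "n", xlab = "", ylab = x$metric, pch = 16,
                 col = grDevices::adjustcolor("black", 0.4),
                 xlim = c(0.5, length(x$groups) + 0.5), ...)
  graphics::axis(1, at = seq_along(x$groups), labels = x$groups)
  for (i in seq_along(x$groups)) {
    s <- x$summary[i, ]
    graphics::segments(i, s$mean - s$sd, i, s$mean + s$sd, lwd = 3)
    graphics::points(i, s$mean, pch = 21, bg = "grey80", cex = 2)
  }
  graphics::mtext(sprintf("H = %.2f, p = %.3g %s", x$H_statistic,
                          x$p_value, x$significance), side = 3, line = 0.5)
  invisible(x)
}
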