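#' Fisher-z confidence interval for a correlation
#'
#' `tanh(arctanh(r) +/- z / sqrt(n - 3))` with `z` the standard normal
#' quantile for the requested level (1.96 at 95%).
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Sample size (>= 4).
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)`.
#' @export
#' @examples
#' fisher_ci(0.944, 27)  # approx (0.88, 0.97)
fisher_ci <- function(r, n, level = 0.95) {
  if (abs(r) >= 1) stop("|r| must be below 1 (the z-transform is degenerate)")
  if (n < 4) stop("n must be at least 4")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z / sqrt(n - 3)
  c(lo = tanh(atanh(r) - half), hi = tanh(atanh(r) + half))
}

#' Wilcoxon signed-rank effect size
#'
#' `Z / sqrt(N)` with `Z` the (normal-approximation) signed-rank test
#' statistic and `N` the total number of observations.
#'
#' @param z Signed-rank Z statistic.
#' @param n Total number of observations (>= 1).
#' @return The effect size.
#' @export
wilcoxon_effect_size <- function(z, n) {
  if (n < 1) stop("N must be at least 1")
  z / sqrt(n)
}

# signed-rank Z statistic (normal approximation with tie correction,
# no continuity correction) for paired samples
signed_rank_z <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(0)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(0)
  (v - mu) / sqrt(sigma2)
}

#' Compare sensor configurations across participants
#'
#' Friedman omnibus test over the configurations-by-participants accuracy
#' table, Wilcoxon signed-rank post-hoc tests for every configuration pair
#' with Benjamini-Hochberg false-discovery-rate correction, and signed-rank
#' effect sizes `Z / sqrt(N)` (N = total observations entering each pairwise
#' comparison, i.e. twice the participant count).
#'
#' @param accuracies Either a configurations x participants numeric matrix
#'   (rownames = configuration names) or a long data frame with columns
#'   `configuration`, `participant`, `accuracy`.
#' @param alpha Significance level applied to the adjusted p-values
#'   (default 0.05).
#' @return A `config_comparison`: list with `omnibus` (tibble: statistic, df,
#'   p_value) and `pairwise` (tibble: the two configurations, Z, raw and
#'   FDR-adjusted p-values, effect size, significance flag).
#' @export
compare_configurations <- function(accuracies, alpha = 0.05) {
  if (is.data.frame(accuracies)) {
    stopifnot(all(c("configuration", "participant", "accuracy") %in%
                    names(accuracies)))
    wide <- tidyr::pivot_wider(accuracies, names_from = "participant",
                               values_from = "accuracy")
    mat <- as.matrix(wide[, -1])
    rownames(mat) <- wide$configuration
  } else {
    mat <- as.matrix(accuracies)
  }
  if (anyNA(mat)) stop("the accuracy table must have no missing cells")
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least two configurations and two participants")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("config", seq_len(nrow(mat)))

  fr <- stats::friedman.test(t(mat))  # blocks = participants
  stat <- unname(fr$statistic)
  pval <- fr$p.value
  if (!is.finite(stat)) { stat <- 0; pval <- 1 }  # fully tied ranks
  omnibus <- tibble::tibble(statistic = stat, df = unname(fr$parameter),
                            p_value = pval)

  combos <- utils::combn(rownames(mat), 2, simplify = FALSE)
  pw <- lapply(combos, function(pr) {
    x <- mat[pr[1], ]; y <- mat[pr[2], ]
    p <- if (all(x == y)) 1 else
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                         correct = FALSE)$p.value
    z <- signed_rank_z(x, y)
    tibble::tibble(config1 = pr[1], config2 = pr[2], z = z, p_value = p,
                   effect_size = wilcoxon_effect_size(z, 2 * length(x)))
  })
  pairwise <- dplyr::bind_rows(pw)
  pairwise$p_adjusted <- stats::p.adjust(pairwise$p_value, method = "BH")
  pairwise$significant <- pairwise$p_adjusted < alpha
  structure(list(omnibus = omnibus, pairwise = pairwise, alpha = alpha),
            class = "config_comparison")
}

#' @export
print.config_comparison <- function(x, ...) {
  cat(sprintf("Friedman test: chi-squared = %.3f, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  print(x$pairwise)
  invisible(x)
}
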