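#' @title Nonparametric test reports
#' @description Light-weight container for the results of the statistical
#'   battery: test name, statistic, p-value, group labels and any extras
#'   (pairwise tables, reconstruction errors, sample sizes).
#' @param test_name,statistic,p_value,group_labels,extras Report fields.
#' @return An object of class `stat_report`.
#' @keywords internal
stat_report <- function(test_name, statistic, p_value, group_labels = character(),
                        extras = list()) {
  stopifnot(is.numeric(p_value), p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 group_labels = group_labels, extras = extras),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic = %.6g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (length(x$group_labels)) cat("  groups:", paste(x$group_labels, collapse = ", "), "\n")
  invisible(x)
}

# tie term sum(t^3 - t) over tied groups of the pooled sample
.tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for a location difference between two independent samples.
#' When the smaller sample has more than 8 observations the normal
#' approximation is used, with tie correction of the variance and a 0.5
#' continuity correction; otherwise the exact permutation distribution of U
#' is enumerated (ties handled exactly via mid-ranks). The pixel-scale
#' samples of a DEM comparison always take the approximate path.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return A `stat_report` with `statistic` = U of `x`, extras `U_x`, `U_y`,
#'   `z` (approximate path only), `n_x`, `n_y`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  nx <- as.numeric(length(x)); ny <- as.numeric(length(y)); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  mu <- nx * ny / 2
  if (min(nx, ny) > 8L) {
    tie <- .tie_term(pooled)
    sig2 <- nx * ny / 12 * ((n + 1) - tie / (n * (n - 1)))
    dev <- abs(ux - mu)
    z <- if (sig2 > 0) max(0, dev - 0.5) / sqrt(sig2) else 0
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal approximation"
  } else {
    # exact permutation distribution of U under relabeling
    combs <- utils::combn(n, nx)
    rs <- colSums(matrix(r[combs], nrow = nx))
    u_all <- rs - nx * (nx + 1) / 2
    dev <- abs(ux - mu)
    p <- mean(abs(u_all - mu) >= dev - 1e-9)
    z <- NA_real_
    method <- "exact permutation"
  }
  stat_report("mann_whitney_u", ux, p, c("x", "y"),
              extras = list(U_x = ux, U_y = uy, z = z, n_x = nx, n_y = ny,
                            method = method))
}

#' Kruskal-Wallis H test
#'
#' Rank-based one-way comparison of k independent groups; H is corrected
#' for ties and referred to the chi-square distribution with k - 1 degrees
#' of freedom.
#'
#' @param groups List of >= 2 non-empty numeric samples.
#' @param labels Optional group labels.
#' @return A `stat_report` with `statistic` = H and extras `df`, `n`,
#'   `mean_ranks`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic  # 7.2
kruskal_wallis <- function(groups, labels = NULL) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  k <- length(groups)
  if (is.null(labels)) labels <- if (!is.null(names(groups)) && all(nzchar(names(groups))))
    names(groups) else paste0("g", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(pooled))) stop("samples must be finite")
  n <- length(pooled)
  g <- rep(seq_len(k), vapply(groups, length, integer(1)))
  r <- rank(pooled)
  ni <- tabulate(g, k)
  rbar <- tapply(r, g, mean)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  tie <- .tie_term(pooled)
  corr <- 1 - tie / (n^3 - n)
  if (corr > 0) h <- h / corr
  p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  stat_report("kruskal_wallis", h, p, labels,
              extras = list(df = k - 1, n = n, mean_ranks = as.numeric(rbar)))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' Follow-up to a significant Kruskal-Wallis test: for every pair (i, j) the
#' statistic is `z = (Rbar_i - Rbar_j) / SE` with the pooled-rank standard
#' error `SE = sqrt((N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j))` where `T`
#' is the tie term. Two-sided p-values are multiplied by the number of pairs
#' `k(k-1)/2` and capped at 1.
#'
#' @param groups List of >= 2 non-empty numeric samples.
#' @param labels Optional group labels.
#' @return A `stat_report`; `statistic` is the largest |z|, `p_value` the
#'   smallest adjusted p, and `extras$pairs` a data.frame with columns
#'   `group1`, `group2`, `z`, `p_unadjusted`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, labels = NULL) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  k <- length(groups)
  if (is.null(labels)) labels <- if (!is.null(names(groups)) && all(nzchar(names(groups))))
    names(groups) else paste0("g", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  g <- rep(seq_len(k), vapply(groups, length, integer(1)))
  r <- rank(pooled)
  ni <- tabulate(g, k)
  rbar <- tapply(r, g, mean)
  tie <- .tie_term(pooled)
  var_base <- n * (n + 1) / 12 - tie / (12 * (n - 1))
  m <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2)
  tab <- data.frame(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
                    z = NA_real_, p_unadjusted = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (p_idx in seq_len(ncol(pairs))) {
    i <- pairs[1, p_idx]; j <- pairs[2, p_idx]
    se <- sqrt(var_base * (1 / ni[i] + 1 / ni[j]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p_un <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    tab$z[p_idx] <- z
    tab$p_unadjusted[p_idx] <- p_un
    tab$p_adjusted[p_idx] <- min(1, p_un * m)
  }
  stat_report("dunn_posthoc", max(abs(tab$z)), min(tab$p_adjusted), labels,
              extras = list(pairs = tab, n = n, mean_ranks = as.numeric(rbar)))
}

#' Ordinary least-squares regression of complexity on (log) cover
#'
#' Simple linear regression `y ~ x` (or `y ~ log(x)` when `log_x = TRUE`,
#' the normalization applied to coral-cover areas; non-positive x values are
#' dropped with a warning). Reports the slope, intercept, coefficient of
#' determination and the two-sided slope t-test p-value.
#'
#' @param x,y Equal-length numeric samples, n >= 3 after any log filtering.
#' @param log_x Take the natural log of `x` first. `r_squared` does not
#'   depend on the log base.
#' @return Object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
#' @examples
#' linear_regression(1:4, c(2, 1, 4, 3))  # slope 0.6, R^2 0.36
linear_regression <- function(x, y, log_x = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (log_x) {
    drop <- !(x > 0)
    if (any(drop)) {
      warning(sum(drop), " non-positive x value(s) dropped before log transform")
      x <- x[!drop]; y <- y[!drop]
    }
    x <- log(x)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in x")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
  rss <- syy - slope * sxy
  se <- sqrt(max(0, rss) / (n - 2) / sxx)
  p <- if (se > 0) 2 * stats::pt(abs(slope) / se, df = n - 2, lower.tail = FALSE)
       else if (slope == 0) 1 else 0
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope = %.6g, intercept = %.6g, R^2 = %.4f, p = %.4g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}
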