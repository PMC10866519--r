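#' Two-dimensional Kolmogorov-Smirnov (Fasano-Franceschini) test
#'
#' Compares two 2D point clouds. Around every data point of each sample the
#' plane is split into four open quadrants (points exactly on a dividing
#' line, including the origin point itself, are excluded) and the statistic
#' is the maximum over origins and quadrants of the absolute difference of
#' the two samples' quadrant fractions, averaged over the two sample-origin
#' passes. Identical samples give `D = 0`; samples confined to opposite
#' quadrants of some point give `D = 1`.
#'
#' The p-value is computed either from the asymptotic 1D KS tail with
#' effective size `n = n1*n2/(n1+n2)` and the samples' coordinate
#' correlation correction (`sqrt(1 - 0.5*(r1^2 + r2^2))`, Press-style), or
#' by permutation of the pooled labels. The asymptotic form is approximate
#' at small n; permutation is the authoritative fallback.
#'
#' @param a,b two-column matrices (or data frames) of points.
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perms number of label permutations.
#' @param seed integer seed for the permutation draw.
#' @return an object of class `"ks2d"`: list with `D`, `p`, `n1`, `n2`,
#'   `method`.
#' @export
ks2d <- function(a, b, method = c("asymptotic", "permutation"),
                 n_perms = 1000, seed = 1) {
  method <- match.arg(method)
  a <- as_point_matrix(a)
  b <- as_point_matrix(b)
  if (nrow(a) < 1 || nrow(b) < 1) stop("both samples need at least one point")
  if (nrow(a) < 10 || nrow(b) < 10)
    warning("fewer than 10 points in a sample: D is very coarse")
  D <- ks2d_stat_(a, b)
  if (method == "asymptotic") {
    n1 <- nrow(a); n2 <- nrow(b)
    neff <- n1 * n2 / (n1 + n2)
    r1 <- if (n1 > 2) abs(stats::cor(a[, 1], a[, 2])) else 0
    r2 <- if (n2 > 2) abs(stats::cor(b[, 1], b[, 2])) else 0
    if (!is.finite(r1)) r1 <- 0
    if (!is.finite(r2)) r2 <- 0
    rr <- sqrt(1 - 0.5 * (r1^2 + r2^2))
    lambda <- sqrt(neff) * D / (1 + rr * (0.25 - 0.75 / sqrt(neff)))
    p <- ks_tail(lambda)
  } else {
    perm <- ks2d_perm_(a, b, as.integer(n_perms), as.double(seed))
    p <- (1 + sum(perm >= D - 1e-12)) / (n_perms + 1)
  }
  structure(list(D = D, p = p, n1 = nrow(a), n2 = nrow(b), method = method),
            class = "ks2d")
}

#' @export
print.ks2d <- function(x, ...) {
  cat(sprintf("2D KS (Fasano-Franceschini): D = %.4f, p = %.3g  (n1 = %d, n2 = %d, %s)\n",
              x$D, x$p, x$n1, x$n2, x$method))
  invisible(x)
}

# Q_KS tail of the Kolmogorov distribution
ks_tail <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

as_point_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("points must be two-dimensional")
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  x
}

#' Brown-Forsythe test for equality of variances
#'
#' Each observation is transformed to its absolute deviation from the group
#' median and a one-way ANOVA F-test is applied to the transformed values.
#' Robust to non-normality; used to compare shape-coefficient variability
#' between simulation conditions.
#'
#' @param group_a,group_b numeric vectors (at least 3 values each).
#' @return list with `statistic` (F), `p`, `df`.
#' @export
brown_forsythe <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 values")
  z <- c(abs(group_a - stats::median(group_a)),
         abs(group_b - stats::median(group_b)))
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  if (stats::var(z) < .Machine$double.eps)
    return(list(statistic = 0, p = 1, df = c(1, length(z) - 2)))
  fit <- stats::anova(stats::lm(z ~ g))
  list(statistic = fit$`F value`[1], p = fit$`Pr(>F)`[1],
       df = c(fit$Df[1], fit$Df[2]))
}
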