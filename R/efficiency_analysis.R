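#' Efficiency plot: log L2 versus log 1/KdC
#'
#' For agonists sharing an efficiency class,
#' `log10 L2 = log10 L0 + m * log10(1/KdC)` with slope
#' `m = 2*eta/(1 - eta)`; the class efficiency is `eta = m/(m + 2)`
#' ([eta_from_slope()]).  When the unliganded gating constant is known a
#' priori the intercept is fixed at `log10 L0`, which anchors every class
#' line at the same point and sharpens the slope estimate; otherwise the
#' intercept is fitted and returns an estimate of `log10 L0`.
#'
#' @param L2 di-liganded gating constants (corrected to the wild-type
#'   scale), one per agonist.
#' @param KdC resting dissociation constants in molar.
#' @param log10_L0 fixed intercept (`log10` of L0), or `NULL` to fit it.
#' @return list with `m` (slope), `intercept`, `eta`, `r` and `p`
#'   (Pearson correlation of the plotted points, two-tailed), and `n`.
#' @examples
#' pop <- generate_population(n_per_class = 6, class_means = 0.51,
#'                            class_sds = 0, seed = 1)
#' fit_efficiency_plot(pop$L2, pop$KdC, log10_L0 = log10(5.2e-7))$eta
#' @export
fit_efficiency_plot <- function(L2, KdC, log10_L0 = NULL) {
  check_positive(L2, "L2")
  check_positive(KdC, "KdC")
  if (length(L2) != length(KdC)) stop("'L2' and 'KdC' lengths differ")
  if (length(L2) < 2) stop("at least 2 points are required")
  x <- log10(1 / KdC)
  y <- log10(L2)
  if (diff(range(x)) < 1e-12)
    stop("degenerate data: all KdC values identical")
  if (is.null(log10_L0)) {
    fit <- lm(y ~ x)
    m <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  } else {
    # least squares through the fixed point (0, log10_L0)
    yc <- y - log10_L0
    m <- sum(x * yc) / sum(x^2)
    b <- log10_L0
  }
  if (m <= 0)
    stop("non-positive efficiency-plot slope (", signif(m, 4),
         "): no efficiency class defined")
  ct <- if (length(x) >= 3 && stats::sd(y) > 0)
    cor.test(x, y) else list(estimate = NA_real_, p.value = NA_real_)
  list(m = m, intercept = b, eta = eta_from_slope(m),
       r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Binding energy correlation: dG_LA versus dG_HA
#'
#' Within an efficiency class the resting and open binding energies are
#' proportional: `dG_LA = (1 - eta) * dG_HA`.  A straight-line fit of
#' `dG_LA` on `dG_HA` therefore estimates the class efficiency as
#' `eta = 1 - slope`.  Unlike the efficiency plot this does not require a
#' shared L0, so it is the appropriate view for binding-site mutants.
#'
#' @param dG_LA,dG_HA binding free energies (kcal/mol), one pair per
#'   member.
#' @return list with `slope`, `intercept`, `eta = 1 - slope`, `r`, `p`,
#'   `n`.
#' @export
fit_energy_correlation <- function(dG_LA, dG_HA) {
  if (length(dG_LA) != length(dG_HA)) stop("input lengths differ")
  if (length(dG_LA) < 2) stop("at least 2 pairs are required")
  if (diff(range(dG_HA)) < 1e-12)
    stop("degenerate data: all dG_HA values identical")
  fit <- lm(dG_LA ~ dG_HA)
  slope <- unname(coef(fit)[2])
  ct <- if (length(dG_LA) >= 3 && stats::sd(dG_LA) > 0)
    cor.test(dG_HA, dG_LA) else list(estimate = NA_real_, p.value = NA_real_)
  list(slope = slope, intercept = unname(coef(fit)[1]), eta = 1 - slope,
       r = unname(ct$estimate), p = ct$p.value, n = length(dG_LA))
}

# AICc of a k-cluster partition under the classification likelihood of a
# one-dimensional Gaussian mixture with shared variance (profiled as
# SSR/n) and multinomial mixing proportions.  The proportion term is what
# stops a genuine Gaussian class from being subdivided: an SSR-only
# criterion is scale-invariant and overfits at any separation.
# Parameters: k centres + (k - 1) proportions + 1 variance = 2k.  When the
# small-sample correction is undefined (n - p - 1 <= 0) the plain AIC is
# used.
.xmeans_aicc <- function(n, k, ssr, sizes) {
  sigma2 <- max(ssr / n, 1e-20)
  logL <- sum(sizes * log(sizes / n)) -
    n / 2 * log(2 * pi * sigma2) - n / 2
  p <- 2 * k
  aic <- -2 * logL + 2 * p
  if (n - p - 1 <= 0) aic else aic + 2 * p * (p + 1) / (n - p - 1)
}

# exact 1-D k-means by dynamic programming over contiguous partitions of
# the sorted values, honouring a minimum cluster size; returns the global
# SSR optimum (in one dimension the optimal partition is contiguous)
.kmeans_1d_exact <- function(x_sorted, k, min_size) {
  n <- length(x_sorted)
  cs <- cumsum(x_sorted)
  cs2 <- cumsum(x_sorted^2)
  seg_cost <- function(j, i) {        # SSR of points j..i
    s <- cs[i] - if (j > 1) cs[j - 1] else 0
    s2 <- cs2[i] - if (j > 1) cs2[j - 1] else 0
    max(s2 - s^2 / (i - j + 1), 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (i in seq_len(n)) if (i >= min_size) D[1, i] <- seg_cost(1, i)
  if (k > 1) for (kk in 2:k) {
    for (i in seq_len(n)) {
      if (i < kk * min_size) next
      js <- ((kk - 1) * min_size):(i - min_size)   # last cluster = js+1..i
      for (j in js) {
        v <- D[kk - 1, j] + seg_cost(j + 1, i)
        if (v < D[kk, i]) { D[kk, i] <- v; B[kk, i] <- j }
      }
    }
  }
  if (!is.finite(D[k, n])) return(NULL)
  bounds <- integer(k + 1); bounds[k + 1] <- n
  if (k > 1) for (kk in k:2) bounds[kk] <- B[kk, bounds[kk + 1]]
  cl <- rep(seq_len(k), times = diff(bounds))
  list(cluster = cl, ssr = D[k, n])
}

#' Classify efficiency values by x-means
#'
#' Partitions the 1-D efficiency values into k = 1 .. `k_max` classes by
#' exact (dynamic-programming) k-means on the sorted values and selects k
#' by the corrected Akaike information criterion (AICc) of the spherical
#' Gaussian classification likelihood (shared variance estimated from the
#' within-class sum of squared residuals SSR, plus multinomial mixing
#' proportions; 2k parameters).  Partitions with any class smaller than
#' `min_size` are excluded; ties are broken by lower SSR, then by smaller
#' k.  Classes are reported in ascending order of their means.  The
#' solver is exact, so the result is deterministic and invariant to the
#' input order; `seed` is accepted for interface stability but does not
#' influence the result.
#'
#' @param values numeric efficiency values (>= 4).
#' @param k_max maximum number of classes considered.
#' @param min_size minimum class size (default 2).
#' @param seed unused (kept so callers can pass one uniformly).
#' @return an object of class `eta_classes`: list with `k`, `assignments`
#'   (class index per input value, in input order), `means`, `sds`,
#'   `sizes`, `SSR`, `AICc` and `table` (per-k SSR/AICc audit trail).
#' @examples
#' xmeans_classify(c(0.30, 0.31, 0.55, 0.56))$k  # 2
#' @export
xmeans_classify <- function(values, k_max = 8, min_size = 2, seed = 1) {
  if (length(values) < 4) stop("at least 4 values are required")
  if (any(!is.finite(values))) stop("values must be finite")
  if (k_max < 1) stop("'k_max' must be >= 1")
  n <- length(values)
  distinct <- length(unique(values))
  ord <- order(values)
  xs <- values[ord]

  best <- NULL
  audit <- data.frame(k = integer(0), SSR = numeric(0), AICc = numeric(0),
                      feasible = logical(0))
  for (k in seq_len(k_max)) {
    if (k > distinct || n < k * min_size) break
    sol_sorted <- .kmeans_1d_exact(xs, k, min_size)
    sol <- NULL
    if (!is.null(sol_sorted)) {
      cl <- integer(n); cl[ord] <- sol_sorted$cluster
      sol <- list(cluster = cl, ssr = sol_sorted$ssr)
    }
    feasible <- !is.null(sol)
    aicc <- if (feasible)
      .xmeans_aicc(n, k, sol$ssr, tabulate(sol$cluster, k)) else Inf
    audit <- rbind(audit, data.frame(k = k,
                                     SSR = if (feasible) sol$ssr else NA,
                                     AICc = aicc, feasible = feasible))
    if (!feasible || !is.finite(aicc)) next
    if (is.null(best) || aicc < best$AICc - 1e-12 ||
        (abs(aicc - best$AICc) <= 1e-12 && sol$ssr < best$SSR - 1e-15)) {
      best <- list(k = k, cluster = sol$cluster, SSR = sol$ssr, AICc = aicc)
    }
  }
  if (is.null(best)) stop("no feasible clustering found")

  # order classes by ascending mean
  mu <- tapply(values, best$cluster, mean)
  ord <- order(mu)
  remap <- match(best$cluster, as.integer(names(mu))[ord])
  means <- as.numeric(mu[ord])
  sds <- as.numeric(tapply(values, best$cluster, stats::sd)[ord])
  sizes <- as.integer(tapply(values, best$cluster, length)[ord])
  structure(list(k = best$k, assignments = remap, means = means, sds = sds,
                 sizes = sizes, SSR = best$SSR, AICc = best$AICc,
                 table = audit),
            class = "eta_classes")
}

#' @export
print.eta_classes <- function(x, ...) {
  cat(sprintf("x-means: %d class(es), SSR = %.4g, AICc = %.4g\n",
              x$k, x$SSR, x$AICc))
  for (i in seq_len(x$k))
    cat(sprintf("  class %d: mean %.3f, sd %.4f, n = %d\n",
                i, x$means[i], if (is.na(x$sds[i])) 0 else x$sds[i],
                x$sizes[i]))
  invisible(x)
}

#' Pearson product-moment correlation with two-tailed p-value
#'
#' Thin wrapper around [stats::cor.test()] with the domain checks used in
#' this package.
#'
#' @param x,y numeric vectors (>= 3 pairs, nonzero variance).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("input lengths differ")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Test for different regression slopes across groups (ANCOVA)
#'
#' Compares the common-slope model `y ~ x + group` against the
#' separate-slopes model `y ~ x * group` with a nested-model F test on the
#' interaction term, the standard ANCOVA homogeneity-of-slopes test.
#'
#' @param x,y numeric vectors.
#' @param group group labels (>= 2 groups with >= 3 points each).
#' @return list with `F`, `p`, `df` (numerator, denominator degrees of
#'   freedom).
#' @export
compare_slopes_ancova <- function(x, y, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("at least 2 groups are required")
  cnt <- table(group)
  if (any(cnt < 3)) stop("every group needs at least 3 points")
  d <- data.frame(x = x, y = y, group = group)
  m0 <- lm(y ~ x + group, data = d)
  m1 <- lm(y ~ x * group, data = d)
  if (any(!is.finite(coef(m1))))
    stop("singular design in slope comparison")
  a <- anova(m0, m1)
  list(F = a$F[2], p = a$`Pr(>F)`[2],
       df = c(a$Df[2], a$Res.Df[2]))
}
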