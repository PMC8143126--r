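#' Arcsine (angular) transform of a proportion
#'
#' The variance-stabilizing form `asin(sqrt(p))`, in radians.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @export
arcsine_transform <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard routine, with explicit rejection of
#' degenerate input (n < 3 or constant values).
#'
#' @param values Numeric vector, n >= 3, non-constant.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  if (length(values) < 3L) stopf("Shapiro-Wilk needs at least 3 values, got %d", length(values))
  if (stats::sd(values) == 0) stopf("Shapiro-Wilk is undefined for constant input")
  t <- stats::shapiro.test(values)
  list(W = unname(t$statistic), p_value = t$p.value)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Mid-ranks with tie correction; p-value from the chi-square approximation
#' with `g - 1` degrees of freedom.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need at least 2 groups, got %s", length(groups))
  if (any(vapply(groups, length, integer(1)) == 0L)) stopf("groups must be non-empty")
  n_tot <- sum(vapply(groups, length, integer(1)))
  if (n_tot < 3L) stopf("need at least 3 observations in total")
  t <- stats::kruskal.test(groups)
  list(H = unname(t$statistic), df = unname(t$parameter), p_value = t$p.value)
}

#' Cohen's d standardized mean difference
#'
#' `(mean_a - mean_b) / s_pooled` with the pooled SD
#' `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2.
#' @return The effect size d (positive when group_a has the larger mean).
#' @export
cohens_d <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stopf("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stopf("pooled SD is zero; d is undefined")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Compare per-color albedo replicates
#'
#' Runs the albedo comparison procedure: arcsine transform, Shapiro-Wilk on
#' pooled within-group residuals, Kruskal-Wallis across colors, then ordered
#' one-sided pairwise contrasts (higher-mean color > lower-mean color) with
#' exact Wilcoxon rank-sum p-values and Cohen's d. Significance letters are
#' the connected components of the graph joining colors whose one-sided
#' contrast is not significant at `alpha` (p > alpha).
#'
#' @param estimates data.frame with columns `color` and `albedo_abs`, at
#'   least two colors with at least two replicates each.
#' @param alpha Significance level for the letters (default 0.05; a contrast
#'   with p <= alpha separates its pair).
#' @param d_scale Scale on which Cohen's d is computed: `"raw"` albedo
#'   values (default) or the `"transformed"` (arcsine) scale.
#' @return Object of class `albedo_comparison`: list with `summary`
#'   (per-color n/mean/se), `shapiro`, `kruskal`, `contrasts` (data.frame of
#'   ordered pairs with one-sided p and d), and `letters` (named character
#'   vector).
#' @export
compare_albedo_groups <- function(estimates, alpha = 0.05,
                                  d_scale = c("raw", "transformed")) {
  d_scale <- match.arg(d_scale)
  stopifnot(is.data.frame(estimates),
            all(c("color", "albedo_abs") %in% names(estimates)),
            alpha > 0, alpha < 1)
  sp <- split(estimates$albedo_abs, estimates$color)
  if (length(sp) < 2L) stopf("need at least 2 colors")
  if (any(vapply(sp, length, integer(1)) < 2L))
    stopf("every color needs at least 2 replicates")
  if (any(unlist(sp) < 0) || any(unlist(sp) > 1))
    stopf("albedo values must lie in [0, 1] for the arcsine transform")

  trans <- lapply(sp, arcsine_transform)
  resid <- unlist(lapply(trans, function(v) v - mean(v)), use.names = FALSE)
  shap <- if (stats::sd(resid) > 0) shapiro_wilk(resid) else
    list(W = NA_real_, p_value = NA_real_)
  kw <- kruskal_wallis(trans)

  # order colors by decreasing mean so each contrast tests "brighter > darker"
  means <- vapply(sp, mean, numeric(1))
  ord <- names(sort(means, decreasing = TRUE))
  pairs <- utils::combn(ord, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    hi <- pairs[1, i]; lo <- pairs[2, i]
    a <- if (d_scale == "raw") sp[[hi]] else trans[[hi]]
    b <- if (d_scale == "raw") sp[[lo]] else trans[[lo]]
    wt <- suppressWarnings(
      stats::wilcox.test(sp[[hi]], sp[[lo]], alternative = "greater"))
    data.frame(hypothesis = sprintf("%s > %s", hi, lo),
               higher = hi, lower = lo,
               p_one_sided = wt$p.value,
               cohens_d = cohens_d(a, b),
               stringsAsFactors = FALSE)
  }))

  # letters: connected components of the "not separated" graph
  comp <- stats::setNames(seq_along(ord), ord)
  for (i in seq_len(nrow(contrasts))) {
    if (contrasts$p_one_sided[i] > alpha) {
      a <- comp[contrasts$higher[i]]; b <- comp[contrasts$lower[i]]
      comp[comp == max(a, b)] <- min(a, b)
    }
  }
  letters_out <- stats::setNames(letters[match(comp, sort(unique(comp)))], ord)

  structure(list(summary = summarize_replicates(estimates),
                 shapiro = shap, kruskal = kw,
                 contrasts = contrasts, letters = letters_out,
                 alpha = alpha, d_scale = d_scale),
            class = "albedo_comparison")
}

#' @export
print.albedo_comparison <- function(x, ...) {
  cat("Albedo comparison across hide colors\n")
  print(x$summary)
  cat(sprintf("Shapiro-Wilk on pooled residuals: W = %.4f, p = %.4g\n",
              x$shapiro$W, x$shapiro$p_value))
  cat(sprintf("Kruskal-Wallis: H = %.4f (df = %d), p = %.4g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p_value))
  print(x$contrasts[, c("hypothesis", "p_one_sided", "cohens_d")])
  cat("Letters:", paste(sprintf("%s = %s", names(x$letters), x$letters),
                        collapse = ", "), "\n")
  invisible(x)
}
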