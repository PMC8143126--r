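#' Per-hide-color regressions of the temperature difference on ambient
#' temperature
#'
#' Fits one least-squares line per color and reports slope, intercept,
#' r-squared, the two-sided slope p-value and the residual SD.
#'
#' @param data data.frame with columns `color`, and the predictor/response
#'   named by `x`/`y`.
#' @param x Predictor column (default `"temp_amb"`).
#' @param y Response column (default `"delta_t"`).
#' @return Object of class `slope_fits`: list with `table` (one row per
#'   color) and `fits` (named list of `lm` objects).
#' @export
fit_color_regressions <- function(data, x = "temp_amb", y = "delta_t") {
  stopifnot(is.data.frame(data), all(c("color", x, y) %in% names(data)))
  sp <- split(data, data$color)
  small <- names(sp)[vapply(sp, nrow, integer(1)) < 3L]
  if (length(small) > 0)
    stopf("fewer than 3 observations for color(s): %s",
          paste(small, collapse = ", "))
  f <- stats::reformulate(x, y)
  fits <- lapply(sp, function(d) stats::lm(f, data = d))
  tab <- do.call(rbind, lapply(names(fits), function(col) {
    fit <- fits[[col]]
    s <- summary(fit)
    data.frame(color = col, n = stats::nobs(fit),
               slope = unname(stats::coef(fit)[x]),
               intercept = unname(stats::coef(fit)["(Intercept)"]),
               slope_se = s$coefficients[x, "Std. Error"],
               r_squared = s$r.squared,
               p_value = s$coefficients[x, "Pr(>|t|)"],
               resid_sd = s$sigma, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, x = x, y = y),
            class = "slope_fits")
}

#' @export
print.slope_fits <- function(x, ...) {
  cat(sprintf("Per-color regressions: %s ~ %s\n", x$y, x$x))
  print(x$table, digits = 4)
  invisible(x)
}

#' 95 percent prediction band for one color's regression line
#'
#' Standard out-of-sample OLS prediction interval; the band half-width is
#' smallest at the mean of the fitted predictor values.
#'
#' @param slope_fits A [fit_color_regressions()] result.
#' @param color Which color's fit to evaluate.
#' @param newx Predictor values at which to evaluate the band.
#' @param level Band level (default 0.95).
#' @return data.frame with the predictor, `fit`, `lwr`, `upr`.
#' @export
predict_band <- function(slope_fits, color, newx, level = 0.95) {
  stopifnot(inherits(slope_fits, "slope_fits"),
            color %in% names(slope_fits$fits), is.numeric(newx))
  nd <- stats::setNames(data.frame(newx), slope_fits$x)
  pr <- stats::predict(slope_fits$fits[[color]], newdata = nd,
                       interval = "prediction", level = level)
  cbind(nd, as.data.frame(pr))
}

#' ANCOVA comparison of per-color slopes
#'
#' Fits the interaction model `y ~ x * color`, tests the slope-heterogeneity
#' interaction block with an F-test, compares all pairwise slope differences
#' with Tukey-adjusted p-values, and adds a median-centered Levene test and
#' a Kruskal-Wallis test on the response by color (the fallback used when
#' variances are unequal).
#'
#' @inheritParams fit_color_regressions
#' @return Object of class `slope_comparison`: list with `fits`
#'   (per-color [fit_color_regressions()]), `interaction` (`F`, `df1`,
#'   `df2`, `p_value`), `pairwise` (data.frame of Tukey-adjusted slope
#'   contrasts), `levene`, `kruskal` and the interaction `lm` as `model`.
#' @export
ancova_slopes <- function(data, x = "temp_amb", y = "delta_t") {
  stopifnot(is.data.frame(data), all(c("color", x, y) %in% names(data)))
  data$color <- factor(data$color)
  if (nlevels(data$color) < 2L) stopf("need at least 2 colors")
  fits <- fit_color_regressions(data, x = x, y = y)

  full <- stats::lm(stats::reformulate(sprintf("%s * color", x), y), data = data)
  reduced <- stats::lm(stats::reformulate(sprintf("%s + color", x), y), data = data)
  an <- stats::anova(reduced, full)
  interaction <- list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                      p_value = an$`Pr(>F)`[2])

  emt <- emmeans::emtrends(full, stats::as.formula("~ color"), var = x,
                           data = data)
  pw <- summary(graphics::pairs(emt, adjust = "tukey"))
  pairwise <- data.frame(contrast = as.character(pw$contrast),
                         estimate = pw$estimate, se = pw$SE,
                         p_tukey = pw$p.value, stringsAsFactors = FALSE)

  lev <- car::leveneTest(stats::reformulate("color", y), data = data,
                         center = stats::median)
  levene <- list(F = lev[1, "F value"], p_value = lev[1, "Pr(>F)"])
  kw <- kruskal_wallis(split(data[[y]], data$color))

  structure(list(fits = fits, interaction = interaction, pairwise = pairwise,
                 levene = levene, kruskal = kw, model = full),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  print(x$fits)
  cat(sprintf("Slope heterogeneity: F(%d, %d) = %.3f, p = %.4g\n",
              x$interaction$df1, x$interaction$df2, x$interaction$F,
              x$interaction$p_value))
  print(x$pairwise, digits = 4)
  cat(sprintf("Levene (median-centered): F = %.3f, p = %.4g\n",
              x$levene$F, x$levene$p_value))
  cat(sprintf("Kruskal-Wallis on response by color: H = %.3f, p = %.4g\n",
              x$kruskal$H, x$kruskal$p_value))
  invisible(x)
}
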