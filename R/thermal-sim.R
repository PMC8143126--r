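# Synthetic thermal observation and daily covariate generator.
#
# Marginal ranges and means follow the field study's summary table; correlated
# covariates are drawn from a Gaussian copula and mapped onto scaled beta
# marginals so each variable respects its declared range and mean.

# variable -> (min, max, mean), units as documented in covariate_sources()
marginal_table <- function() {
  list(
    temp_amb   = c(-32.8, 35.6, 4.4),
    temp_dew   = c(-27.6, 7.1, -10.0),
    humidity   = c(9.0, 84.0, 56.7),
    vpd        = c(0.6, 32.5, 13.5),
    wind       = c(11.3, 53.1, 29.0),
    temp_earth = c(-24.6, 23.0, -0.1),
    ktclear    = c(0.3, 0.8, 0.6),
    rad_lw     = c(3.6, 8.7, 5.9),
    rad_sw     = c(1.3, 8.5, 3.9)
  )
}

#' Measurement source of each analysis variable
#'
#' Groups used when pruning correlated covariates: in-situ animal
#' measurements, ground weather products (station + interpolated), and
#' satellite radiation products.
#'
#' @return Named character vector mapping variable name to source group.
#' @export
covariate_sources <- function() {
  c(temp_amb = "field", temp_cow = "field", albedo = "field",
    temp_dew = "weather", humidity = "weather", vpd = "weather",
    wind = "weather",
    temp_earth = "satellite", ktclear = "satellite",
    rad_lw = "satellite", rad_sw = "satellite")
}

default_cor_pairs <- function() {
  data.frame(var1 = c("temp_earth", "temp_earth", "rad_lw", "humidity", "vpd"),
             var2 = c("rad_lw", "rad_sw", "rad_sw", "wind", "temp_dew"),
             rho  = c(0.85, 0.85, 0.60, 0.85, 0.85),
             stringsAsFactors = FALSE)
}

#' Parameters for the synthetic thermal observation generator
#'
#' Defaults reproduce the study conditions: n = 638 paired surface/ambient
#' temperature records split white/red/black 183/158/297, surface
#' temperature generated from the linear model
#' `temp_cow = b0 + 0.1770 temp_amb + 19.172 ktclear - 27.026 albedo + noise`
#' with 5 degC residual SD. The intercept `b0` is derived at construction
#' time from the identity `mean response = beta . mean covariates`, using the
#' declared covariate means and the color-weighted mean albedo, so that mean
#' surface temperature is 32.4 degC.
#'
#' @param n Number of observations.
#' @param color_props Named proportions for white/red/black hides.
#' @param color_albedo Absolute albedo assigned to each hide color.
#' @param coef Generating coefficients for the surface-temperature model
#'   (named: `temp_amb`, `ktclear`, `albedo`).
#' @param mean_temp_cow Target mean surface temperature used to derive the
#'   intercept.
#' @param noise_sd Residual SD in degC.
#' @param mode `"model"` draws temp_cow from the linear model above;
#'   `"slope"` instead draws the temperature difference directly from
#'   per-color lines `delta_t = slope_intercepts[c] + slopes[c] * temp_amb`.
#' @param slopes Per-color delta-T slopes for slope mode (defaults -0.45,
#'   -0.92, -1.07 for white/red/black).
#' @param slope_intercepts Per-color intercepts for slope mode, in degC.
#' @param cor_pairs data.frame (`var1`, `var2`, `rho`) of latent copula
#'   correlations among daily covariates.
#' @param beta_conc Concentration (a + b) of the scaled beta marginals.
#' @param seed Integer random seed.
#' @return Object of class `thermal_gen_params` (includes the derived
#'   `intercept`).
#' @export
thermal_gen_params <- function(n = 638L,
                               color_props = c(white = 183, red = 158, black = 297) / 638,
                               color_albedo = c(white = 0.69, red = 0.16, black = 0.04),
                               coef = c(temp_amb = 0.1770, ktclear = 19.172, albedo = -27.026),
                               mean_temp_cow = 32.4,
                               noise_sd = 5,
                               mode = c("model", "slope"),
                               slopes = c(white = -0.45, red = -0.92, black = -1.07),
                               slope_intercepts = c(white = 25, red = 30, black = 35),
                               cor_pairs = default_cor_pairs(),
                               beta_conc = 4,
                               seed = 1L) {
  mode <- match.arg(mode)
  colors <- names(color_props)
  stopifnot(length(colors) >= 1, !is.null(colors),
            identical(sort(colors), sort(names(color_albedo))),
            abs(sum(color_props) - 1) < 1e-8,
            all(c("temp_amb", "ktclear", "albedo") %in% names(coef)),
            noise_sd >= 0, beta_conc > 0)
  if (n < 2L * length(colors))
    stopf("n = %d is below 2 observations per hide color", n)
  if (mode == "slope")
    stopifnot(identical(sort(colors), sort(names(slopes))),
              identical(sort(colors), sort(names(slope_intercepts))))
  if (any(abs(cor_pairs$rho) >= 1))
    stopf("declared correlations must lie in (-1, 1)")
  marg <- marginal_table()
  # intercept from mean_response = beta . mean_covariates at declared means
  mean_albedo <- sum(color_props[colors] * color_albedo[colors])
  b0 <- mean_temp_cow -
    coef[["temp_amb"]] * marg$temp_amb[3] -
    coef[["ktclear"]] * marg$ktclear[3] -
    coef[["albedo"]] * mean_albedo
  structure(list(n = as.integer(n), color_props = color_props,
                 color_albedo = color_albedo, coef = coef,
                 intercept = unname(b0), mean_temp_cow = mean_temp_cow,
                 noise_sd = noise_sd, mode = mode, slopes = slopes,
                 slope_intercepts = slope_intercepts, cor_pairs = cor_pairs,
                 beta_conc = beta_conc, marginals = marg,
                 seed = as.integer(seed)),
            class = "thermal_gen_params")
}

# latent correlation matrix for the 8 daily covariates
build_sigma <- function(vars, cor_pairs) {
  S <- diag(length(vars)); dimnames(S) <- list(vars, vars)
  for (i in seq_len(nrow(cor_pairs))) {
    a <- cor_pairs$var1[i]; b <- cor_pairs$var2[i]
    if (a %in% vars && b %in% vars) S[a, b] <- S[b, a] <- cor_pairs$rho[i]
  }
  S
}

# scaled beta with declared range and mean: qbeta(pnorm(z), mu*conc, (1-mu)*conc)
scale_marginal <- function(u, rng, conc) {
  mu <- (rng[3] - rng[1]) / (rng[2] - rng[1])
  stopifnot(mu > 0, mu < 1)
  rng[1] + (rng[2] - rng[1]) * stats::qbeta(u, mu * conc, (1 - mu) * conc)
}

#' Generate synthetic thermal observations and daily covariates
#'
#' Draws hide colors, an ambient-temperature marginal, and a copula-coupled
#' set of daily weather/radiation covariates, then constructs the surface
#' temperature (model mode) or the temperature difference directly (slope
#' mode). Each observation carries its own date index; the covariate table
#' has one matching row per date.
#'
#' @param params A [thermal_gen_params()] object.
#' @return List with
#'   \describe{
#'     \item{observations}{data.frame: `date`, `color`, `albedo`,
#'       `temp_amb`, `temp_cow`, `delta_t` (all temperatures degC).}
#'     \item{covariates}{data.frame: `date` plus the 8 daily variables.}
#'     \item{truth}{the `params` object (every injected parameter).}
#'   }
#' @export
generate_thermal_observations <- function(params) {
  stopifnot(inherits(params, "thermal_gen_params"))
  set.seed(params$seed)
  n <- params$n
  marg <- params$marginals
  colors <- names(params$color_props)

  # color assignment by largest-remainder apportionment, then shuffled
  exact <- params$color_props * n
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  color <- sample(rep(colors, counts))
  albedo <- unname(params$color_albedo[color])

  temp_amb <- scale_marginal(stats::pnorm(stats::rnorm(n)), marg$temp_amb,
                             params$beta_conc)

  daily_vars <- c("temp_dew", "humidity", "vpd", "wind",
                  "temp_earth", "ktclear", "rad_lw", "rad_sw")
  S <- build_sigma(daily_vars, params$cor_pairs)
  R <- tryCatch(chol(S), error = function(e)
    stopf("declared correlation matrix is not positive definite"))
  Z <- matrix(stats::rnorm(n * length(daily_vars)), nrow = n) %*% R
  U <- stats::pnorm(Z)
  cov_tab <- data.frame(date = seq_len(n))
  for (j in seq_along(daily_vars)) {
    v <- daily_vars[j]
    cov_tab[[v]] <- scale_marginal(U[, j], marg[[v]], params$beta_conc)
  }

  noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else
    numeric(n)
  if (params$mode == "model") {
    temp_cow <- params$intercept +
      params$coef[["temp_amb"]] * temp_amb +
      params$coef[["ktclear"]] * cov_tab$ktclear +
      params$coef[["albedo"]] * albedo + noise
    delta_t <- compute_delta_t(temp_cow, temp_amb)
  } else {
    delta_t <- unname(params$slope_intercepts[color]) +
      unname(params$slopes[color]) * temp_amb + noise
    temp_cow <- delta_t + temp_amb
  }

  obs <- data.frame(date = seq_len(n), color = color, albedo = albedo,
                    temp_amb = temp_amb, temp_cow = temp_cow,
                    delta_t = delta_t, stringsAsFactors = FALSE)
  list(observations = obs, covariates = cov_tab, truth = params)
}
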