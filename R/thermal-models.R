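#' Convert degrees Fahrenheit to Celsius
#'
#' @param f Temperature(s) in degrees Fahrenheit.
#' @return Temperature(s) in degrees Celsius, `(f - 32) * 5/9`.
#' @export
fahrenheit_to_celsius <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  (f - 32) * 5 / 9
}

#' Signed surface-minus-ambient temperature difference
#'
#' `delta_t = temp_cow - temp_amb`, kept signed: an animal colder than the
#' air yields a negative difference, and the regression slopes relating the
#' difference to ambient temperature are negative.
#'
#' @param temp_cow Animal surface temperature(s), degC.
#' @param temp_amb Ambient air temperature(s), degC.
#' @return Signed difference(s), degC.
#' @export
compute_delta_t <- function(temp_cow, temp_amb) {
  stopifnot(is.numeric(temp_cow), is.numeric(temp_amb),
            all(is.finite(temp_cow)), all(is.finite(temp_amb)))
  temp_cow - temp_amb
}

#' Join observations to daily covariates by date
#'
#' @param observations data.frame with a `date` column.
#' @param covariates data.frame with a unique `date` column.
#' @return Merged data.frame, one row per observation.
#' @export
assemble_dataset <- function(observations, covariates) {
  stopifnot(is.data.frame(observations), is.data.frame(covariates),
            "date" %in% names(observations), "date" %in% names(covariates))
  if (anyDuplicated(covariates$date))
    stopf("covariate dates must be unique")
  missing <- setdiff(observations$date, covariates$date)
  if (length(missing) > 0)
    stopf("no covariate row for date(s): %s",
          paste(utils::head(missing, 10), collapse = ", "))
  merged <- merge(observations, covariates, by = "date", sort = FALSE)
  stopifnot(nrow(merged) == nrow(observations))
  merged
}

#' Prune correlated covariates within source groups
#'
#' Within each measurement-source group, every pair with `|Pearson r|`
#' above the threshold loses one member, chosen by an explicit drop
#' preference list; the procedure repeats until no retained pair is flagged,
#' so it is idempotent.
#'
#' @param data data.frame containing the candidate covariates.
#' @param sources Named character vector mapping variable to source group
#'   (default [covariate_sources()]).
#' @param threshold Flagging cutoff on `|r|` (strict), default 0.7.
#' @param drop_preference Character vector naming which variables to drop
#'   when flagged; for a flagged pair with no member (or both members) in
#'   this list and no unambiguous choice, an error demands a rule.
#' @param exclude Columns never considered (default: the two response
#'   variables, which are not candidate predictors of themselves).
#' @return List with `retained` (character), `dropped` (character) and
#'   `report` (data.frame: `var1`, `var2`, `r`, `removed`, `source`).
#' @export
prune_correlated <- function(data, sources = covariate_sources(),
                             threshold = 0.7,
                             drop_preference = c("temp_earth", "humidity", "vpd"),
                             exclude = c("temp_cow", "delta_t")) {
  stopifnot(is.data.frame(data), threshold > 0, threshold < 1)
  vars <- setdiff(intersect(names(sources), names(data)), exclude)
  vars <- vars[vapply(data[vars], is.numeric, logical(1))]
  if (length(vars) < 2L) stopf("need at least 2 numeric covariates to prune")
  retained <- vars
  report <- data.frame(var1 = character(), var2 = character(), r = numeric(),
                       removed = character(), source = character(),
                       stringsAsFactors = FALSE)
  repeat {
    flagged <- NULL
    for (grp in unique(sources[retained])) {
      gv <- retained[sources[retained] == grp]
      if (length(gv) < 2L) next
      cm <- stats::cor(data[gv])
      idx <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      for (k in seq_len(nrow(idx)))
        flagged <- rbind(flagged, data.frame(
          var1 = gv[idx[k, 1]], var2 = gv[idx[k, 2]],
          r = cm[idx[k, 1], idx[k, 2]], source = grp,
          stringsAsFactors = FALSE))
    }
    if (is.null(flagged)) break
    flagged <- flagged[order(-abs(flagged$r)), , drop = FALSE]
    pair <- flagged[1, ]
    in_pref <- c(pair$var1, pair$var2) %in% drop_preference
    drop <- if (sum(in_pref) == 1L) c(pair$var1, pair$var2)[in_pref]
      else if (sum(in_pref) == 2L) {
        # both listed: preference order decides
        pref_pos <- match(c(pair$var1, pair$var2), drop_preference)
        c(pair$var1, pair$var2)[which.min(pref_pos)]
      } else
        stopf(paste0("|r| = %.3f between '%s' and '%s' (%s source) but neither ",
                     "is in drop_preference; extend the rule"),
              abs(pair$r), pair$var1, pair$var2, pair$source)
    retained <- setdiff(retained, drop)
    report <- rbind(report, data.frame(var1 = pair$var1, var2 = pair$var2,
                                       r = pair$r, removed = drop,
                                       source = pair$source,
                                       stringsAsFactors = FALSE))
  }
  list(retained = retained, dropped = setdiff(vars, retained), report = report)
}

#' Fit an ordinary least-squares model
#'
#' Wraps a Gaussian linear fit and records the quantities model selection
#' needs: parameter count K (intercept + slope terms + residual variance, so
#' the intercept-only null model has K = 2), log-likelihood, small-sample
#' AICc and 95 percent t-based confidence intervals.
#'
#' @param response Name of the response column.
#' @param terms Character vector of predictor columns; `character(0)` or
#'   `"1"` fits the null (intercept-only) model.
#' @param data data.frame containing response and terms.
#' @param level Confidence level for the coefficient intervals.
#' @return Object of class `model_fit`: list with `response`, `terms`, `n`,
#'   `K`, `loglik`, `aicc`, `coefficients` (data.frame term/estimate/lower/
#'   upper), `rss`, `sigma` and the underlying `lm` object.
#' @export
fit_ols <- function(response, terms, data, level = 0.95) {
  stopifnot(is.character(response), length(response) == 1L,
            is.data.frame(data), response %in% names(data))
  terms <- setdiff(terms, "1")
  if (length(terms) > 0 && !all(terms %in% names(data)))
    stopf("terms not in data: %s",
          paste(setdiff(terms, names(data)), collapse = ", "))
  f <- stats::reformulate(if (length(terms)) terms else "1", response)
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit)))
    stopf("design is rank deficient (aliased terms: %s)",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  n <- stats::nobs(fit)
  K <- length(stats::coef(fit)) + 1L  # + residual variance
  if (n < K) stopf("n = %d too small for K = %d parameters", n, K)
  ll <- as.numeric(stats::logLik(fit))
  ci <- stats::confint(fit, level = level)
  coefs <- data.frame(term = names(stats::coef(fit)),
                      estimate = unname(stats::coef(fit)),
                      lower = ci[, 1], upper = ci[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(response = response, terms = terms, n = n, K = K,
                 loglik = ll,
                 # AICc needs n > K + 1; saturated fits get NA, not an error
                 aicc = if (n - K - 1 > 0) aicc(ll, K, n) else NA_real_,
                 coefficients = coefs,
                 rss = sum(stats::residuals(fit)^2),
                 sigma = stats::sigma(fit), level = level, lm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %s ~ %s\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  cat(sprintf("n = %d, K = %d, logLik = %.2f, AICc = %.2f\n",
              x$n, x$K, x$loglik, x$aicc))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param loglik Model log-likelihood.
#' @param K Parameter count (including intercept and residual variance).
#' @param n Sample size; must exceed `K + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, K, n) {
  stopifnot(is_scalar_number(loglik), is_scalar_number(K), is_scalar_number(n))
  if (n - K - 1 <= 0) stopf("AICc undefined: n = %s <= K + 1 = %s", n, K + 1)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike differences and weights
#'
#' @param aicc_values Numeric vector of AICc values (>= 1 finite value).
#' @return List with `delta` (`AICc_i - min AICc`) and `weight`
#'   (`exp(-delta/2)` renormalized to sum to 1).
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(is.numeric(aicc_values), length(aicc_values) >= 1,
            all(is.finite(aicc_values)))
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' Flag informative coefficients by confidence-interval screening
#'
#' A coefficient is informative when its confidence interval excludes zero.
#'
#' @param fit A `model_fit`.
#' @param level Confidence level (recomputed if it differs from the fit's).
#' @return data.frame with `term`, `estimate`, `lower`, `upper`,
#'   `informative`.
#' @export
ci_screen <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "model_fit"))
  coefs <- fit$coefficients
  if (!isTRUE(all.equal(level, fit$level))) {
    ci <- stats::confint(fit$lm, level = level)
    coefs$lower <- ci[, 1]; coefs$upper <- ci[, 2]
  }
  coefs$informative <- coefs$lower > 0 | coefs$upper < 0
  coefs
}

model_label <- function(terms) {
  if (length(terms) == 0L) "Null" else paste(terms, collapse = " + ")
}

# fit candidates, rank by AICc with parsimony then lexicographic tie-break
rank_candidates <- function(response, candidates, data) {
  fits <- lapply(candidates, function(tr) fit_ols(response, tr, data))
  tab <- data.frame(model = vapply(candidates, model_label, character(1)),
                    n_terms = vapply(candidates, length, integer(1)),
                    K = vapply(fits, `[[`, integer(1), "K"),
                    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
                    stringsAsFactors = FALSE)
  ord <- order(tab$aicc, tab$n_terms, tab$model)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  aw <- akaike_weights(tab$aicc)
  tab$delta_aicc <- aw$delta
  tab$weight <- aw$weight
  rownames(tab) <- NULL
  list(table = tab[, c("model", "K", "aicc", "delta_aicc", "weight")],
       fits = fits,
       candidates = lapply(ord, function(i) candidates[[i]]))
}

#' Staged AICc model selection for animal thermal responses
#'
#' Three categorical steps, each ranked by AICc with a null model included:
#' step 1 picks the best single weather variable, step 2 the best single
#' solar-radiation variable, and step 3 ranks nested combinations of the two
#' step winners plus in-situ animal attributes (hide albedo, and the surface
#' temperature when the response is the temperature difference). Models
#' within 2 AICc of the step's best form the top set; Akaike weights are
#' reported per step, and the final model's coefficients are screened by
#' 95 percent confidence interval.
#'
#' @param data Merged analysis table (see [assemble_dataset()]).
#' @param response `"temp_cow"` or `"delta_t"`.
#' @param weather Candidate weather terms for step 1.
#' @param radiation Candidate radiation terms for step 2.
#' @param animal Animal-attribute terms added in step 3; defaults to
#'   `"albedo"`, plus `"temp_cow"` when the response is `"delta_t"`.
#' @return Object of class `selection_report`: list with `steps` (named
#'   list of ranked data.frames), `top_sets` (models with delta AICc <= 2
#'   per step), `weather_term`, `radiation_term`, `final_terms`,
#'   `final_fit` (a `model_fit`) and `screen` ([ci_screen()] output).
#' @export
staged_selection <- function(data, response = c("temp_cow", "delta_t"),
                             weather = c("temp_amb", "temp_dew", "wind"),
                             radiation = c("ktclear", "rad_lw", "rad_sw"),
                             animal = NULL) {
  response <- match.arg(response)
  stopifnot(is.data.frame(data), length(weather) >= 1, length(radiation) >= 1)
  if (is.null(animal))
    animal <- if (response == "delta_t") c("albedo", "temp_cow") else "albedo"
  null_model <- list(character(0))

  step1 <- rank_candidates(response, c(as.list(weather), null_model), data)
  step2 <- rank_candidates(response, c(as.list(radiation), null_model), data)
  # chosen step winner: the best-ranked single-term model (the null can sit
  # in the top set, but carries no term forward)
  best_single <- function(step) {
    tab <- step$table
    tab$model[tab$model != "Null"][1]
  }
  w_term <- best_single(step1)
  r_term <- best_single(step2)

  # nested combinations of the step winners plus animal attributes
  base <- c(w_term, r_term)
  cands <- list(c(base, animal))
  if (length(animal) > 1)
    for (i in seq_along(animal)) cands <- c(cands, list(c(base, animal[-i])))
  cands <- c(cands, list(base), as.list(base), null_model)
  cands <- unique(cands)
  step3 <- rank_candidates(response, cands, data)

  final_terms <- step3$candidates[[1]]
  final_fit <- step3$fits[[1]]
  steps <- list(weather = step1$table, radiation = step2$table,
                combined = step3$table)
  structure(list(
    response = response,
    steps = steps,
    top_sets = lapply(steps, function(t) t$model[t$delta_aicc <= 2]),
    weather_term = w_term, radiation_term = r_term,
    final_terms = final_terms, final_fit = final_fit,
    screen = ci_screen(final_fit)),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Staged AICc selection for response '%s'\n", x$response))
  for (nm in names(x$steps)) {
    cat(sprintf("\nStep: %s\n", nm))
    print(x$steps[[nm]], digits = 6)
  }
  cat(sprintf("\nFinal model: %s ~ %s\n", x$response,
              model_label(x$final_terms)))
  print(x$screen, digits = 4)
  invisible(x)
}
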