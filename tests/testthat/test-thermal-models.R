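test_that("temperature conversion and difference have their fixed points", {
  expect_equal(fahrenheit_to_celsius(32), 0)
  expect_equal(fahrenheit_to_celsius(212), 100)
  expect_equal(fahrenheit_to_celsius(-40), -40)
  expect_equal(compute_delta_t(32.4, 4.4), 28.0)
  expect_equal(compute_delta_t(5, 5), 0)
  expect_equal(compute_delta_t(0, 2.2), -2.2)
  # antisymmetry
  expect_equal(compute_delta_t(3, 10), -compute_delta_t(10, 3))
})

test_that("assembly joins by date, preserves rows, and names missing dates", {
  obs <- data.frame(date = c(1, 2, 3), temp_cow = c(30, 31, 32))
  cov <- data.frame(date = c(1, 2, 3, 4), wind = c(10, 20, 30, 40))
  m <- assemble_dataset(obs, cov)
  expect_equal(nrow(m), 3)
  expect_setequal(names(m), c("date", "temp_cow", "wind"))
  expect_error(assemble_dataset(data.frame(date = 9, temp_cow = 1), cov), "9")
  expect_error(assemble_dataset(obs, rbind(cov, cov)), "unique")
})

test_that("pruning removes one of a duplicated pair and nothing below cutoff", {
  set.seed(4)
  d <- data.frame(rad_lw = rnorm(50))
  d$rad_sw <- d$rad_lw  # r = 1
  d$ktclear <- rnorm(50)
  pr <- prune_correlated(d, drop_preference = "rad_sw")
  expect_equal(pr$dropped, "rad_sw")
  expect_equal(nrow(pr$report), 1)
  expect_equal(pr$report$r, 1)
  # independent columns survive untouched
  d2 <- data.frame(rad_lw = rnorm(200), rad_sw = rnorm(200), ktclear = rnorm(200))
  pr2 <- prune_correlated(d2)
  expect_equal(pr2$dropped, character(0))
})

test_that("pruning reproduces the three standard removals and is idempotent", {
  m <- make_merged(thermal_gen_params(seed = 7))
  pr <- prune_correlated(m)
  expect_setequal(pr$dropped, c("temp_earth", "humidity", "vpd"))
  again <- prune_correlated(m[c("date", pr$retained)])
  expect_equal(nrow(again$report), 0)
  expect_setequal(again$retained, pr$retained)
})

test_that("pruning demands a rule when the preference list is silent", {
  set.seed(5)
  d <- data.frame(rad_lw = rnorm(50))
  d$rad_sw <- d$rad_lw + rnorm(50, 0, 0.1)
  expect_error(prune_correlated(d, drop_preference = character(0)),
               "drop_preference")
})

test_that("OLS fit matches hand normal equations and flags collinearity", {
  d <- data.frame(x = c(0, 1), y = c(0, 1))
  f <- fit_ols("y", "x", rbind(d, data.frame(x = 2, y = 2)))
  expect_equal(f$coefficients$estimate, c(0, 1), tolerance = 1e-12)
  d2 <- data.frame(x = c(0, 1, 2), y = c(1, 2, 4))
  # Sxy = 10 - 7 = 3, Sxx = 5 - 3 = 2, so slope 3/2 and intercept 7/3 - 3/2
  f2 <- fit_ols("y", "x", d2)
  expect_equal(f2$coefficients$estimate, c(5 / 6, 1.5), tolerance = 1e-12)
  d2$x2 <- d2$x
  expect_error(fit_ols("y", c("x", "x2"), d2), "rank deficient")
  # K convention: slopes + intercept + residual variance
  expect_equal(f2$K, 3)
  m <- make_merged(thermal_gen_params(n = 50, seed = 2))
  expect_equal(fit_ols("temp_cow", character(0), m)$K, 2)
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-10, 3, 10), 20 + 6 + 24 / 6)
  expect_equal(aicc(-10, 3, 1e9), 26, tolerance = 1e-6)
  expect_equal(aicc(-5, 2, 30), aicc(-5, 2, 30))
  expect_error(aicc(-10, 3, 4), "undefined")
})

test_that("AICc agrees with the RSS-based Gaussian likelihood on OLS fits", {
  m <- make_merged(thermal_gen_params(n = 100, seed = 3))
  f <- fit_ols("temp_cow", c("temp_amb", "ktclear"), m)
  n <- f$n
  ll_rss <- -n / 2 * (log(2 * pi) + log(f$rss / n) + 1)
  expect_equal(f$aicc, aicc(ll_rss, f$K, n))
})

test_that("Akaike weights sum to one and are shift invariant", {
  w <- akaike_weights(c(100, 100))
  expect_equal(w$delta, c(0, 0))
  expect_equal(w$weight, c(0.5, 0.5))
  a <- c(4988.16, 4995.78, 4998.08, 5023.93)
  w1 <- akaike_weights(a)
  w2 <- akaike_weights(a + 1234.5)
  expect_equal(sum(w1$weight), 1)
  expect_equal(w1$weight, w2$weight)
  expect_equal(round(w1$weight, 2), c(0.97, 0.02, 0.01, 0.00))
})

test_that("CI screening flags exactly the intervals excluding zero", {
  m <- make_merged(thermal_gen_params(seed = 19))
  f <- fit_ols("temp_cow", c("temp_amb", "ktclear", "albedo"), m)
  sc <- ci_screen(f)
  expect_true(all(sc$informative == (sc$lower > 0 | sc$upper < 0)))
  # a coefficient straddling zero is uninformative: regress on pure noise
  set.seed(8)
  d <- data.frame(y = rnorm(50), x = rnorm(50))
  sc2 <- ci_screen(fit_ols("y", "x", d))
  expect_false(sc2$informative[sc2$term == "x"])
})

test_that("step ledgers have top delta zero, weights summing to one", {
  m <- make_merged(thermal_gen_params(seed = 23))
  sel <- staged_selection(m, "temp_cow")
  for (tab in sel$steps) {
    expect_equal(tab$delta_aicc[1], 0)
    expect_equal(sum(tab$weight), 1)
    expect_true("Null" %in% tab$model)
  }
  expect_equal(sel$weather_term, "temp_amb")
  expect_equal(sel$radiation_term, "ktclear")
  expect_equal(sel$final_terms, c("temp_amb", "ktclear", "albedo"))
})

test_that("delta_t selection adds surface temperature to the candidate set", {
  m <- make_merged(thermal_gen_params(seed = 29))
  sel <- staged_selection(m, "delta_t")
  expect_true(any(grepl("temp_cow", sel$steps$combined$model)))
  expect_true(all(c("albedo", "temp_cow") %in% sel$final_terms) ||
                length(sel$final_terms) <= 4)
})

test_that("a pure-noise response keeps the null model in the top set", {
  hits <- 0L
  n_seeds <- 30L
  for (seed in seq_len(n_seeds)) {
    m <- make_merged(thermal_gen_params(n = 200, seed = 900 + seed))
    set.seed(900 + seed)
    m$temp_cow <- rnorm(nrow(m))  # response independent of every covariate
    sel <- staged_selection(m, "temp_cow", animal = "albedo")
    in_top <- vapply(sel$top_sets[c("weather", "radiation")],
                     function(s) "Null" %in% s, logical(1))
    if (all(in_top)) hits <- hits + 1L
  }
  expect_gt(hits / n_seeds, 0.5)
})

test_that("parameter recovery: CIs cover the generating coefficients", {
  truth <- c(0.1770, 19.172, -27.026)
  cover <- matrix(FALSE, nrow = 50, ncol = 3)
  for (s in 1:50) {
    m <- make_merged(thermal_gen_params(seed = 3000 + s))
    f <- fit_ols("temp_cow", c("temp_amb", "ktclear", "albedo"), m)
    co <- f$coefficients[-1, ]
    cover[s, ] <- co$lower <= truth & truth <= co$upper
  }
  expect_gte(min(colMeans(cover)), 0.88)
})
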