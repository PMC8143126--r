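test_that("per-color fits demand 3 observations and name the offender", {
  d <- data.frame(color = c("white", "white", "white", "red", "red"),
                  temp_amb = c(1, 2, 3, 1, 2), delta_t = c(3, 2, 1, 5, 4))
  expect_error(fit_color_regressions(d), "red")
})

test_that("collinear points give r-squared 1 and a defined p-value", {
  d <- data.frame(color = rep("black", 3), temp_amb = c(0, 1, 2),
                  delta_t = c(10, 9, 8))
  f <- fit_color_regressions(d)
  expect_equal(f$table$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$table$slope, -1, tolerance = 1e-12)
  expect_false(is.na(f$table$p_value))
})

test_that("stratified slopes equal the interaction model's per-color slopes", {
  m <- make_merged(thermal_gen_params(mode = "slope", n = 120, noise_sd = 3,
                                      seed = 41))
  strat <- fit_color_regressions(m)
  cmp <- ancova_slopes(m)
  full <- cmp$model
  co <- coef(full)
  lev <- levels(factor(m$color))
  base_slope <- co[["temp_amb"]]
  for (col in lev) {
    inter_term <- sprintf("temp_amb:color%s", col)
    slope_full <- base_slope + if (inter_term %in% names(co)) co[[inter_term]] else 0
    expect_equal(strat$table$slope[strat$table$color == col], slope_full,
                 tolerance = 1e-10)
  }
})

test_that("identical generating slopes give a near-zero interaction", {
  p <- thermal_gen_params(mode = "slope", n = 120, noise_sd = 0,
                          slopes = c(white = -0.7, red = -0.7, black = -0.7),
                          seed = 43)
  m <- make_merged(p)
  cmp <- ancova_slopes(m)
  # noise-free common slope: every pairwise slope difference is numerically zero
  expect_true(all(abs(cmp$pairwise$estimate) < 1e-10))
  expect_equal(unname(cmp$fits$table$slope), rep(-0.7, 3), tolerance = 1e-12)
  expect_equal(nrow(cmp$pairwise), 3)  # colors choose 2
})

test_that("heterogeneous slopes are detected with Tukey-separated pairs", {
  m <- make_merged(thermal_gen_params(mode = "slope", n = 300, noise_sd = 3,
                                      seed = 47))
  cmp <- ancova_slopes(m)
  expect_lt(cmp$interaction$p_value, 1e-6)
  expect_true(all(cmp$pairwise$p_tukey < 0.01))
  expect_true(cmp$levene$p_value < 0.05)  # unequal residual spread by design
  expect_true(cmp$kruskal$H >= 0)
})

test_that("ANCOVA rejects a single color", {
  d <- data.frame(color = rep("black", 10), temp_amb = 1:10,
                  delta_t = 10:1 + rnorm(10, 0, 0.1))
  expect_error(ancova_slopes(d), "at least 2 colors")
})

test_that("prediction bands are narrowest at the predictor mean and cover", {
  m <- make_merged(thermal_gen_params(mode = "slope", n = 300, noise_sd = 3,
                                      seed = 53))
  fits <- fit_color_regressions(m)
  xbar <- mean(m$temp_amb[m$color == "black"])
  grid <- c(xbar - 20, xbar - 5, xbar, xbar + 5, xbar + 20)
  b <- predict_band(fits, "black", grid)
  hw <- (b$upr - b$lwr) / 2
  expect_equal(which.min(hw), 3L)
  expect_true(all(diff(hw[3:5]) > 0))

  # coverage of fresh points at nominal 95 percent
  covered <- 0L; total <- 0L
  for (s in 1:20) {
    p <- thermal_gen_params(mode = "slope", n = 300, noise_sd = 3, seed = 600 + s)
    train <- make_merged(p)
    p2 <- p; p2$seed <- 7000L + s
    fresh <- make_merged(p2)
    f <- fit_color_regressions(train)
    for (col in unique(fresh$color)) {
      nd <- fresh[fresh$color == col, ]
      band <- predict_band(f, col, nd$temp_amb)
      covered <- covered + sum(nd$delta_t >= band$lwr & nd$delta_t <= band$upr)
      total <- total + nrow(nd)
    }
  }
  expect_gte(covered / total, 0.93)
})

test_that("Kruskal-Wallis on the response ignores location shifts", {
  m <- make_merged(thermal_gen_params(mode = "slope", n = 90, noise_sd = 3,
                                      seed = 59))
  h1 <- kruskal_wallis(split(m$delta_t, m$color))$H
  h2 <- kruskal_wallis(split(m$delta_t + 100, m$color))$H
  expect_equal(h1, h2)
})
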