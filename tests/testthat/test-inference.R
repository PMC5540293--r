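test_that("collinearity screen flags duplicates and infinite VIF", {
  withr::with_seed(1, {
    x <- rnorm(100)
    sc <- screen_collinearity(data.frame(a = x, b = x, c = rnorm(100)))
    ab <- sc$pairwise[sc$pairwise$var1 == "a" & sc$pairwise$var2 == "b", ]
    expect_equal(ab$r, 1.0)
    expect_true(ab$flag)
    expect_true(sc$any_flag)
    const <- screen_collinearity(data.frame(a = rnorm(50), k = rep(2, 50)))
    expect_true(is.infinite(const$vif$vif[const$vif$variable == "k"]))
    expect_true(const$vif$flag[const$vif$variable == "k"])
  })
})

test_that("VIF of an orthogonal design is exactly 1 and matches car", {
  x <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  y <- c(-1, 1, -1, 1, -1, 1, -1, 1)
  z <- c(-1, 1, 1, -1, 1, -1, -1, 1)
  sc <- screen_collinearity(data.frame(x = x, y = y, z = z))
  expect_equal(unname(sc$vif$vif), rep(1, 3))
  expect_false(sc$any_flag)
  withr::with_seed(10, {
    d <- data.frame(a = rnorm(80), b = rnorm(80), cc = rnorm(80))
    d$b <- d$b + 0.7 * d$a
    sc2 <- screen_collinearity(d)
    fit <- lm(rnorm(80) ~ a + b + cc, data = d)
    vif_car <- car::vif(fit)
    expect_equal(unname(sc2$vif$vif), unname(vif_car[sc2$vif$variable]),
                 tolerance = 1e-8)
  })
})

test_that("independent covariates are rarely flagged", {
  withr::with_seed(40, {
    flags <- vapply(1:40, function(i) {
      screen_collinearity(data.frame(a = rnorm(500), b = rnorm(500),
                                     cc = rnorm(500)))$any_flag
    }, logical(1))
    expect_gte(mean(!flags), 0.95)
  })
})

test_that("AR1 fit without correlation reduces to ordinary least squares", {
  d <- simulate_ar1_whale_days(n_whales = 3, n_days = 50, phi = 0, seed = 5)
  f <- fit_model(d, "y", c("tide", "wet"), correlation = "none",
                 include_whale = FALSE, method = "ML")
  ols <- lm(log(y) ~ tide + wet, data = d)
  expect_equal(unname(coef(f$fit)), unname(coef(ols)), tolerance = 1e-6)
  # AR1 machinery with phi ~ 0 data agrees closely too
  f2 <- fit_model(d, "y", c("tide", "wet"), include_whale = FALSE, method = "ML")
  expect_lt(abs(f2$phi), 0.15)
  expect_equal(unname(coef(f2$fit)), unname(coef(ols)), tolerance = 0.01)
})

test_that("doubling the response shifts only the intercept by log 2", {
  d <- simulate_ar1_whale_days(n_whales = 3, n_days = 60, seed = 8)
  f1 <- fit_model(d, "y", c("tide", "wet"), include_whale = FALSE)
  d2 <- dplyr::mutate(d, y = 2 * y)
  f2 <- fit_model(d2, "y", c("tide", "wet"), include_whale = FALSE)
  c1 <- coef(f1$fit); c2 <- coef(f2$fit)
  expect_equal(c2[["(Intercept)"]] - c1[["(Intercept)"]], log(2), tolerance = 1e-6)
  expect_equal(c2[["tide"]], c1[["tide"]], tolerance = 1e-6)
  expect_equal(f2$phi, f1$phi, tolerance = 1e-6)
})

test_that("model fitting validates its inputs", {
  d <- simulate_ar1_whale_days(n_whales = 2, n_days = 20, seed = 3)
  d$y[1] <- -1
  expect_error(fit_model(d, "y", "tide"), "strictly positive")
  d2 <- simulate_ar1_whale_days(n_whales = 2, n_days = 20, seed = 3)
  d2$day_of_year[2] <- d2$day_of_year[1]
  expect_error(fit_model(d2, "y", "tide"), "duplicated time")
})

test_that("AICc reproduces published model-table values", {
  expect_equal(round(aicc(-1682.236, 5, 1426), 1), 3374.5)
  expect_equal(round(aicc(-346.450, 7, 1426), 1), 707.0)
  expect_equal(aicc(-10, 0, 50), 20)
  expect_error(aicc(-10, 5, 6), "n > k")
})

test_that("model ranking orders by AICc with normalised Akaike weights", {
  w <- akaike_weights(c(0, 0.90, 1.86, 3.86, 14.21))
  expect_equal(round(w, 3), c(0.459, 0.293, 0.181, 0.067, 0.000))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(akaike_weights(0), 1)
  expect_equal(akaike_weights(c(3, 3)), c(0.5, 0.5))
  scores <- tibble::tibble(model = c("m1", "m2", "m3"), k = c(2, 3, 4),
                           loglik = c(-100, -98, -97.9))
  rk <- rank_models(scores, n = 200)
  expect_equal(rk$delta[1], 0)
  expect_false(is.unsorted(rk$aicc))
  expect_equal(sum(rk$weight), 1, tolerance = 1e-9)
})

test_that("Durbin-Watson statistic matches closed forms", {
  e <- rep(c(1, -1), 50)
  n <- length(e)
  expect_equal(durbin_watson(e), 4 * (n - 1) / n)
  expect_equal(durbin_watson(c(5, 5, 5, 5)), 0)
  withr::with_seed(2, {
    wn <- rnorm(1000)
    dw <- durbin_watson(wn)
    expect_gt(dw, 1.8); expect_lt(dw, 2.2)
  })
  expect_error(durbin_watson(c(0, 0, 0)), "all-zero")
  expect_error(durbin_watson(c(1, 2)), "at least 3")
})

test_that("fitted AR1 residuals are whitened (Durbin-Watson near 2)", {
  d <- simulate_ar1_whale_days(n_whales = 4, n_days = 150, phi = 0.6, seed = 11)
  f <- fit_model(d, "y", c("tide", "wet"), include_whale = FALSE)
  raw <- resid(f$fit)
  # innovations after removing the fitted AR1 component
  phi <- f$phi
  innov <- unlist(lapply(split(raw, d$whale_id), function(e) e[-1] - phi * e[-length(e)]))
  expect_gt(durbin_watson(innov), 1.8)
  expect_lt(durbin_watson(innov), 2.2)
  expect_lt(durbin_watson(raw), 1.5)  # raw residuals are autocorrelated
})

test_that("group summaries use linear-interpolation percentiles", {
  d <- data.frame(v = 1:100, g = "all")
  gs <- group_summary(d, "v", "g")
  expect_equal(gs$median, 50.5)
  expect_equal(gs$q25, 25.75)
  expect_equal(gs$q75, 75.25)
  expect_equal(gs$n, 100L)
  one <- group_summary(data.frame(v = 7), "v")
  expect_equal(c(one$q25, one$median, one$q75), c(7, 7, 7))
  withr::with_seed(4, {
    v <- rlnorm(37)
    a <- group_summary(data.frame(v = v), "v")
    b <- group_summary(data.frame(v = 10 * v), "v")
    expect_equal(10 * c(a$q25, a$median, a$q75), c(b$q25, b$median, b$q75))
  })
})
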