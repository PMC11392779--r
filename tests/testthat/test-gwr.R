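fixture_xy <- function(n, seed = 1, noise = 0.5) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  x <- rnorm(n)
  y <- 2 + 3 * x + rnorm(n, 0, noise)
  list(y = y, x = x, coords = coords)
}

test_that("an exactly linear response is fitted perfectly everywhere", {
  f <- fixture_xy(20, noise = 0)
  fit <- gwr_fit(f$y, f$x, f$coords, bandwidth = 2)
  expect_equal(fit$intercept, rep(2, 20), tolerance = 1e-8)
  expect_equal(fit$slope, rep(3, 20), tolerance = 1e-8)
  expect_equal(fit$residuals, rep(0, 20), tolerance = 1e-8)
  expect_equal(fit$local_r2, rep(1, 20), tolerance = 1e-8)
})

test_that("a huge bandwidth reproduces ordinary least squares", {
  f <- fixture_xy(25, seed = 2)
  fit <- gwr_fit(f$y, f$x, f$coords, bandwidth = 1e6 * 15)
  ols <- lm(f$y ~ f$x)
  expect_equal(fit$intercept, rep(unname(coef(ols)[1]), 25),
               tolerance = 1e-6)
  expect_equal(fit$slope, rep(unname(coef(ols)[2]), 25), tolerance = 1e-6)
  r2 <- summary(ols)$r.squared
  expect_equal(fit$local_r2, rep(r2, 25), tolerance = 1e-6)
  # AICc limit: tr(S) -> 2, AICc equals the formula on the OLS fit
  rss <- sum(residuals(ols)^2)
  n <- 25
  ref <- 2 * n * log(sqrt(rss / n)) + n * log(2 * pi) +
    n * (n + 2) / (n - 4)
  expect_equal(aicc(fit), ref, tolerance = 1e-4)
})

test_that("local estimates equal the brute-force weighted normal
           equations at every location", {
  for (seed in 1:5) {
    f <- fixture_xy(sample(6:25, 1), seed = seed)
    n <- length(f$y)
    b <- runif(1, 1, 8)
    fit <- gwr_fit(f$y, f$x, f$coords, b)
    for (i in seq_len(n)) {
      d <- sqrt(colSums((t(f$coords) - f$coords[i, ])^2))
      w <- exp(-0.5 * (d / b)^2)
      X <- cbind(1, f$x)
      beta <- solve(t(X) %*% (w * X), t(X) %*% (w * f$y))
      expect_equal(fit$intercept[i], beta[1], tolerance = 1e-8)
      expect_equal(fit$slope[i], beta[2], tolerance = 1e-8)
      # local R2 from the same weights
      yhat <- X %*% beta
      rss <- sum(w * (f$y - yhat)^2)
      tss <- sum(w * (f$y - weighted.mean(f$y, w))^2)
      expect_equal(fit$local_r2[i], 1 - rss / tss, tolerance = 1e-8)
    }
    expect_equal(fit$residuals, f$y - fit$fitted)
  }
})

test_that("AICc penalty is monotone in effective parameters and matches
           an independent evaluation", {
  f <- fixture_xy(20, seed = 3)
  fit <- gwr_fit(f$y, f$x, f$coords, 2)
  n <- fit$n
  ref <- 2 * n * log(sqrt(fit$rss / n)) + n * log(2 * pi) +
    n * (n + fit$trS) / (n - 2 - fit$trS)
  expect_equal(aicc(fit), ref)
  # same RSS, larger tr(S) -> strictly larger AICc
  mk <- function(trS) {
    x <- fit; x$trS <- trS; x
  }
  expect_gt(aicc(mk(fit$trS + 1)), aicc(fit))
  expect_error(aicc(mk(n - 2)), class = "divscape_aicc_undefined")
})

test_that("golden-section search finds known minima", {
  b <- golden_section_bandwidth(objective = function(b) (b - 3)^2,
                                interval = c(0.1, 10))
  expect_equal(b, 3, tolerance = 1e-2)
  expect_error(
    golden_section_bandwidth(objective = function(b) b, interval = c(2, 2)),
    class = "divscape_invalid_config")
})

test_that("the selected bandwidth agrees with a dense grid search", {
  f <- fixture_xy(40, seed = 5)
  b <- golden_section_bandwidth(f$y, f$x, f$coords)
  D <- dist(f$coords)
  lo <- min(D[D > 0])
  hi <- sqrt(sum((apply(f$coords, 2, max) - apply(f$coords, 2, min))^2))
  grid <- seq(lo, hi, length.out = 200)
  vals <- vapply(grid, function(bb) {
    fit <- gwr_fit(f$y, f$x, f$coords, bb)
    v <- tryCatch(aicc(fit), error = function(e) Inf)
    v
  }, numeric(1))
  b_grid <- grid[which.min(vals)]
  step <- (hi - lo) / 199 + 1e-3 * (lo + hi) / 2
  expect_lt(abs(b - b_grid), step + 1e-9)
  # the search's objective equals AICc recomputed from the fit it returns
  expect_equal(aicc(gwr_fit(f$y, f$x, f$coords, b)),
               min(vals), tolerance = 0.05)
})

test_that("tied bandwidths make the multiscale fit identical to plain
           GWR", {
  f <- fixture_xy(25, seed = 6)
  g <- gwr_fit(f$y, f$x, f$coords, 2.5)
  m <- mgwr_fit(f$y, f$x, f$coords, bandwidths = c(2.5, 2.5))
  expect_equal(m$fitted, g$fitted, tolerance = 1e-8)
  expect_equal(m$residuals, g$residuals, tolerance = 1e-8)
  expect_equal(m$trS, g$trS, tolerance = 1e-8)
  expect_error(mgwr_fit(f$y, rep(1, 25), f$coords),
               class = "divscape_invalid_input")
})

test_that("multiscale backfitting recovers a spatially varying slope", {
  set.seed(77)
  corrs <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 80
    coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    slope_true <- 1 + 0.3 * coords[, 1]      # varies west-east
    x <- rnorm(n)
    y <- 2 + slope_true * x + rnorm(n, 0, 0.2)
    m <- suppressWarnings(mgwr_fit(y, x, coords))
    cor(m$slope, slope_true)
  }, numeric(1))
  expect_gt(median(corrs), 0.8)
})

test_that("degenerate local designs are flagged, not fatal", {
  n <- 12
  coords <- cbind(seq_len(n), rep(0, n))
  x <- rep(1, n)   # no predictor variance anywhere
  y <- rnorm(n)
  fit <- gwr_fit(y, x, coords, 2)
  expect_true(all(fit$degenerate))
  expect_true(all(is.na(fit$slope)))
  expect_true(all(is.finite(fit$fitted)))
})

test_that("the model suite fits the six stated directions and classifies
           residual signs", {
  run <- run_pipeline(pipeline_config(scenario = small_scenario(seed = 4)))
  expect_named(run$suite, c("FD ~ TD", "PD ~ TD", "FD ~ PD",
                            "WE ~ FE", "WE ~ PE", "FE ~ PE"))
  cl <- tidy(run$suite)
  expect_true(all(cl$sign_label[cl$residual > 0] == "positive"))
  expect_true(all(cl$sign_label[cl$residual < 0] == "negative"))
  expect_true(all(cl$sign_label[cl$residual == 0] == "neutral"))
  g <- glance(run$suite)
  expect_equal(nrow(g), 6)
  expect_true(all(is.finite(g$aicc)))
  # too few usable cells is a clean error
  s10 <- run$surfaces[1:8, ]
  class(s10) <- class(run$surfaces)
  expect_error(run_model_suite(s10), class = "divscape_insufficient_data")
})
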