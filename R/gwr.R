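#' Geographically weighted regression of one surface on another
#'
#' At each location `i`, fits weighted least squares of `y` on
#' `(1, x)` with Gaussian kernel weights
#' `w_ij = exp(-0.5 * (d_ij / bandwidth)^2)` over all locations `j`.
#' Returns local coefficients, fitted values (each location's own local
#' prediction), residuals `observed - fitted`, geographically weighted
#' local R-squared, the hat-matrix trace (effective number of
#' parameters), and the corrected AIC. Locations where the weighted
#' predictor carries no variance are flagged degenerate rather than
#' crashing; their slope is undefined and the local fit falls back to the
#' weighted mean.
#'
#' @param y,x Numeric response and predictor vectors (length n >= 3).
#' @param coords Two-column matrix or data frame of location coordinates.
#' @param bandwidth Positive kernel bandwidth (distance units of
#'   `coords`).
#' @param model Optional label (e.g. `"FD ~ TD"`) carried in the result.
#' @return A `divscape_gwr` object; see [tidy.divscape_gwr()] and
#'   [glance.divscape_gwr()].
#' @export
gwr_fit <- function(y, x, coords, bandwidth, model = "y ~ x") {
  coords <- as.matrix(coords)
  n <- length(y)
  stopifnot(length(x) == n, nrow(coords) == n)
  if (n < 3) {
    abort("GWR needs at least 3 locations.",
          class = "divscape_invalid_input")
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    abort("`bandwidth` must be positive.", class = "divscape_invalid_config")
  }
  D <- as.matrix(dist(coords))
  W <- exp(-0.5 * (D / bandwidth)^2)
  mom <- local_moments(W, x, y)
  den <- mom$sw * mom$sxx - mom$sx^2
  degenerate <- den <= .Machine$double.eps * pmax(mom$sw * mom$sxx, 1)
  beta1 <- ifelse(degenerate, NA_real_,
                  (mom$sw * mom$sxy - mom$sx * mom$sy) / den)
  beta0 <- ifelse(degenerate, mom$sy / mom$sw,
                  (mom$sy - beta1 * mom$sx) / mom$sw)
  fitted <- ifelse(degenerate, beta0, beta0 + beta1 * x)
  resid <- y - fitted
  # hat diagonal: s_ii = w_ii [1, x_i] M_i^{-1} [1, x_i]'; w_ii = 1
  hat_ii <- ifelse(degenerate, 1 / mom$sw,
                   (mom$sxx - 2 * x * mom$sx + x^2 * mom$sw) / den)
  trS <- sum(hat_ii)
  # local weighted RSS/TSS from the same moments
  b0 <- beta0; b1 <- ifelse(degenerate, 0, beta1)
  rss_i <- mom$syy - 2 * b0 * mom$sy - 2 * b1 * mom$sxy +
    b0^2 * mom$sw + 2 * b0 * b1 * mom$sx + b1^2 * mom$sxx
  tss_i <- mom$syy - mom$sy^2 / mom$sw
  local_r2 <- ifelse(tss_i > 0, pmin(pmax(1 - rss_i / tss_i, 0), 1), NA_real_)
  rss <- sum(resid^2)
  structure(
    list(model = model, coords = coords, bandwidth = bandwidth,
         intercept = beta0, slope = beta1, observed = y, predictor = x,
         fitted = fitted, residuals = resid, local_r2 = local_r2,
         degenerate = degenerate, hat_ii = hat_ii, trS = trS, rss = rss,
         n = n, aicc = gwr_aicc_value(rss, n, trS), converged = TRUE,
         method = "gwr"),
    class = "divscape_gwr"
  )
}

local_moments <- function(W, x, y) {
  list(
    sw = as.numeric(W %*% rep(1, length(x))),
    sx = as.numeric(W %*% x),
    sy = as.numeric(W %*% y),
    sxx = as.numeric(W %*% (x * x)),
    sxy = as.numeric(W %*% (x * y)),
    syy = as.numeric(W %*% (y * y))
  )
}

gwr_aicc_value <- function(rss, n, trS) {
  if (trS >= n - 2) return(NA_real_)
  sigma <- sqrt(rss / n)
  2 * n * log(sigma) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
}

#' Corrected AIC of a fitted geographically weighted regression
#'
#' `AICc = 2 n log(sigma) + n log(2 pi) + n (n + tr(S)) / (n - 2 - tr(S))`
#' with `sigma^2 = RSS / n` and `tr(S)` the hat-matrix trace. Undefined
#' (an error) when `tr(S) >= n - 2`; the bandwidth search treats such
#' bandwidths as inadmissible.
#'
#' @param result A `divscape_gwr` fit.
#' @return The AICc value.
#' @export
aicc <- function(result) {
  stopifnot(inherits(result, "divscape_gwr"))
  val <- gwr_aicc_value(result$rss, result$n, result$trS)
  if (is.na(val)) {
    abort(sprintf("AICc undefined: tr(S) = %.2f >= n - 2 = %d.",
                  result$trS, result$n - 2L),
          class = "divscape_aicc_undefined")
  }
  val
}

#' Golden-section search for the AICc-optimal bandwidth
#'
#' Minimises `AICc(bandwidth)` by golden-section search over
#' `[interval[1], interval[2]]`, stopping when the bracket has shrunk
#' below a relative tolerance of `1e-3`. Bandwidths at which the AICc is
#' undefined (effective parameters too close to n) are treated as
#' infinitely bad; if every probed bandwidth is inadmissible the search
#' fails with an error.
#'
#' @inheritParams gwr_fit
#' @param interval Search bracket `c(lo, hi)`, `0 < lo < hi`. Defaults to
#'   the smallest non-zero inter-point distance up to the extent diagonal.
#' @param objective Objective function of bandwidth; defaults to the AICc
#'   of [gwr_fit()]. Exposed so other smoothers can reuse the search.
#' @param tol Relative bracket tolerance; default `1e-3`.
#' @return The located bandwidth.
#' @export
golden_section_bandwidth <- function(y, x, coords, interval = NULL,
                                     objective = NULL, tol = 1e-3) {
  if (is.null(objective)) {
    objective <- function(b) {
      fit <- gwr_fit(y, x, coords, b)
      val <- gwr_aicc_value(fit$rss, fit$n, fit$trS)
      if (is.na(val)) Inf else val
    }
    coords <- as.matrix(coords)
  }
  if (is.null(interval)) {
    D <- dist(coords)
    lo <- min(D[D > 0])
    hi <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
    interval <- c(lo, hi)
  }
  lo <- interval[1]; hi <- interval[2]
  if (!(lo > 0) || !(lo < hi)) {
    abort("Bandwidth interval must satisfy 0 < lo < hi.",
          class = "divscape_invalid_config")
  }
  phi <- (sqrt(5) - 1) / 2
  b1 <- hi - phi * (hi - lo)
  b2 <- lo + phi * (hi - lo)
  f1 <- objective(b1); f2 <- objective(b2)
  while ((hi - lo) > tol * (abs(lo) + abs(hi)) / 2) {
    if (f1 <= f2) {
      hi <- b2; b2 <- b1; f2 <- f1
      b1 <- hi - phi * (hi - lo); f1 <- objective(b1)
    } else {
      lo <- b1; b1 <- b2; f1 <- f2
      b2 <- lo + phi * (hi - lo); f2 <- objective(b2)
    }
  }
  if (!is.finite(f1) && !is.finite(f2)) {
    abort("AICc undefined over the whole bandwidth interval.",
          class = "divscape_search_failure")
  }
  if (f1 <= f2) b1 else b2
}

# single-term local smoothers used by MGWR backfitting ---------------------

local_constant_fit <- function(p, W) {
  sw <- as.numeric(W %*% rep(1, length(p)))
  sp <- as.numeric(W %*% p)
  list(term = sp / sw, hat_ii = 1 / sw)
}

local_slope_fit <- function(p, x, W) {
  sxx <- as.numeric(W %*% (x * x))
  sxp <- as.numeric(W %*% (x * p))
  beta <- ifelse(sxx > 0, sxp / sxx, 0)
  list(term = beta * x, beta = beta, hat_ii = ifelse(sxx > 0, x^2 / sxx, 0))
}

term_bandwidth <- function(p, coords, interval, smoother) {
  n <- length(p)
  golden_section_bandwidth(
    objective = function(b) {
      D <- as.matrix(dist(coords))
      W <- exp(-0.5 * (D / b)^2)
      fit <- smoother(W)
      rss <- sum((p - fit$term)^2)
      val <- gwr_aicc_value(rss, n, sum(fit$hat_ii))
      if (is.na(val)) Inf else val
    },
    interval = interval
  )
}

#' Multiscale geographically weighted regression
#'
#' Allows the intercept and slope terms their own kernel bandwidths. When
#' the two bandwidths coincide the additive model is exactly ordinary
#' GWR, and it is computed as the joint local fit; with free bandwidths
#' the fit is obtained by backfitting: starting from the AICc-optimal
#' single-bandwidth GWR, each term in turn is re-smoothed against its
#' partial residual at its own golden-section AICc bandwidth, until the
#' square-root change in fitted values relative to their norm (SOC-RSS)
#' falls below `soc_tol` or `max_iter` sweeps have run. Non-convergence
#' returns the current fit with `converged = FALSE` and a warning.
#'
#' @inheritParams gwr_fit
#' @param bandwidths Optional fixed `c(intercept, slope)` bandwidths;
#'   `NULL` (default) selects both by AICc.
#' @param soc_tol Backfitting convergence tolerance on SOC-RSS; default
#'   `1e-5`.
#' @param max_iter Backfitting sweep cap; default 200.
#' @return A `divscape_gwr` object with `method = "mgwr"` and a
#'   `bandwidths` field `c(intercept = , slope = )`.
#' @export
mgwr_fit <- function(y, x, coords, bandwidths = NULL, model = "y ~ x",
                     soc_tol = 1e-5, max_iter = 200) {
  coords <- as.matrix(coords)
  n <- length(y)
  stopifnot(length(x) == n, nrow(coords) == n)
  if (var(x) == 0) {
    abort("Predictor has zero variance.", class = "divscape_invalid_input")
  }
  if (!is.null(bandwidths) && length(bandwidths) == 2 &&
      isTRUE(all.equal(bandwidths[1], bandwidths[2]))) {
    fit <- gwr_fit(y, x, coords, bandwidths[1], model = model)
    fit$method <- "mgwr"
    fit$bandwidths <- c(intercept = bandwidths[1], slope = bandwidths[2])
    return(fit)
  }
  D <- as.matrix(dist(coords))
  lo <- min(D[D > 0]); hi <- sqrt(sum((apply(coords, 2, max) -
                                         apply(coords, 2, min))^2))
  interval <- c(lo, hi)
  if (is.null(bandwidths)) {
    b_init <- golden_section_bandwidth(y, x, coords, interval = interval)
  } else {
    b_init <- mean(bandwidths)
  }
  init <- gwr_fit(y, x, coords, b_init, model = model)
  f0 <- init$intercept
  f1 <- ifelse(init$degenerate, 0, init$slope) * x
  beta1 <- init$slope
  bw <- c(intercept = b_init, slope = b_init)
  fitted_old <- f0 + f1
  converged <- FALSE
  hat0 <- init$hat_ii; hat1 <- rep(0, n)
  for (it in seq_len(max_iter)) {
    # intercept term on its partial residual
    p0 <- y - f1
    bw[1] <- if (is.null(bandwidths)) {
      term_bandwidth(p0, coords, interval,
                     function(W) local_constant_fit(p0, W))
    } else bandwidths[1]
    W0 <- exp(-0.5 * (D / bw[1])^2)
    s0 <- local_constant_fit(p0, W0)
    f0 <- s0$term; hat0 <- s0$hat_ii
    # slope term on its partial residual
    p1 <- y - f0
    bw[2] <- if (is.null(bandwidths)) {
      term_bandwidth(p1, coords, interval,
                     function(W) local_slope_fit(p1, x, W))
    } else bandwidths[2]
    W1 <- exp(-0.5 * (D / bw[2])^2)
    s1 <- local_slope_fit(p1, x, W1)
    f1 <- s1$term; beta1 <- s1$beta; hat1 <- s1$hat_ii
    fitted <- f0 + f1
    soc <- sqrt(sum((fitted - fitted_old)^2) / max(sum(fitted^2),
                                                   .Machine$double.eps))
    fitted_old <- fitted
    if (soc < soc_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("MGWR backfitting did not converge in %d sweeps.", max_iter))
  }
  resid <- y - fitted_old
  rss <- sum(resid^2)
  trS <- sum(hat0) + sum(hat1)
  # local fit quality at the slope-term scale, from the additive fit
  Wr2 <- exp(-0.5 * (D / bw[2])^2)
  rss_i <- as.numeric(Wr2 %*% (resid^2))
  sw <- as.numeric(Wr2 %*% rep(1, n))
  ybar_i <- as.numeric(Wr2 %*% y) / sw
  tss_i <- as.numeric(Wr2 %*% (y^2)) - sw * ybar_i^2
  local_r2 <- ifelse(tss_i > 0, pmin(pmax(1 - rss_i / tss_i, 0), 1),
                     NA_real_)
  structure(
    list(model = model, coords = coords, bandwidth = unname(bw[2]),
         bandwidths = bw, intercept = f0, slope = beta1, observed = y,
         predictor = x, fitted = fitted_old, residuals = resid,
         local_r2 = local_r2, degenerate = rep(FALSE, n),
         hat_ii = hat0 + hat1, trS = trS, rss = rss, n = n,
         aicc = gwr_aicc_value(rss, n, trS), converged = converged,
         method = "mgwr"),
    class = "divscape_gwr"
  )
}

#' @export
print.divscape_gwr <- function(x, ...) {
  cat(sprintf("<divscape_gwr> %s (%s): n = %d, bandwidth = %.4g, AICc = %.4g\n",
              x$model, x$method, x$n, x$bandwidth,
              if (is.na(x$aicc)) NA else x$aicc))
  invisible(x)
}

#' Classify residual signs into mismatch labels
#'
#' Positive residuals mark locations where the response exceeds its local
#' expectation given the predictor (e.g. for FD ~ TD, functional
#' diversity higher than taxonomic diversity predicts); negative
#' residuals mark the reverse; residuals within `epsilon` of zero are
#' neutral.
#'
#' @param result A `divscape_gwr` fit.
#' @param epsilon Half-width of the neutral band; default 0 (pure sign).
#' @return Tibble with coordinates, `residual` and `sign_label`.
#' @export
classify_residuals <- function(result, epsilon = 0) {
  stopifnot(inherits(result, "divscape_gwr"), epsilon >= 0)
  r <- result$residuals
  tibble::tibble(
    x = result$coords[, 1], y = result$coords[, 2],
    residual = r,
    sign_label = dplyr::case_when(
      r > epsilon ~ "positive",
      r < -epsilon ~ "negative",
      TRUE ~ "neutral"
    )
  )
}

#' Fit the six diversity/endemism congruence models
#'
#' Fits the model suite FD ~ TD, PD ~ TD, FD ~ PD, WE ~ FE, WE ~ PE and
#' FE ~ PE (response ~ predictor, exactly these directions) on cell
#' centroids of a surface set, selecting each bandwidth by golden-section
#' AICc. Interpolated cells are included; cells with missing values are
#' excluded. Residual signs are classified per model.
#'
#' @param surfaces A `divscape_surfaces` tibble.
#' @param method `"gwr"` (single bandwidth per model, default) or
#'   `"mgwr"` (per-term bandwidths by backfitting).
#' @param models Character vector of models to fit, a subset of the six
#'   defaults, each `"resp ~ pred"` with names among td, we, pd, pe, fd,
#'   fe.
#' @param epsilon Neutral band for residual classification; default 0.
#' @return A `divscape_suite`: named list of `divscape_gwr` fits with a
#'   `classification` attribute (stacked per-model sign labels).
#' @export
run_model_suite <- function(surfaces,
                            method = c("gwr", "mgwr"),
                            models = c("fd ~ td", "pd ~ td", "fd ~ pd",
                                       "we ~ fe", "we ~ pe", "fe ~ pe"),
                            epsilon = 0) {
  method <- match.arg(method)
  stopifnot(inherits(surfaces, "divscape_surfaces"))
  dat <- tibble::as_tibble(surfaces)
  metrics <- c("td", "we", "pd", "pe", "fd", "fe")
  dat <- dat[complete.cases(dat[, metrics]), ]
  if (nrow(dat) < 10) {
    abort(sprintf("Only %d usable cells; at least 10 required.", nrow(dat)),
          class = "divscape_insufficient_data")
  }
  coords <- as.matrix(dat[, c("x", "y")])
  fits <- purrr::map(models, function(m) {
    parts <- trimws(strsplit(m, "~", fixed = TRUE)[[1]])
    y <- as.numeric(dat[[parts[1]]]); x <- as.numeric(dat[[parts[2]]])
    label <- paste0(toupper(parts[1]), " ~ ", toupper(parts[2]))
    if (method == "gwr") {
      b <- golden_section_bandwidth(y, x, coords)
      gwr_fit(y, x, coords, b, model = label)
    } else {
      mgwr_fit(y, x, coords, model = label)
    }
  })
  names(fits) <- purrr::map_chr(fits, "model")
  classification <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(classify_residuals(f, epsilon), model = nm,
                  row = dat$row, col = dat$col, .before = 1)
  })
  structure(fits, classification = classification,
            class = "divscape_suite")
}

#' @export
print.divscape_suite <- function(x, ...) {
  cat("<divscape_suite>\n")
  for (f in x) {
    cat(sprintf("  %-9s bandwidth = %8.4g  AICc = %10.4g\n",
                f$model, f$bandwidth, f$aicc))
  }
  invisible(x)
}
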