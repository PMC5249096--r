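#' Fit an MSD motion model to a trajectory or MSD curve
#'
#' Least-squares fit of one of the four motion-model MSD curves over lags
#' `1 ... floor(N/2)` (long lags average few displacement pairs and are
#' noisy, so they are excluded):
#'
#' * `"nd"` normal diffusion, `<r^2> = 4 D t`: ordinary least squares with a
#'   free intercept (localization noise offsets the curve), `D = slope / 4`.
#' * `"ad"` anomalous diffusion, `<r^2> = 4 D t^alpha`: straight line in
#'   log-log space.
#' * `"dm"` directed motion, `<r^2> = 4 D t + (v t)^2`: linear least squares
#'   in `(t, t^2)` without intercept; negative coefficients are clipped at 0
#'   with a warning.
#' * `"cd"` confined diffusion, `<r^2> = rc^2 (1 - A1 exp(-4 A2 D t / rc^2))`:
#'   bounded Levenberg-Marquardt fit of `rc^2`, `A1` and `A2` with `D` fixed
#'   at the short-time estimate from the first two lags (only the product
#'   `A2 D` is identifiable jointly). Initial values `rc^2 = max(msd)`,
#'   `A1 = A2 = 1`.
#'
#' @param object A track table with a single trajectory, or an MSD curve as
#'   returned by [track_msd()] (columns `time` and `msd`).
#' @param model One of `"nd"`, `"ad"`, `"dm"`, `"cd"` (or the class labels
#'   `"normal"`, `"anomalous"`, `"directed"`, `"confined"`).
#' @param max_lag Largest lag used; defaults to `floor(N/2)` for track input
#'   and all rows for curve input.
#' @return An object of class `msd_model_fit` with `tidy()` and `glance()`
#'   methods: a list with the model code, named `params` (`D` and, per
#'   model, `alpha`, `v`, or `r_c`, `A1`, `A2`), the fitted curve and
#'   residual sum of squares.
#' @examples
#' curve <- tibble::tibble(time = (1:20) / 30, msd = 4 * 0.05 * (1:20) / 30)
#' fit_msd_model(curve, "nd")$params$D
#' @export
fit_msd_model <- function(object, model = c("nd", "ad", "dm", "cd"),
                          max_lag = NULL) {
  model <- normalize_model(match.arg(model[1], c("nd", "ad", "dm", "cd",
                                                 "normal", "anomalous",
                                                 "directed", "confined")))
  curve <- as_msd_curve(object, max_lag)
  t <- curve$time
  msd <- curve$msd
  min_lags <- if (model == "cd") 4L else 3L
  if (length(t) < min_lags) {
    abort(sprintf("need at least %d usable lags for a '%s' fit",
                  min_lags, model), class = "sptmotion_fit_error")
  }
  dt <- t[2] - t[1]
  params <- switch(model,
    nd = {
      slope <- ols_slope(t, msd)
      D <- slope / 4
      if (D < 0) {
        warn("negative diffusion slope clipped at 0")
        D <- 0
      }
      list(D = D)
    },
    ad = {
      if (any(msd <= 0)) {
        abort("log-log fit needs strictly positive MSD values",
              class = "sptmotion_fit_error")
      }
      co <- coef(lm(log(msd) ~ log(t)))
      list(D = unname(exp(co[1]) / 4), alpha = unname(co[2]))
    },
    dm = {
      co <- coef(lm(msd ~ 0 + t + I(t^2)))
      if (any(co < 0)) warn("negative directed-motion coefficient clipped at 0")
      list(D = unname(max(co[1], 0)) / 4, v = sqrt(unname(max(co[2], 0))))
    },
    cd = {
      D_short <- max(((msd[2] - msd[1]) / dt) / 4, 1e-12)
      df <- data.frame(t = t, msd = msd)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          msd ~ r2 * (1 - A1 * exp(-4 * A2 * D_short * t / r2)),
          data = df,
          start = list(r2 = max(msd), A1 = 1, A2 = 1),
          lower = c(r2 = 1e-12, A1 = 0, A2 = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) {
          abort(paste0("confined-diffusion fit failed: ", conditionMessage(e)),
                class = "sptmotion_fit_error")
        })
      co <- coef(fit)
      list(D = D_short, r_c = sqrt(unname(co["r2"])), A1 = unname(co["A1"]),
           A2 = unname(co["A2"]))
    })
  fitted <- msd_model_curve(model, params, t)
  structure(list(model = model, params = params, curve = curve,
                 fitted = fitted, rss = sum((msd - fitted)^2),
                 n_lags = length(t)),
            class = "msd_model_fit")
}

normalize_model <- function(model) {
  map <- c(nd = "nd", ad = "ad", dm = "dm", cd = "cd",
           normal = "nd", anomalous = "ad", directed = "dm", confined = "cd")
  unname(map[[model]])
}

msd_model_curve <- function(model, p, t) {
  switch(model,
    nd = 4 * p$D * t,
    ad = 4 * p$D * t^p$alpha,
    dm = 4 * p$D * t + (p$v * t)^2,
    cd = p$r_c^2 * (1 - p$A1 * exp(-4 * p$A2 * p$D * t / p$r_c^2)))
}

as_msd_curve <- function(object, max_lag = NULL) {
  if (all(c("time", "msd") %in% names(object)) && !"x" %in% names(object)) {
    curve <- as_tibble(object)
    if ("id" %in% names(curve) && length(unique(curve$id)) > 1) {
      abort("fit one trajectory's curve at a time",
            class = "sptmotion_schema_error")
    }
  } else {
    validate_tracks(object)
    if (length(unique(object$id)) > 1) {
      abort("fit one trajectory at a time", class = "sptmotion_schema_error")
    }
    N <- nrow(object)
    curve <- track_msd(object, lags = seq_len(max(2L, floor(N / 2))))
  }
  if (!is.null(max_lag)) curve <- curve[seq_len(min(max_lag, nrow(curve))), ]
  curve
}

#' @export
print.msd_model_fit <- function(x, ...) {
  cat("<msd_model_fit>", x$model, "model,", x$n_lags, "lags\n")
  p <- unlist(x$params)
  cat(paste0("  ", names(p), " = ", signif(p, 5), collapse = "\n"), "\n")
  cat("  rss =", signif(x$rss, 5), "\n")
  invisible(x)
}

#' @describeIn fit_msd_model One row per fitted parameter (`term`,
#'   `estimate`).
#' @param x An `msd_model_fit` object.
#' @param ... Unused.
#' @method tidy msd_model_fit
#' @export
tidy.msd_model_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unlist(x$params, use.names = FALSE))
}

#' @describeIn fit_msd_model One-row model summary (`model`, `r.squared`,
#'   `rss`, `n_lags`).
#' @method glance msd_model_fit
#' @export
glance.msd_model_fit <- function(x, ...) {
  tss <- sum((x$curve$msd - mean(x$curve$msd))^2)
  tibble(model = x$model, r.squared = if (tss > 0) 1 - x$rss / tss else NA_real_,
         rss = x$rss, n_lags = x$n_lags)
}

#' Covariance-based localization-noise estimate
#'
#' Static localization error makes successive displacements anticorrelated;
#' the lag-one displacement autocovariance therefore estimates the noise
#' variance, and the covariance-corrected displacement variance estimates the
#' diffusion coefficient. Per coordinate,
#' \eqn{\hat\sigma^2 = -\mathrm{cov}(d_i, d_{i+1})} and
#' \eqn{\hat D = \mathrm{var}(d)/(2\Delta t) +
#' \mathrm{cov}(d_i, d_{i+1})/\Delta t}; both are averaged over x and y and
#' negative noise-variance estimates are floored at zero.
#'
#' @param tracks A track table.
#' @return A tibble with one row per trajectory: `id`, `sigma` (um) and `D`
#'   (um^2/s).
#' @export
estimate_localization_noise <- function(tracks) {
  validate_tracks(tracks)
  out <- lapply(track_list(tracks), function(tr) {
    est <- function(p) {
      d <- diff(p)
      c1 <- cov(d[-length(d)], d[-1])
      c(sig2 = -c1, D = var(d) / (2 * tr$dt) + c1 / tr$dt)
    }
    ex <- est(tr$x)
    ey <- est(tr$y)
    tibble(id = tr$id,
           sigma = sqrt(max((ex["sig2"] + ey["sig2"]) / 2, 0)),
           D = unname((ex["D"] + ey["D"]) / 2))
  })
  dplyr::bind_rows(out)
}
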