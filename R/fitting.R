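#' @title Energy-transfer estimation by nonlinear spectrum fitting
#' @description Internal least-squares engine shared by [fit_E_CY()] and
#'   [fit_E_RY()]: bounded Levenberg-Marquardt over one free transfer rate
#'   plus a free positive amplitude, multi-started over a fixed grid of
#'   initial rates, best objective kept, ties broken toward the smaller
#'   rate.
#' @noRd
.ls_engine <- function(y, mfun1, lower_e, upper_e,
                       starts_e = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  starts_e <- unique(pmin(pmax(starts_e, lower_e + 1e-6), upper_e - 1e-6))
  if (!length(starts_e)) starts_e <- (lower_e + upper_e) / 2
  best <- NULL
  for (e0 in starts_e) {
    m1 <- mfun1(e0)
    a0 <- max(sum(y * m1) / max(sum(m1 * m1), 1e-300), 1e-8)
    fit <- minpack.lm::nls.lm(
      par = c(E = e0, A = a0),
      fn = function(p) y - p[["A"]] * mfun1(p[["E"]]),
      lower = c(lower_e, 1e-12), upper = c(upper_e, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-15, ptol = 1e-15))
    ss <- sum(fit$fvec^2)
    if (is.null(best)) {
      best <- list(fit = fit, ss = ss)
    } else {
      tiny <- 1e-12 * (1 + best$ss)
      if (ss < best$ss - tiny ||
          (abs(ss - best$ss) <= tiny &&
             fit$par[["E"]] < best$fit$par[["E"]]))
        best <- list(fit = fit, ss = ss)
    }
  }
  best
}

.fit_result <- function(y, grid, mfun1, engine, e_name, lower_e, upper_e,
                        fixed, n_boot, seed, mode) {
  fit <- engine$fit
  n <- length(y)
  est <- c(fit$par[["E"]], fit$par[["A"]])
  names(est) <- c(e_name, "amplitude")
  curve <- est[2] * mfun1(est[1])
  resid <- y - curve
  rms <- sqrt(mean(resid^2))
  dof <- max(n - 2L, 1L)
  sigma2 <- engine$ss / dof
  se <- rep(NA_real_, 2)
  covm <- try(solve(fit$hessian) * sigma2, silent = TRUE)
  if (inherits(covm, "try-error")) covm <- NULL
  else se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(est)
  at_bound <- abs(est[1] - c(lower_e, upper_e)) < 1e-9
  res <- structure(list(
    estimate = est, se = se,
    ci95 = NULL, fixed = fixed,
    residual_rms = rms, objective = engine$ss,
    fitted_curve = spectrum(grid, pmax(curve, 0), meta = list(mode = mode)),
    envelope_lo = NULL, envelope_hi = NULL,
    cov = covm,
    at_bound = stats::setNames(any(at_bound), e_name),
    converged = fit$info %in% 1:4,
    n_obs = n, e_name = e_name,
    lower_e = lower_e, upper_e = upper_e,
    data = list(wavelength_nm = grid, intensity = y),
    mfun1 = mfun1
  ), class = "et_fit")
  # asymptotic normal CI as default; replaced by bootstrap when requested
  ci <- cbind(lo = est - 1.96 * se, hi = est + 1.96 * se)
  ci[1, ] <- pmin(pmax(ci[1, ], lower_e), upper_e)
  res$ci95 <- ci
  if (n_boot > 0) {
    env <- confidence_envelope(res, n_boot = n_boot, seed = seed)
    res$ci95 <- env$ci95
    res$envelope_lo <- env$envelope_lo
    res$envelope_hi <- env$envelope_hi
  }
  res
}

#' @export
print.et_fit <- function(x, ...) {
  cat(sprintf("<et_fit> %s = %.6g (se %.3g), amplitude = %.6g\n",
              x$e_name, x$estimate[1], x$se[1], x$estimate[2]))
  cat(sprintf("  residual RMS %.4g over %d points; converged: %s%s\n",
              x$residual_rms, x$n_obs, x$converged,
              if (isTRUE(x$at_bound[[1]])) " (at bound)" else ""))
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), signif(unlist(x$fixed), 4),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the CFP-to-YFP FRET efficiency from a fluorescence spectrum
#'
#' Fits the forward fluorescence model to a measured spectrum by bounded
#' least squares over `(E_CY, amplitude)`, with `E_CY` constrained to
#' `[0, 1]`. The optimizer is Levenberg-Marquardt multi-started from a
#' fixed grid of initial rates (0.1, 0.3, 0.5, 0.7, 0.9); the best
#' objective wins and ties go to the smaller rate, so the result is
#' deterministic given the data. An estimate pinned at a bound is flagged
#' (`at_bound`), not an error.
#'
#' @param measured a fluorescence-mode `spectrum` (raw counts or
#'   normalized).
#' @param basis a [reference_basis()] providing `f_C`, `f_Y` and
#'   photophysics.
#' @param n_boot number of residual-resampling bootstrap replicates for
#'   the 95% CI and pointwise envelope; 0 (default) uses the asymptotic
#'   normal CI and no envelope.
#' @param seed RNG seed for the bootstrap.
#' @param weights optional per-point weights (e.g. inverse-variance
#'   Poisson weights); default unweighted.
#' @return An `et_fit` with the estimate, standard error, 95% CI,
#'   residual RMS, fitted curve and (if bootstrapped) pointwise envelope.
#' @export
fit_E_CY <- function(measured, basis, n_boot = 0, seed = 1, weights = NULL) {
  stopifnot(inherits(measured, "spectrum"),
            inherits(basis, "reference_basis"))
  grid <- measured$wavelength_nm
  y <- measured$intensity
  if (any(!is.finite(y))) stop("non-finite intensities in measured spectrum")
  w <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  mfun1 <- function(e)
    w * fluorescence_model(basis,
                           transfer_params(E_CY = e, amplitude = 1),
                           grid = grid)$intensity
  eng <- .ls_engine(w * y, mfun1, 0, 1)
  .fit_result(w * y, grid, mfun1, eng, "E_CY", 0, 1,
              fixed = list(), n_boot = n_boot, seed = seed,
              mode = "fluorescence")
}

#' Estimate the direct luciferase-to-YFP BRET rate from a bioluminescence
#' spectrum
#'
#' Fits the forward bioluminescence model over `(E_RY, amplitude)` with
#' `E_RC` and `E_CY` held fixed: `E_RC` comes from [solve_E_RC()] (the
#' luciferase-CFP linker is assumed rigid, so the rate does not move with
#' biosensor conformation) and `E_CY` from the paired fluorescence fit
#' (assumed identical in FRET and BRET modes). `E_RY` is bounded to
#' `[0, 1 - E_RC]` so the residual luciferase branch stays nonnegative.
#'
#' With `fit_param = "E_NC"` the NanoLuc donor-to-CFP rate is fitted
#' instead, holding `E_NY = E_CY = 0` (used to characterize the
#' NanoLuc-CFP fusion itself).
#'
#' @inheritParams fit_E_CY
#' @param measured a bioluminescence-mode `spectrum`.
#' @param E_RC,E_CY fixed transfer rates (ignored for `fit_param="E_NC"`).
#' @param donor `"rluc8"` or `"nanoluc"`.
#' @param fit_param which rate to fit: `"E_RY"` (default; `E_NY` when
#'   `donor = "nanoluc"`) or `"E_NC"`.
#' @return An `et_fit`.
#' @export
fit_E_RY <- function(measured, basis, E_RC, E_CY,
                     donor = c("rluc8", "nanoluc"),
                     fit_param = c("E_RY", "E_NC"),
                     n_boot = 0, seed = 1, weights = NULL) {
  stopifnot(inherits(measured, "spectrum"),
            inherits(basis, "reference_basis"))
  donor <- match.arg(donor)
  fit_param <- match.arg(fit_param)
  grid <- measured$wavelength_nm
  y <- measured$intensity
  if (any(!is.finite(y))) stop("non-finite intensities in measured spectrum")
  w <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  if (fit_param == "E_NC") {
    if (donor != "nanoluc")
      stop("fit_param='E_NC' requires donor='nanoluc'")
    mfun1 <- function(e)
      w * bioluminescence_model(
        basis, transfer_params(E_NC = e, amplitude = 1),
        grid = grid, donor = "nanoluc")$intensity
    fixed <- list(E_NY = 0, E_CY = 0)
    lower_e <- 0; upper_e <- 1
    e_name <- "E_NC"
  } else {
    if (!is.finite(E_RC) || E_RC < 0 || E_RC > 1)
      stop("fixed E_RC must be in [0, 1]")
    if (!is.finite(E_CY) || E_CY < 0 || E_CY > 1)
      stop("fixed E_CY must be in [0, 1]")
    upper_e <- 1 - E_RC
    if (upper_e <= 0)
      stop("E_RC = 1 leaves no admissible range for E_RY")
    mfun1 <- if (donor == "rluc8") {
      function(e)
        w * bioluminescence_model(
          basis,
          transfer_params(E_CY = E_CY, E_RC = E_RC, E_RY = e,
                          amplitude = 1),
          grid = grid, donor = "rluc8")$intensity
    } else {
      function(e)
        w * bioluminescence_model(
          basis,
          transfer_params(E_CY = E_CY, E_NC = E_RC, E_NY = e,
                          amplitude = 1),
          grid = grid, donor = "nanoluc")$intensity
    }
    fixed <- list(E_RC = E_RC, E_CY = E_CY)
    lower_e <- 0
    e_name <- if (donor == "rluc8") "E_RY" else "E_NY"
  }
  eng <- .ls_engine(w * y, mfun1, lower_e, upper_e)
  .fit_result(w * y, grid, mfun1, eng, e_name, lower_e, upper_e,
              fixed = fixed, n_boot = n_boot, seed = seed,
              mode = "bioluminescence")
}

#' Bootstrap confidence envelope and parameter intervals for a spectrum fit
#'
#' Residual-resampling parametric bootstrap: residuals of the converged fit
#' are resampled with replacement onto the fitted curve and the model is
#' refitted (single start at the point estimate) for each replicate.
#' Pointwise 2.5/97.5 percentile curves form the envelope; parameter
#' percentiles form the 95% CI. Spectra residuals are heteroscedastic
#' (photon noise scales with intensity), which is why the percentile
#' bootstrap is the method of record; [delta_method_band()] is the
#' linearized cross-check.
#'
#' @param fit an `et_fit`.
#' @param n_boot replicates (>= 200 recommended; < 50 draws a warning but
#'   is still computed).
#' @param seed RNG seed; same seed and inputs give identical envelopes.
#' @return List with `envelope_lo`, `envelope_hi` (numeric vectors on the
#'   fit grid), `ci95` (matrix), and `boot_estimates`.
#' @export
confidence_envelope <- function(fit, n_boot = 500, seed = 1) {
  stopifnot(inherits(fit, "et_fit"))
  if (!fit$converged) stop("fit did not converge; no envelope")
  if (n_boot < 50)
    warning("n_boot < 50: envelope will be noisy; computed anyway")
  grid <- fit$data$wavelength_nm
  curve <- fit$estimate[2] * fit$mfun1(fit$estimate[1])
  resid <- fit$data$intensity - curve
  set.seed(seed)
  n <- length(resid)
  est_b <- matrix(NA_real_, n_boot, 2)
  curves <- matrix(NA_real_, n_boot, n)
  for (b in seq_len(n_boot)) {
    yb <- curve + sample(resid, n, replace = TRUE)
    eng <- .ls_engine(yb, fit$mfun1, fit$lower_e, fit$upper_e,
                      starts_e = fit$estimate[1])
    est_b[b, ] <- eng$fit$par
    curves[b, ] <- eng$fit$par[["A"]] * fit$mfun1(eng$fit$par[["E"]])
  }
  lo <- apply(curves, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(curves, 2, stats::quantile, probs = 0.975, names = FALSE)
  # the point fit is inside its own envelope by construction
  lo <- pmin(lo, curve)
  hi <- pmax(hi, curve)
  ci <- t(apply(est_b, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  dimnames(ci) <- list(names(fit$estimate), c("lo", "hi"))
  list(envelope_lo = lo, envelope_hi = hi, ci95 = ci,
       boot_estimates = stats::setNames(
         as.data.frame(est_b), names(fit$estimate)))
}

#' Delta-method pointwise band for a spectrum fit
#'
#' Linearized 95% band: numerical gradient of the model curve with respect
#' to the fitted parameters, propagated through the asymptotic parameter
#' covariance. Cross-check for the bootstrap envelope.
#'
#' @param fit an `et_fit`.
#' @return List with `band_lo`, `band_hi`.
#' @export
delta_method_band <- function(fit) {
  stopifnot(inherits(fit, "et_fit"))
  e <- fit$estimate[1]; a <- fit$estimate[2]
  h_e <- max(1e-6, 1e-6 * abs(e))
  e_up <- min(e + h_e, fit$upper_e); e_dn <- max(e - h_e, fit$lower_e)
  g_e <- a * (fit$mfun1(e_up) - fit$mfun1(e_dn)) / (e_up - e_dn)
  g_a <- fit$mfun1(e)
  covm <- fit$cov
  if (is.null(covm)) stop("parameter covariance unavailable (singular fit)")
  G <- cbind(g_e, g_a)
  v <- rowSums((G %*% covm) * G)
  curve <- a * fit$mfun1(e)
  list(band_lo = curve - 1.96 * sqrt(pmax(v, 0)),
       band_hi = curve + 1.96 * sqrt(pmax(v, 0)))
}
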