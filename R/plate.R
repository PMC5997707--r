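#' Z-prime screening-assay quality factor
#'
#' \deqn{Z' = 1 - \frac{3 (SD_0 + SD_1)}{Ave_0 - Ave_1}}
#' where group 0 is untreated and group 1 is treated at the reference
#' dose; sample (n-1) standard deviations, denominator
#' untreated-minus-treated as printed in the screening literature.
#' Z' approaches 1 for a tight, well-separated assay.
#'
#' @param neg_wells numeric readouts (e.g. BRET ratios) of untreated
#'   wells; at least 2.
#' @param pos_wells readouts of treated wells; at least 2.
#' @return Z' (scalar, \eqn{\le 1}).
#' @export
zprime <- function(neg_wells, pos_wells) {
  if (length(neg_wells) < 2 || length(pos_wells) < 2)
    stop("need at least 2 wells per group")
  d <- mean(neg_wells) - mean(pos_wells)
  if (d == 0) stop("group means are equal: Z' undefined")
  1 - 3 * (stats::sd(neg_wells) + stats::sd(pos_wells)) / d
}

#' Hill dose-response model (decreasing form)
#'
#' \deqn{r(X) = min + \frac{amp \cdot IC50^{nH}}{X^{nH} + IC50^{nH}}}
#' so the response falls from `min + amp` at zero dose to `min` at
#' saturation, crossing `min + amp/2` at `X = IC50`.
#'
#' @param X dose (same units as `IC50`, conventionally uM).
#' @param min baseline at saturating dose.
#' @param amp amplitude (\eqn{\ge 0}).
#' @param IC50 half-maximal inhibitory concentration (> 0).
#' @param nH Hill coefficient (> 0).
#' @return Model response.
#' @export
hill_model <- function(X, min, amp, IC50, nH) {
  min + amp * IC50^nH / (X^nH + IC50^nH)
}

#' Fit the Hill equation to dose-response data
#'
#' Bounded Levenberg-Marquardt least squares over
#' `(min, amp, log IC50, nH)`; `min` and `amp` are initialized from the
#' data extremes, the dose axis is handled in log space internally for
#' conditioning (doses of exactly zero are supported by the model form),
#' and the fit is multi-started over `nH` in {0.5, 1, 2, 4} with ties
#' broken toward the smallest `nH`, so the result is deterministic.
#' Degenerate data (zero amplitude, unidentifiable IC50) return a fit
#' with `converged = FALSE` rather than an error.
#'
#' @param doses nonnegative doses (uM); at least 4 distinct values.
#' @param responses per-well responses, same length.
#' @param fixed optional named list fixing any of `min`, `amp`.
#' @return A `hill_fit`: list with `params` (min, amp, IC50, nH), `se`,
#'   `residual_rms`, `converged`, and `predict(X)`.
#' @export
hill_fit <- function(doses, responses, fixed = list()) {
  stopifnot(length(doses) == length(responses))
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct doses")
  if (any(doses < 0)) stop("doses must be nonnegative")
  ord <- order(doses)
  lo_resp <- mean(responses[ord][doses[ord] >= max(doses) * 0.99])
  hi_resp <- mean(responses[ord][doses[ord] <= min(doses) * 1.01])
  min0 <- if (!is.null(fixed$min)) fixed$min else lo_resp
  amp0 <- if (!is.null(fixed$amp)) fixed$amp else max(hi_resp - lo_resp, 0)
  pos <- doses[doses > 0]
  if (!length(pos)) stop("need at least one positive dose")
  lic0 <- mean(log(range(pos)))
  free_min <- is.null(fixed$min); free_amp <- is.null(fixed$amp)
  resid_fun <- function(p) {
    mn <- if (free_min) p[["min"]] else fixed$min
    am <- if (free_amp) p[["amp"]] else fixed$amp
    responses - hill_model(doses, mn, am, exp(p[["lIC50"]]), p[["nH"]])
  }
  lb <- c(lIC50 = log(min(pos)) - log(1e4), nH = 0.05)
  ub <- c(lIC50 = log(max(pos)) + log(1e4), nH = 20)
  if (free_min) { lb <- c(min = -Inf, lb); ub <- c(min = Inf, ub) }
  if (free_amp) { lb <- c(amp = 0, lb); ub <- c(amp = Inf, ub) }
  best <- NULL
  for (nh0 in c(0.5, 1, 2, 4)) {
    p0 <- c(lIC50 = lic0, nH = nh0)
    if (free_amp) p0 <- c(amp = amp0, p0)
    if (free_min) p0 <- c(min = min0, p0)
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fun, lower = lb[names(p0)], upper = ub[names(p0)],
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-15, ptol = 1e-15)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ss <- sum(fit$fvec^2)
    tiny <- if (is.null(best)) 0 else 1e-12 * (1 + best$ss)
    if (is.null(best) || ss < best$ss - tiny ||
        (abs(ss - best$ss) <= tiny && fit$par[["nH"]] < best$fit$par[["nH"]]))
      best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  p <- best$fit$par
  params <- list(
    min = if (free_min) p[["min"]] else fixed$min,
    amp = if (free_amp) p[["amp"]] else fixed$amp,
    IC50 = exp(p[["lIC50"]]), nH = p[["nH"]])
  n <- length(responses); k <- length(p)
  sigma2 <- best$ss / max(n - k, 1)
  se <- rep(NA_real_, k); names(se) <- names(p)
  covm <- try(solve(best$fit$hessian) * sigma2, silent = TRUE)
  if (!inherits(covm, "try-error")) se <- sqrt(pmax(diag(covm), 0))
  # IC50 unidentifiable when the amplitude collapses or the IC50
  # uncertainty spans the whole dose grid
  converged <- best$fit$info %in% 1:4 &&
    params$amp > 1e-8 * max(abs(responses), 1) &&
    (!is.na(se[["lIC50"]]) && se[["lIC50"]] < log(1e4))
  structure(list(params = params, se = se,
                 residual_rms = sqrt(best$ss / n),
                 converged = converged,
                 predict = function(X) hill_model(X, params$min, params$amp,
                                                 params$IC50, params$nH)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> min=%.4g amp=%.4g IC50=%.4g uM nH=%.3g (RMS %.3g%s)\n",
    x$params$min, x$params$amp, x$params$IC50, x$params$nH,
    x$residual_rms, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Invert the ERK Hill curve: dose implied by an observed ERK ratio
#'
#' \deqn{X = \left( \frac{amp \cdot IC50^{nH}}{ERK - min} -
#'   IC50^{nH} \right)^{1/nH}}
#' Defined only for ERK strictly inside `(min, min + amp)`; an
#' admissibility guard of `1e-9 * amp` (relative) is applied at both
#' ends.
#'
#' @param erk observed ERK ratio(s).
#' @param min,amp,IC50,nH ERK Hill parameters.
#' @return Implied dose(s); `NA` where inadmissible.
#' @export
dose_from_erk <- function(erk, min, amp, IC50, nH) {
  eps <- 1e-9 * amp
  ok <- erk > min + eps & erk < min + amp - eps
  x <- rep(NA_real_, length(erk))
  x[ok] <- (amp * IC50^nH / (erk[ok] - min) - IC50^nH)^(1 / nH)
  x
}

#' Fit the coupled ERK-activity / live-cell dose-response model
#'
#' The multiplexed plate assay reads two quantities per well: the BRET
#' ratio (ERK activity) and the total luminescence (live-cell proxy),
#' both Hill functions of the drug dose `X` with shared dose axis:
#' live cells follow a decreasing Hill in `X`, and `X` itself can be
#' recovered from the observed ERK ratio through the inverse ERK Hill
#' ([dose_from_erk()]). The minima and amplitudes of both curves are
#' supplied fixed (they are read off the assay plateaus unambiguously);
#' the two IC50s and Hill coefficients are free.
#'
#' Estimation is staged to keep every parameter identifiable:
#' `(IC50_ERK, nH_ERK)` are fitted from the ERK-vs-dose curve; then each
#' well's implied dose is computed from its ERK value via the inverse
#' ERK Hill (wells with ERK outside the admissible open interval are
#' excluded and counted), and `(IC50_L, nH_L)` minimize the SSE of the
#' live-cell counts against the live Hill at those implied doses. From
#' ERK/live pairs alone (no doses) only the ratio `IC50_ERK/IC50_L` and
#' `nH_L/nH_ERK` are identifiable, which is why the dose column is
#' required; see the methods vignette.
#'
#' @param erk_ratios per-well ERK (BRET) ratios.
#' @param live_counts per-well total luminescence counts.
#' @param doses per-well doses (uM), same length.
#' @param fixed named list with `min_ERK`, `amp_ERK`, `min_L`, `amp_L`.
#' @return A `coupled_fit`: `IC50_ERK`, `nH_ERK`, `IC50_L`, `nH_L`,
#'   `n_excluded`, component `hill_fit`s, and `live_vs_erk(erk)` giving
#'   the predicted live-vs-ERK correlation curve.
#' @export
coupled_fit <- function(erk_ratios, live_counts, doses, fixed) {
  stopifnot(length(erk_ratios) == length(live_counts),
            length(doses) == length(erk_ratios))
  need <- c("min_ERK", "amp_ERK", "min_L", "amp_L")
  miss <- setdiff(need, names(fixed))
  if (length(miss))
    stop("fixed must supply: ", paste(miss, collapse = ", "))
  erk_fit <- hill_fit(doses, erk_ratios,
                      fixed = list(min = fixed$min_ERK, amp = fixed$amp_ERK))
  x_hat <- dose_from_erk(erk_ratios, fixed$min_ERK, fixed$amp_ERK,
                         erk_fit$params$IC50, erk_fit$params$nH)
  ok <- !is.na(x_hat)
  n_excl <- sum(!ok)
  if (n_excl > 0)
    message(sprintf(
      "coupled_fit: %d well(s) with ERK outside (min, min+amp) excluded",
      n_excl))
  if (sum(ok) < 4) stop("too few admissible wells for the live-cell fit")
  live_fit <- hill_fit(x_hat[ok], live_counts[ok],
                       fixed = list(min = fixed$min_L, amp = fixed$amp_L))
  live_vs_erk <- function(erk) {
    x <- dose_from_erk(erk, fixed$min_ERK, fixed$amp_ERK,
                       erk_fit$params$IC50, erk_fit$params$nH)
    hill_model(x, fixed$min_L, fixed$amp_L,
               live_fit$params$IC50, live_fit$params$nH)
  }
  structure(list(
    IC50_ERK = erk_fit$params$IC50, nH_ERK = erk_fit$params$nH,
    IC50_L = live_fit$params$IC50, nH_L = live_fit$params$nH,
    fixed = fixed, n_excluded = n_excl,
    erk_fit = erk_fit, live_fit = live_fit,
    live_vs_erk = live_vs_erk,
    converged = erk_fit$converged && live_fit$converged
  ), class = "coupled_fit")
}

#' @export
print.coupled_fit <- function(x, ...) {
  cat(sprintf(
    "<coupled_fit> IC50_ERK=%.4g uM (nH %.3g); IC50_L=%.4g uM (nH %.3g)\n",
    x$IC50_ERK, x$nH_ERK, x$IC50_L, x$nH_L))
  if (x$n_excluded)
    cat("  excluded wells (inadmissible ERK):", x$n_excluded, "\n")
  invisible(x)
}
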