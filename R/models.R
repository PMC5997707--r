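#' Energy-transfer parameters
#'
#' Fractional energy-transfer rates between the emitters of a hyBRET
#' biosensor: `E_CY` (CFP to YFP FRET efficiency), `E_RC` (RLuc8 to CFP
#' BRET efficiency), `E_RY` (direct RLuc8 to YFP), and the NanoLuc
#' analogues `E_NC`, `E_NY`. `amplitude` is an overall positive scale so
#' the forward models can describe raw-count spectra; the published model
#' equations omit it because only branch ratios carry information.
#'
#' @param E_CY,E_RC,E_RY,E_NC,E_NY transfer rates in `[0, 1]`;
#'   `E_RC + E_RY <= 1` and `E_NC + E_NY <= 1` (the residual donor branch
#'   weight must be nonnegative).
#' @param amplitude positive overall scale.
#' @return An object of class `transfer_params`.
#' @export
transfer_params <- function(E_CY = 0, E_RC = 0, E_RY = 0,
                            E_NC = 0, E_NY = 0, amplitude = 1) {
  p <- list(E_CY = E_CY, E_RC = E_RC, E_RY = E_RY,
            E_NC = E_NC, E_NY = E_NY, amplitude = amplitude)
  for (nm in c("E_CY", "E_RC", "E_RY", "E_NC", "E_NY")) {
    v <- p[[nm]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("%s = %g outside [0, 1]", nm, v))
  }
  if (p$E_RC + p$E_RY > 1 + 1e-12)
    stop("E_RC + E_RY > 1: negative residual luciferase branch")
  if (p$E_NC + p$E_NY > 1 + 1e-12)
    stop("E_NC + E_NY > 1: negative residual luciferase branch")
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("amplitude must be positive")
  structure(p, class = "transfer_params")
}

#' Forward fluorescence emission model
#'
#' Steady-state branch-ratio model of the biosensor fluorescence spectrum
#' under donor excitation:
#' \deqn{F(\lambda) = \epsilon_C [(1 - E_{CY}) \phi_C f_C(\lambda) +
#'   E_{CY} \phi_Y f_Y(\lambda)] + \epsilon_Y \phi_Y f_Y(\lambda)}
#' with `eps_C = 1` (relative units) and the YFP cross-excitation weight
#' `eps_Y = cross_excitation_fraction * eps_ratio`. The result is scaled by
#' `params$amplitude`. An optional per-wavelength weight vector can stand in
#' for an instrument response; the default is uniform.
#'
#' @param basis a [reference_basis()].
#' @param params a [transfer_params()].
#' @param grid wavelength grid; must lie within the basis support.
#' @param response optional per-wavelength multiplicative weights
#'   (length of `grid`).
#' @return A `spectrum` with `mode = "fluorescence"`.
#' @export
fluorescence_model <- function(basis, params, grid = basis$grid,
                               response = NULL) {
  stopifnot(inherits(basis, "reference_basis"),
            inherits(params, "transfer_params"))
  fC <- interp_spectrum(basis_shape(basis, "f_C"), grid)$intensity
  fY <- interp_spectrum(basis_shape(basis, "f_Y"), grid)$intensity
  eps_C <- 1
  eps_Y <- basis$cross_excitation_fraction * basis$eps_ratio
  y <- eps_C * ((1 - params$E_CY) * basis$phi$C * fC +
                  params$E_CY * basis$phi$Y * fY) +
    eps_Y * basis$phi$Y * fY
  y <- params$amplitude * y
  if (!is.null(response)) {
    stopifnot(length(response) == length(grid))
    y <- y * response
  }
  spectrum(grid, y, meta = list(mode = "fluorescence"))
}

#' Forward bioluminescence emission model
#'
#' Branch-ratio model of the biosensor bioluminescence spectrum. Each
#' catalytic event on the luciferase partitions into three emission
#' branches: transfer to CFP without onward FRET, arrival at YFP (direct
#' plus CFP-mediated), and residual luciferase emission:
#' \deqn{B(\lambda) = E_{RC}(1 - E_{CY}) \phi_C f_C +
#'   (E_{RY} + E_{RC} E_{CY}) \phi_Y f_Y +
#'   (1 - E_{RC} - E_{RY}) \phi_R f_R}
#' scaled by `params$amplitude`. With `donor = "nanoluc"` the NanoLuc
#' analogues `E_NC`, `E_NY`, `phi$N`, `f_N` are substituted.
#'
#' @inheritParams fluorescence_model
#' @param donor `"rluc8"` or `"nanoluc"`.
#' @return A `spectrum` with `mode = "bioluminescence"`.
#' @export
bioluminescence_model <- function(basis, params, grid = basis$grid,
                                  donor = c("rluc8", "nanoluc"),
                                  response = NULL) {
  stopifnot(inherits(basis, "reference_basis"),
            inherits(params, "transfer_params"))
  donor <- match.arg(donor)
  if (donor == "rluc8") {
    E_DC <- params$E_RC; E_DY <- params$E_RY
    phi_D <- basis$phi$R
    fD <- interp_spectrum(basis_shape(basis, "f_R"), grid)$intensity
  } else {
    E_DC <- params$E_NC; E_DY <- params$E_NY
    if (is.null(basis$phi$N))
      stop("reference basis is missing required constant 'phi$N'")
    phi_D <- basis$phi$N
    fD <- interp_spectrum(basis_shape(basis, "f_N"), grid)$intensity
  }
  if (E_DC + E_DY > 1 + 1e-12)
    stop("donor transfer rates sum above 1: negative residual branch")
  fC <- interp_spectrum(basis_shape(basis, "f_C"), grid)$intensity
  fY <- interp_spectrum(basis_shape(basis, "f_Y"), grid)$intensity
  w <- branch_weights(E_DC, params$E_CY, E_DY)
  y <- params$amplitude *
    (w[["donor_to_cfp"]] * basis$phi$C * fC +
       w[["to_yfp"]] * basis$phi$Y * fY +
       w[["residual"]] * phi_D * fD)
  if (!is.null(response)) {
    stopifnot(length(response) == length(grid))
    y <- y * response
  }
  spectrum(grid, y, meta = list(mode = "bioluminescence", donor = donor))
}

# The three branch weights of the bioluminescence model; they always sum
# to 1 exactly because the yellow weight absorbs E_DC*E_CY.
branch_weights <- function(E_DC, E_CY, E_DY) {
  E_DC <- unname(E_DC); E_CY <- unname(E_CY); E_DY <- unname(E_DY)
  c(donor_to_cfp = E_DC * (1 - E_CY),
    to_yfp = E_DY + E_DC * E_CY,
    residual = 1 - E_DC - E_DY)
}

#' Solve for the RLuc8-to-CFP BRET efficiency from quantum efficiencies
#'
#' The quantum efficiency of the cyan Nano-lantern fusion is the
#' transfer-weighted mixture `phi_CNL = phi_C * E_RC + phi_R * (1 - E_RC)`;
#' this inverts it:
#' \deqn{E_{RC} = (\phi_{CNL} - \phi_R) / (\phi_C - \phi_R)}
#'
#' @param phi_CNL quantum efficiency of the luciferase-CFP fusion.
#' @param phi_C quantum efficiency of CFP.
#' @param phi_R quantum efficiency of the luciferase.
#' @return `E_RC` in `[0, 1]`; a result outside that range is an error
#'   (inconsistent photophysics), never clipped.
#' @export
solve_E_RC <- function(phi_CNL, phi_C, phi_R) {
  for (v in c(phi_CNL = phi_CNL, phi_C = phi_C, phi_R = phi_R))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("quantum efficiencies must lie in [0, 1]")
  if (phi_C == phi_R)
    stop("phi_C equals phi_R: E_RC is unidentifiable from quantum efficiencies")
  e <- (phi_CNL - phi_R) / (phi_C - phi_R)
  if (e < 0 || e > 1)
    stop(sprintf(
      "E_RC = %.4g outside [0, 1]: inconsistent quantum efficiencies", e))
  e
}

#' Decompose the yellow-emission pathways of the BRET mode
#'
#' Splits the energy leaving the luciferase into the direct RLuc8-to-YFP
#' route (`direct_RY = E_RY`), the CFP-mediated route
#' (`CFP_mediated_RY = E_RC * E_CY`), and the residual donor emission
#' (`donor_residual = 1 - E_RC - E_RY`).
#'
#' @param params a [transfer_params()].
#' @return Named list with `direct_RY`, `CFP_mediated_RY`, `donor_residual`.
#' @export
pathway_decomposition <- function(params) {
  stopifnot(inherits(params, "transfer_params"))
  list(direct_RY = params$E_RY,
       CFP_mediated_RY = params$E_RC * params$E_CY,
       donor_residual = 1 - params$E_RC - params$E_RY)
}
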