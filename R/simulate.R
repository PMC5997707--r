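#' Parametric stand-in reference emission shapes
#'
#' Builds area-normalized emission shapes for the component emitters as
#' two-Gaussian mixtures: smooth, integrable curves qualitatively matched
#' to the real emission spectra (CFP peaked near 475 nm with a ~500 nm
#' shoulder, YFP near 527 nm, RLuc8 broad around 480 nm, NanoLuc broad
#' around 460 nm). Fully deterministic: the shapes are closed-form
#' functions of the configuration, so repeated calls are identical.
#' Measured reference tables can be dropped in instead via
#' [read_spectrum()].
#'
#' @param grid wavelength grid (nm).
#' @param shapes named list of per-emitter mixture parameters; each entry
#'   is `list(mu = c(..), sd = c(..), w = c(..))`.
#' @return List with `spectrum` elements `f_C`, `f_Y`, `f_R`, `f_N`, each
#'   of unit trapezoidal area, plus the `shapes` used.
#' @export
gen_reference_basis <- function(grid = default_grid(), shapes = NULL) {
  if (is.null(shapes)) shapes <- list(
    f_C = list(mu = c(475, 503), sd = c(13, 24), w = c(0.67, 0.33)),
    f_Y = list(mu = c(527, 560), sd = c(11, 26), w = c(0.74, 0.26)),
    f_R = list(mu = c(480, 530), sd = c(28, 40), w = c(0.75, 0.25)),
    f_N = list(mu = c(460, 505), sd = c(24, 38), w = c(0.78, 0.22)))
  mix <- function(p) {
    y <- rep(0, length(grid))
    for (i in seq_along(p$mu))
      y <- y + p$w[i] * stats::dnorm(grid, p$mu[i], p$sd[i])
    sp <- spectrum(grid, y)
    normalize_area(sp)
  }
  out <- lapply(shapes, mix)
  out$shapes <- shapes
  out
}

#' Generate a synthetic biosensor emission spectrum with known truth
#'
#' Evaluates the forward fluorescence or bioluminescence model for a known
#' set of transfer rates, scales it so the noiseless curve peaks at
#' `peak_counts`, and adds photon noise. The generating truth is returned
#' alongside the spectrum so round-trip fitting tests have an oracle.
#'
#' @param basis a [reference_basis()].
#' @param truth a [transfer_params()] (its `amplitude` is overridden by
#'   the peak scaling).
#' @param mode `"fluorescence"` or `"bioluminescence"`.
#' @param donor donor for bioluminescence mode.
#' @param noise `"none"`, `"poisson"`, or `"gaussian"`.
#' @param peak_counts peak of the noiseless curve (counts).
#' @param sigma Gaussian noise SD (counts), for `noise = "gaussian"`.
#' @param seed RNG seed; the same seed reproduces the array exactly.
#' @return List with `spectrum` and `truth` (the manifest: transfer rates,
#'   effective amplitude, noise settings, seed).
#' @export
gen_biosensor_spectrum <- function(basis, truth,
                                   mode = c("fluorescence",
                                            "bioluminescence"),
                                   donor = c("rluc8", "nanoluc"),
                                   noise = c("none", "poisson", "gaussian"),
                                   peak_counts = 1e4, sigma = 50, seed = 1) {
  mode <- match.arg(mode)
  donor <- match.arg(donor)
  noise <- match.arg(noise)
  clean <- if (mode == "fluorescence")
    fluorescence_model(basis, truth) else
      bioluminescence_model(basis, truth, donor = donor)
  scale <- peak_counts / max(clean$intensity)
  y <- clean$intensity * scale
  set.seed(seed)
  y_noised <- switch(noise,
    none = y,
    poisson = stats::rpois(length(y), y),
    gaussian = pmax(y + stats::rnorm(length(y), 0, sigma), 0))
  list(
    spectrum = spectrum(clean$wavelength_nm, y_noised,
                        meta = list(mode = mode, synthetic = TRUE)),
    truth = list(E_CY = truth$E_CY, E_RC = truth$E_RC, E_RY = truth$E_RY,
                 E_NC = truth$E_NC, E_NY = truth$E_NY,
                 amplitude = truth$amplitude * scale,
                 mode = mode, donor = donor, noise = noise,
                 peak_counts = peak_counts, seed = seed))
}

#' Generate a synthetic dual-channel ratio image stack with known truth
#'
#' Emulates time-lapse BRET imaging of cells: elliptical cells placed in
#' the field, each with its own true yellow/cyan ratio drawn uniformly
#' from `ratio_range` (the in vivo BRET ratio spread), channel
#' intensities decaying exponentially with the configured substrate
#' half-life applied commonly to both channels, constant background,
#' Poisson photon noise, and single-pixel cosmic-ray spikes at
#' `spike_rate`. The truth manifest records per-cell ratios and spike
#' coordinates, so every downstream stage has an oracle. Overlapping
#' cells are allowed (later cells overwrite).
#'
#' @param H,W,T field size (pixels) and number of frames.
#' @param n_cells number of cells.
#' @param ratio_range range of true per-cell yellow/cyan ratios.
#' @param cell_intensity peak cyan counts of a cell at t = 0.
#' @param background constant background counts added to both channels.
#' @param spike_rate per-pixel probability of a cosmic-ray spike.
#' @param spike_counts spike magnitude (counts).
#' @param half_life_min substrate decay half-life in minutes (Inf = no
#'   decay); the decay multiplies both channels identically.
#' @param frame_interval_min minutes between frames.
#' @param noise `"poisson"` or `"none"`.
#' @param seed RNG seed.
#' @return List with `stack` (a [ratio_stack()] with `$labels`), and
#'   `truth` (per-cell ratios, spike coordinates, decay factors, config).
#' @export
gen_ratio_stack <- function(H = 96, W = 96, T = 10, n_cells = 5,
                            ratio_range = c(0.35, 0.65),
                            cell_intensity = 2000, background = 100,
                            spike_rate = 1e-4, spike_counts = 1e5,
                            half_life_min = 9, frame_interval_min = 1,
                            noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  set.seed(seed)
  labels <- matrix(0L, H, W)
  centers <- cbind(stats::runif(n_cells, H * 0.15, H * 0.85),
                   stats::runif(n_cells, W * 0.15, W * 0.85))
  axes <- cbind(stats::runif(n_cells, H * 0.06, H * 0.12),
                stats::runif(n_cells, W * 0.06, W * 0.12))
  rr <- row(labels); cc <- col(labels)
  for (i in seq_len(n_cells)) {
    inside <- ((rr - centers[i, 1]) / axes[i, 1])^2 +
      ((cc - centers[i, 2]) / axes[i, 2])^2 <= 1
    labels[inside] <- i
  }
  true_ratio <- stats::runif(n_cells, ratio_range[1], ratio_range[2])
  times <- (seq_len(T) - 1) * frame_interval_min
  decay <- if (is.finite(half_life_min)) 0.5^(times / half_life_min)
  else rep(1, T)
  cyan0 <- matrix(0, H, W); yellow0 <- matrix(0, H, W)
  for (i in seq_len(n_cells)) {
    sel <- labels == i
    cyan0[sel] <- cell_intensity
    yellow0[sel] <- cell_intensity * true_ratio[i]
  }
  cyan <- array(0, c(H, W, T)); yellow <- array(0, c(H, W, T))
  spikes <- NULL
  for (t in seq_len(T)) {
    cy <- cyan0 * decay[t] + background
    ye <- yellow0 * decay[t] + background
    if (noise == "poisson") {
      cy <- matrix(stats::rpois(H * W, cy), H, W)
      ye <- matrix(stats::rpois(H * W, ye), H, W)
    }
    if (spike_rate > 0) {
      for (ch in c("cy", "ye")) {
        hit <- which(stats::runif(H * W) < spike_rate)
        if (length(hit)) {
          m <- get(ch)
          m[hit] <- spike_counts
          assign(ch, m)
          spikes <- rbind(spikes, cbind(
            frame = t, channel = match(ch, c("cy", "ye")),
            pixel = hit))
        }
      }
    }
    cyan[, , t] <- cy
    yellow[, , t] <- ye
  }
  list(
    stack = ratio_stack(cyan, yellow, labels = labels),
    truth = list(ratio = true_ratio, labels = labels, spikes = spikes,
                 decay = decay, background = background,
                 cell_intensity = cell_intensity,
                 half_life_min = half_life_min,
                 frame_interval_min = frame_interval_min,
                 noise = noise, seed = seed))
}

#' Generate a synthetic dose-response plate with known truth
#'
#' Per-well ERK (BRET) ratio and total luminescence from the coupled
#' dose-response model: the ERK ratio follows a decreasing Hill in dose,
#' the total counts (live-cell proxy) follow a second decreasing Hill,
#' and both readouts receive independent multiplicative log-normal noise
#' of the given coefficient of variation (the well-to-well noise of a
#' luminescence plate reader). Each total is split into cyan and yellow
#' counts consistent with the well's ERK ratio.
#'
#' @param doses dose grid (uM); each dose is replicated `replicates`
#'   times. A zero dose is admissible.
#' @param replicates wells per dose.
#' @param erk_params named list (`min`, `amp`, `IC50`, `nH`) for the ERK
#'   ratio curve.
#' @param live_params named list for the total-counts curve.
#' @param cv multiplicative noise coefficient of variation (0.02 = 2%).
#' @param seed RNG seed.
#' @return List with `plate` (data frame: `well_id`, `condition`, `dose`,
#'   `cyan`, `yellow`, `bret_ratio`, `total`) and `truth`.
#' @export
gen_plate <- function(doses = c(0, 10^seq(-3, 0.5, length.out = 9)),
                      replicates = 2,
                      erk_params = list(min = 0.30, amp = 0.30,
                                        IC50 = 0.015, nH = 1),
                      live_params = list(min = 1000, amp = 9000,
                                         IC50 = 0.028, nH = 1.5),
                      cv = 0.02, seed = 1) {
  set.seed(seed)
  dose_w <- rep(doses, each = replicates)
  n <- length(dose_w)
  erk_true <- hill_model(dose_w, erk_params$min, erk_params$amp,
                         erk_params$IC50, erk_params$nH)
  live_true <- hill_model(dose_w, live_params$min, live_params$amp,
                          live_params$IC50, live_params$nH)
  lnoise <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)  # unit mean
  }
  erk <- erk_true * lnoise(n, cv)
  total <- live_true * lnoise(n, cv)
  cyan <- total / (1 + erk)
  yellow <- total - cyan
  plate <- data.frame(
    well_id = sprintf("%s%02d", LETTERS[(seq_len(n) - 1) %/% 12 + 1],
                      (seq_len(n) - 1) %% 12 + 1),
    condition = "drug", dose = dose_w,
    cyan = cyan, yellow = yellow)
  plate$bret_ratio <- plate$yellow / plate$cyan
  plate$total <- plate$cyan + plate$yellow
  list(plate = plate,
       truth = list(erk_params = erk_params, live_params = live_params,
                    cv = cv, seed = seed, doses = doses,
                    replicates = replicates))
}

#' Generate a two-group Z-prime validation plate
#'
#' Untreated and reference-dose wells with normal well-to-well spread,
#' matching the screening protocol of the luminescence assay (three wells
#' per group by default).
#'
#' @param n_wells wells per group.
#' @param mean_neg,mean_pos group mean BRET ratios (untreated, treated).
#' @param sd_well per-group well SD.
#' @param seed RNG seed.
#' @return List with `neg`, `pos` ratio vectors and `truth` (the
#'   population Z').
#' @export
gen_zprime_plate <- function(n_wells = 3, mean_neg = 1.0, mean_pos = 0.6,
                             sd_well = 0.0047, seed = 1) {
  set.seed(seed)
  list(neg = stats::rnorm(n_wells, mean_neg, sd_well),
       pos = stats::rnorm(n_wells, mean_pos, sd_well),
       truth = list(
         zprime_population =
           1 - 3 * (sd_well + sd_well) / (mean_neg - mean_pos),
         mean_neg = mean_neg, mean_pos = mean_pos,
         sd_well = sd_well, n_wells = n_wells, seed = seed))
}
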