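#' Dual-channel ratio image stack
#'
#' Container for a registered dual-channel luminescence/fluorescence time
#' series. Arrays are `H x W x T` (each `[, , t]` slice is one frame,
#' origin top-left); the two channels are assumed registered by the
#' splitter optics, no subpixel registration is attempted. The ratio map
#' (yellow/cyan) is filled in by [compute_ratio()]; in BRET mode the cyan
#' channel physically contains both CFP and luciferase emission, so the
#' same yellow/cyan operation yields the BRET ratio.
#'
#' @param cyan,yellow numeric arrays `H x W x T` (a matrix is promoted to
#'   a single frame), nonnegative counts.
#' @param background optional per-channel scalar or length-`T` vector of
#'   background levels already known (e.g. from a dark region); estimated
#'   during preprocessing when `NULL`.
#' @param labels optional `H x W` integer matrix of cell regions
#'   (0 = background).
#' @return An object of class `ratio_stack`.
#' @export
ratio_stack <- function(cyan, yellow, background = NULL, labels = NULL) {
  as_stack_array <- function(x, nm) {
    if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
    if (!is.array(x) || length(dim(x)) != 3L)
      stop(sprintf("%s must be an H x W x T array", nm))
    if (any(!is.finite(x)) || any(x < 0))
      stop(sprintf("%s must be finite and nonnegative", nm))
    x
  }
  cyan <- as_stack_array(cyan, "cyan")
  yellow <- as_stack_array(yellow, "yellow")
  if (!identical(dim(cyan), dim(yellow)))
    stop("cyan and yellow channel dimensions differ")
  if (!is.null(labels) && !identical(dim(labels), dim(cyan)[1:2]))
    stop("labels must be an H x W matrix matching the frames")
  structure(list(cyan = cyan, yellow = yellow, background = background,
                 labels = labels, mask = NULL, ratio = NULL,
                 intensity = NULL),
            class = "ratio_stack")
}

#' @export
print.ratio_stack <- function(x, ...) {
  d <- dim(x$cyan)
  cat(sprintf("<ratio_stack> %d x %d px, %d frame(s)%s%s\n", d[1], d[2], d[3],
              if (!is.null(x$ratio)) ", ratio computed" else "",
              if (!is.null(x$labels))
                sprintf(", %d labelled cells", max(x$labels)) else ""))
  invisible(x)
}

# Exact spatial median filter over a (2r+1)^2 window with edge replication.
# Written in-package: the constant-time approximate filters quantize
# intensities, which would perturb the count arithmetic asserted exactly
# in the pipeline tests.
median_filter2 <- function(m, radius) {
  if (radius <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  idx_r <- pmin(pmax(seq_len(h + 2 * radius) - radius, 1L), h)
  idx_c <- pmin(pmax(seq_len(w + 2 * radius) - radius, 1L), w)
  pad <- m[idx_r, idx_c, drop = FALSE]
  k <- 2L * radius + 1L
  vals <- matrix(NA_real_, h * w, k * k)
  j <- 0L
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
    j <- j + 1L
    vals[, j] <- as.vector(pad[dr + seq_len(h), dc + seq_len(w)])
  }
  matrix(apply(vals, 1L, stats::median), h, w)
}

# Histogram-mode background: most frequent rounded count among the darkest
# quartile of pixels in a frame.
estimate_background <- function(frame, dark_fraction = 0.25) {
  v <- as.vector(frame)
  cut <- stats::quantile(v, dark_fraction, names = FALSE)
  dark <- v[v <= cut]
  tab <- table(round(dark))
  as.numeric(names(tab)[which.max(tab)])
}

#' Preprocess a dual-channel stack: spike removal, denoising, background
#' subtraction
#'
#' Per channel and frame: (1) cosmic-ray removal -- each pixel is compared
#' to its 3x3 spatial median and replaced by it when the robust z-score
#' (deviation over 1.4826 x median absolute deviation of all such
#' deviations in the frame) exceeds `spike_z`; a single-frame spatial test
#' is used because luminescence exposures are long and frames few.
#' (2) A spatial median filter of radius `filter_radius` (0 = off)
#' standing in for proprietary denoising software. (3) Background
#' subtraction: the supplied per-channel scalar, or else the histogram
#' mode of the darkest 25% of pixels, estimated per channel per frame;
#' negative results are clipped to 0.
#'
#' @param stack a [ratio_stack()].
#' @param spike_z robust z threshold for spike replacement (`Inf`
#'   disables).
#' @param filter_radius median filter radius in pixels.
#' @param background optional named list `list(cyan=, yellow=)` of scalars
#'   or length-`T` vectors overriding estimation; `stack$background` is
#'   used if set.
#' @return A preprocessed `ratio_stack`; the applied backgrounds are
#'   recorded in `$background`.
#' @export
preprocess_stack <- function(stack, spike_z = 8, filter_radius = 0,
                             background = NULL) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (is.null(background)) background <- stack$background
  d <- dim(stack$cyan)
  applied <- list()
  for (ch in c("cyan", "yellow")) {
    a <- stack[[ch]]
    if (all(a == 0)) stop(sprintf("channel '%s' is all zero", ch))
    bg_ch <- if (!is.null(background)) background[[ch]] else NULL
    bg_used <- numeric(d[3])
    for (t in seq_len(d[3])) {
      fr <- a[, , t]
      if (is.finite(spike_z)) {
        med3 <- median_filter2(fr, 1L)
        dev <- fr - med3
        s <- 1.4826 * stats::median(abs(dev))
        if (s > 0) {
          hit <- abs(dev) / s > spike_z
          fr[hit] <- med3[hit]
        }
      }
      if (filter_radius > 0) fr <- median_filter2(fr, as.integer(filter_radius))
      bg <- if (!is.null(bg_ch)) {
        if (length(bg_ch) == 1L) bg_ch else bg_ch[t]
      } else estimate_background(fr)
      fr <- pmax(fr - bg, 0)
      bg_used[t] <- bg
      a[, , t] <- fr
    }
    stack[[ch]] <- a
    applied[[ch]] <- bg_used
  }
  stack$background <- applied
  stack
}

#' Compute the yellow/cyan ratio map
#'
#' Per-pixel yellow over cyan, defined only where the denominator channel
#' reaches `min_denominator` counts (the foreground mask). The identical
#' operation serves FRET (FRET/CFP) and BRET modes; in BRET mode the
#' denominator physically contains the summed CFP and luciferase
#' emission.
#'
#' @param stack a preprocessed [ratio_stack()].
#' @param min_denominator minimum cyan counts for a pixel to enter the
#'   mask.
#' @return The stack with `$ratio` (`NA` outside the mask), `$mask`, and
#'   `$intensity` (per-pixel mean of the two channels) filled in.
#' @export
compute_ratio <- function(stack, min_denominator = 0) {
  stopifnot(inherits(stack, "ratio_stack"))
  mask <- stack$cyan >= min_denominator & stack$cyan > 0
  if (!any(mask)) warning("ratio mask is empty")
  ratio <- array(NA_real_, dim(stack$cyan))
  ratio[mask] <- stack$yellow[mask] / stack$cyan[mask]
  stack$mask <- mask
  stack$ratio <- ratio
  stack$intensity <- (stack$cyan + stack$yellow) / 2
  stack
}

#' Eight-hue blue-to-red lookup table for IMD rendering
#' @return Character vector of 8 colors ordered low (blue) to high (red).
#' @export
imd_lut <- function() {
  grDevices::colorRampPalette(
    c("#0000FF", "#00BFFF", "#00FFBF", "#00FF00",
      "#BFFF00", "#FFFF00", "#FF7F00", "#FF0000"))(8)
}

#' Intensity-modulated display (IMD) rendering of a ratio stack
#'
#' Maps the ratio into one of exactly eight hue bins spanning
#' `[r_min, r_max]` (uniform bin edges, out-of-range values clipped to the
#' end bins, blue = low to red = high) and modulates brightness by the
#' mean of the two channel intensities, linearly rescaled over a
#' percentile window. Pixels outside the mask are black.
#'
#' @param stack a stack with the ratio computed.
#' @param r_min,r_max display ratio range (`r_min < r_max`).
#' @param p_lo,p_hi intensity percentile window for brightness scaling.
#' @return An `imd_rendering`: `color_index` (`H x W x T`, integer 0-7,
#'   `NA` outside mask), `brightness` in `[0, 1]`, and `rgb`
#'   (`H x W x 3 x T`).
#' @export
render_imd <- function(stack, r_min, r_max, p_lo = 0.01, p_hi = 0.99) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (is.null(stack$ratio)) stop("compute_ratio() first")
  if (r_min >= r_max) stop("r_min must be less than r_max")
  idx <- floor((stack$ratio - r_min) / (r_max - r_min) * 8)
  idx[idx < 0] <- 0L
  idx[idx > 7] <- 7L
  q <- stats::quantile(stack$intensity[stack$mask],
                       c(p_lo, p_hi), names = FALSE, na.rm = TRUE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  bright <- pmin(pmax((stack$intensity - q[1]) / (q[2] - q[1]), 0), 1)
  bright[!stack$mask] <- 0
  lut <- t(grDevices::col2rgb(imd_lut()) / 255)
  d <- dim(stack$ratio)
  rgb <- array(0, c(d[1], d[2], 3L, d[3]))
  for (t in seq_len(d[3])) {
    it <- idx[, , t]
    bt <- bright[, , t]
    ok <- !is.na(it)
    for (k in 1:3) {
      plane <- matrix(0, d[1], d[2])
      plane[ok] <- lut[it[ok] + 1L, k] * bt[ok]
      rgb[, , k, t] <- plane
    }
  }
  structure(list(color_index = idx, brightness = bright, rgb = rgb,
                 r_min = r_min, r_max = r_max, lut = imd_lut()),
            class = "imd_rendering")
}

#' Write one frame of an IMD rendering to a PNG file
#'
#' @param imd an `imd_rendering`.
#' @param path output PNG path.
#' @param frame frame index.
#' @return `path`, invisibly.
#' @export
write_imd <- function(imd, path, frame = 1) {
  stopifnot(inherits(imd, "imd_rendering"))
  png::writePNG(imd$rgb[, , , frame], path)
  invisible(path)
}

#' Linear unmixing of two co-occurring luminophores
#'
#' Solves, per pixel, the 2x2 linear system `A %*% abundance = observed`
#' where the columns of the mixing matrix are the (cyan, yellow) channel
#' signatures of the two luminophores. Negative abundances are clipped to
#' 0 and the per-pixel residual norm after clipping is reported.
#'
#' @param stack a [ratio_stack()].
#' @param mixing_matrix 2x2 numeric, columns = luminophore signatures,
#'   rows = (cyan, yellow) channels; must be nonsingular.
#' @return List of `H x W x T` arrays: `abundance1`, `abundance2`,
#'   `residual`.
#' @export
unmix_two_luminophores <- function(stack, mixing_matrix) {
  stopifnot(inherits(stack, "ratio_stack"))
  A <- as.matrix(mixing_matrix)
  if (!identical(dim(A), c(2L, 2L))) stop("mixing matrix must be 2x2")
  if (abs(det(A)) < 1e-12) stop("mixing matrix is singular")
  Ainv <- solve(A)
  d <- dim(stack$cyan)
  obs <- rbind(as.vector(stack$cyan), as.vector(stack$yellow))
  ab <- Ainv %*% obs
  ab_clip <- pmax(ab, 0)
  res <- sqrt(colSums((A %*% ab_clip - obs)^2))
  list(abundance1 = array(ab_clip[1, ], d),
       abundance2 = array(ab_clip[2, ], d),
       residual = array(res, d))
}

#' Per-cell ratio traces from a labelled stack
#'
#' @param stack a stack with ratio computed and `$labels` set (or passed).
#' @param labels optional `H x W` label matrix overriding `stack$labels`.
#' @param stat summary statistic per cell per frame (default median).
#' @return Data frame with `frame`, `cell_id`, `ratio`.
#' @export
cell_traces <- function(stack, labels = NULL, stat = stats::median) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (is.null(stack$ratio)) stop("compute_ratio() first")
  if (is.null(labels)) labels <- stack$labels
  if (is.null(labels)) stop("no cell labels available")
  ids <- sort(unique(labels[labels > 0]))
  d <- dim(stack$ratio)
  out <- expand.grid(frame = seq_len(d[3]), cell_id = ids)
  out$ratio <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- labels == out$cell_id[i]
    r <- stack$ratio[, , out$frame[i]][sel]
    out$ratio[i] <- stat(r[!is.na(r)])
  }
  out
}

#' Normalize a per-cell trace to its pre-stimulation baseline
#'
#' Divides a ratio time course by the mean of the frames preceding the
#' stimulus, so the baseline of the output averages exactly 1.
#'
#' @param trace numeric time course.
#' @param baseline_frames integer indices of pre-stimulus frames.
#' @return Normalized trace.
#' @export
normalize_timecourse <- function(trace, baseline_frames) {
  if (!length(baseline_frames)) stop("baseline_frames must be nonempty")
  if (any(baseline_frames < 1 | baseline_frames > length(trace)))
    stop("baseline_frames outside trace")
  b <- mean(trace[baseline_frames])
  if (!is.finite(b) || b == 0) stop("baseline mean is zero or undefined")
  trace / b
}
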