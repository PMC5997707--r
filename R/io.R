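#' Read an emission spectrum from a CSV/TSV table
#'
#' Expected schema: header `wavelength_nm,intensity`, one row per grid
#' point; lines starting with `#` and blank lines are ignored. Malformed
#' rows and non-monotonic wavelength grids are hard errors naming the
#' offending line.
#'
#' @param path file path.
#' @param sep field separator (`","` default; `"\t"` for TSV).
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  body <- lines[keep]
  if (length(body) < 2) stop("spectrum file has no data rows: ", path)
  hdr <- tolower(gsub("\\s", "", body[1]))
  if (!identical(strsplit(hdr, sep, fixed = TRUE)[[1]][1:2],
                 c("wavelength_nm", "intensity")))
    stop(sprintf("%s line %d: expected header 'wavelength_nm%sintensity'",
                 path, lineno[1], sep))
  wl <- numeric(0); it <- numeric(0)
  for (i in seq_along(body)[-1]) {
    f <- strsplit(body[i], sep, fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2 || any(is.na(v[1:2])))
      stop(sprintf("%s line %d: malformed row '%s'",
                   path, lineno[i], body[i]))
    wl <- c(wl, v[1]); it <- c(it, v[2])
  }
  bad <- which(diff(wl) <= 0)
  if (length(bad))
    stop(sprintf(
      "%s line %d: wavelength %g not strictly increasing (duplicate or out of order)",
      path, lineno[bad[1] + 2L], wl[bad[1] + 1L]))
  spectrum(wl, it, meta = list(path = path))
}

#' Write a spectrum to CSV
#'
#' Values are printed with fixed precision so write-then-read round-trips
#' exactly at the printed precision.
#'
#' @param x a [spectrum()].
#' @param path output path.
#' @param digits significant digits for intensities.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, digits = 8) {
  stopifnot(inherits(x, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavelength_nm,intensity", con)
  writeLines(sprintf("%.10g,%s", x$wavelength_nm,
                     formatC(x$intensity, digits = digits, format = "g")),
             con)
  invisible(path)
}

#' Read a dual-channel image stack from TIFF files
#'
#' Either two single-channel multi-page TIFFs (`layout = "separate"`,
#' `paths = c(cyan, yellow)`) or one interleaved dual-channel TIFF
#' (`layout = "interleaved"`, pages alternating cyan, yellow; an odd page
#' count is a hard error). Pixel values are read as stored integers and
#' cast to numeric counts.
#'
#' @param paths one or two TIFF paths, per `layout`.
#' @param layout `"separate"` or `"interleaved"`.
#' @param channel_order for interleaved input, the channel of the first
#'   page.
#' @return A [ratio_stack()].
#' @export
read_stack <- function(paths, layout = c("separate", "interleaved"),
                       channel_order = c("cyan", "yellow")) {
  layout <- match.arg(layout)
  as_arr <- function(pages) {
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra samples
      p
    })
    d <- dim(pages[[1]])
    if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
      stop("TIFF pages have inconsistent dimensions")
    array(unlist(pages), c(d, length(pages)))
  }
  if (layout == "separate") {
    if (length(paths) != 2)
      stop("layout='separate' needs exactly two paths (cyan, yellow)")
    cy <- as_arr(tiff::readTIFF(paths[1], all = TRUE, as.is = TRUE))
    ye <- as_arr(tiff::readTIFF(paths[2], all = TRUE, as.is = TRUE))
    if (!identical(dim(cy), dim(ye)))
      stop("channel stacks have different shapes")
  } else {
    if (length(paths) != 1)
      stop("layout='interleaved' needs exactly one path")
    pages <- tiff::readTIFF(paths, all = TRUE, as.is = TRUE)
    if (length(pages) %% 2L != 0L)
      stop("interleaved TIFF has an odd page count: channel mismatch")
    first <- match.arg(channel_order)
    odd <- as_arr(pages[seq(1, length(pages), 2)])
    even <- as_arr(pages[seq(2, length(pages), 2)])
    if (first == "cyan") { cy <- odd; ye <- even }
    else { cy <- even; ye <- odd }
  }
  ratio_stack(cy, ye)
}

#' Write a dual-channel stack to two 16-bit multi-page TIFFs
#'
#' Counts are stored as 16-bit integers (values above 65535 are clipped).
#'
#' @param stack a [ratio_stack()].
#' @param path_cyan,path_yellow output TIFF paths.
#' @return The paths, invisibly.
#' @export
write_stack <- function(stack, path_cyan, path_yellow) {
  stopifnot(inherits(stack, "ratio_stack"))
  wr <- function(a, path) {
    pages <- lapply(seq_len(dim(a)[3]), function(t)
      pmin(round(a[, , t]), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  wr(stack$cyan, path_cyan)
  wr(stack$yellow, path_yellow)
  invisible(c(path_cyan, path_yellow))
}

#' Read a microplate table from CSV
#'
#' Schema: `well_id, condition, dose, cyan, yellow` (header required).
#' Rows with nonpositive cyan counts cannot form a ratio and are dropped
#' with a message. Derived columns `bret_ratio = yellow/cyan` and
#' `total = cyan + yellow` are appended.
#'
#' @param path CSV path.
#' @return Data frame (a `PlateTable`).
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "condition", "dose", "cyan", "yellow")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plate CSV missing columns: ", paste(miss, collapse = ", "))
  if (any(df$dose < 0, na.rm = TRUE)) stop("negative doses in plate")
  bad <- !is.finite(df$cyan) | df$cyan <= 0
  if (any(bad)) {
    message(sprintf("read_plate: dropping %d row(s) with cyan <= 0",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  df$bret_ratio <- df$yellow / df$cyan
  df$total <- df$cyan + df$yellow
  df
}

#' Write a plate table to CSV
#' @param plate data frame with the plate schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(
    plate[, c("well_id", "condition", "dose", "cyan", "yellow")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records the package version, the invoking call, seeds, parameter
#' values and input-file digests, so any figure of record can be
#' recomputed from inputs alone.
#'
#' @param ... named entries to record (seeds, configs, truth lists).
#' @param inputs character vector of input file paths to digest.
#' @return Named list (class `run_manifest`).
#' @export
run_manifest <- function(..., inputs = character(0)) {
  digests <- vapply(inputs, function(p)
    as.character(tools::md5sum(p)), character(1))
  structure(list(
    package = "hybret",
    version = as.character(utils::packageVersion("hybret")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    call = paste(deparse(sys.call(-1)), collapse = " "),
    inputs = as.list(digests),
    ...), class = "run_manifest")
}

#' Write a manifest (or any result record) as JSON
#' @param x list to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
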