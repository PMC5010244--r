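#' Construct a 1D NMR spectrum object
#'
#' A spectrum is a (ppm, intensity) series on a strictly monotone chemical
#' shift axis. Intensities must be finite; at least two points are required.
#'
#' @param ppm numeric, strictly monotone chemical shift axis (ppm).
#' @param intensity numeric, same length as `ppm`.
#' @param subject_id character scalar identifier.
#' @return An object of class `nmr_spectrum` (a list with elements `ppm`,
#'   `intensity`, `subject_id`).
#' @export
nmr_spectrum <- function(ppm, intensity, subject_id = "S1") {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) < 2 || length(ppm) != length(intensity))
    stop("spectrum error: ppm and intensity must have equal length >= 2",
         call. = FALSE)
  d <- diff(ppm)
  if (!all(is.finite(ppm)) || !(all(d > 0) || all(d < 0)))
    stop("spectrum error: ppm axis must be strictly monotone and finite",
         call. = FALSE)
  if (!all(is.finite(intensity)))
    stop("spectrum error: intensities must be finite", call. = FALSE)
  if (all(d < 0)) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(ppm = ppm, intensity = intensity,
                 subject_id = as.character(subject_id)[1]),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> subject %s: %d points, %.3f-%.3f ppm\n",
              x$subject_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

# Exact integral of the piecewise-linear interpolant of (x, y) from x[1] up
# to each point in `pts` (pts clamped to [x[1], x[n]] must hold).
# Closed form per segment, so sums of bin integrals reproduce the total
# trapezoidal integral to machine precision.
.pl_cumint_at <- function(x, y, pts) {
  n <- length(x)
  C <- c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
  k <- findInterval(pts, x, rightmost.closed = TRUE)
  k[k < 1] <- 1L; k[k > n - 1] <- n - 1L
  dx <- x[k + 1] - x[k]
  w <- (pts - x[k]) / dx
  ye <- y[k] + (y[k + 1] - y[k]) * w
  C[k] + (pts - x[k]) * (y[k] + ye) / 2
}

# Integral of piecewise-linear (x, y) over [a, b]; a, b may be vectors.
.pl_integral <- function(x, y, a, b) {
  .pl_cumint_at(x, y, b) - .pl_cumint_at(x, y, a)
}

#' Read / write spectra as two-column delimited text
#'
#' `read_spectrum_tsv()` reads a two-column (ppm, intensity) tab-separated
#' file (with header) into an [nmr_spectrum()]; `write_spectrum_tsv()` is its
#' inverse.
#'
#' @param path file path.
#' @param subject_id identifier for the spectrum (default: file base name).
#' @return An `nmr_spectrum` (reader) or the path, invisibly (writer).
#' @export
read_spectrum_tsv <- function(path, subject_id = NULL) {
  d <- read.delim(path, header = TRUE, sep = "\t")
  if (ncol(d) < 2)
    stop("spectrum error: expected two columns (ppm, intensity) in ", path,
         call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  nmr_spectrum(d[[1]], d[[2]], subject_id)
}

#' @rdname read_spectrum_tsv
#' @param spectrum an `nmr_spectrum`.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  d <- data.frame(ppm = spectrum$ppm, intensity = spectrum$intensity)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
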