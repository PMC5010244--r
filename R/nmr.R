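#' Reference a spectrum on the alanine doublet
#'
#' Serum spectra are chemical-shift referenced on the alanine CH3 doublet at
#' 1.478 ppm. The doublet is detected as the highest-amplitude pair of local
#' maxima within `target_ppm +/- search_halfwidth` whose separation lies in
#' `[min_sep, max_sep]` ppm with a trough between them; the ppm axis is then
#' shifted by a constant so that the doublet midpoint equals `target_ppm`.
#' Intensities are untouched.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param target_ppm reference position of the doublet centre (ppm).
#' @param search_halfwidth half-width of the search region (ppm).
#' @param min_sep,max_sep admissible doublet peak separation (ppm).
#' @return The referenced `nmr_spectrum`, with the applied shift in
#'   `attr(, "shift")`.
#' @export
reference_spectrum <- function(spectrum, target_ppm = 1.478,
                               search_halfwidth = 0.05,
                               min_sep = 0.008, max_sep = 0.03) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  x <- spectrum$ppm; y <- spectrum$intensity
  idx <- which(x >= target_ppm - search_halfwidth &
                 x <= target_ppm + search_halfwidth)
  fail <- function()
    stop(sprintf("referencing error: no alanine doublet found near %.3f ppm for subject %s",
                 target_ppm, spectrum$subject_id), call. = FALSE)
  if (length(idx) < 5) fail()
  yi <- y[idx]; xi <- x[idx]
  k <- which(diff(sign(diff(yi))) < 0) + 1L     # local maxima (interior)
  if (length(k) < 2) fail()
  best <- NULL; best_h <- -Inf
  for (a in seq_along(k)) for (b in seq_along(k)) {
    if (b <= a) next
    sep <- xi[k[b]] - xi[k[a]]
    if (sep < min_sep || sep > max_sep) next
    trough <- min(yi[k[a]:k[b]])
    if (trough >= min(yi[k[a]], yi[k[b]])) next
    h <- yi[k[a]] + yi[k[b]]
    if (h > best_h) { best_h <- h; best <- c(k[a], k[b]) }
  }
  if (is.null(best)) fail()
  centre <- (xi[best[1]] + xi[best[2]]) / 2
  shift <- target_ppm - centre
  out <- nmr_spectrum(x + shift, y, spectrum$subject_id)
  attr(out, "shift") <- shift
  out
}

#' Bin (bucket) a spectrum into fixed-width ppm buckets
#'
#' Integrates the piecewise-linear spectrum over consecutive half-open ppm
#' intervals `[lo + k*width, lo + (k+1)*width)` — the defaults give the 420
#' buckets of 0.01 ppm covering the 0.50-4.70 ppm aliphatic region. Each
#' bucket value is the exact (trapezoidal) integral over its interval, so
#' the bucket sum equals the integral over the whole region to numerical
#' precision.
#'
#' @param spectrum an [nmr_spectrum()] spanning at least `[lo, hi]`.
#' @param lo,hi analyzed region bounds (ppm); `(hi - lo)/width` must be an
#'   integer (no trailing partial bucket is allowed).
#' @param width bucket width (ppm).
#' @return named numeric vector of bucket integrals (names are bucket
#'   centres), with bucket edges in `attr(, "edges")`.
#' @export
bin_spectrum <- function(spectrum, lo = 0.50, hi = 4.70, width = 0.01) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  nb <- (hi - lo) / width
  if (abs(nb - round(nb)) > 1e-8)
    stop("binning error: (hi - lo) / width must be an integer number of ",
         "buckets", call. = FALSE)
  nb <- as.integer(round(nb))
  x <- spectrum$ppm
  if (min(x) > lo + 1e-9 || max(x) < hi - 1e-9)
    stop(sprintf("coverage error: spectrum of subject %s spans [%.3f, %.3f] but [%g, %g] is required",
                 spectrum$subject_id, min(x), max(x), lo, hi), call. = FALSE)
  edges <- lo + width * (0:nb)
  edges <- pmin(pmax(edges, min(x)), max(x))
  cum <- .pl_cumint_at(x, spectrum$intensity, edges)
  bins <- diff(cum)
  names(bins) <- sprintf("%.3f", lo + width * (seq_len(nb) - 0.5))
  attr(bins, "edges") <- lo + width * (0:nb)
  bins
}

#' Total-area normalization
#'
#' Rescales a bucket vector (or each row of a subjects x buckets matrix) to
#' sum to the constant `S`, removing overall-concentration (dilution)
#' differences between samples. The operation is idempotent and invariant to
#' positive rescaling of the input. Applied to an [nmr_spectrum()], it
#' rescales intensities so that the integral over `region` equals `S`.
#'
#' @param x numeric vector of bucket integrals, matrix (subjects in rows),
#'   or an `nmr_spectrum`.
#' @param S normalization constant (default 100).
#' @param region for spectra, the region whose integral is normalized.
#' @return Object of the same shape as `x`, normalized.
#' @export
normalize_total_area <- function(x, S = 100, region = c(0.50, 4.70)) {
  if (S <= 0) stop("normalization error: S must be positive", call. = FALSE)
  if (inherits(x, "nmr_spectrum")) {
    tot <- .pl_integral(x$ppm, x$intensity,
                        max(region[1], min(x$ppm)), min(region[2], max(x$ppm)))
    if (!is.finite(tot) || tot <= 0)
      stop("normalization error: nonpositive spectral area", call. = FALSE)
    out <- nmr_spectrum(x$ppm, x$intensity * (S / tot), x$subject_id)
    return(out)
  }
  if (is.matrix(x)) {
    rs <- rowSums(x)
    if (any(!is.finite(rs)) || any(rs <= 0))
      stop("normalization error: every row sum must be positive",
           call. = FALSE)
    return(x * (S / rs))
  }
  tot <- sum(x)
  if (!is.finite(tot) || tot <= 0)
    stop("normalization error: nonpositive total area", call. = FALSE)
  out <- x * (S / tot)
  attributes(out) <- attributes(x)
  out
}

#' Quantify metabolite windows
#'
#' Integrates a normalized spectrum (or bucket vector/matrix) over each ppm
#' window of the panel, yielding relative metabolite levels. When quantifying
#' from buckets, a bucket straddling a window boundary contributes pro-rata
#' by its overlap fraction.
#'
#' @param x a normalized [nmr_spectrum()], a bucket vector from
#'   [bin_spectrum()] (with its `edges` attribute), or a subjects x buckets
#'   matrix accompanied by `edges`.
#' @param panel metabolite window panel (see [serum_metabolite_panel()]).
#' @param edges bucket edges, required for matrix input without attribute.
#' @return Named numeric vector of relative levels (or a subjects x
#'   metabolites matrix for matrix input).
#' @export
quantify_windows <- function(x, panel = serum_metabolite_panel(),
                             edges = NULL) {
  panel <- validate_panel(panel, region = c(-Inf, Inf))
  if (inherits(x, "nmr_spectrum")) {
    if (min(x$ppm) > min(panel$ppm_lo) + 1e-9 ||
        max(x$ppm) < max(panel$ppm_hi) - 1e-9)
      stop("panel error: window outside the spectral region", call. = FALSE)
    v <- .pl_integral(x$ppm, x$intensity, panel$ppm_lo, panel$ppm_hi)
    return(setNames(v, panel$metabolite))
  }
  if (is.null(edges)) edges <- attr(x, "edges")
  if (is.null(edges))
    stop("quantification error: bucket edges are required (pass a vector ",
         "from bin_spectrum() or supply `edges`)", call. = FALSE)
  nb <- length(edges) - 1L
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nb)
    stop("quantification error: length of bucket vector does not match ",
         "edges", call. = FALSE)
  if (min(panel$ppm_lo) < edges[1] - 1e-9 ||
      max(panel$ppm_hi) > edges[nb + 1] + 1e-9)
    stop("panel error: window outside the analyzed region", call. = FALSE)
  W <- matrix(0, nb, nrow(panel))          # pro-rata overlap fractions
  bw <- diff(edges)
  for (j in seq_len(nrow(panel))) {
    ov <- pmin(edges[-1], panel$ppm_hi[j]) - pmax(edges[-(nb + 1)], panel$ppm_lo[j])
    W[, j] <- pmax(ov, 0) / bw
  }
  V <- X %*% W
  colnames(V) <- panel$metabolite
  if (is.matrix(x)) {
    rownames(V) <- rownames(x)
    V
  } else {
    setNames(drop(V), panel$metabolite)
  }
}

#' Process a set of raw spectra into a binned matrix and quantification table
#'
#' Applies the standard serum workflow to each spectrum: chemical-shift
#' referencing on the alanine doublet, 0.01-ppm bucketing of the 0.50-4.70
#' ppm region, total-area normalization to `S`, and metabolite window
#' integration.
#'
#' @param spectra list of [nmr_spectrum()] objects.
#' @param panel metabolite window panel.
#' @param lo,hi,width bucketing parameters, see [bin_spectrum()].
#' @param S normalization constant.
#' @param reference logical, apply [reference_spectrum()] first.
#' @return list with `binned` (subjects x buckets matrix, bucket edges in
#'   `attr(,"edges")`) and `quant` (subjects x metabolites matrix).
#' @export
process_spectra <- function(spectra, panel = serum_metabolite_panel(),
                            lo = 0.50, hi = 4.70, width = 0.01, S = 100,
                            reference = TRUE) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  rows <- lapply(spectra, function(sp) {
    if (reference) sp <- reference_spectrum(sp)
    bin_spectrum(sp, lo, hi, width)
  })
  B <- do.call(rbind, rows)
  ids <- vapply(spectra, function(sp) sp$subject_id, character(1))
  rownames(B) <- ids
  edges <- attr(rows[[1]], "edges")
  Bn <- normalize_total_area(B, S)
  Q <- quantify_windows(Bn, panel, edges = edges)
  attr(Bn, "edges") <- edges
  list(binned = Bn, quant = Q)
}

#' Read / write a binned spectral matrix as TSV
#'
#' The TSV has subject ids in the first column and one column per bucket,
#' with bucket centres as header names.
#'
#' @param x subjects x buckets matrix with an `edges` attribute.
#' @param path file path.
#' @return The matrix (reader; edges reconstructed from the header) or the
#'   path, invisibly (writer).
#' @export
write_binned_tsv <- function(x, path) {
  d <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binned_tsv
#' @export
read_binned_tsv <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  centres <- as.numeric(colnames(m))
  w <- diff(centres)
  if (length(w) && max(abs(w - w[1])) < 1e-9) {
    attr(m, "edges") <- c(centres - w[1] / 2, centres[length(centres)] + w[1] / 2)
  }
  m
}
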