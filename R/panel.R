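#' Serum metabolite integration panel
#'
#' The default quantification panel: 27 named ppm integration windows on the
#' 0.50-4.70 ppm aliphatic region of 1D 1H-NMR serum spectra, together with
#' reference relative levels (mean and SD, total-area-normalized scale) for
#' subjects with fewer than two cardiometabolic risk factors ("group 1") and
#' subjects with three or more ("group 3"). These reference levels drive the
#' synthetic-cohort generator and serve as targets for round-trip validation
#' of the quantification pipeline.
#'
#' Windows may touch (share an endpoint) but must not overlap; several amino
#' acid and lipid windows in serum are contiguous.
#'
#' @return A `data.frame` with columns `metabolite`, `ppm_lo`, `ppm_hi`,
#'   `mean_g1`, `sd_g1`, `mean_g3`, `sd_g3`.
#' @seealso [validate_panel()], [quantify_windows()]
#' @export
#' @examples
#' panel <- serum_metabolite_panel()
#' nrow(panel)  # 27 windows
serum_metabolite_panel <- function() {
  p <- data.frame(
    metabolite = c(
      "cholesterol", "lipid_CH3", "leucine", "isoleucine", "valine",
      "isobutyrate", "lipid_CH2_chain", "lactate", "phenylpropionate_2",
      "alanine", "lipid_CH2CH2CO", "acetate", "N_acetylglutamine",
      "lipid_CH2CH3", "acetone", "pyruvate", "citrate", "lipid_CHCH2CH",
      "trimethylamine", "proline", "methanol", "creatine", "tyrosine",
      "creatine_phosphate", "phosphoethanolamine", "creatinine",
      "tryptophan_choline"),
    ppm_lo = c(0.60, 0.80, 0.95, 0.99, 1.02, 1.05, 1.18, 1.32, 1.40, 1.46,
               1.55, 1.91, 1.92, 1.95, 2.21, 2.35, 2.50, 2.71, 2.90, 3.30,
               3.35, 3.91, 3.92, 3.94, 3.95, 4.03, 4.05),
    ppm_hi = c(0.75, 0.90, 0.97, 1.02, 1.05, 1.07, 1.31, 1.35, 1.44, 1.50,
               1.60, 1.92, 1.95, 2.03, 2.23, 2.36, 2.54, 2.80, 2.95, 3.35,
               3.36, 3.92, 3.94, 3.95, 3.99, 4.05, 4.07),
    mean_g1 = c(3.53, 8.06, 1.02, 0.99, 1.10, 0.71, 14.05, 2.02, 1.35, 1.66,
                1.85, 0.56, 0.92, 3.77, 0.64, 0.18, 0.46, 1.25, 0.66, 0.34,
                0.08, 0.17, 0.27, 0.17, 0.61, 0.31, 0.33),
    sd_g1 = c(0.49, 0.39, 0.05, 0.04, 0.05, 0.04, 1.98, 0.41, 0.07, 0.08,
              0.16, 0.03, 0.05, 0.17, 0.09, 0.02, 0.04, 0.09, 0.06, 0.05,
              0.01, 0.01, 0.02, 0.01, 0.05, 0.02, 0.02),
    mean_g3 = c(3.24, 8.11, 0.95, 0.95, 1.03, 0.66, 16.47, 2.34, 1.26, 1.54,
                2.03, 0.52, 0.86, 3.91, 0.76, 0.17, 0.41, 1.26, 0.60, 0.32,
                0.07, 0.16, 0.25, 0.15, 0.57, 0.30, 0.35),
    sd_g3 = c(0.46, 0.38, 0.06, 0.05, 0.07, 0.05, 2.76, 0.47, 0.10, 0.12,
              0.22, 0.05, 0.06, 0.22, 0.14, 0.02, 0.05, 0.10, 0.07, 0.05,
              0.02, 0.02, 0.03, 0.02, 0.06, 0.02, 0.03),
    stringsAsFactors = FALSE
  )
  validate_panel(p)
  p
}

#' Validate a metabolite window panel
#'
#' Checks the structural invariants of a quantification panel: unique
#' metabolite names, `ppm_lo < ppm_hi`, all windows inside the analyzed
#' region, and pairwise non-overlapping interiors (windows may touch).
#'
#' @param panel data.frame with at least `metabolite`, `ppm_lo`, `ppm_hi`.
#' @param region numeric length-2, the analyzed chemical-shift region in ppm.
#' @return The panel, invisibly, ordered by `ppm_lo`. Errors on violation.
#' @export
validate_panel <- function(panel, region = c(0.50, 4.70)) {
  need <- c("metabolite", "ppm_lo", "ppm_hi")
  if (!is.data.frame(panel) || !all(need %in% names(panel)))
    stop("panel must be a data.frame with columns metabolite, ppm_lo, ppm_hi",
         call. = FALSE)
  if (anyDuplicated(panel$metabolite))
    stop("panel error: duplicated metabolite names", call. = FALSE)
  if (!all(is.finite(panel$ppm_lo)) || !all(is.finite(panel$ppm_hi)))
    stop("panel error: non-finite window bounds", call. = FALSE)
  if (any(panel$ppm_lo >= panel$ppm_hi))
    stop("panel error: ppm_lo must be < ppm_hi for every window", call. = FALSE)
  if (any(panel$ppm_lo < region[1] - 1e-9) || any(panel$ppm_hi > region[2] + 1e-9))
    stop(sprintf("panel error: windows must lie within [%.2f, %.2f] ppm",
                 region[1], region[2]), call. = FALSE)
  o <- order(panel$ppm_lo)
  p <- panel[o, , drop = FALSE]
  if (nrow(p) > 1) {
    gap <- p$ppm_lo[-1] - p$ppm_hi[-nrow(p)]
    if (any(gap < -1e-9)) {
      bad <- which(gap < -1e-9)[1]
      stop(sprintf("panel error: windows '%s' and '%s' overlap",
                   p$metabolite[bad], p$metabolite[bad + 1]), call. = FALSE)
    }
  }
  invisible(p)
}
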