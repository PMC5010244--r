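#' Score the five ATP-III cardiometabolic risk components
#'
#' Flags, per subject, the five metabolic-syndrome components:
#'
#' * abdominal obesity: waist >= 102 cm (men) / >= 88 cm (women);
#' * high triglycerides: TG >= 150 mg/dL;
#' * low HDL cholesterol: HDL < 40 mg/dL (men) / < 50 mg/dL (women);
#' * high blood pressure: SBP >= 130 mmHg and/or DBP >= 85 mmHg, or
#'   antihypertensive treatment;
#' * high fasting glucose: >= 110 mg/dL, or glucose-lowering treatment.
#'
#' All thresholds are inclusive (`>=` / for HDL strictly `<`). Lipid
#' treatment does not trigger the TG or HDL flags. A missing measurement
#' leaves its flag `FALSE` by default and tags the subject incomplete
#' (`missing = "false"`); with `missing = "na"` the count and group are set
#' to `NA` instead.
#'
#' @param phenotypes data.frame with columns `sex` (`"M"`/`"F"`), `waist`,
#'   `tg`, `hdl`, `sbp`, `dbp`, `glucose`, and logical `htn_treat`,
#'   `dm_treat` (missing treatment flags are treated as `FALSE`).
#' @param missing missing-measurement policy, `"false"` or `"na"`.
#' @return data.frame with the five logical flags, `count` (0-5), `group`
#'   (1, 2 or 3, see [assign_group()]) and `incomplete`.
#' @export
score_cmrf <- function(phenotypes, missing = c("false", "na")) {
  missing <- match.arg(missing)
  p <- as.data.frame(phenotypes)
  if (!"sex" %in% names(p) || any(is.na(p$sex)))
    stop("input error: sex must be present for every subject", call. = FALSE)
  sex <- as.character(p$sex)
  if (!all(sex %in% c("M", "F")))
    stop("input error: unknown sex code (expected \"M\" or \"F\")",
         call. = FALSE)
  male <- sex == "M"
  gv <- function(col) if (col %in% names(p)) p[[col]] else rep(NA, nrow(p))
  tv <- function(col) {
    v <- if (col %in% names(p)) p[[col]] else rep(FALSE, nrow(p))
    v[is.na(v)] <- FALSE
    as.logical(v)
  }
  flag <- function(x) { miss <- is.na(x); x[miss] <- FALSE; list(f = x, m = miss) }

  ab <- flag(ifelse(male, gv("waist") >= 102, gv("waist") >= 88))
  tg <- flag(gv("tg") >= 150)
  hd <- flag(ifelse(male, gv("hdl") < 40, gv("hdl") < 50))
  bp_meas <- gv("sbp") >= 130 | gv("dbp") >= 85
  bp <- flag(bp_meas)
  bp$f <- bp$f | tv("htn_treat")
  bp$m <- bp$m & !tv("htn_treat")   # treatment alone settles the flag
  gl <- flag(gv("glucose") >= 110)
  gl$f <- gl$f | tv("dm_treat")
  gl$m <- gl$m & !tv("dm_treat")

  out <- data.frame(
    abdominal_obesity = ab$f, high_TG = tg$f, low_HDL = hd$f,
    high_BP = bp$f, high_glucose = gl$f
  )
  if ("id" %in% names(p)) out <- cbind(id = p$id, out)
  out$count <- rowSums(out[, c("abdominal_obesity", "high_TG", "low_HDL",
                               "high_BP", "high_glucose")])
  out$incomplete <- ab$m | tg$m | hd$m | bp$m | gl$m
  if (missing == "na") out$count[out$incomplete] <- NA_integer_
  out$group <- ifelse(is.na(out$count), NA_integer_, assign_group(
    ifelse(is.na(out$count), 0L, out$count)))
  out
}

#' Assign the risk-factor clustering group
#'
#' Subjects with fewer than two components form group 1, exactly two form
#' group 2, and three or more (the metabolic-syndrome definition) form
#' group 3.
#'
#' @param count integer vector of component counts in 0..5.
#' @return integer vector of group labels in `{1, 2, 3}`.
#' @export
assign_group <- function(count) {
  if (any(is.na(count)) || any(count < 0 | count > 5) ||
      any(count != round(count)))
    stop("logic error: component count must be an integer in 0..5",
         call. = FALSE)
  ifelse(count >= 3, 3L, ifelse(count == 2, 2L, 1L))
}
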