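#' Per-metabolite group comparison with covariate adjustment
#'
#' Tests, for each metabolite, the difference in relative levels between the
#' fewer-than-two (group 1) and three-or-more (group 3) risk-factor groups,
#' by a linear model `metabolite ~ group + covariates` fitted by least
#' squares; the reported p-value is the two-sided test of the group
#' coefficient. With no covariates this is the pooled two-sample t test.
#' Either group having fewer than 3 subjects marks every p-value
#' unavailable (`NA`).
#'
#' @param quant subjects x metabolites numeric matrix of relative levels.
#' @param groups integer vector (per subject); only groups 1 and 3 enter the
#'   comparison.
#' @param covariates optional data.frame (e.g. age, sex, smoking), aligned
#'   with the rows of `quant`.
#' @param subset optional logical/integer subset of subjects (a genotype
#'   stratum).
#' @return named numeric vector of p-values, one per metabolite.
#' @export
metabolite_group_test <- function(quant, groups, covariates = NULL,
                                  subset = NULL) {
  quant <- as.matrix(quant)
  n <- nrow(quant)
  keep <- rep(TRUE, n)
  if (!is.null(subset)) {
    keep <- rep(FALSE, n)
    keep[subset] <- TRUE
  }
  keep <- keep & groups %in% c(1L, 3L)
  g <- as.numeric(groups[keep] == 3)
  out <- setNames(rep(NA_real_, ncol(quant)), colnames(quant))
  if (sum(g == 0) < 3 || sum(g == 1) < 3) return(out)
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  for (j in seq_len(ncol(quant))) {
    d <- data.frame(.m = quant[keep, j], .g = g)
    if (!is.null(Z)) d <- cbind(d, Z)
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (length(unique(d$.g)) < 2) next
    fit <- lm(.m ~ ., data = d)
    cf <- summary(fit)$coefficients
    if (".g" %in% rownames(cf)) out[j] <- cf[".g", "Pr(>|t|)"]
  }
  out
}

#' Significance-band classification of p-values
#'
#' Maps p-values onto the four display bands of the stratified significance
#' pattern: `band0` for p > 0.01, `band1` for p < 0.01, `band2` for
#' p < 0.001 and `band3` for p < 0.00001. Thresholds are strict, so a
#' p-value exactly at a boundary falls in the wider band. The assignment is
#' a monotone step function of p; `NA` inputs (unavailable tests) stay `NA`.
#'
#' @param p numeric vector or matrix of p-values in (0, 1].
#' @return character object of the same shape with values
#'   `"band0" ... "band3"`.
#' @export
significance_pattern <- function(p) {
  v <- as.numeric(p)
  ok <- is.na(v) | (v > 0 & v <= 1)
  if (!all(ok))
    stop("input error: p-values must lie in (0, 1]", call. = FALSE)
  b <- ifelse(v < 1e-5, "band3",
              ifelse(v < 1e-3, "band2",
                     ifelse(v < 1e-2, "band1", "band0")))
  attributes(b) <- attributes(p)[intersect(names(attributes(p)),
                                           c("dim", "dimnames", "names"))]
  b
}

#' Genotype-stratified normalized metabolic-difference ratio
#'
#' The integration statistic: for each metabolite, the group-3 minus group-1
#' mean difference within a genotype stratum, divided by the same difference
#' in the entire cohort:
#' \deqn{r = (\bar m_{3,stratum} - \bar m_{1,stratum}) /
#'           (\bar m_{3,global} - \bar m_{1,global}).}
#' A ratio near 1 means the stratum shows the cohort-wide metabolic change;
#' near 0, no change; negative, a change in the opposite direction. When the
#' stratum is the entire cohort the ratio is identically 1. Metabolites
#' whose global difference is below `tol` in magnitude are returned as `NA`
#' (never infinite).
#'
#' @param quant subjects x metabolites matrix of relative levels.
#' @param groups integer group labels (1/2/3) per subject.
#' @param stratum logical or integer subset of subjects forming the stratum.
#' @param tol magnitude below which the global difference is treated as
#'   zero.
#' @return named numeric vector of ratios, one per metabolite.
#' @export
stratified_ratio <- function(quant, groups, stratum, tol = 1e-12) {
  quant <- as.matrix(quant)
  keep <- rep(FALSE, nrow(quant)); keep[stratum] <- TRUE
  g1 <- groups == 1L; g3 <- groups == 3L
  gd <- colMeans(quant[g3, , drop = FALSE]) -
    colMeans(quant[g1, , drop = FALSE])
  sd_ <- colMeans(quant[keep & g3, , drop = FALSE]) -
    colMeans(quant[keep & g1, , drop = FALSE])
  r <- ifelse(abs(gd) < tol, NA_real_, sd_ / gd)
  setNames(r, colnames(quant))
}

#' Fold change of group means
#'
#' The relative change of the three-or-more-risk-factor group mean with
#' respect to itself: `(mean_g3 - mean_g1) / mean_g3`. Positive values mean
#' the metabolite is higher in group 3.
#'
#' @param mean_g1,mean_g3 group mean relative levels (vectors allowed).
#' @return numeric vector of fold changes.
#' @export
#' @examples
#' fold_change(3.53, 3.24)  # cholesterol, lower in group 3
fold_change <- function(mean_g1, mean_g3) {
  if (any(mean_g3 == 0))
    stop("input error: group-3 mean must be nonzero", call. = FALSE)
  (mean_g3 - mean_g1) / mean_g3
}

#' Build the genotype-stratified integration report
#'
#' For every SNP and genotype, restricted to subjects in groups 1 and 3:
#' the per-metabolite covariate-adjusted p-values ([metabolite_group_test()]),
#' their significance bands ([significance_pattern()]), and the normalized
#' difference ratios ([stratified_ratio()]); plus a `global` column over all
#' subjects. Strata with fewer than `min_n` subjects in either group are
#' excluded and listed with the reason.
#'
#' @param quant subjects x metabolites matrix of relative levels.
#' @param groups integer group labels (1/2/3).
#' @param genotypes subjects x SNPs character call matrix.
#' @param covariates optional covariate data.frame (age, sex, smoking).
#' @param snps SNP ids to stratify on (default: all columns).
#' @param min_n minimum per-group stratum size (default 15).
#' @return list of class `stratified_report`: matrices `pvalues`, `bands`,
#'   `ratios` (metabolites x [global + strata]), the `strata` table with
#'   sizes and inclusion reasons, `min_n`, and `metabolites`.
#' @export
stratified_report <- function(quant, groups, genotypes, covariates = NULL,
                              snps = NULL, min_n = 15) {
  quant <- as.matrix(quant)
  stopifnot(nrow(quant) == length(groups), nrow(quant) == nrow(genotypes))
  if (is.null(snps)) snps <- colnames(genotypes)
  mets <- colnames(quant)
  strata <- data.frame(stratum = character(), snp = character(),
                       genotype = character(), n_g1 = integer(),
                       n_g3 = integer(), included = logical(),
                       reason = character(), stringsAsFactors = FALSE)
  p_global <- metabolite_group_test(quant, groups, covariates)
  P <- matrix(p_global, ncol = 1, dimnames = list(mets, "global"))
  R <- matrix(1, nrow = length(mets), ncol = 1,
              dimnames = list(mets, "global"))
  gd <- colMeans(quant[groups == 3L, , drop = FALSE]) -
    colMeans(quant[groups == 1L, , drop = FALSE])
  R[abs(gd) < 1e-12, 1] <- NA_real_
  for (s in snps) {
    for (gt in c("AA", "AB", "BB")) {
      sel <- !is.na(genotypes[, s]) & genotypes[, s] == gt
      nm <- paste(s, gt, sep = "_")
      n1 <- sum(sel & groups == 1L); n3 <- sum(sel & groups == 3L)
      ok <- n1 >= min_n && n3 >= min_n
      strata <- rbind(strata, data.frame(
        stratum = nm, snp = s, genotype = gt, n_g1 = n1, n_g3 = n3,
        included = ok,
        reason = if (ok) "" else sprintf("fewer than %d subjects in %s",
                                         min_n,
                                         paste(c("group 1", "group 3")[c(n1, n3) < min_n],
                                               collapse = " and ")),
        stringsAsFactors = FALSE))
      if (!ok) next
      P <- cbind(P, setNames(data.frame(
        metabolite_group_test(quant, groups, covariates, subset = sel)), nm))
      R <- cbind(R, setNames(data.frame(
        stratified_ratio(quant, groups, sel)), nm))
    }
  }
  P <- as.matrix(P); R <- as.matrix(R)
  structure(list(pvalues = P, bands = significance_pattern(P), ratios = R,
                 strata = strata, min_n = min_n, metabolites = mets),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  inc <- sum(x$strata$included)
  cat(sprintf(paste0("<stratified_report> %d metabolites, %d strata ",
                     "included (of %d), min_n = %d\n"),
              length(x$metabolites), inc, nrow(x$strata), x$min_n))
  invisible(x)
}

#' Filter a stratified report by minimum stratum size
#'
#' Removes strata with fewer than `min_n` subjects in group 1 or group 3
#' from the report matrices; excluded strata remain listed in the `strata`
#' table with their reason.
#'
#' @param report a [stratified_report()].
#' @param min_n minimum per-group size (>= 1).
#' @return The filtered `stratified_report`.
#' @export
stratum_size_filter <- function(report, min_n) {
  stopifnot(inherits(report, "stratified_report"), min_n >= 1)
  st <- report$strata
  drop_ <- st$included & (st$n_g1 < min_n | st$n_g3 < min_n)
  st$included[drop_] <- FALSE
  st$reason[drop_] <- sprintf("fewer than %d subjects in %s", min_n,
                              ifelse(st$n_g1[drop_] < min_n & st$n_g3[drop_] < min_n,
                                     "group 1 and group 3",
                                     ifelse(st$n_g1[drop_] < min_n,
                                            "group 1", "group 3")))
  keep_cols <- c("global", st$stratum[st$included])
  keep_cols <- intersect(colnames(report$pvalues), keep_cols)
  report$pvalues <- report$pvalues[, keep_cols, drop = FALSE]
  report$bands <- report$bands[, keep_cols, drop = FALSE]
  report$ratios <- report$ratios[, keep_cols, drop = FALSE]
  report$strata <- st
  report$min_n <- min_n
  report
}

#' Flag genotype strata with a null metabolic profile
#'
#' A stratum is flagged "null profile" when both hold:
#'
#' * significance clause: no metabolite reaches `band2` or deeper, and at
#'   most `max_band1` reach `band1`;
#' * magnitude clause: the median absolute normalized difference ratio over
#'   metabolites is below `ratio_cut`.
#'
#' These strata show minimal or no group-associated metabolic change despite
#' the cohort-wide differences.
#'
#' @param report a [stratified_report()].
#' @param max_band1 maximum number of band1 metabolites tolerated.
#' @param ratio_cut threshold on the median absolute ratio.
#' @return named logical vector over the included strata (global excluded).
#' @export
flag_null_profile <- function(report, max_band1 = 2, ratio_cut = 0.5) {
  stopifnot(inherits(report, "stratified_report"))
  cols <- setdiff(colnames(report$pvalues), "global")
  out <- setNames(logical(length(cols)), cols)
  for (s in cols) {
    b <- report$bands[, s]
    deep <- sum(b %in% c("band2", "band3"), na.rm = TRUE)
    nb1 <- sum(b == "band1", na.rm = TRUE)
    medr <- median(abs(report$ratios[, s]), na.rm = TRUE)
    out[s] <- deep == 0 && nb1 <= max_band1 &&
      is.finite(medr) && medr < ratio_cut
  }
  out
}

#' Write a stratified report to delimited text
#'
#' Emits the significance-band pattern matrix, the ratio matrix and the
#' strata table as TSV files (rows ordered from the highest-ppm metabolite
#' window down, matching the conventional stacked-bar display), plus the
#' null-profile flags.
#'
#' @param report a [stratified_report()].
#' @param dir output directory.
#' @param ... passed to [flag_null_profile()].
#' @return `dir`, invisibly.
#' @export
write_stratified_report <- function(report, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ord <- rev(seq_along(report$metabolites))
  wr <- function(m, f) {
    d <- data.frame(metabolite = rownames(m)[ord],
                    m[ord, , drop = FALSE], check.names = FALSE)
    write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(report$bands, "pattern_bands.tsv")
  wr(report$ratios, "difference_ratios.tsv")
  wr(report$pvalues, "pvalues.tsv")
  write.table(report$strata, file.path(dir, "strata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fl <- flag_null_profile(report, ...)
  write.table(data.frame(stratum = names(fl), null_profile = fl),
              file.path(dir, "null_profile_flags.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
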