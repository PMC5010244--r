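#' Genotyping call rate of a SNP
#'
#' Fraction of subjects with a non-missing call. Markers qualify for
#' analysis only when strictly more than 90% of subjects are genotyped, so a
#' call rate of exactly 0.90 fails.
#'
#' @param calls character vector of genotype calls (`NA` = missing).
#' @return fraction called, in `[0, 1]`.
#' @export
call_rate <- function(calls) {
  if (length(calls) == 0)
    stop("input error: empty genotype column", call. = FALSE)
  mean(!is.na(calls))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Compares observed genotype counts with the counts expected from the
#' sample allele frequencies (\eqn{n\hat p^2, 2n\hat p\hat q, n\hat q^2})
#' using a chi-square statistic with one degree of freedom. Monomorphic
#' markers return `chisq = 0`, `p = 1` and are flagged.
#'
#' @param nAA,nAB,nBB observed genotype counts.
#' @return list with `chisq`, `p`, `monomorphic`.
#' @export
#' @examples
#' hwe_chisq(10, 10, 10)$chisq  # 10/3
hwe_chisq <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (is.na(n) || n <= 0)
    stop("input error: total genotype count must be positive", call. = FALSE)
  p <- (2 * nAA + nAB) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0)
    return(list(chisq = 0, p = 1, monomorphic = TRUE))
  expd <- n * c(p^2, 2 * p * q, q^2)
  chisq <- sum((c(nAA, nAB, nBB) - expd)^2 / expd)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

# allele-B frequency and minor-allele dose coding from call strings
.allele_freq_B <- function(calls) {
  calls <- calls[!is.na(calls)]
  n <- length(calls)
  if (n == 0) return(NA_real_)
  (2 * sum(calls == "BB") + sum(calls == "AB")) / (2 * n)
}

#' Code genotype calls numerically
#'
#' Additive coding counts copies of the minor allele (0/1/2); dominant
#' ("carrier") coding is 1 for at least one copy; recessive is 1 for two
#' copies. The minor allele is determined from the sample frequencies.
#'
#' @param calls character vector of `"AA"/"AB"/"BB"` calls.
#' @param coding `"additive"`, `"dominant"` or `"recessive"`.
#' @return numeric vector (NA where the call is missing).
#' @export
code_genotypes <- function(calls,
                           coding = c("additive", "dominant", "recessive")) {
  coding <- match.arg(coding)
  fB <- .allele_freq_B(calls)
  dose <- .dose_B(calls)
  if (!is.na(fB) && fB > 0.5) dose <- 2 - dose   # count the minor allele
  switch(coding,
         additive = dose,
         dominant = as.numeric(dose >= 1),
         recessive = as.numeric(dose == 2))
}

#' Logistic association of a binary outcome with one SNP
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of the outcome on the coded genotype plus optional covariates,
#' with a Wald test for the genotype term. Subjects with a missing genotype
#' are dropped. Complete separation or non-convergence never raises an
#' error: the result is flagged (`converged = FALSE`) with the p-value
#' marked unavailable.
#'
#' @param genotypes character calls (`"AA"/"AB"/"BB"`) or an already-coded
#'   numeric vector.
#' @param outcome binary (0/1 or logical) outcome vector.
#' @param covariates optional data.frame of covariates.
#' @param coding genotype coding, see [code_genotypes()].
#' @return list with `beta`, `se`, `or`, `p`, `n`, `converged`.
#' @export
logistic_assoc <- function(genotypes, outcome, covariates = NULL,
                           coding = "additive") {
  g <- if (is.character(genotypes)) code_genotypes(genotypes, coding)
       else as.numeric(genotypes)
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1) | is.na(y)))
    stop("input error: outcome must be binary", call. = FALSE)
  d <- data.frame(.y = y, .g = g)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 2 || length(unique(d$.y)) < 2 || stats::var(d$.g) == 0)
    return(list(beta = NA_real_, se = NA_real_, or = NA_real_, p = NA_real_,
                n = nrow(d), converged = FALSE))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  beta <- cf[".g", "Estimate"]
  se <- cf[".g", "Std. Error"]
  converged <- isTRUE(fit$converged) && !sep_warn && is.finite(se) && se < 100
  list(beta = beta, se = se, or = exp(beta),
       p = if (converged) cf[".g", "Pr(>|z|)"] else NA_real_,
       n = nrow(d), converged = converged)
}

#' Per-SNP quality control and association scan
#'
#' For every SNP: call rate, minor-allele frequency, Hardy-Weinberg
#' chi-square test (on all subjects), logistic association of the outcome
#' with the coded genotype, and a QC flag requiring call rate strictly above
#' `call_rate_min` and HWE p-value at or above `hwe_alpha`.
#'
#' @param genotypes subjects x SNPs character matrix of calls.
#' @param outcome binary outcome (e.g. membership of the three-or-more
#'   risk-factor group).
#' @param covariates optional data.frame of covariates.
#' @param coding genotype coding for the association model.
#' @param call_rate_min call-rate bound (strict inequality).
#' @param hwe_alpha Hardy-Weinberg exclusion level.
#' @return data.frame of class `association_result`, one row per SNP:
#'   `snp_id`, `call_rate`, `maf`, `hwe_chisq`, `hwe_p`, `beta`, `or`, `p`,
#'   `n`, `converged`, `passed_qc`.
#' @export
snp_association <- function(genotypes, outcome, covariates = NULL,
                            coding = "additive", call_rate_min = 0.90,
                            hwe_alpha = 0.05) {
  stopifnot(is.matrix(genotypes))
  snps <- colnames(genotypes)
  rows <- lapply(seq_along(snps), function(j) {
    calls <- genotypes[, j]
    cr <- call_rate(calls)
    fB <- .allele_freq_B(calls)
    maf <- if (is.na(fB)) NA_real_ else min(fB, 1 - fB)
    cc <- calls[!is.na(calls)]
    hw <- hwe_chisq(sum(cc == "AA"), sum(cc == "AB"), sum(cc == "BB"))
    as_ <- logistic_assoc(calls, outcome, covariates, coding)
    data.frame(snp_id = snps[j], call_rate = cr, maf = maf,
               hwe_chisq = hw$chisq, hwe_p = hw$p,
               monomorphic = hw$monomorphic,
               beta = as_$beta, or = as_$or, p = as_$p, n = as_$n,
               converged = as_$converged,
               passed_qc = cr > call_rate_min && hw$p >= hwe_alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", class(out))
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha experiment-wise error rate, in (0, 1).
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 1251)  # 3.9968e-05
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("input error: alpha must lie in (0, 1)", call. = FALSE)
  if (!is.finite(m) || m < 1)
    stop("input error: the number of tests m must be >= 1", call. = FALSE)
  alpha / m
}

#' Read / write genotype tables
#'
#' `write_genotypes_raw()` writes an additive-coded text file in PLINK
#' `.raw` style (space-separated, header `FID IID PAT MAT SEX PHENOTYPE`
#' then one `<snp>_B` dose column per SNP counting B alleles);
#' `read_genotypes_raw()` reads such a file into a numeric dose matrix.
#' `read_genotypes_tsv()` reads a calls TSV (first column subject id,
#' remaining columns `AA/AB/BB`/`NA`) into a character matrix.
#'
#' @param genotypes subjects x SNPs character call matrix.
#' @param path file path.
#' @param phenotype optional integer vector for the PHENOTYPE column
#'   (PLINK convention 1 = control, 2 = case; default -9).
#' @return matrices for the readers; the path, invisibly, for the writer.
#' @export
write_genotypes_raw <- function(genotypes, path, phenotype = NULL) {
  n <- nrow(genotypes)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("S%0*d", max(4L, nchar(n)), seq_len(n))
  if (is.null(phenotype)) phenotype <- rep(-9L, n)
  dose <- apply(genotypes, 2, .dose_B)
  d <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L,
                  PHENOTYPE = phenotype, dose, check.names = FALSE)
  names(d)[-(1:6)] <- paste0(colnames(genotypes), "_B")
  write.table(d, path, sep = " ", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_genotypes_raw
#' @export
read_genotypes_raw <- function(path) {
  d <- read.delim(path, header = TRUE, sep = " ", check.names = FALSE)
  m <- as.matrix(d[, -(1:6), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d$IID
  colnames(m) <- sub("_[ACGTB]$", "", colnames(m))
  m
}

#' @rdname write_genotypes_raw
#' @export
read_genotypes_tsv <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                  na.strings = c("NA", ""))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
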