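test_that("group tests are calibrated under the null and powered under a shift", {
  set.seed(3)
  null_p <- replicate(60, {
    q <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "m"))
    g <- rep(c(1L, 3L), each = 100)
    metabolite_group_test(q, g)[["m"]]
  })
  ks <- suppressWarnings(ks.test(null_p, "punif"))
  expect_gt(ks$p.value, 0.001)

  hits <- replicate(100, {
    q <- matrix(c(rnorm(100), rnorm(100, 1)), ncol = 1,
                dimnames = list(NULL, "m"))
    g <- rep(c(1L, 3L), each = 100)
    metabolite_group_test(q, g)[["m"]] < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("tiny or single-class strata yield unavailable p-values", {
  q <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_true(all(is.na(metabolite_group_test(q, rep(1L, 10)))))
  g <- c(rep(1L, 8), 3L, 3L)   # only 2 subjects in group 3
  expect_true(all(is.na(metabolite_group_test(q, g))))
})

test_that("covariate adjustment removes a confounded group difference", {
  set.seed(7)
  n <- 300
  g <- rep(c(1L, 3L), each = n / 2)
  age <- 50 + 10 * (g == 3L) + rnorm(n, sd = 3)
  q <- matrix(0.05 * age + rnorm(n, sd = 0.1), ncol = 1,
              dimnames = list(NULL, "m"))   # depends on age only
  p_plain <- metabolite_group_test(q, g)[["m"]]
  p_adj <- metabolite_group_test(q, g, covariates = data.frame(age = age))[["m"]]
  expect_lt(p_plain, 1e-6)
  expect_gt(p_adj, 0.01)
})

test_that("significance bands follow the strict display thresholds", {
  expect_equal(unname(significance_pattern(c(0.5, 0.005, 0.0005, 1e-6))),
               c("band0", "band1", "band2", "band3"))
  expect_equal(unname(significance_pattern(0.01)), "band0")   # boundary
  expect_equal(unname(significance_pattern(0.001)), "band1")
  expect_equal(unname(significance_pattern(1e-5)), "band2")
  expect_error(significance_pattern(0), "input error")
  expect_error(significance_pattern(1.5), "input error")
  # monotone step function of p
  p <- sort(runif(50, 1e-8, 1))
  idx <- match(significance_pattern(p), paste0("band", 0:3))
  expect_true(all(diff(idx) <= 0))
  # matrix shape preserved
  m <- matrix(c(0.5, 1e-6, 0.005, 0.02), 2,
              dimnames = list(c("x", "y"), c("s1", "s2")))
  b <- significance_pattern(m)
  expect_identical(dim(b), dim(m))
  expect_identical(dimnames(b), dimnames(m))
})

test_that("the normalized difference ratio obeys its identities", {
  cohort <- quant_cohort(n = 300, seed = 17)
  q <- cohort$metabolites; g <- cohort$groups
  r_all <- stratified_ratio(q, g, seq_len(nrow(q)))
  expect_lt(max(abs(r_all - 1), na.rm = TRUE), 1e-12)

  # constructed arithmetic: stratum difference half / opposite the global
  qq <- matrix(c(rep(0, 40), rep(0.30, 40),          # global diff 0.30
                 rep(0, 40), rep(c(0.15, 0.45), each = 20)), ncol = 2)
  colnames(qq) <- c("base", "m")
  gg <- rep(c(1L, 3L), each = 40)
  stratum <- c(1:20, 41:60)     # group-3 part has mean 0.15
  r <- stratified_ratio(qq[, 2, drop = FALSE], gg, stratum)
  expect_equal(unname(r), 0.5)
  qq2 <- qq; qq2[41:60, 2] <- -0.10; qq2[61:80, 2] <- 0.70  # global 0.30
  r2 <- stratified_ratio(qq2[, 2, drop = FALSE], gg, stratum)
  expect_equal(unname(r2), -0.10 / 0.30)

  # zero global difference: undefined, never infinite
  qz <- matrix(rep(1, 80), ncol = 1, dimnames = list(NULL, "flat"))
  expect_true(is.na(stratified_ratio(qz, gg, stratum)))
})

test_that("ratio and fold change are invariant to common positive rescaling", {
  cohort <- quant_cohort(n = 200, seed = 19)
  q <- cohort$metabolites; g <- cohort$groups
  stratum <- which(cohort$genotypes[, 1] == "AB")
  r1 <- stratified_ratio(q, g, stratum)
  r2 <- stratified_ratio(q * 7.3, g, stratum)
  expect_equal(r1, r2, tolerance = 1e-12)
  m1 <- colMeans(q[g == 1, ]); m3 <- colMeans(q[g == 3, ])
  expect_equal(fold_change(m1, m3), fold_change(7.3 * m1, 7.3 * m3),
               tolerance = 1e-12)
})

test_that("fold change matches hand arithmetic on the reference levels", {
  expect_equal(fold_change(3.53, 3.24), (3.24 - 3.53) / 3.24)
  expect_equal(fold_change(3.53, 3.24), -0.0895, tolerance = 1e-3)
  expect_equal(fold_change(2.02, 2.34), 0.1368, tolerance = 1e-3)
  expect_equal(fold_change(5, 5), 0)
  expect_error(fold_change(1, 0), "input error")
})

test_that("strata below the minimum size are excluded with a reason", {
  cohort <- quant_cohort(n = 500, seed = 23, maf = 0.2)
  rep_ <- stratified_report(cohort$metabolites, cohort$groups,
                            cohort$genotypes, min_n = 15)
  st <- rep_$strata
  # rare homozygote stratum (q^2 = 4%) cannot reach 15 in group 3
  expect_false(st$included[st$genotype == "BB"])
  expect_match(st$reason[st$genotype == "BB"], "fewer than 15")
  expect_true(all(c("global", st$stratum[st$included]) %in%
                    colnames(rep_$pvalues)))

  # filtering at min_n = 1 drops nothing that was already included
  rep2 <- stratum_size_filter(rep_, min_n = 1)
  expect_identical(rep2$strata$included, rep_$strata$included)
  expect_identical(colnames(rep2$pvalues), colnames(rep_$pvalues))
  big <- stratum_size_filter(rep_, min_n = 400)
  expect_false(any(big$strata$included))
  expect_identical(colnames(big$pvalues), "global")
})

test_that("retention honours the minimum count rule at the printed sizes", {
  # 19 group-3 and 151 group-1 subjects: retained at min_n = 15
  q <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  g <- rep(c(1L, 3L), c(151, 49))
  geno <- matrix("AA", 200, 1, dimnames = list(NULL, "rs"))
  geno[c(1:151, 152:170), 1] <- "AA"      # 151 g1 + 19 g3
  geno[171:200, 1] <- "AB"
  rep_ <- stratified_report(q, g, geno, min_n = 15)
  st <- rep_$strata
  expect_true(st$included[st$stratum == "rs_AA"])
  expect_equal(st$n_g1[st$stratum == "rs_AA"], 151)
  expect_equal(st$n_g3[st$stratum == "rs_AA"], 19)
  # 30 subjects but only 0 in group 1 -> excluded
  expect_false(st$included[st$stratum == "rs_AB"])
})

test_that("null-profile flagging needs both quiet bands and small ratios", {
  mk_report <- function(p, r) {
    P <- cbind(global = rep(1e-7, 10), s = p)
    R <- cbind(global = rep(1, 10), s = r)
    rownames(P) <- rownames(R) <- paste0("m", 1:10)
    structure(list(pvalues = P, bands = significance_pattern(P), ratios = R,
                   strata = data.frame(stratum = "s", snp = "rs",
                                       genotype = "AA", n_g1 = 50, n_g3 = 50,
                                       included = TRUE, reason = ""),
                   min_n = 15, metabolites = rownames(P)),
              class = "stratified_report")
  }
  expect_true(flag_null_profile(mk_report(rep(0.5, 10), rep(0.1, 10)))[["s"]])
  # significant bands block the flag even with small ratios
  expect_false(flag_null_profile(mk_report(c(1e-4, rep(0.5, 9)),
                                           rep(0.1, 10)))[["s"]])
  # cohort-like ratios block the flag even with quiet bands
  expect_false(flag_null_profile(mk_report(rep(0.5, 10),
                                           rep(c(0.9, 1.1), 5)))[["s"]])
  # more than max_band1 borderline metabolites block the flag
  expect_false(flag_null_profile(mk_report(c(rep(0.005, 3), rep(0.5, 7)),
                                           rep(0.1, 10)))[["s"]])
})

test_that("a genotype with no metabolic group effect is flagged end to end", {
  ok <- vapply(1:20, function(s) {
    cohort <- quant_cohort(n = 600, seed = 1000 + s,
                           null_genotype = list(snp = "rs1",
                                                genotype = "BB"))
    rep_ <- stratified_report(cohort$metabolites, cohort$groups,
                              cohort$genotypes, min_n = 15)
    fl <- flag_null_profile(rep_)
    isTRUE(fl[["rs1_BB"]]) && !isTRUE(fl[["rs1_AA"]]) &&
      !isTRUE(fl[["rs1_AB"]])
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("stratified reports persist to delimited text in display order", {
  cohort <- quant_cohort(n = 300, seed = 29)
  rep_ <- stratified_report(cohort$metabolites, cohort$groups,
                            cohort$genotypes, min_n = 10)
  dir <- withr::local_tempdir()
  write_stratified_report(rep_, dir)
  bands <- read.delim(file.path(dir, "pattern_bands.tsv"))
  expect_equal(nrow(bands), length(rep_$metabolites))
  # rows run from the highest-ppm window downwards
  expect_equal(bands$metabolite, rev(rep_$metabolites))
  expect_true(file.exists(file.path(dir, "null_profile_flags.tsv")))
})
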