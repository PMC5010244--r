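test_that("generated genotypes follow Hardy-Weinberg proportions", {
  specs <- data.frame(snp_id = "s1", chromosome = 1, maf = 0.5, effect = 0)
  g <- generate_genotypes(specs, 1e5, seed = 11)
  het <- mean(g[, 1] == "AB")
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(het - 0.5), 3 * se)

  # minor-homozygote frequency at q = 0.2 matches q^2
  specs$maf <- 0.2
  g2 <- generate_genotypes(specs, 1e5, seed = 12)
  fBB <- mean(g2[, 1] == "BB")
  expect_lt(abs(fBB - 0.04), 3 * sqrt(0.04 * 0.96 / 1e5))
})

test_that("monomorphic or invalid MAFs are rejected and seeds reproduce", {
  bad <- data.frame(snp_id = "s1", chromosome = 1, maf = 0, effect = 0)
  expect_error(generate_genotypes(bad, 10), "MAF")
  bad$maf <- 0.7
  expect_error(generate_genotypes(bad, 10), "MAF")
  bad$maf <- NA_real_
  expect_error(generate_genotypes(bad, 10), "MAF")

  specs <- default_snp_specs()
  expect_identical(generate_genotypes(specs, 500, seed = 3),
                   generate_genotypes(specs, 500, seed = 3))
})

test_that("HWE chi-square test rejects at the nominal rate on generated SNPs", {
  specs <- data.frame(snp_id = sprintf("s%03d", 1:500), chromosome = 1,
                      maf = 0.3, effect = 0)
  g <- generate_genotypes(specs, 300, seed = 21)
  pvals <- apply(g, 2, function(cc) {
    hwe_chisq(sum(cc == "AA"), sum(cc == "AB"), sum(cc == "BB"))$p
  })
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("phenotypes follow the group-conditional clinical distributions", {
  cfg <- sim_config(n_subjects = 5000, seed = 5)
  ph <- generate_phenotypes(cfg, seed = 5)
  g3 <- ph$groups == 3
  expect_gt(sum(g3), 1000)
  se <- 21 / sqrt(sum(g3))
  expect_lt(abs(mean(ph$phenotypes$sbp[g3]) - 146), 3 * se)
  # group sizes track the mixing proportions
  props <- tabulate(ph$groups, 3) / 5000
  expect_lt(max(abs(props - cfg$group_proportions)), 0.03)
})

test_that("degenerate group proportions put every subject in one group", {
  cfg <- sim_config(n_subjects = 200, group_proportions = c(1, 0, 0),
                    seed = 2)
  ph <- generate_phenotypes(cfg, seed = 2)
  expect_true(all(ph$groups == 1L))
})

test_that("a per-allele log-odds effect on group 3 is recoverable", {
  specs <- data.frame(snp_id = "rs_eff", chromosome = 1, maf = 0.3,
                      effect = log(2))
  cfg <- sim_config(n_subjects = 1e4, snp_specs = specs, seed = 31)
  geno <- generate_genotypes(specs, 1e4, seed = 31)
  ph <- generate_phenotypes(cfg, geno, seed = 32)
  fit <- logistic_assoc(geno[, 1], as.integer(ph$groups == 3))
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - log(2)), 3 * fit$se)
})

test_that("noiseless spectra reproduce their window targets through the full pipeline", {
  panel <- serum_metabolite_panel()
  targets <- setNames(panel$mean_g1, panel$metabolite)
  sp <- generate_spectrum(targets)
  q <- quantify_windows(normalize_total_area(
    bin_spectrum(reference_spectrum(sp))), panel)
  expect_lt(max(abs(q - targets) / targets), 0.01)
})

test_that("zero targets give zero window integrals and scaling cancels", {
  panel <- serum_metabolite_panel()
  z <- setNames(rep(0, nrow(panel)), panel$metabolite)
  sp <- generate_spectrum(z)
  q <- quantify_windows(normalize_total_area(bin_spectrum(sp)), panel)
  expect_lt(max(abs(q)), 1e-8)

  targets <- setNames(panel$mean_g1, panel$metabolite)
  sp1 <- generate_spectrum(targets)
  sp2 <- nmr_spectrum(sp1$ppm, 2 * sp1$intensity, sp1$subject_id)
  q1 <- quantify_windows(normalize_total_area(bin_spectrum(sp1)), panel)
  q2 <- quantify_windows(normalize_total_area(bin_spectrum(sp2)), panel)
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("targets exceeding the normalization constant are rejected", {
  panel <- serum_metabolite_panel()
  big <- setNames(rep(5, nrow(panel)), panel$metabolite)  # sums to 135 > 100
  expect_error(generate_spectrum(big), "normalization constant")
  neg <- setNames(panel$mean_g1, panel$metabolite); neg[1] <- -1
  expect_error(generate_spectrum(neg), "nonnegative")
})

test_that("spectra are bit-reproducible under a fixed seed", {
  panel <- serum_metabolite_panel()
  targets <- setNames(panel$mean_g1, panel$metabolite)
  s1 <- generate_spectrum(targets, noise_sd = 0.05, seed = 9)
  s2 <- generate_spectrum(targets, noise_sd = 0.05, seed = 9)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("mean recovery over 200 noiseless spectra matches arbitrary targets within 1%", {
  panel <- serum_metabolite_panel()
  model <- spectrum_model(panel)
  set.seed(41)
  n <- 200
  targets <- sapply(seq_len(nrow(panel)), function(j)
    pmax(rnorm(n, panel$mean_g1[j], panel$sd_g1[j]), 0.01))
  colnames(targets) <- panel$metabolite
  spectra <- generate_spectra(targets, model = model)
  out <- process_spectra(spectra, panel)
  rel <- abs(colMeans(out$quant) - colMeans(targets)) / colMeans(targets)
  expect_lt(max(rel), 0.01)
})

test_that("cohort tables share subject ids and persist to delimited text", {
  cohort <- quant_cohort(n = 60, seed = 7)
  cfg2 <- sim_config(n_subjects = 20, snp_specs = cohort$config$snp_specs,
                     seed = 8)
  full <- generate_cohort(cfg2, spectra = TRUE)
  expect_identical(rownames(full$genotypes), full$phenotypes$id)
  expect_identical(rownames(full$metabolites), full$phenotypes$id)
  expect_identical(names(full$spectra), full$phenotypes$id)
  expect_true(all(full$metabolites >= 0))

  dir <- withr::local_tempdir()
  write_cohort(full, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "phenotypes.tsv", "genotypes.tsv", "genotypes.raw",
    "metabolites_true.tsv", "manifest.tsv")))))
  g <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"))
  calls <- full$genotypes
  attr(calls, "snp_info") <- NULL
  expect_identical(unname(g), unname(calls))
  raw <- read_genotypes_raw(file.path(dir, "genotypes.raw"))
  expect_identical(colnames(raw), colnames(full$genotypes))
  expect_equal(raw[, 1], setNames(
    match(full$genotypes[, 1], c("AA", "AB", "BB")) - 1,
    full$phenotypes$id))
  sp <- read_spectrum_tsv(file.path(dir, "spectra",
                                    paste0(full$phenotypes$id[1], ".tsv")))
  expect_equal(sp$ppm, full$spectra[[1]]$ppm, tolerance = 1e-8)
})
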