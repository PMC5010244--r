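#' Default SNP specifications for the synthetic cohort
#'
#' Five candidate SNPs on four genes implicated in lipid metabolism and
#' adipogenesis, with minor-allele frequencies typical of European
#' populations (for rs174577 and rs3803 the frequencies are back-computed
#' from published genotype counts; the others use a generic 0.30).
#' `effect` is the per-minor-allele log-odds of membership in the
#' three-or-more-risk-factor group (0 = no genetic effect).
#'
#' @return data.frame with columns `snp_id`, `chromosome`, `maf`, `effect`.
#' @export
default_snp_specs <- function() {
  data.frame(
    snp_id = c("rs174589", "rs174577", "rs2978663", "rs3803", "rs2272903"),
    chromosome = c(11, 11, 8, 3, 6),
    maf = c(0.30, 0.34, 0.30, 0.27, 0.30),
    effect = 0,
    stringsAsFactors = FALSE
  )
}

# Group-conditional phenotype distributions for the three risk-factor groups
# (group 1: <2 components; group 2: exactly 2; group 3: >= 3). Means/SDs on
# conventional clinical scales; triglycerides are generated on log10 scale.
.phenotype_params <- function() {
  list(
    male_frac = c(0.463, 0.579, 0.541),
    age      = list(mean = c(47, 57, 67),    sd = c(18, 19, 15)),
    bmi      = list(mean = c(24, 27, 30),    sd = c(3, 4, 4)),
    sbp      = list(mean = c(122, 134, 146), sd = c(17, 20, 21)),
    dbp      = list(mean = c(75, 81, 86),    sd = c(9, 10, 10)),
    glucose  = list(mean = c(86, 93, 109),   sd = c(11, 17, 30)),
    hdl      = list(mean = c(58, 47, 43),    sd = c(12, 12, 11)),
    log10_tg = list(mean = c(2.1, 2.3, 2.4), sd = c(0.2, 0.2, 0.2)),
    creatinine = list(mean = c(0.8, 0.9, 0.9), sd = c(0.2, 0.4, 0.6)),
    # abdominal-obesity prevalence by group drives sex-specific waist means
    # (thresholds 102 cm men / 88 cm women, waist sd 10 cm)
    abd_obesity_prev = c(0.299, 0.541, 0.676),
    waist_sd = 10,
    htn_treat_prev   = c(0.104, 0.203, 0.388),
    dm_treat_prev    = c(0.010, 0.034, 0.128),
    lipid_treat_prev = c(0.042, 0.062, 0.128),
    smoking_prev = 0.25
  )
}

#' Simulation configuration for a synthetic cohort
#'
#' Bundles and validates every parameter of the synthetic-cohort generator:
#' cohort size, SNP specifications, risk-group mixing proportions,
#' group-conditional metabolite relative levels, and the spectral model
#' (Lorentzian half-width, grid, noise, normalization constant).
#'
#' Group-2 metabolite parameters default to the midpoint of the group-1 and
#' group-3 reference means (SDs averaged), since reference levels are
#' tabulated for the two extreme groups only.
#'
#' @param n_subjects positive integer cohort size.
#' @param snp_specs data.frame as [default_snp_specs()]; `maf` must lie in
#'   (0, 0.5] (monomorphic markers are rejected).
#' @param group_proportions length-3 nonnegative vector summing to 1:
#'   baseline probabilities of risk groups 1, 2, 3.
#' @param metabolite_params data.frame with columns `metabolite`, `mean_g1`,
#'   `sd_g1`, `mean_g2`, `sd_g2`, `mean_g3`, `sd_g3`; defaults derived from
#'   the panel's reference levels.
#' @param panel metabolite window panel, see [serum_metabolite_panel()].
#' @param peak_width_ppm Lorentzian half-width at half-maximum (ppm).
#' @param noise_sd additive Gaussian noise SD per spectral grid point.
#' @param S total-area normalization constant for the analyzed region.
#' @param region analyzed chemical-shift region (ppm).
#' @param dppm spectral grid spacing (ppm).
#' @param null_genotype optional `list(snp =, genotype =)`: subjects carrying
#'   this genotype draw their metabolites from the group-1 distribution
#'   regardless of risk group, producing a metabolically "null-profile"
#'   stratum for end-to-end validation.
#' @param missing_rate per-call genotype missingness probability.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 600,
                       snp_specs = default_snp_specs(),
                       group_proportions = c(596, 290, 281) / 1167,
                       metabolite_params = NULL,
                       panel = serum_metabolite_panel(),
                       peak_width_ppm = 0.004,
                       noise_sd = 0.05,
                       S = 100,
                       region = c(0.50, 4.70),
                       dppm = 0.001,
                       null_genotype = NULL,
                       missing_rate = 0,
                       seed = 1L) {
  panel <- validate_panel(panel, region)
  if (is.null(metabolite_params)) {
    metabolite_params <- data.frame(
      metabolite = panel$metabolite,
      mean_g1 = panel$mean_g1, sd_g1 = panel$sd_g1,
      mean_g2 = (panel$mean_g1 + panel$mean_g3) / 2,
      sd_g2 = (panel$sd_g1 + panel$sd_g3) / 2,
      mean_g3 = panel$mean_g3, sd_g3 = panel$sd_g3,
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(n_subjects = as.integer(n_subjects), snp_specs = snp_specs,
              group_proportions = group_proportions,
              metabolite_params = metabolite_params, panel = panel,
              peak_width_ppm = peak_width_ppm, noise_sd = noise_sd, S = S,
              region = region, dppm = dppm, null_genotype = null_genotype,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` to validate.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (!is.numeric(n_subjects) || n_subjects < 1)
      stop("configuration error: n_subjects must be a positive integer",
           call. = FALSE)
    if (!all(is.finite(snp_specs$maf)) ||
        any(snp_specs$maf <= 0) || any(snp_specs$maf > 0.5))
      stop("configuration error: MAF must lie in (0, 0.5]", call. = FALSE)
    if (length(group_proportions) != 3 || any(group_proportions < 0) ||
        abs(sum(group_proportions) - 1) > 1e-9)
      stop("configuration error: group_proportions must be 3 nonnegative ",
           "values summing to 1", call. = FALSE)
    sds <- as.matrix(metabolite_params[, c("sd_g1", "sd_g2", "sd_g3")])
    if (any(!is.finite(sds)) || any(sds < 0))
      stop("configuration error: metabolite SDs must be nonnegative",
           call. = FALSE)
    if (!setequal(metabolite_params$metabolite, panel$metabolite))
      stop("configuration error: metabolite_params must cover the panel",
           call. = FALSE)
    if (peak_width_ppm <= 0 || noise_sd < 0 || S <= 0)
      stop("configuration error: peak_width_ppm and S must be positive, ",
           "noise_sd nonnegative", call. = FALSE)
  })
  invisible(config)
}

#' Generate genotype calls under Hardy-Weinberg equilibrium
#'
#' Draws each subject's genotype at each SNP from the multinomial
#' \eqn{(p^2, 2pq, q^2)} implied by the specified minor-allele frequency
#' \eqn{q}, with `B` the minor allele, so that by construction the simulated
#' markers satisfy Hardy-Weinberg equilibrium.
#'
#' @param snp_specs data.frame with `snp_id` and `maf` (in (0, 0.5]);
#'   see [default_snp_specs()].
#' @param n_subjects number of subjects.
#' @param seed integer seed (the call is deterministic given the seed).
#' @param missing_rate per-call probability of a missing genotype.
#' @return character matrix (subjects x SNPs) of calls `"AA"/"AB"/"BB"` (and
#'   `NA` for missing), with SNP metadata in `attr(, "snp_info")`.
#' @export
generate_genotypes <- function(snp_specs, n_subjects, seed = 1L,
                               missing_rate = 0) {
  if (!all(is.finite(snp_specs$maf)) ||
      any(snp_specs$maf <= 0) || any(snp_specs$maf > 0.5))
    stop("configuration error: MAF must lie in (0, 0.5]", call. = FALSE)
  set.seed(as.integer(seed))
  n <- as.integer(n_subjects)
  g <- matrix(NA_character_, n, nrow(snp_specs),
              dimnames = list(NULL, snp_specs$snp_id))
  for (j in seq_len(nrow(snp_specs))) {
    q <- snp_specs$maf[j]
    pr <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    g[, j] <- sample(c("AA", "AB", "BB"), n, replace = TRUE, prob = pr)
  }
  if (missing_rate > 0)
    g[matrix(runif(length(g)) < missing_rate, n)] <- NA_character_
  attr(g, "snp_info") <- snp_specs
  g
}

# minor-allele (B) dose 0/1/2 from call strings
.dose_B <- function(calls) {
  d <- match(calls, c("AA", "AB", "BB")) - 1L
  storage.mode(d) <- "double"
  d
}

#' Generate group-conditional phenotypes and true risk-group labels
#'
#' Assigns each subject a risk group (1: fewer than two components, 2:
#' exactly two, 3: three or more) and draws anthropometric, blood-pressure,
#' lipid, glucose, treatment and smoking variables from group-conditional
#' distributions. When any SNP in the configuration carries a nonzero
#' `effect`, group-3 membership follows a logistic model
#' \eqn{logit P(G=3) = logit \pi_3 + \sum_s \beta_s d_s} on the additive
#' minor-allele dose \eqn{d_s}; the remaining mass is split between groups 1
#' and 2 in their baseline ratio.
#'
#' @param config a [sim_config()].
#' @param genotypes genotype matrix from [generate_genotypes()] (required
#'   when any SNP effect is nonzero).
#' @param seed integer seed.
#' @return list with `phenotypes` (data.frame, one row per subject) and
#'   `groups` (integer vector in 1:3).
#' @export
generate_phenotypes <- function(config, genotypes = NULL, seed = 1L) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  n <- config$n_subjects
  pp <- .phenotype_params()
  pi3 <- config$group_proportions[3]
  eta <- rep(qlogis(pi3), n)
  beta <- config$snp_specs$effect
  if (any(beta != 0)) {
    if (is.null(genotypes))
      stop("configuration error: genotypes required when SNP effects are ",
           "nonzero", call. = FALSE)
    for (j in which(beta != 0)) {
      d <- .dose_B(genotypes[, config$snp_specs$snp_id[j]])
      d[is.na(d)] <- 2 * config$snp_specs$maf[j]  # impute at expectation
      eta <- eta + beta[j] * d
    }
  }
  in3 <- rbinom(n, 1, plogis(eta)) == 1
  p12 <- config$group_proportions[1] + config$group_proportions[2]
  p2given <- if (p12 > 0) config$group_proportions[2] / p12 else 0
  groups <- ifelse(in3, 3L, ifelse(runif(n) < p2given, 2L, 1L))

  draw <- function(par) rnorm(n, par$mean[groups], par$sd[groups])
  sex <- ifelse(runif(n) < pp$male_frac[groups], "M", "F")
  thr <- ifelse(sex == "M", 102, 88)
  waist_mu <- thr + pp$waist_sd * qnorm(pp$abd_obesity_prev[groups])
  ph <- data.frame(
    id = sprintf("S%0*d", max(4L, nchar(n)), seq_len(n)),
    sex = sex,
    age = draw(pp$age),
    bmi = draw(pp$bmi),
    waist = rnorm(n, waist_mu, pp$waist_sd),
    sbp = draw(pp$sbp),
    dbp = draw(pp$dbp),
    glucose = draw(pp$glucose),
    hdl = draw(pp$hdl),
    tg = 10^draw(pp$log10_tg),
    creatinine = pmax(draw(pp$creatinine), 0.3),
    htn_treat = runif(n) < pp$htn_treat_prev[groups],
    dm_treat = runif(n) < pp$dm_treat_prev[groups],
    lipid_treat = runif(n) < pp$lipid_treat_prev[groups],
    smoking = runif(n) < pp$smoking_prev,
    stringsAsFactors = FALSE
  )
  list(phenotypes = ph, groups = as.integer(groups))
}

#' Generate true metabolite relative levels
#'
#' Draws each subject's metabolite vector from the group-conditional normal
#' distributions of the configuration (independent across metabolites),
#' truncated at zero. If `config$null_genotype` is set, carriers of that
#' genotype draw from the group-1 distribution regardless of their group,
#' creating a stratum without any group-associated metabolic change.
#'
#' @param config a [sim_config()].
#' @param groups integer vector of risk groups (1:3).
#' @param genotypes genotype matrix (only needed for `null_genotype`).
#' @param seed integer seed.
#' @return numeric matrix (subjects x metabolites), panel order.
#' @export
generate_metabolites <- function(config, groups, genotypes = NULL, seed = 1L) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  n <- length(groups)
  mp <- config$metabolite_params
  mp <- mp[match(config$panel$metabolite, mp$metabolite), ]
  eff_groups <- groups
  if (!is.null(config$null_genotype)) {
    ng <- config$null_genotype
    if (is.null(genotypes))
      stop("configuration error: genotypes required for null_genotype",
           call. = FALSE)
    isnull <- !is.na(genotypes[, ng$snp]) & genotypes[, ng$snp] == ng$genotype
    eff_groups[isnull] <- 1L
  }
  means <- cbind(mp$mean_g1, mp$mean_g2, mp$mean_g3)
  sds <- cbind(mp$sd_g1, mp$sd_g2, mp$sd_g3)
  out <- matrix(0, n, nrow(mp), dimnames = list(NULL, mp$metabolite))
  for (j in seq_len(nrow(mp)))
    out[, j] <- pmax(rnorm(n, means[j, eff_groups], sds[j, eff_groups]), 0)
  out
}

#' Precompute the spectral peak model for a panel
#'
#' Builds, once per panel/grid combination, the quantities the spectrum
#' generator needs: unit-area Lorentzian peak shapes centred in each window
#' (a 1:1 doublet split by 0.012 ppm about 1.478 ppm for the window
#' containing the alanine doublet, used for chemical-shift referencing), the
#' discrete window-by-peak leakage matrix, per-peak in-region mass, and a
#' smooth filler signal (Hann bumps spanning the gaps between windows, hence
#' identically zero inside every window).
#'
#' Because Lorentzian tails extend beyond their window, the generator solves
#' the leakage system so that every window's integral matches its target
#' exactly rather than only approximately; see [generate_spectra()].
#'
#' @inheritParams sim_config
#' @param doublet_ppm centre of the reference doublet (ppm).
#' @param doublet_sep doublet peak separation (ppm).
#' @return list of class `spectrum_model`.
#' @export
spectrum_model <- function(panel = serum_metabolite_panel(),
                           peak_width_ppm = 0.004,
                           region = c(0.50, 4.70), dppm = 0.001,
                           doublet_ppm = 1.478, doublet_sep = 0.012) {
  panel <- validate_panel(panel, region)
  npt <- round((region[2] - region[1]) / dppm) + 1L
  x <- region[1] + dppm * (0:(npt - 1L))
  m <- nrow(panel)
  shapes <- matrix(0, npt, m, dimnames = list(NULL, panel$metabolite))
  for (j in seq_len(m)) {
    lo <- panel$ppm_lo[j]; hi <- panel$ppm_hi[j]
    if (lo < doublet_ppm && doublet_ppm < hi) {
      shapes[, j] <- 0.5 * dcauchy(x, doublet_ppm - doublet_sep / 2, peak_width_ppm) +
        0.5 * dcauchy(x, doublet_ppm + doublet_sep / 2, peak_width_ppm)
    } else {
      shapes[, j] <- dcauchy(x, (lo + hi) / 2, peak_width_ppm)
    }
  }
  M <- matrix(0, m, m, dimnames = list(panel$metabolite, panel$metabolite))
  region_mass <- numeric(m)
  for (j in seq_len(m)) {
    M[, j] <- .pl_integral(x, shapes[, j], panel$ppm_lo, panel$ppm_hi)
    region_mass[j] <- .pl_integral(x, shapes[, j], x[1], x[npt])
  }
  # filler: Hann bumps over the gaps between windows (and region edges)
  bounds <- rbind(c(region[1], panel$ppm_lo[1]),
                  cbind(panel$ppm_hi[-m], panel$ppm_lo[-1]),
                  c(panel$ppm_hi[m], region[2]))
  filler <- numeric(npt)
  for (k in seq_len(nrow(bounds))) {
    a <- bounds[k, 1]; b <- bounds[k, 2]
    if (b - a > 3 * dppm) {
      inside <- x > a & x < b
      filler[inside] <- filler[inside] + sin(pi * (x[inside] - a) / (b - a))^2
    }
  }
  filler_area <- .pl_integral(x, filler, x[1], x[npt])
  structure(list(ppm = x, shapes = shapes, leakage = M,
                 region_mass = region_mass, filler = filler,
                 filler_area = filler_area, panel = panel,
                 peak_width_ppm = peak_width_ppm, region = region,
                 dppm = dppm),
            class = "spectrum_model")
}

#' Generate synthetic serum spectra with prescribed window areas
#'
#' Builds one spectrum per subject as a sum of Lorentzian peaks (one per
#' panel window; the alanine window is rendered as the 1.478-ppm reference
#' doublet), a broad filler signal in the gaps between windows, and optional
#' additive Gaussian noise. Peak amplitudes are obtained by solving the
#' window-by-peak leakage system so that, on the noiseless spectrum, the
#' integral of every panel window equals its target, and the total area over
#' the analyzed region equals the normalization constant `S`. Consequently
#' the referencing -> binning -> normalization -> window-integration pipeline
#' recovers the targets exactly in the absence of noise, and unbiasedly in
#' expectation with noise.
#'
#' @param targets numeric matrix (subjects x metabolites) or vector of
#'   nonnegative window-area targets on the relative-level scale; columns
#'   must match the panel metabolites. Row sums must stay below `S`.
#' @param panel metabolite window panel.
#' @param peak_width_ppm Lorentzian half-width (ppm).
#' @param noise_sd additive Gaussian noise SD per grid point.
#' @param seed integer seed.
#' @param S normalization constant (total in-region area of each noiseless
#'   spectrum).
#' @param subject_ids optional character ids (default `S0001`, ...).
#' @param model optional precomputed [spectrum_model()] (overrides `panel`
#'   and `peak_width_ppm`).
#' @return list of [nmr_spectrum()] objects (`generate_spectra`), or a
#'   single one (`generate_spectrum`).
#' @export
generate_spectra <- function(targets, panel = serum_metabolite_panel(),
                             peak_width_ppm = 0.004, noise_sd = 0,
                             seed = 1L, S = 100, subject_ids = NULL,
                             model = NULL) {
  if (is.null(model))
    model <- spectrum_model(panel, peak_width_ppm)
  pm <- model$panel$metabolite
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1,
                                               dimnames = list(NULL, names(targets)))
  if (!is.null(colnames(targets))) {
    if (!setequal(colnames(targets), pm))
      stop("configuration error: target names must match the panel",
           call. = FALSE)
    targets <- targets[, pm, drop = FALSE]
  } else if (ncol(targets) != length(pm)) {
    stop("configuration error: one target per panel metabolite is required",
         call. = FALSE)
  }
  if (any(!is.finite(targets)) || any(targets < 0))
    stop("configuration error: targets must be finite and nonnegative",
         call. = FALSE)
  if (any(rowSums(targets) >= S))
    stop("configuration error: window targets exceed the normalization ",
         "constant S", call. = FALSE)
  n <- nrow(targets)
  A <- solve(model$leakage, t(targets))          # peak amplitudes, m x n
  if (min(A) < -1e-8)
    warning("leakage correction produced a negative peak amplitude; ",
            "spectra may dip below zero near narrow windows")
  mass <- colSums(A * model$region_mass)
  fscale <- (S - mass) / model$filler_area
  if (any(fscale < 0))
    stop("configuration error: window targets leave no room for the filler ",
         "signal under normalization constant S", call. = FALSE)
  Y <- model$shapes %*% A + outer(model$filler, fscale)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    Y <- Y + matrix(rnorm(length(Y), 0, noise_sd), nrow(Y))
  }
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%0*d", max(4L, nchar(n)), seq_len(n))
  lapply(seq_len(n), function(i)
    nmr_spectrum(model$ppm, Y[, i], subject_ids[i]))
}

#' @rdname generate_spectra
#' @param metabolite_targets named numeric vector, one target per panel
#'   metabolite.
#' @export
generate_spectrum <- function(metabolite_targets,
                              panel = serum_metabolite_panel(),
                              peak_width_ppm = 0.004, noise_sd = 0,
                              seed = 1L, S = 100, model = NULL) {
  generate_spectra(metabolite_targets, panel, peak_width_ppm, noise_sd,
                   seed, S, model = model)[[1]]
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative model of a [sim_config()]: HWE genotypes,
#' risk-group labels and phenotypes (with optional genotype effects on
#' group-3 membership), true metabolite levels, and per-subject 1H-NMR
#' spectra whose window areas match those levels. All component tables share
#' the same subject ids and order; all randomness derives from the
#' configuration seed.
#'
#' @param config a [sim_config()].
#' @param spectra logical; set `FALSE` to skip spectrum synthesis (faster
#'   when only tabular stages are exercised).
#' @return list of class `synthetic_cohort` with elements `phenotypes`,
#'   `groups`, `genotypes`, `metabolites`, `spectra`, `config`.
#' @export
generate_cohort <- function(config, spectra = TRUE) {
  validate_sim_config(config)
  s <- config$seed
  geno <- generate_genotypes(config$snp_specs, config$n_subjects, seed = s,
                             missing_rate = config$missing_rate)
  ph <- generate_phenotypes(config, geno, seed = s + 1L)
  met <- generate_metabolites(config, ph$groups, geno, seed = s + 2L)
  rownames(geno) <- ph$phenotypes$id
  rownames(met) <- ph$phenotypes$id
  spec <- NULL
  if (spectra) {
    model <- spectrum_model(config$panel, config$peak_width_ppm,
                            config$region, config$dppm)
    spec <- generate_spectra(met, noise_sd = config$noise_sd, seed = s + 3L,
                             S = config$S, subject_ids = ph$phenotypes$id,
                             model = model)
    names(spec) <- ph$phenotypes$id
  }
  structure(list(phenotypes = ph$phenotypes, groups = ph$groups,
                 genotypes = geno, metabolites = met, spectra = spec,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d subjects, %d SNPs, %d metabolites",
                     ", spectra: %s\n"),
              nrow(x$phenotypes), ncol(x$genotypes), ncol(x$metabolites),
              if (is.null(x$spectra)) "no" else "yes"))
  cat("  groups:", paste(sprintf("%d: n=%d", 1:3, tabulate(x$groups, 3)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to delimited text files
#'
#' Persists phenotypes (TSV, including the true group label), genotype calls
#' (TSV), an additive-coded 0/1/2 genotype file in PLINK `.raw` style, true
#' metabolite levels (TSV), per-subject spectra (two-column TSVs under
#' `spectra/`), and a manifest tying the pieces together.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- cohort$phenotypes
  ph$group <- cohort$groups
  write.table(ph, file.path(dir, "phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- data.frame(id = rownames(cohort$genotypes), cohort$genotypes,
                   check.names = FALSE)
  write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  write_genotypes_raw(cohort$genotypes, file.path(dir, "genotypes.raw"),
                      phenotype = as.integer(cohort$groups == 3) + 1L)
  met <- data.frame(id = rownames(cohort$metabolites), cohort$metabolites,
                    check.names = FALSE)
  write.table(met, file.path(dir, "metabolites_true.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- data.frame(id = ph$id, spectrum = NA_character_)
  if (!is.null(cohort$spectra)) {
    sdir <- file.path(dir, "spectra")
    dir.create(sdir, showWarnings = FALSE)
    for (id in names(cohort$spectra)) {
      f <- file.path("spectra", paste0(id, ".tsv"))
      write_spectrum_tsv(cohort$spectra[[id]], file.path(dir, f))
      files$spectrum[files$id == id] <- f
    }
  }
  write.table(files, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
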