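#' Configuration of a synthetic family methylation study
#'
#' Defaults emulate the study population the pipeline was built for:
#' ~183 phenotyped individuals sampled from extended Mexican-American-style
#' families, ages truncated-normal 19-75 (mean 42.15, sd 13.74), 55%
#' female, BMI mean 32.40 (sd 7.40) and waist circumference mean 104.86 cm
#' (sd 16.14), with sex-specific means as printed for the cohort. The
#' default pedigree template (18 three-generation families of 18: a founder
#' couple, 4 married children, 2 grandchildren per couple; cohort = 183
#' sampled members) reproduces the printed pair census in expectation
#' (about 195 first-degree and 229 second-degree cohort pairs versus the
#' printed 196 and 221).
#'
#' @param n_families number of families.
#' @param n_children founder couple's children per family.
#' @param n_grandchildren children per married child couple.
#' @param cohort_size number of phenotyped individuals sampled from the
#'   pedigree (`NA` = everyone).
#' @param family_template `"extended"` (3 generations) or `"trio"`.
#' @param p_female probability an individual is female.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age model
#'   (years).
#' @param bmi_mean_male,bmi_mean_female,bmi_sd BMI model (kg/m^2); the sd is
#'   the target total sd across the cohort.
#' @param waist_mean_male,waist_mean_female,waist_sd waist model (cm).
#' @param pheno_h2 familial (additive genetic) fraction of BMI/waist
#'   variance.
#' @param n_snps,maf_range,ld_rho variant model: SNPs simulated inside each
#'   probe's cis window, founder MAF range, first-order (adjacent-locus
#'   Gaussian copula) LD parameter.
#' @param window cis window (bp) within which simulated SNPs are placed.
#' @param detect_fail_rate fraction of detection p-values simulated as
#'   failures (>= 0.05).
#' @return list of class `study_config`.
#' @export
study_config <- function(n_families = 18, n_children = 4,
                         n_grandchildren = 2, cohort_size = 183,
                         family_template = c("extended", "trio"),
                         p_female = 0.55,
                         age_mean = 42.15, age_sd = 13.74,
                         age_min = 19, age_max = 75,
                         bmi_mean_male = 31.21, bmi_mean_female = 33.38,
                         bmi_sd = 7.40,
                         waist_mean_male = 104.08,
                         waist_mean_female = 105.50, waist_sd = 16.14,
                         pheno_h2 = 0.4,
                         n_snps = 3, maf_range = c(0.05, 0.5),
                         ld_rho = 0.5, window = 100000,
                         detect_fail_rate = 0.005) {
  cfg <- list(n_families = n_families, n_children = n_children,
              n_grandchildren = n_grandchildren, cohort_size = cohort_size,
              family_template = match.arg(family_template),
              p_female = p_female,
              age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, age_max = age_max,
              bmi_mean_male = bmi_mean_male,
              bmi_mean_female = bmi_mean_female, bmi_sd = bmi_sd,
              waist_mean_male = waist_mean_male,
              waist_mean_female = waist_mean_female, waist_sd = waist_sd,
              pheno_h2 = pheno_h2,
              n_snps = n_snps, maf_range = maf_range, ld_rho = ld_rho,
              window = window, detect_fail_rate = detect_fail_rate)
  stopifnot(cfg$pheno_h2 >= 0, cfg$pheno_h2 < 1,
            cfg$ld_rho >= 0, cfg$ld_rho < 1)
  class(cfg) <- "study_config"
  cfg
}

rsex <- function(n, p_female) {
  ifelse(stats::runif(n) < p_female, "female", "male")
}

#' Simulate an extended-family pedigree and its cohort pair census
#'
#' Builds `n_families` families from the configured template. The
#' `"extended"` template is three generations: a founder couple,
#' `n_children` children each married to an unrelated founder spouse, and
#' `n_grandchildren` children per couple. The phenotyped cohort is a random
#' sample of `cohort_size` members (the full pedigree is retained for the
#' relationship matrix, mirroring a study that profiles a subset of large
#' pedigrees). The pair census over the cohort is reported by relationship
#' degree.
#'
#' @param config a [study_config()].
#' @param seed RNG seed (mandatory: generation is fully deterministic given
#'   config + seed).
#' @return list of class `sim_pedigree`: `ped` (the full [pedigree]),
#'   `cohort` (ids), `A` (`relmat` over the full pedigree) and `census`
#'   (tibble over cohort pairs).
#' @export
simulate_pedigree <- function(config = study_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%02d", f)
    if (config$family_template == "trio") {
      dad <- paste0(fam, "_P1"); mom <- paste0(fam, "_P2")
      kid <- paste0(fam, "_C1")
      rows[[length(rows) + 1]] <- tibble::tibble(
        fam = fam,
        id = c(dad, mom, kid),
        father = c(NA, NA, dad),
        mother = c(NA, NA, mom),
        sex = c("male", "female", rsex(1, config$p_female)))
      next
    }
    gpa <- paste0(fam, "_G1A"); gma <- paste0(fam, "_G1B")
    rows[[length(rows) + 1]] <- tibble::tibble(
      fam = fam, id = c(gpa, gma), father = NA_character_,
      mother = NA_character_, sex = c("male", "female"))
    for (c in seq_len(config$n_children)) {
      child <- sprintf("%s_G2C%d", fam, c)
      child_sex <- rsex(1, config$p_female)
      spouse <- sprintf("%s_G2S%d", fam, c)
      spouse_sex <- ifelse(child_sex == "male", "female", "male")
      rows[[length(rows) + 1]] <- tibble::tibble(
        fam = fam, id = c(child, spouse),
        father = c(gpa, NA), mother = c(gma, NA),
        sex = c(child_sex, spouse_sex))
      kf <- if (child_sex == "male") child else spouse
      km <- if (child_sex == "male") spouse else child
      for (g in seq_len(config$n_grandchildren)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          fam = fam, id = sprintf("%s_G3C%d_%d", fam, c, g),
          father = kf, mother = km, sex = rsex(1, config$p_female))
      }
    }
  }
  ped <- pedigree(dplyr::bind_rows(rows))
  cohort <- if (is.na(config$cohort_size) ||
                config$cohort_size >= nrow(ped)) {
    ped$id
  } else {
    sort(sample(ped$id, config$cohort_size))
  }
  A <- additive_relationship(ped)
  census <- pair_degree_census(A, ids = cohort)
  structure(list(ped = ped, cohort = cohort, A = A, census = census),
            class = "sim_pedigree")
}

#' @export
print.sim_pedigree <- function(x, ...) {
  cat("sim_pedigree:", nrow(x$ped), "individuals,",
      length(x$cohort), "in cohort\n")
  print(x$census)
  invisible(x)
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder haplotypes are drawn from a Gaussian-copula model: latent AR(1)
#' normals with adjacent-locus correlation `ld_rho` thresholded at the
#' locus MAF, giving first-order linkage disequilibrium; `ld_rho = 0` gives
#' independent loci. Offspring receive one whole haplotype from each parent
#' (complete linkage within the simulated window), so genotypes are
#' Mendelian-consistent by construction.
#'
#' @param ped a [pedigree].
#' @param maf numeric vector of minor allele frequencies in (0, 0.5].
#' @param positions optional bp positions (default evenly spaced).
#' @param chrom chromosome label (default `"1"`).
#' @param ld_rho adjacent-locus copula correlation in `[0, 1)`.
#' @param seed RNG seed.
#' @return a [variant_set] with complete dosages (minor-allele copies).
#' @export
simulate_genotypes <- function(ped, maf, positions = NULL, chrom = "1",
                               ld_rho = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(maf <= 0 | maf > 0.5)) stop("MAF must lie in (0, 0.5]")
  set.seed(seed)
  L <- length(maf)
  if (is.null(positions)) positions <- seq_len(L) * 1000L
  ord <- topo_order(ped)
  n <- length(ord)
  father <- stats::setNames(ped$father, ped$id)
  mother <- stats::setNames(ped$mother, ped$id)
  H1 <- matrix(0L, n, L, dimnames = list(ord, NULL))
  H2 <- H1
  draw_hap <- function() {
    z <- numeric(L)
    z[1] <- stats::rnorm(1)
    if (L > 1) {
      for (j in 2:L) {
        z[j] <- ld_rho * z[j - 1] +
          sqrt(1 - ld_rho^2) * stats::rnorm(1)
      }
    }
    as.integer(z < stats::qnorm(maf))
  }
  for (i in ord) {
    if (is.na(father[[i]])) {
      H1[i, ] <- draw_hap()
      H2[i, ] <- draw_hap()
    } else {
      H1[i, ] <- if (stats::runif(1) < 0.5) H1[father[[i]], ] else
        H2[father[[i]], ]
      H2[i, ] <- if (stats::runif(1) < 0.5) H1[mother[[i]], ] else
        H2[mother[[i]], ]
    }
  }
  dosage <- H1 + H2
  dosage <- dosage[ped$id, , drop = FALSE]
  storage.mode(dosage) <- "double"
  ids <- sprintf("snp%04d", seq_len(L))
  colnames(dosage) <- ids
  info <- tibble::tibble(snp_id = ids, chrom = as.character(chrom),
                         pos = as.integer(positions),
                         allele_major = "A", allele_minor = "B",
                         maf_true = maf)
  variant_set(info, dosage)
}

#' Default 50-probe panel of generating models
#'
#' 10 heritable probes (h2 = 0.6), 10 cis-regulated probes (q2 = 0.3),
#' 10 age-affected probes and 20 pure-noise nulls; the labeled truth for
#' end-to-end discrimination tests.
#'
#' @param h2 heritability of the heritable probes.
#' @param q2 cis-SNP variance fraction of the cis probes.
#' @param age_sd_per_latent_sd age effect size: latent-trait SDs per age SD.
#' @return tibble of per-probe generating parameters.
#' @export
probe_panel_default <- function(h2 = 0.6, q2 = 0.3,
                                age_sd_per_latent_sd = 0.5) {
  tibble::tibble(
    probe_id = sprintf("GENE%03d_P%d_F", 1:50, 100 + 1:50),
    class = rep(c("heritable", "cis", "age", "null"), c(10, 10, 10, 20)),
    baseline = 0.5,
    h2 = rep(c(h2, 0, 0, 0), c(10, 10, 10, 20)),
    q2 = rep(c(0, q2, 0, 0), c(10, 10, 10, 20)),
    age_beta = rep(c(0, 0, age_sd_per_latent_sd, 0), c(10, 10, 10, 20)),
    sex_beta = 0
  )
}

#' Simulate methylation beta values over a pedigree
#'
#' Per probe, a latent trait
#' `y = g + a * dosage + b_age * age_std + b_sex * sex + e` is generated
#' with `g ~ MVN(0, h2 * A)`, the cis coefficient `a` chosen so the SNP
#' explains `q2` of the (unit) genetic-plus-residual variance, and
#' `e ~ N(0, 1 - h2 - q2)`. In `"bounded"` mode the beta value is the
#' inverse logit of `logit(baseline) + latent_scale * y` (always inside
#' (0, 1)); `"latent"` mode returns `baseline + latent_scale * y` directly
#' so variance-component recovery is exact. Detection p-values are drawn
#' near 0 with a configurable failure fraction.
#'
#' @param sim a `sim_pedigree` (or list with `ped`, `A`, `cohort`).
#' @param phenotypes phenotype tibble (`id`, `sex`, `age`) from
#'   [simulate_phenotypes()].
#' @param probe_models tibble as [probe_panel_default()]; columns
#'   `probe_id`, `baseline`, `h2`, `q2`, `age_beta`, `sex_beta`.
#' @param variants optional [variant_set]; cis probes are assigned SNPs
#'   round-robin. Required when any `q2 > 0`.
#' @param mode `"bounded"` or `"latent"`.
#' @param latent_scale SD of the latent trait on the (logit) beta scale.
#' @param detect_fail_rate fraction of detection p-values `>= 0.05`.
#' @param seed RNG seed.
#' @return list: `meth` (a [meth_set] over the cohort), `truth` (the probe
#'   models augmented with the assigned `snp_id`).
#' @export
simulate_methylation <- function(sim, phenotypes,
                                 probe_models = probe_panel_default(),
                                 variants = NULL,
                                 mode = c("bounded", "latent"),
                                 latent_scale = 0.35,
                                 detect_fail_rate = 0.005, seed) {
  if (missing(seed)) stop("seed is mandatory")
  mode <- match.arg(mode)
  if (any(probe_models$h2 + probe_models$q2 > 1)) {
    stop("h2 + q2 must be <= 1 for every probe")
  }
  set.seed(seed)
  cohort <- sim$cohort
  eg <- eigen_relationship(as.matrix(sim$A)[cohort, cohort])
  n <- length(cohort)
  phen <- phenotypes[match(cohort, phenotypes$id), ]
  age_std <- as.numeric(scale(phen$age))
  sexf <- as.numeric(phen$sex == "female")
  if (any(probe_models$q2 > 0) && is.null(variants)) {
    stop("variants required when any probe has q2 > 0")
  }
  snp_ids <- if (!is.null(variants)) variants$info$snp_id else character(0)
  truth <- probe_models
  if (!"snp_id" %in% names(truth)) truth$snp_id <- NA_character_
  cis_rows <- which(truth$q2 > 0 & is.na(truth$snp_id))
  if (length(cis_rows) > 0) {
    truth$snp_id[cis_rows] <-
      snp_ids[(seq_along(cis_rows) - 1) %% length(snp_ids) + 1]
  }
  beta <- matrix(NA_real_, n, nrow(truth),
                 dimnames = list(cohort, truth$probe_id))
  for (j in seq_len(nrow(truth))) {
    h2 <- truth$h2[j]; q2 <- truth$q2[j]
    g <- if (h2 > 0) simulate_polygenic_trait(eg, 1) * sqrt(h2) else 0
    cis <- 0
    if (q2 > 0) {
      d <- variants$dosage[cohort, truth$snp_id[j]]
      cis <- sqrt(q2) * (d - mean(d)) / stats::sd(d)
    }
    e <- stats::rnorm(n, sd = sqrt(max(1 - h2 - q2, 1e-12)))
    y <- g + cis + truth$age_beta[j] * age_std +
      truth$sex_beta[j] * sexf + e
    if (mode == "bounded") {
      beta[, j] <- stats::plogis(stats::qlogis(truth$baseline[j]) +
                                   latent_scale * y)
    } else {
      beta[, j] <- truth$baseline[j] + latent_scale * y
    }
  }
  detp <- matrix(stats::runif(length(beta), 0, 0.04), n, ncol(beta),
                 dimnames = dimnames(beta))
  fail <- matrix(stats::runif(length(beta)) < detect_fail_rate,
                 n, ncol(beta))
  detp[fail] <- stats::runif(sum(fail), 0.05, 1)
  list(meth = meth_set(beta, detp, check_range = (mode == "bounded")),
       truth = truth)
}

# truncated-normal sampler by rejection (bounds are a few sd wide)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate cohort phenotypes: age, sex, BMI, waist circumference
#'
#' Sex comes from the pedigree; age is truncated normal; BMI and waist are
#' sex-specific means plus an additive familial component
#' (`pheno_h2` of the residual variance, covariance `A`) plus noise, with
#' total variance calibrated to the configured cohort sds. An optional
#' methylation effect adds `meth_effect` trait-sd per methylation-sd of the
#' chosen probe to both obesity traits.
#'
#' @param sim a `sim_pedigree`.
#' @param config a [study_config()].
#' @param seed RNG seed.
#' @param methylation optional [meth_set] (for a methylation -> obesity
#'   effect).
#' @param meth_effect standardized effect of `meth_probe` on BMI and waist.
#' @param meth_probe probe id in `methylation` carrying the effect.
#' @return tibble: `id`, `sex`, `age`, `bmi`, `waist` (cohort individuals).
#' @export
simulate_phenotypes <- function(sim, config = study_config(), seed,
                                methylation = NULL, meth_effect = 0,
                                meth_probe = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cohort <- sim$cohort
  ped <- sim$ped
  n <- length(cohort)
  sex <- ped$sex[match(cohort, ped$id)]
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_min, config$age_max)
  eg <- if (config$pheno_h2 > 0) {
    eigen_relationship(as.matrix(sim$A)[cohort, cohort])
  } else NULL
  make_trait <- function(mean_male, mean_female, sd_total) {
    mu <- ifelse(sex == "female", mean_female, mean_male)
    # remove the between-sex variance from the residual budget
    pf <- mean(sex == "female")
    v_sex <- pf * (1 - pf) * (mean_female - mean_male)^2
    v_res <- max(sd_total^2 - v_sex, 0.1 * sd_total^2)
    y <- if (is.null(eg)) stats::rnorm(n) * sqrt(v_res) else
      simulate_polygenic_trait(eg, config$pheno_h2) * sqrt(v_res)
    out <- mu + unname(y)
    if (!is.null(methylation) && meth_effect != 0) {
      pid <- meth_probe %||% colnames(methylation$beta)[1]
      mv <- methylation$beta[cohort, pid]
      out <- out + meth_effect * sqrt(v_res) *
        (mv - mean(mv)) / stats::sd(mv)
    }
    out
  }
  tibble::tibble(
    id = cohort, sex = sex, age = age,
    bmi = make_trait(config$bmi_mean_male, config$bmi_mean_female,
                     config$bmi_sd),
    waist = make_trait(config$waist_mean_male, config$waist_mean_female,
                       config$waist_sd)
  )
}

#' Simulate a complete synthetic study
#'
#' Pedigree + cohort, phenotypes, cis SNP genotypes around each probe's
#' CpG, methylation matrix and the truth record, plus a probe manifest in
#' the pipeline's input format. All randomness derives from `seed`.
#'
#' @param config a [study_config()].
#' @param probe_models per-probe generating parameters
#'   (default [probe_panel_default()]).
#' @param mode `"bounded"` or `"latent"` (see [simulate_methylation()]).
#' @param seed RNG seed.
#' @return list of class `sim_study`: `ped`, `cohort`, `A`, `census`,
#'   `phenotypes`, `variants`, `meth`, `truth`, `manifest`, `config`,
#'   `seed`.
#' @export
simulate_study <- function(config = study_config(),
                           probe_models = probe_panel_default(),
                           mode = "bounded", seed) {
  if (missing(seed)) stop("seed is mandatory")
  sim <- simulate_pedigree(config, seed = seed)
  phen <- simulate_phenotypes(sim, config, seed = seed + 1L)
  n_probes <- nrow(probe_models)
  # one CpG per probe, spread over autosomes; cis SNPs inside the window
  manifest <- tibble::tibble(
    probe_id = probe_models$probe_id,
    chrom = as.character(rep_len(1:22, n_probes)),
    cpg_pos = 1000000L + 500000L * (seq_len(n_probes) - 1L),
    strand = "F"
  )
  manifest$probe_start <- manifest$cpg_pos - 25L
  manifest$probe_end <- manifest$cpg_pos + 25L
  vs <- NULL
  if (config$n_snps > 0) {
    # a block of n_snps SNPs inside every probe's cis window
    set.seed(seed + 2L)
    blocks <- rep(seq_len(n_probes), each = config$n_snps)
    maf <- stats::runif(length(blocks), config$maf_range[1],
                        config$maf_range[2])
    offsets <- as.integer(round(stats::runif(length(blocks), -0.9, 0.9) *
                                  config$window))
    vs <- simulate_genotypes(sim$ped, maf = maf, ld_rho = config$ld_rho,
                             seed = seed + 3L)
    vs$info$chrom <- manifest$chrom[blocks]
    vs$info$pos <- manifest$cpg_pos[blocks] + offsets
    probe_models$snp_id <- NA_character_
    cis_rows <- which(probe_models$q2 > 0)
    # wire each cis probe to the first SNP of its own block
    probe_models$snp_id[cis_rows] <-
      vs$info$snp_id[(cis_rows - 1) * config$n_snps + 1]
  }
  sm <- simulate_methylation(sim, phen, probe_models, variants = vs,
                             mode = mode,
                             detect_fail_rate = config$detect_fail_rate,
                             seed = seed + 4L)
  structure(list(ped = sim$ped, cohort = sim$cohort, A = sim$A,
                 census = sim$census, phenotypes = phen, variants = vs,
                 meth = sm$meth, truth = sm$truth, manifest = manifest,
                 config = config, seed = seed),
            class = "sim_study")
}

#' Engineered 1,505-probe QC demonstration panel
#'
#' Generates a beta/detection-p panel whose probe strata trip the QC chain
#' stages in its canonical order with fixed counts: 103 probes fail the
#' 0.97 call-rate filter, 355 show beta variation below 0.17, 641 are
#' strongly non-normal (bimodal) and fail the Lilliefors screen, 11 are
#' X-linked, and 395 survive. The strata are built with wide margins
#' (retained probes are regenerated until their Lilliefors Monte-Carlo
#' p-value exceeds 0.25 and their beta range exceeds 0.2), so the stage
#' counts are invariant to the seed.
#'
#' @param n_samples number of samples (default 183).
#' @param seed RNG seed.
#' @return list with `meth` (a [meth_set]), `manifest`, and
#'   `expected_counts` (the engineered per-stage exclusions).
#' @export
simulate_qc_panel <- function(n_samples = 183, seed = 1L) {
  set.seed(seed)
  strata <- rep(c("lowcall", "flat", "nonnormal", "xlinked", "good"),
                c(103, 355, 641, 11, 395))
  n_probes <- length(strata)
  beta <- matrix(NA_real_, n_samples, n_probes)
  detp <- matrix(stats::runif(n_samples * n_probes, 0, 0.04),
                 n_samples, n_probes)
  null_d <- lilliefors_null(n_samples, n_mc = 4000, seed = seed + 999L)
  clamp01 <- function(x) pmin(pmax(x, 0.001), 0.999)
  n_fail <- ceiling(n_samples * 0.04) + 2 # call rate safely below 0.97
  for (j in seq_len(n_probes)) {
    beta[, j] <- switch(
      strata[j],
      lowcall = clamp01(stats::rnorm(n_samples, 0.5, 0.06)),
      flat = clamp01(0.5 + stats::rnorm(n_samples, 0, 0.015)),
      nonnormal = clamp01(ifelse(stats::runif(n_samples) < 0.5,
                                 stats::rnorm(n_samples, 0.15, 0.02),
                                 stats::rnorm(n_samples, 0.85, 0.02))),
      {
        # xlinked / good: normal, variable, regenerated to wide margins
        repeat {
          b <- clamp01(stats::rnorm(n_samples, 0.5, 0.06))
          rng <- max(b) - min(b)
          p <- (1 + sum(null_d >= lilliefors_D(b))) / (length(null_d) + 1)
          if (rng > 0.2 && p > 0.25) break
        }
        b
      })
    if (strata[j] == "lowcall") {
      detp[sample.int(n_samples, n_fail), j] <-
        stats::runif(n_fail, 0.06, 1)
    }
  }
  ids <- sprintf("GENE%04d_P%d_%s", seq_len(n_probes),
                 100 + seq_len(n_probes),
                 rep_len(c("F", "R"), n_probes))
  rownames(beta) <- rownames(detp) <- sprintf("S%03d", seq_len(n_samples))
  colnames(beta) <- colnames(detp) <- ids
  manifest <- tibble::tibble(
    probe_id = ids,
    chrom = ifelse(strata == "xlinked", "X",
                   as.character(rep_len(1:22, n_probes))),
    cpg_pos = 1000L + 100L * seq_len(n_probes),
    strand = rep_len(c("F", "R"), n_probes),
    probe_start = 1000L + 100L * seq_len(n_probes) - 25L,
    probe_end = 1000L + 100L * seq_len(n_probes) + 25L
  )
  list(meth = meth_set(beta, detp),
       manifest = manifest,
       expected_counts = c(call_rate = 103, variation = 355,
                           lilliefors = 641, x_linked = 11,
                           remaining = 395))
}
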