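cohort_fixture <- function(seed = 20) {
  sp <- simulate_pedigree(study_config(n_families = 6, cohort_size = NA),
                          seed = seed)
  list(sp = sp, A = as.matrix(sp$A),
       eg = eigen_relationship(sp$A))
}

test_that("genotype QC removes monomorphic, rare-carrier and HWE failures", {
  fx <- cohort_fixture()
  ids <- fx$sp$ped$id
  n <- length(ids)
  set.seed(21)
  dos <- cbind(
    mono = rep(0, n),
    rare = c(rep(1, 9), rep(0, n - 9)),          # 9 carriers < 10
    lowcall = ifelse(runif(n) < 0.10, NA, rbinom(n, 2, 0.3)),
    good = rbinom(n, 2, 0.4))
  rownames(dos) <- ids
  info <- tibble::tibble(snp_id = colnames(dos), chrom = "1",
                         pos = c(100L, 200L, 300L, 400L))
  vs <- variant_set(info, dos)
  res <- genotype_qc(vs, fx$sp$ped)
  expect_false("mono" %in% res$data$info$snp_id)
  expect_false("rare" %in% res$data$info$snp_id)
  expect_false("lowcall" %in% res$data$info$snp_id)
  expect_true("good" %in% res$data$info$snp_id)
  expect_equal(res$report$n_after, res$report$n_before -
                 res$report$n_excluded)
})

test_that("founder HWE chi-square matches the textbook statistic", {
  # extreme disequilibrium: AA = 50, Aa = 0, aa = 50 among founders
  g <- c(rep(0, 50), rep(2, 50))
  p_obs <- methkin:::hwe_chisq_p(g)
  counts <- c(50, 0, 50); n <- 100; p <- 0.5
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((counts - expd)^2 / expd)
  expect_equal(p_obs, pchisq(x2, 1, lower.tail = FALSE))
  expect_lt(p_obs, 1e-4)

  # a pedigree whose genotyped samples contain no founders: HWE skipped
  fx <- cohort_fixture()
  kids <- setdiff(fx$sp$ped$id, founders(fx$sp$ped))
  set.seed(22)
  dos <- matrix(rbinom(length(kids) * 2, 2, 0.3), ncol = 2,
                dimnames = list(kids, c("s1", "s2")))
  vs <- variant_set(tibble::tibble(snp_id = c("s1", "s2"), chrom = "1",
                                   pos = c(1L, 2L)), dos)
  expect_warning(res <- genotype_qc(vs, fx$sp$ped), "founders")
  expect_equal(res$report$n_excluded[res$report$filter == "hwe_founders"],
               0L)
})

test_that("expected-dosage imputation preserves the mean exactly", {
  fx <- cohort_fixture()
  ids <- fx$sp$ped$id
  set.seed(23)
  d <- rbinom(length(ids), 2, 0.35)
  d[sample(length(d), 4)] <- NA
  dos <- matrix(as.double(d), ncol = 1, dimnames = list(ids, "s1"))
  vs <- variant_set(tibble::tibble(snp_id = "s1", chrom = "1", pos = 1L),
                    dos)
  res <- genotype_qc(vs, fx$sp$ped)
  expect_false(anyNA(res$data$dosage))
  expect_equal(mean(res$data$dosage[, 1]), mean(d, na.rm = TRUE))
})

test_that("proximal SNP selection: inclusive 100 kb window, signed distance", {
  cpg <- list(probe_id = "G1_P5_F", chrom = "7", cpg_pos = 500000L)
  info <- tibble::tibble(
    snp_id = c("at_edge_up", "beyond", "inside", "wrong_chr", "at_edge_dn"),
    chrom = c("7", "7", "chr7", "8", "7"),
    pos = c(400000L, 399999L, 512345L, 500000L, 600000L))
  sel <- select_proximal_snps(cpg, info, window = 100000)
  expect_setequal(sel$snp_id, c("at_edge_up", "inside", "at_edge_dn"))
  expect_equal(sel$distance[sel$snp_id == "at_edge_up"], -100000)
  expect_equal(sel$distance[sel$snp_id == "at_edge_dn"], 100000)

  # brute-force linear scan oracle on a random fixture
  set.seed(24)
  info2 <- tibble::tibble(snp_id = sprintf("s%02d", 1:20), chrom = "7",
                          pos = as.integer(runif(20, 3e5, 7e5)))
  sel2 <- select_proximal_snps(cpg, info2, window = 100000)
  keep <- abs(info2$pos - cpg$cpg_pos) <= 100000
  expect_setequal(sel2$snp_id, info2$snp_id[keep])

  # unannotated probe: skipped with a warning, empty result
  expect_warning(
    none <- select_proximal_snps(
      list(probe_id = "x", chrom = NA, cpg_pos = NA), info),
    "annotation")
  expect_equal(nrow(none), 0)
})

test_that("measured-genotype test equals the OLS likelihood-ratio slope
           test when A = I and no covariates", {
  n <- 40
  A <- diag(n)
  rownames(A) <- colnames(A) <- sprintf("i%02d", 1:n)
  set.seed(25)
  d <- stats::setNames(rbinom(n, 2, 0.3), rownames(A))
  y <- stats::setNames(0.4 * d + rnorm(n), rownames(A))
  res <- suppressWarnings(measured_genotype_test(y, d, NULL, A))
  # OLS LRT oracle: ML variance = RSS / n in both models
  rss1 <- sum(resid(lm(y ~ d))^2)
  rss0 <- sum(resid(lm(y ~ 1))^2)
  lambda <- n * log(rss0 / rss1)
  expect_equal(res$lambda, lambda, tolerance = 1e-6)
  expect_equal(res$p, pchisq(lambda, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("allele-label swap flips the sign but not the p-value", {
  fx <- cohort_fixture()
  ids <- fx$sp$ped$id
  set.seed(26)
  d <- stats::setNames(as.double(rbinom(length(ids), 2, 0.3)), ids)
  y <- stats::setNames(0.3 * d + rnorm(length(ids)), ids)
  r1 <- suppressWarnings(measured_genotype_test(y, d, NULL, fx$A))
  r2 <- suppressWarnings(measured_genotype_test(y, 2 - d, NULL, fx$A))
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
  expect_equal(r1$beta_std, -r2$beta_std, tolerance = 1e-6)
})

test_that("cis effect sign is recovered and nulls stay null", {
  fx <- cohort_fixture(seed = 27)
  ids <- fx$sp$ped$id
  n <- length(ids)
  set.seed(28)
  signs <- replicate(60, {
    d <- stats::setNames(as.double(rbinom(n, 2, 0.3)), ids)
    y <- stats::setNames(-0.5 * scale(d)[, 1] +
                           rnorm(n, sd = sqrt(0.75)), ids)
    suppressWarnings(measured_genotype_test(y, d, NULL, fx$A))$beta_std
  })
  expect_gte(mean(signs < 0), 0.95)

  # null: standardized effect near zero on average
  set.seed(29)
  null_effects <- replicate(60, {
    d <- stats::setNames(as.double(rbinom(n, 2, 0.3)), ids)
    y <- stats::setNames(rnorm(n), ids)
    suppressWarnings(measured_genotype_test(y, d, NULL, fx$A))$beta_std
  })
  expect_lt(abs(mean(null_effects)), 0.1)

  # monomorphic-in-subset error
  d0 <- stats::setNames(rep(1, n), ids)
  y <- stats::setNames(rnorm(n), ids)
  expect_error(suppressWarnings(measured_genotype_test(y, d0, NULL, fx$A)),
               "monomorphic")
})

test_that("obesity covariate test recovers direction and handles missing", {
  fx <- cohort_fixture(seed = 30)
  ids <- fx$sp$ped$id
  n <- length(ids)
  set.seed(31)
  meth <- stats::setNames(plogis(rnorm(n, 0, 0.5)), ids)
  # negative methylation -> waist effect
  waist <- stats::setNames(104 - 8 * scale(meth)[, 1] + rnorm(n, sd = 12),
                           ids)
  res <- suppressWarnings(
    obesity_covariate_test(waist, meth, NULL, fx$A))
  expect_lt(res$beta_std, 0)
  expect_lt(res$p, 0.01)

  # per-trait listwise n_used
  waist_na <- waist; waist_na[1] <- NA
  res_na <- suppressWarnings(
    obesity_covariate_test(waist_na, meth, NULL, fx$A))
  expect_equal(res_na$n_used, n - 1)

  # methylation independent of the trait: no signal
  set.seed(32)
  ps <- replicate(40, {
    bmi <- stats::setNames(32 + rnorm(n, sd = 7), ids)
    suppressWarnings(obesity_covariate_test(bmi, meth, NULL, fx$A))$p
  })
  expect_gt(mean(ps > 0.05), 0.8)
})
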