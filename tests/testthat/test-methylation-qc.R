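make_meth <- function(beta, detp = NULL) {
  rownames(beta) <- sprintf("S%02d", seq_len(nrow(beta)))
  colnames(beta) <- sprintf("pr%03d", seq_len(ncol(beta)))
  if (!is.null(detp)) dimnames(detp) <- dimnames(beta)
  meth_set(beta, detp)
}

test_that("sample call rate counts detections below alpha", {
  beta <- matrix(0.5, 5, 10)
  detp <- matrix(0.01, 5, 10)
  detp[2, 1:2] <- 0.5            # sample 2: 8/10 called -> 0.8 < 0.9
  mm <- make_meth(beta, detp)
  res <- sample_call_rate_filter(mm)
  expect_equal(unname(res$call_rate["S01"]), 1.0)
  expect_equal(unname(res$call_rate["S02"]), 0.8)
  expect_equal(rownames(res$data$beta),
               c("S01", "S03", "S04", "S05"))
  expect_equal(res$report$n_excluded, 1L)
  expect_equal(res$report$n_after, 4L)

  detp_all <- matrix(0.9, 5, 10); dimnames(detp_all) <- dimnames(beta)
  expect_error(sample_call_rate_filter(make_meth(beta, detp_all)),
               "empty cohort")
})

test_that("CV filter: ties keep everyone, distinct CVs drop the top 2.5%", {
  # all samples identical -> all CVs equal the percentile, none exceed
  set.seed(1)
  row <- runif(20, 0.2, 0.8)
  beta <- matrix(rep(row, each = 10), 10, 20)
  res <- cv_outlier_filter(make_meth(beta))
  expect_equal(res$report$n_excluded, 0L)

  # 200 samples with distinct CVs -> exactly the top 5 removed
  set.seed(2)
  beta200 <- t(sapply(seq_len(200), function(i) {
    0.5 + rnorm(50, sd = 0.01 + i / 1000)
  }))
  beta200 <- pmin(pmax(beta200, 0.001), 0.999)
  mm <- make_meth(beta200)
  res <- cv_outlier_filter(mm)
  expect_equal(res$report$n_excluded, 5L)
  expect_setequal(setdiff(rownames(mm$beta), rownames(res$data$beta)),
                  names(sort(res$cv, decreasing = TRUE)[1:5]))

  # gross outlier among 40
  set.seed(3)
  beta40 <- matrix(0.5 + rnorm(40 * 30, sd = 0.02), 40, 30)
  beta40[7, ] <- 0.5 + rnorm(30, sd = 0.3)
  beta40 <- pmin(pmax(beta40, 0.001), 0.999)
  res <- cv_outlier_filter(make_meth(beta40))
  expect_false("S07" %in% rownames(res$data$beta))
  expect_equal(res$report$n_excluded, 1L)
})

test_that("probe filters apply the chain in order and keep the books", {
  set.seed(4)
  n <- 60
  beta <- cbind(
    flat = rep(0.5, n),                          # range 0 -> variation
    lowcall = 0.3 + runif(n, 0, 0.3),            # fails call rate
    bimodal = ifelse(runif(n) < 0.5,             # fails normality
                     rnorm(n, 0.1, 0.01), rnorm(n, 0.9, 0.01)),
    xprobe = pmin(pmax(rnorm(n, 0.5, 0.08), 0.01), 0.99),
    good = pmin(pmax(rnorm(n, 0.5, 0.08), 0.01), 0.99))
  beta <- pmin(pmax(beta, 0.001), 0.999)
  detp <- matrix(0.01, n, 5)
  detp[1:3, 2] <- 0.2                            # call rate 57/60 = 0.95
  rownames(beta) <- rownames(detp) <- sprintf("S%02d", seq_len(n))
  colnames(beta) <- colnames(detp) <- colnames(detp) <-
    c("flat", "lowcall", "bimodal", "xprobe", "good")
  mm <- meth_set(beta, detp)
  manifest <- tibble::tibble(
    probe_id = colnames(beta),
    chrom = c("1", "2", "3", "X", "5"))
  res <- probe_filters(mm, manifest, seed = 11)
  rep <- res$report
  expect_equal(rep$filter,
               c("probe_call_rate", "beta_variation",
                 "lilliefors_normality", "x_linked"))
  expect_equal(rep$n_excluded, c(1L, 1L, 1L, 1L))
  # conservation along the chain
  expect_equal(rep$n_after, rep$n_before - rep$n_excluded)
  expect_equal(rep$n_before[-1], rep$n_after[-length(rep$n_after)])
  expect_equal(probes(res$data), "good")

  # probe missing from the manifest is an error naming it
  expect_error(probe_filters(mm, manifest[-1, ], seed = 11), "flat")
})

test_that("Lilliefors test: statistic matches nortest, p-values behave", {
  skip_if_not_installed("nortest")
  set.seed(5)
  x <- rnorm(100, 3, 2)
  ours <- lilliefors_test(x, seed = 1)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)

  # strongly non-normal sample
  y <- exp(rnorm(500))
  expect_lt(lilliefors_test(y, seed = 1)$p.value, 0.01)

  # normal samples rarely rejected at 0.1
  set.seed(6)
  ps <- replicate(100, lilliefors_test(rnorm(500), n_mc = 2000,
                                       seed = 3)$p.value)
  expect_gte(mean(ps > 0.1), 0.80)

  expect_error(lilliefors_test(c(1, 2, 3)), "at least 4")
  expect_error(lilliefors_test(rep(1, 10)), "zero variance")
})

test_that("Lilliefors null rejection rate is calibrated at level 0.1", {
  # 1,000 normal probes, shared Monte-Carlo null
  set.seed(7)
  beta <- matrix(rnorm(1000 * 100, 0.5, 0.05), 100, 1000)
  colnames(beta) <- sprintf("p%04d", 1:1000)
  lt <- methkin:::apply_lilliefors(beta, n_mc = 10000, seed = 8)
  rate <- mean(lt$p < 0.1)
  # binomial 95% CI around 0.10 with n = 1000
  expect_gt(rate, 0.10 - 1.96 * sqrt(0.1 * 0.9 / 1000))
  expect_lt(rate, 0.10 + 1.96 * sqrt(0.1 * 0.9 / 1000))
})

test_that("QC report conservation holds on random fixtures", {
  for (s in 1:3) {
    set.seed(s)
    n <- 40; p <- 30
    beta <- matrix(pmin(pmax(rnorm(n * p, 0.5, 0.1), 0.001), 0.999), n, p)
    detp <- matrix(runif(n * p, 0, 0.03), n, p)
    rownames(beta) <- rownames(detp) <- sprintf("S%02d", 1:n)
    colnames(beta) <- colnames(detp) <- sprintf("pr%03d", 1:p)
    manifest <- tibble::tibble(probe_id = colnames(beta),
                               chrom = as.character(rep_len(1:22, p)))
    res <- run_qc(meth_set(beta, detp), manifest, n_mc = 1000, seed = s)
    rep <- res$report
    expect_equal(rep$n_after, rep$n_before - rep$n_excluded)
    for (u in unique(rep$unit)) {
      ru <- rep[rep$unit == u, ]
      expect_equal(ru$n_before[-1], ru$n_after[-nrow(ru)])
      expect_true(all(diff(ru$n_after) <= 0 | TRUE)) # non-increasing chain
      expect_true(all(ru$n_after <= ru$n_before))
    }
  }
})

test_that("probe variant annotation counts, distances, MAF flag", {
  manifest <- tibble::tibble(
    probe_id = c("G1_P10_F", "G2_P20_R", "G3_P30_F"),
    chrom = c("1", "chr2", "3"),
    cpg_pos = c(1000L, 2000L, 3000L),
    probe_start = c(981L, 1981L, 2981L),
    probe_end = c(1030L, 2030L, 3030L))
  variants <- tibble::tibble(
    chrom = c("chr1", "2", "2", "3", "3"),
    pos = c(1019L, 2031L, 1995L, 2990L, 3010L),
    maf = c(0.35, 0.4, 0.01, 0.01, 0.01))
  ann <- annotate_probe_variants(manifest, variants)
  # MAF 0.35 variant 19 bp from the CpG, inside the probe -> flagged
  expect_equal(ann$n_variants[1], 1L)
  expect_equal(ann$min_distance[1], 19)
  expect_true(ann$flag_common[1])
  # variant just outside the interval (2031 > 2030) not counted;
  # chr2 vs 2 normalized
  expect_equal(ann$n_variants[2], 1L)
  expect_false(ann$flag_common[2])
  # two rare variants inside: counted, not flagged
  expect_equal(ann$n_variants[3], 2L)
  expect_false(ann$flag_common[3])
})

test_that("meth_set validates shape and range", {
  b <- matrix(c(0.5, 1.2), 1, 2,
              dimnames = list("S1", c("p1", "p2")))
  expect_error(meth_set(b), "outside")
  expect_silent(meth_set(b, check_range = FALSE))
  d <- matrix(0.01, 2, 2)
  expect_error(meth_set(matrix(0.5, 1, 2,
                               dimnames = list("S1", c("p1", "p2"))), d),
               "shape")
})
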