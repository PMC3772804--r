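# shared small pedigree cohort for the fits
ped_cohort <- function(n_families = 11, seed = 100) {
  sp <- simulate_pedigree(study_config(n_families = n_families,
                                       cohort_size = NA), seed = seed)
  eigen_relationship(sp$A)
}

test_that("rotated likelihood equals the dense MVN oracle", {
  # fixed parameters on the 6-member pedigree, loglik to 1e-8
  A <- as.matrix(additive_relationship(sixmember_ped()))
  set.seed(1)
  y <- rnorm(6)
  names(y) <- rownames(A)
  fit <- suppressWarnings(fit_polygenic(y, NULL, A))
  X <- matrix(1, 6, 1)
  s2 <- fit$sigma_g2 + fit$sigma_e2
  expect_equal(fit$loglik,
               dense_mvn_loglik(unname(y), X, fit$m, s2, fit$h2, A),
               tolerance = 1e-8)

  # eigen fit equals the dense-covariance ML fit on pedigrees <= 30
  for (s in 1:3) {
    sp <- simulate_pedigree(study_config(n_families = 1, n_children = 3,
                                         cohort_size = NA), seed = s)
    A <- as.matrix(sp$A) # 14 members
    set.seed(s)
    eg <- eigen_relationship(A)
    y <- methkin:::simulate_polygenic_trait(eg, 0.5)
    x <- rnorm(length(y))
    names(y) <- rownames(A)
    fit <- suppressWarnings(
      fit_polygenic(y, data.frame(x = x), A))
    oracle <- dense_ml_fit(unname(y), cbind(1, x), A)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
    expect_equal(fit$h2, oracle$h2, tolerance = 1e-4)
  }
})

test_that("identity A: h2 unidentifiable, boundary fit equals null model", {
  A <- diag(20)
  rownames(A) <- colnames(A) <- sprintf("i%02d", 1:20)
  set.seed(2)
  y <- stats::setNames(rnorm(20), rownames(A))
  expect_warning(fit <- fit_polygenic(y, NULL, A), "identifiable")
  null <- fit_polygenic(y, NULL, A, estimate_h2 = FALSE)
  expect_false(fit$identifiable)
  expect_equal(fit$loglik, null$loglik, tolerance = 1e-6)
})

test_that("h2 estimates respect bounds and trait-rescaling invariance", {
  eg <- ped_cohort(2)
  set.seed(3)
  for (h2 in c(0, 0.4, 0.9)) {
    y <- methkin:::simulate_polygenic_trait(eg, h2)
    fit <- suppressWarnings(fit_polygenic(y, NULL, eg))
    expect_gte(fit$h2, 0)
    expect_lt(fit$h2, 1)
    expect_gte(fit$sigma_g2, 0)
    expect_gt(fit$sigma_e2, 0)
    fit10 <- suppressWarnings(fit_polygenic(y * 10, NULL, eg))
    expect_equal(fit$h2, fit10$h2, tolerance = 1e-4)
  }
})

test_that("h2 recovery: small bias at h2 = 0.6, n about 200", {
  eg <- ped_cohort()
  expect_equal(length(eg$ids), 198)
  set.seed(4)
  est <- replicate(100, {
    y <- methkin:::simulate_polygenic_trait(eg, 0.6)
    suppressWarnings(fit_polygenic(y, NULL, eg))$h2
  })
  expect_lt(abs(mean(est) - 0.6), 0.07)
  expect_lt(sqrt(mean((est - 0.6)^2)), 0.17)
})

test_that("mixture LRT: boundary mass and chi-square tail oracle", {
  f <- structure(list(loglik = 10, n_used = 50), class = "polygenic_fit")
  n0 <- structure(list(loglik = 10, n_used = 50), class = "polygenic_fit")
  expect_equal(lrt_h2(f, n0)$p, 0.5)

  f$loglik <- 10 + 2.706 / 2
  res <- lrt_h2(f, n0)
  expect_equal(res$lambda, 2.706, tolerance = 1e-12)
  expect_equal(res$p, 0.5 * pchisq(2.706, 1, lower.tail = FALSE))
  expect_equal(res$p, 0.05, tolerance = 1e-3)

  f$loglik <- 10 - 1 # negative lambda beyond tolerance
  expect_error(lrt_h2(f, n0), "negative")
})

test_that("mixture LRT is never anticonservative under the null", {
  # the boundary mixture is conservative in finite family samples: the
  # null rejection rate must not exceed the binomial upper bound
  eg <- ped_cohort()
  set.seed(5)
  rate <- mean(replicate(400, {
    y <- methkin:::simulate_polygenic_trait(eg, 0)
    full <- suppressWarnings(fit_polygenic(y, NULL, eg))
    null <- fit_polygenic(y, NULL, eg, estimate_h2 = FALSE)
    lrt_h2(full, null)$p
  }) < 0.05)
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
})

test_that("covariate LRT: null p-values uniform, effects recovered", {
  eg <- ped_cohort(6, seed = 7) # 108 individuals
  n <- length(eg$ids)
  # null: covariate orthogonal to an h2 = 0 trait
  set.seed(8)
  ps <- replicate(150, {
    y <- stats::setNames(rnorm(n), eg$ids)
    X <- matrix(rnorm(n), n, 1, dimnames = list(eg$ids, "x"))
    suppressWarnings(covariate_lrt(y, X, eg, "x"))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # recovery of a simulated age effect: sign and magnitude
  set.seed(9)
  age <- rnorm(n, 45, 12)
  bs <- replicate(100, {
    y <- stats::setNames(0.03 * age + rnorm(n), eg$ids)
    X <- matrix(age, n, 1, dimnames = list(eg$ids, "age"))
    suppressWarnings(covariate_lrt(y, X, eg, "age"))$beta
  })
  expect_true(all(bs > 0))
  expect_lt(abs(mean(bs) - 0.03) / 0.03, 0.2)

  # constant covariate
  Xc <- matrix(1, n, 1, dimnames = list(eg$ids, "const"))
  y <- stats::setNames(rnorm(n), eg$ids)
  expect_error(covariate_lrt(y, Xc, eg, "const"), "constant")
  expect_error(covariate_lrt(y, Xc, eg, "absent"), "not present")
})

test_that("rank-deficient covariates raise a named error", {
  eg <- ped_cohort(2)
  n <- length(eg$ids)
  set.seed(10)
  x <- rnorm(n)
  X <- cbind(a = x, b = 2 * x)
  rownames(X) <- eg$ids
  y <- stats::setNames(rnorm(n), eg$ids)
  expect_error(suppressWarnings(fit_polygenic(y, X, eg)), "rank-deficient")
})

test_that("missing data are dropped listwise with A subset accordingly", {
  sp <- simulate_pedigree(study_config(n_families = 2, cohort_size = NA),
                          seed = 11)
  A <- as.matrix(sp$A)
  set.seed(11)
  y <- stats::setNames(rnorm(nrow(A)), rownames(A))
  y[3] <- NA
  fit <- suppressWarnings(fit_polygenic(y, NULL, A))
  expect_equal(fit$n_used, nrow(A) - 1)
  expect_false(names(y)[3] %in% fit$ids_used)
})

test_that("heritability power: null level, monotonicity, determinism", {
  eg <- ped_cohort(6, seed = 12)
  p0 <- heritability_power(eg, h2 = 0, n_reps = 200, seed = 13)
  expect_lt(p0$power, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
  p3 <- heritability_power(eg, h2 = 0.3, n_reps = 150, seed = 14)
  p6 <- heritability_power(eg, h2 = 0.6, n_reps = 150, seed = 14)
  expect_gte(p6$power, p3$power)
  expect_identical(p6,
                   heritability_power(eg, h2 = 0.6, n_reps = 150,
                                      seed = 14))
})

test_that("tidy and glance methods expose coefficients and fit stats", {
  eg <- ped_cohort(2)
  set.seed(15)
  y <- methkin:::simulate_polygenic_trait(eg, 0.5)
  x <- rnorm(length(y))
  fit <- suppressWarnings(
    fit_polygenic(y, data.frame(covar = x), eg))
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "covar"))
  gl <- glance(fit)
  expect_true(all(c("h2", "loglik", "n_used") %in% names(gl)))
  # refitting at the returned parameters reproduces the loglik
  A <- as.matrix(simulate_pedigree(
    study_config(n_families = 2, cohort_size = NA), seed = 100)$A)
  s2 <- fit$sigma_g2 + fit$sigma_e2
  ll <- dense_mvn_loglik(unname(y[eg$ids]), cbind(1, x),
                         fit$coefficients, s2, fit$h2, A)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})
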