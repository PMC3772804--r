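#' Precompute the eigendecomposition of a relationship matrix
#'
#' The polygenic likelihood is evaluated after rotating trait and design by
#' the eigenvectors of A, which diagonalizes the covariance
#' `sigma_g^2 A + sigma_e^2 I`. The decomposition depends only on A, so it
#' can be computed once and reused across probes or simulation replicates.
#'
#' @param A a `relmat` or symmetric relationship matrix.
#' @param tol PSD tolerance: smallest eigenvalue must be `>= -tol`.
#' @return object of class `relmat_eigen` with `ids`, `U`, `lambda`.
#' @export
eigen_relationship <- function(A, tol = 1e-8) {
  M <- as.matrix(A)
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- paste0("i", seq_len(nrow(M)))
  }
  if (max(abs(M - t(M))) > 1e-8) stop("relationship matrix not symmetric")
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -tol) {
    stop("relationship matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  }
  structure(list(ids = rownames(M), U = e$vectors,
                 lambda = pmax(e$values, 0)),
            class = "relmat_eigen")
}

# profile log-likelihood at a given h2 after rotation
# returns list(loglik, beta, s2) for weights w = h2*lambda + (1-h2)
.pg_profile <- function(h2, ystar, Xstar, lambda) {
  n <- length(ystar)
  w <- h2 * lambda + (1 - h2)
  w <- pmax(w, 1e-12)
  Xw <- Xstar / w
  XtWX <- crossprod(Xstar, Xw)
  XtWy <- crossprod(Xw, ystar)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf, beta = NULL, s2 = NA_real_))
  r <- ystar - Xstar %*% beta
  rss <- sum(r^2 / w)
  s2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(w)) + n)
  list(loglik = as.numeric(ll), beta = drop(beta), s2 = s2)
}

#' Fit the polygenic variance-components model by maximum likelihood
#'
#' Fits `t = m + sum_k b_k x_k + g + e` with `g ~ MVN(0, sigma_g^2 A)` and
#' `e ~ MVN(0, sigma_e^2 I)` by full maximum likelihood. The likelihood is
#' evaluated via a single eigendecomposition of A (rotate once, then 1-D
#' optimization of the profile likelihood over `h2 = sigma_g^2 /
#' (sigma_g^2 + sigma_e^2)`): a 64-point grid on `[0, 1 - 1e-6]` brackets
#' the optimum, refined by [stats::optimize()] to tolerance `1e-8`.
#' Samples with missing trait or covariates are dropped listwise and A is
#' subset accordingly.
#'
#' @param trait numeric trait vector; if named, names are matched to A's
#'   ids, otherwise positional alignment is assumed.
#' @param covariates optional numeric matrix / data frame of fixed-effect
#'   covariates (an intercept is always added).
#' @param A a `relmat`, relationship matrix, or a precomputed
#'   [eigen_relationship()] (only valid when no samples are dropped).
#' @param estimate_h2 if `FALSE`, fixes `sigma_g^2 = 0` (the null model).
#' @return object of class `polygenic_fit`: `m` (mean / intercept), `b`
#'   (named covariate coefficients), `sigma_g2`, `sigma_e2`, `h2`, `loglik`,
#'   `n_used`, `ids_used`, and `identifiable` (FALSE when the likelihood is
#'   flat in h2, e.g. A = I, in which case the boundary fit h2 = 0 is
#'   returned with a warning).
#' @export
fit_polygenic <- function(trait, covariates = NULL, A, estimate_h2 = TRUE) {
  al <- .pg_align(trait, covariates, A)
  y <- al$y; X <- al$X; ids <- al$ids
  n <- length(y)
  if (n < ncol(X) + 2) {
    stop("too few complete samples (", n, ") for ", ncol(X), " coefficients")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate set; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  eg <- al$eigen
  ystar <- drop(crossprod(eg$U, y))
  Xstar <- crossprod(eg$U, X)

  identifiable <- TRUE
  if (!estimate_h2) {
    h2 <- 0
    prof <- .pg_profile(0, ystar, Xstar, eg$lambda)
  } else {
    grid <- seq(0, 1 - 1e-6, length.out = 64)
    ll <- vapply(grid, function(h) .pg_profile(h, ystar, Xstar,
                                               eg$lambda)$loglik,
                 numeric(1))
    if (max(ll) - min(ll) < 1e-8) {
      identifiable <- FALSE
      warning("h2 not identifiable (likelihood flat in h2); ",
              "returning boundary fit h2 = 0")
      h2 <- 0
      prof <- .pg_profile(0, ystar, Xstar, eg$lambda)
    } else {
      k <- which.max(ll)
      lo <- grid[max(1, k - 1)]
      hi <- grid[min(length(grid), k + 1)]
      if (lo == hi) {
        h2 <- lo
      } else {
        opt <- stats::optimize(function(h) .pg_profile(h, ystar, Xstar,
                                                       eg$lambda)$loglik,
                               lower = lo, upper = hi, maximum = TRUE,
                               tol = 1e-8)
        h2 <- opt$maximum
        # the bracket endpoints can beat the interior optimum
        cand <- c(lo, h2, hi)
        cll <- vapply(cand, function(h) .pg_profile(h, ystar, Xstar,
                                                    eg$lambda)$loglik,
                      numeric(1))
        h2 <- cand[which.max(cll)]
      }
      prof <- .pg_profile(h2, ystar, Xstar, eg$lambda)
    }
  }
  beta <- stats::setNames(prof$beta, colnames(X))
  structure(list(
    m = unname(beta["(Intercept)"]),
    b = beta[setdiff(names(beta), "(Intercept)")],
    coefficients = beta,
    sigma_g2 = h2 * prof$s2,
    sigma_e2 = (1 - h2) * prof$s2,
    h2 = h2,
    loglik = prof$loglik,
    n_used = n,
    ids_used = ids,
    identifiable = identifiable,
    estimate_h2 = estimate_h2
  ), class = "polygenic_fit")
}

# align trait / covariates / A, listwise-drop missing, return rotation
.pg_align <- function(trait, covariates, A) {
  if (inherits(A, "relmat_eigen")) {
    ids <- A$ids
    y <- .pg_match(trait, ids)
    X <- .pg_design(covariates, ids, length(y))
    if (anyNA(y) || anyNA(X)) {
      stop("precomputed eigendecomposition cannot be used with missing ",
           "data; pass the relationship matrix itself")
    }
    return(list(y = y, X = X, ids = ids, eigen = A))
  }
  M <- as.matrix(A)
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- paste0("i", seq_len(nrow(M)))
  }
  ids <- rownames(M)
  y <- .pg_match(trait, ids)
  X <- .pg_design(covariates, ids, length(y))
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; ids <- ids[keep]
  M <- M[keep, keep, drop = FALSE]
  list(y = y, X = X, ids = ids, eigen = eigen_relationship(M))
}

.pg_match <- function(trait, ids) {
  if (!is.null(names(trait))) {
    unname(trait[ids])
  } else {
    if (length(trait) != length(ids)) {
      stop("unnamed trait vector must match the relationship matrix order (",
           length(trait), " vs ", length(ids), ")")
    }
    trait
  }
}

.pg_design <- function(covariates, ids, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(as.data.frame(covariates))
  if (ncol(X) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  if (!is.null(rownames(covariates)) &&
      all(ids %in% rownames(covariates))) {
    X <- X[ids, , drop = FALSE]
  } else if (nrow(X) != n) {
    stop("covariates must have one row per individual in A")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cbind("(Intercept)" = 1, X)
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat("Polygenic ML fit: n =", x$n_used,
      " h2 =", signif(x$h2, 4),
      " sigma_g2 =", signif(x$sigma_g2, 4),
      " sigma_e2 =", signif(x$sigma_e2, 4),
      " loglik =", format(x$loglik), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy polygenic_fit
#' @export
tidy.polygenic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance polygenic_fit
#' @export
glance.polygenic_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 loglik = x$loglik, n_used = x$n_used,
                 identifiable = x$identifiable)
}

#' Boundary-mixture likelihood-ratio test for heritability
#'
#' The LRT statistic `lambda = 2 (loglik_full - loglik_null)` for
#' `sigma_g^2 = 0` lies on the boundary of the parameter space, so its null
#' distribution is the mixture `1/2 chi^2_0 + 1/2 chi^2_1`:
#' `p = 0.5 * Pr(chi^2_1 > lambda)` (and `p = 0.5` at `lambda = 0`).
#'
#' @param full [fit_polygenic()] with `estimate_h2 = TRUE`.
#' @param null matching fit with `estimate_h2 = FALSE`.
#' @return tibble with `lambda`, `df`, `p`, `null_type`.
#' @export
lrt_h2 <- function(full, null) {
  if (full$n_used != null$n_used) stop("fits use different samples")
  lambda <- 2 * (full$loglik - null$loglik)
  if (lambda < -1e-6) {
    stop("negative LRT statistic (", format(lambda),
         "): optimization failure")
  }
  lambda <- max(lambda, 0)
  p <- if (lambda == 0) 0.5 else
    0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  tibble::tibble(lambda = lambda, df = 1L, p = p,
                 null_type = "mixture_boundary")
}

#' Heritability estimate with mixture-LRT p-value
#'
#' Fits the full polygenic model and the `sigma_g^2 = 0` null with the same
#' covariates and returns the heritability estimate and boundary-mixture
#' LRT p-value.
#'
#' @inheritParams fit_polygenic
#' @return one-row tibble: `h2`, `sigma_g2`, `sigma_e2`, `lambda`, `p`,
#'   `n_used`.
#' @export
estimate_heritability <- function(trait, covariates = NULL, A) {
  full <- fit_polygenic(trait, covariates, A, estimate_h2 = TRUE)
  null <- fit_polygenic(trait, covariates, A, estimate_h2 = FALSE)
  lrt <- lrt_h2(full, null)
  tibble::tibble(h2 = full$h2, sigma_g2 = full$sigma_g2,
                 sigma_e2 = full$sigma_e2, lambda = lrt$lambda, p = lrt$p,
                 n_used = full$n_used)
}

#' Likelihood-ratio test for a fixed-effect covariate
#'
#' Compares polygenic models with and without the target covariate (both
#' with the polygenic background re-estimated); p from `chi^2_1`. The
#' standardized coefficient is `b * sd(x) / sd(t)` over the samples used,
#' with the sign convention that a positive value means higher methylation
#' with increasing covariate value (e.g. older age, or female when sex is
#' coded female = 1).
#'
#' @param trait numeric trait vector (see [fit_polygenic()]).
#' @param covariates matrix / data frame containing `target`.
#' @param A relationship matrix or `relmat`.
#' @param target name of the covariate column to test.
#' @return one-row tibble: `term`, `beta`, `beta_std`, `lambda`, `df`, `p`,
#'   `n_used`.
#' @export
covariate_lrt <- function(trait, covariates, A, target) {
  covariates <- as.data.frame(covariates)
  if (!target %in% colnames(covariates)) {
    stop("target covariate not present: ", target)
  }
  x <- covariates[[target]]
  if (stats::sd(x, na.rm = TRUE) == 0) {
    stop("target covariate is constant: ", target)
  }
  full <- fit_polygenic(trait, covariates, A, estimate_h2 = TRUE)
  reduced_cols <- setdiff(colnames(covariates), target)
  red <- fit_polygenic(trait,
                       if (length(reduced_cols) == 0) NULL else
                         covariates[, reduced_cols, drop = FALSE],
                       A, estimate_h2 = TRUE)
  lambda <- max(0, 2 * (full$loglik - red$loglik))
  p <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  used <- full$ids_used
  tvec <- .pg_match(trait, used)
  xvec <- if (!is.null(rownames(covariates)) &&
              all(used %in% rownames(covariates))) {
    covariates[used, target]
  } else {
    x[match(used, .pg_align_ids(trait, A))]
  }
  b <- unname(full$b[target])
  tibble::tibble(term = target, beta = b,
                 beta_std = b * stats::sd(xvec, na.rm = TRUE) /
                   stats::sd(tvec, na.rm = TRUE),
                 lambda = lambda, df = 1L, p = p, n_used = full$n_used)
}

# ids in A order (helper for positional covariate alignment)
.pg_align_ids <- function(trait, A) {
  if (inherits(A, "relmat_eigen")) return(A$ids)
  M <- as.matrix(A)
  if (is.null(rownames(M))) paste0("i", seq_len(nrow(M))) else rownames(M)
}

#' Default covariate design: sex, age, age^2 and their interactions
#'
#' Builds the standard fixed-effect design from a phenotype table: `sex`
#' (female = 1, male = 0), `age`, `age2`, `sex_age`, `sex_age2`. Age is
#' mean-centered before the quadratic and interaction terms are formed;
#' raw age, age-squared and the interactions are otherwise so collinear
#' (r > 0.98 for adult age ranges) that single-term likelihood-ratio tests
#' lose nearly all power. Centering changes neither the model fit nor the
#' joint null, only the parameterization.
#'
#' @param phenotypes tibble with columns `id`, `sex`, `age`.
#' @return numeric matrix with row names = `id`.
#' @export
default_covariates <- function(phenotypes) {
  sex <- as.numeric(normalize_sex(phenotypes$sex) == "female")
  age <- phenotypes$age - mean(phenotypes$age, na.rm = TRUE)
  X <- cbind(sex = sex, age = age, age2 = age^2,
             sex_age = sex * age, sex_age2 = sex * age^2)
  rownames(X) <- phenotypes$id
  X
}

#' Simulation-based power to detect heritability
#'
#' Simulates traits with `t ~ MVN(0, h2 A + (1 - h2) I)`, fits the full and
#' null polygenic models and returns the fraction of replicates whose
#' boundary-mixture LRT p-value falls below `alpha`, with a binomial 95%
#' Monte-Carlo confidence interval.
#'
#' @param A relationship matrix, `relmat`, or [eigen_relationship()].
#' @param h2 true heritability in `[0, 1)`.
#' @param alpha test level.
#' @param n_reps number of replicates (>= 100).
#' @param seed RNG seed.
#' @return one-row tibble: `h2`, `alpha`, `n_reps`, `power`, `ci_lo`,
#'   `ci_hi`.
#' @export
heritability_power <- function(A, h2, alpha = 0.05, n_reps = 500,
                               seed = 1L) {
  stopifnot(h2 >= 0, h2 < 1, n_reps >= 100)
  eg <- if (inherits(A, "relmat_eigen")) A else eigen_relationship(A)
  set.seed(seed)
  hits <- vapply(seq_len(n_reps), function(i) {
    y <- simulate_polygenic_trait(eg, h2)
    full <- fit_polygenic(y, NULL, eg, estimate_h2 = TRUE)
    null <- fit_polygenic(y, NULL, eg, estimate_h2 = FALSE)
    lrt_h2(full, null)$p < alpha
  }, logical(1))
  pw <- mean(hits)
  se <- sqrt(pw * (1 - pw) / n_reps)
  tibble::tibble(h2 = h2, alpha = alpha, n_reps = n_reps, power = pw,
                 ci_lo = max(0, pw - 1.96 * se),
                 ci_hi = min(1, pw + 1.96 * se))
}

# draw one trait ~ MVN(0, h2*A + (1-h2)*I) using the rotated representation
simulate_polygenic_trait <- function(eg, h2, mean = 0) {
  w <- h2 * eg$lambda + (1 - h2)
  y <- drop(eg$U %*% (sqrt(w) * stats::rnorm(length(eg$lambda))))
  stats::setNames(y + mean, eg$ids)
}
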