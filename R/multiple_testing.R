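#' Bonferroni per-test threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("m must be a positive test count")
  }
  alpha / m
}

#' Sidak per-test threshold
#'
#' @inheritParams bonferroni_threshold
#' @return `1 - (1 - alpha)^(1/m)`.
#' @export
sidak_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("m must be a positive test count")
  }
  1 - (1 - alpha)^(1 / m)
}

#' Effective number of independent tests (Li & Ji)
#'
#' From the eigenvalues `lambda_i` of the test-statistic correlation matrix,
#' `Meff = sum_i f(|lambda_i|)` with
#' `f(x) = I(x >= 1) + (x - floor(x))`. A set of m independent tests gives
#' `Meff = m`; m copies of one test give `Meff = 1`.
#'
#' @param correlation square symmetric correlation matrix with unit
#'   diagonal.
#' @return effective test count (numeric scalar).
#' @export
li_ji_meff <- function(correlation) {
  C <- as.matrix(correlation)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8) {
    stop("correlation matrix must be square and symmetric")
  }
  if (max(abs(diag(C) - 1)) > 1e-8) stop("diagonal must be 1")
  l <- abs(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  sum((l >= 1) + (l - floor(l)))
}

#' Combine per-chromosome effective test counts
#'
#' The scans are corrected per chromosome and the effective counts summed;
#' the per-test threshold is `alpha / Meff_total` (`"division"`, the
#' default) or the exact Sidak value `1 - (1 - alpha)^(1/Meff_total)`.
#'
#' @param meffs numeric vector of per-chromosome effective counts (each
#'   >= 1).
#' @param alpha family level.
#' @param mode `"division"` or `"sidak"`.
#' @return one-row tibble: `meff_total`, `alpha`, `mode`, `threshold`.
#' @export
combine_meff <- function(meffs, alpha = 0.05, mode = c("division", "sidak")) {
  mode <- match.arg(mode)
  if (length(meffs) == 0) stop("empty list of effective test counts")
  if (any(meffs < 1)) stop("each effective count must be >= 1")
  total <- sum(meffs)
  thr <- if (mode == "division") bonferroni_threshold(alpha, total)
         else sidak_threshold(alpha, total)
  tibble::tibble(meff_total = total, alpha = alpha, mode = mode,
                 threshold = thr)
}

#' Per-chromosome Li-Ji correction for a dosage matrix
#'
#' Computes the SNP x SNP correlation matrix per chromosome
#' (pairwise-complete) on the post-QC dosages, the Li-Ji effective count per
#' chromosome, and the combined per-test threshold.
#'
#' @param vs a [variant_set] (or a dosage matrix plus `chrom` vector).
#' @param chrom chromosome per SNP (taken from `vs$info` when `vs` is a
#'   [variant_set]).
#' @param alpha family level.
#' @param mode threshold mode, see [combine_meff()].
#' @return list with `per_chromosome` (tibble `chrom`, `m`, `meff`) and
#'   `summary` (the [combine_meff()] row, plus `m_total`).
#' @export
li_ji_correction <- function(vs, chrom = NULL, alpha = 0.05,
                             mode = "division") {
  if (inherits(vs, "variant_set")) {
    dosage <- vs$dosage
    chrom <- vs$info$chrom
  } else {
    dosage <- vs
    if (is.null(chrom)) stop("chrom vector required with a dosage matrix")
  }
  chrom <- normalize_chrom(chrom)
  per <- purrr::map_dfr(unique(chrom), function(ch) {
    D <- dosage[, chrom == ch, drop = FALSE]
    keep <- apply(D, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
    D <- D[, keep, drop = FALSE]
    meff <- if (ncol(D) == 0) 0 else if (ncol(D) == 1) 1 else {
      C <- stats::cor(D, use = "pairwise.complete.obs")
      C[is.na(C)] <- 0
      diag(C) <- 1
      li_ji_meff(C)
    }
    tibble::tibble(chrom = ch, m = ncol(D), meff = meff)
  })
  per <- per[per$meff >= 1, ]
  summary <- combine_meff(per$meff, alpha = alpha, mode = mode)
  summary$m_total <- sum(per$m)
  list(per_chromosome = per, summary = summary)
}

#' Tail-area false discovery rate (q-values)
#'
#' Benjamini-Hochberg step-up q-values scaled by the estimated null
#' proportion `eta0` (Storey's estimator at `lambda`, clamped to (0, 1]):
#' `q_i = eta0 * min_{j: p_j >= p_i} (m * p_(j) / j)`. The significant set
#' at `q < 0.05` corresponds to an FDR of 5%.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param lambda Storey tuning parameter (default 0.5).
#' @param eta0 optionally force the null proportion (e.g. 1 for plain BH).
#' @return list with `q_values` (same order as input), `eta0` and `n`.
#' @export
tail_area_fdr <- function(pvalues, lambda = 0.5, eta0 = NULL) {
  p <- pvalues
  if (length(p) < 1) stop("need at least one p-value")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(eta0)) {
    # ">= lambda" so that boundary-mixture p-values (atom at 0.5) count:
    # under both the uniform and the half-chi-square-mixture null,
    # Pr(p >= 0.5) = 0.5 exactly
    eta0 <- mean(p >= lambda) / (1 - lambda)
    eta0 <- min(1, max(eta0, 1 / length(p)))
  } else {
    stopifnot(eta0 > 0, eta0 <= 1)
  }
  q <- pmin(1, eta0 * stats::p.adjust(p, method = "BH"))
  list(q_values = q, eta0 = eta0, n = length(p))
}
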