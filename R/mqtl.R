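#' Variant container: SNP info table plus dosage matrix
#'
#' @param info tibble with columns `snp_id`, `chrom`, `pos` and optionally
#'   `allele_major`, `allele_minor`, `maf`, `hwe_p`.
#' @param dosage numeric matrix, samples x SNPs (minor-allele copies in
#'   `[0, 2]`, possibly fractional, `NA` for missing); column names must
#'   match `info$snp_id`.
#' @return object of class `variant_set`.
#' @export
variant_set <- function(info, dosage) {
  info <- tibble::as_tibble(info)
  stopifnot(is.matrix(dosage),
            all(c("snp_id", "chrom", "pos") %in% names(info)))
  if (!identical(colnames(dosage), as.character(info$snp_id))) {
    stop("dosage column names must equal info$snp_id (same order)")
  }
  if (is.null(rownames(dosage))) stop("dosage needs sample row names")
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    stop("dosages outside [0, 2]")
  }
  structure(list(info = info, dosage = dosage), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$dosage), "samples x", nrow(x$info), "SNPs\n")
  invisible(x)
}

subset_variants <- function(vs, snps = NULL, samples = NULL) {
  info <- vs$info
  dos <- vs$dosage
  if (!is.null(snps)) {
    info <- info[match(snps, info$snp_id), ]
    dos <- dos[, snps, drop = FALSE]
  }
  if (!is.null(samples)) dos <- dos[samples, , drop = FALSE]
  variant_set(info, dos)
}

#' SNP quality control
#'
#' Applies, in order, on hard-called genotypes (`round(dosage)`): removal of
#' SNPs with call rate below `min_call`; monomorphic SNPs; SNPs whose minor
#' allele is carried by fewer than `min_minor_carriers` individuals; and
#' SNPs failing a founders-only chi-square Hardy-Weinberg test at
#' `p <= hwe_alpha`. Missing dosages of surviving SNPs are then replaced by
#' the SNP's observed mean dosage (expected dosage `2 x allele frequency`),
#' which preserves the mean exactly. Minor allele frequency is recomputed
#' from founders and stored in `info$maf`.
#'
#' @param vs a [variant_set].
#' @param ped the study [pedigree] (founders are used for HWE and MAF). If
#'   no founders overlap the samples, HWE is skipped with a warning.
#' @param min_call minimum call rate (default 0.95).
#' @param min_minor_carriers minimum number of minor-allele carriers
#'   (default 10).
#' @param hwe_alpha HWE exclusion level (default 1e-4).
#' @return list with `data` (filtered, imputed [variant_set]) and `report`
#'   (QC tibble).
#' @export
genotype_qc <- function(vs, ped, min_call = 0.95, min_minor_carriers = 10,
                        hwe_alpha = 1e-4) {
  hard <- round(vs$dosage)
  report <- list()

  rate <- colMeans(!is.na(hard))
  keep <- rate >= min_call
  report$call <- qc_row("snp_call_rate", min_call, "snps",
                        ncol(hard), sum(!keep))
  vs <- subset_variants(vs, snps = vs$info$snp_id[keep]); hard <- round(vs$dosage)

  mono <- apply(hard, 2, function(g) length(unique(g[!is.na(g)])) < 2)
  report$mono <- qc_row("monomorphic", NA_real_, "snps",
                        ncol(hard), sum(mono))
  vs <- subset_variants(vs, snps = vs$info$snp_id[!mono]); hard <- round(vs$dosage)

  # orient to the minor allele before carrier counting
  freq <- colMeans(hard, na.rm = TRUE) / 2
  flip <- freq > 0.5
  if (any(flip)) {
    vs$dosage[, flip] <- 2 - vs$dosage[, flip]
    hard <- round(vs$dosage)
    if (all(c("allele_major", "allele_minor") %in% names(vs$info))) {
      tmp <- vs$info$allele_major[flip]
      vs$info$allele_major[flip] <- vs$info$allele_minor[flip]
      vs$info$allele_minor[flip] <- tmp
    }
  }
  carriers <- colSums(hard >= 1, na.rm = TRUE)
  keep <- carriers >= min_minor_carriers
  report$carriers <- qc_row("minor_carriers", min_minor_carriers, "snps",
                            ncol(hard), sum(!keep))
  vs <- subset_variants(vs, snps = vs$info$snp_id[keep]); hard <- round(vs$dosage)

  fnd <- intersect(founders(ped), rownames(hard))
  if (length(fnd) == 0) {
    warning("no founders among genotyped samples: HWE filter skipped")
    hwe_p <- rep(NA_real_, ncol(hard))
    keep <- rep(TRUE, ncol(hard))
  } else {
    hwe_p <- apply(hard[fnd, , drop = FALSE], 2, hwe_chisq_p)
    keep <- is.na(hwe_p) | hwe_p > hwe_alpha
  }
  report$hwe <- qc_row("hwe_founders", hwe_alpha, "snps",
                       ncol(hard), sum(!keep))
  vs <- subset_variants(vs, snps = vs$info$snp_id[keep])
  hwe_p <- hwe_p[keep]

  # expected-dosage imputation (preserves the mean dosage exactly)
  mu <- colMeans(vs$dosage, na.rm = TRUE)
  for (j in seq_len(ncol(vs$dosage))) {
    nas <- is.na(vs$dosage[, j])
    if (any(nas)) vs$dosage[nas, j] <- mu[j]
  }
  fnd <- intersect(founders(ped), rownames(vs$dosage))
  maf_base <- if (length(fnd) > 0) vs$dosage[fnd, , drop = FALSE] else vs$dosage
  vs$info$maf <- colMeans(maf_base, na.rm = TRUE) / 2
  vs$info$hwe_p <- hwe_p
  list(data = vs, report = as_qc_report(dplyr::bind_rows(report)))
}

# chi-square HWE test (1 df) on hard-called genotype counts
hwe_chisq_p <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0) return(NA_real_)
  counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(NA_real_)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((counts - expd)^2 / expd)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Select SNPs proximal to a CpG site
#'
#' SNPs on the CpG's chromosome within `window` bp of the CpG position
#' (closed interval: a SNP exactly `window` bp away is included). The
#' signed distance `pos - cpg_pos` is retained (negative = upstream of the
#' CpG).
#'
#' @param cpg one-row manifest entry (list or tibble row) with `chrom` and
#'   `cpg_pos`. Probes without coordinates (`NA`) return an empty subset
#'   with a warning, mirroring unannotatable probes.
#' @param variants a [variant_set] or its `info` tibble.
#' @param window half-width in bp (default 100000).
#' @return tibble of selected SNP info rows with an added `distance` column.
#' @export
select_proximal_snps <- function(cpg, variants, window = 100000) {
  info <- if (inherits(variants, "variant_set")) variants$info else
    tibble::as_tibble(variants)
  if (is.na(cpg$chrom) || is.na(cpg$cpg_pos)) {
    warning("probe ", cpg$probe_id %||% "?",
            " has no annotation; skipped")
    return(dplyr::mutate(info[0, ], distance = integer(0)))
  }
  d <- info$pos - cpg$cpg_pos
  sel <- normalize_chrom(info$chrom) == normalize_chrom(cpg$chrom) &
    abs(d) <= window
  dplyr::mutate(info[sel, ], distance = d[sel])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measured-genotype association test
#'
#' Adds the SNP dosage as a fixed effect to the polygenic model and tests it
#' by likelihood ratio against the model without the dosage (both with the
#' polygenic background re-estimated); p from `chi^2_1`. The standardized
#' effect is `b / sd(r)` where `r` is the trait residualized on the
#' covariates (OLS) over the samples used: the per-minor-allele-copy effect
#' in trait-SD units, positive when the minor allele increases methylation.
#'
#' @param trait methylation vector (named by individual id, or aligned to
#'   A).
#' @param dosage named dosage vector for one SNP.
#' @param covariates optional covariate matrix / data frame.
#' @param A relationship matrix / `relmat` / [eigen_relationship()].
#' @return one-row tibble: `beta`, `beta_std`, `lambda`, `df`, `p`,
#'   `n_used`.
#' @export
measured_genotype_test <- function(trait, dosage, covariates = NULL, A) {
  ids <- .pg_align_ids(trait, A)
  dvec <- if (!is.null(names(dosage))) dosage[ids] else dosage
  if (stats::sd(dvec, na.rm = TRUE) == 0) {
    stop("SNP monomorphic in the analyzed subset")
  }
  Xd <- if (is.null(covariates)) {
    data.frame(dosage = unname(dvec))
  } else {
    cbind(as.data.frame(covariates), dosage = unname(dvec))
  }
  full <- fit_polygenic(trait, Xd, A, estimate_h2 = TRUE)
  used <- full$ids_used
  d_used <- dvec[match(used, ids)]
  if (stats::sd(d_used) == 0) {
    stop("SNP monomorphic in the analyzed subset")
  }
  red <- fit_polygenic(trait, covariates, A, estimate_h2 = TRUE)
  lambda <- max(0, 2 * (full$loglik - red$loglik))
  p <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  tvec <- .pg_match(trait, used)
  resid_sd <- if (is.null(covariates)) {
    stats::sd(tvec)
  } else {
    Xc <- as.data.frame(covariates)
    Xc <- if (!is.null(rownames(Xc)) && all(used %in% rownames(Xc))) {
      Xc[used, , drop = FALSE]
    } else {
      Xc[match(used, ids), , drop = FALSE]
    }
    stats::sd(stats::resid(stats::lm(tvec ~ ., data = Xc)))
  }
  b <- unname(full$b["dosage"])
  tibble::tibble(beta = b, beta_std = b / resid_sd,
                 lambda = lambda, df = 1L, p = p, n_used = full$n_used)
}

#' Test a CpG site as covariate of an obesity trait
#'
#' Polygenic model for the obesity trait (waist circumference or BMI) with
#' the methylation beta value added as a fixed covariate on top of the base
#' covariates; LRT (`chi^2_1`) of the methylation term. The standardized
#' coefficient is `b * sd(methylation) / sd(trait)`; positive values mean
#' increased methylation goes with increased obesity measure.
#'
#' @param obesity_trait named numeric vector (waist or BMI; `NA` allowed,
#'   dropped listwise).
#' @param methylation named methylation vector for one CpG site.
#' @param covariates base covariate matrix (see [default_covariates()]).
#' @param A relationship matrix / `relmat`.
#' @return one-row tibble: `beta`, `beta_std`, `lambda`, `df`, `p`,
#'   `n_used`.
#' @export
obesity_covariate_test <- function(obesity_trait, methylation,
                                   covariates = NULL, A) {
  ids <- .pg_align_ids(obesity_trait, A)
  mvec <- if (!is.null(names(methylation))) methylation[ids] else methylation
  Xm <- if (is.null(covariates)) {
    data.frame(methylation = unname(mvec))
  } else {
    cbind(as.data.frame(covariates), methylation = unname(mvec))
  }
  rownames(Xm) <- ids
  res <- covariate_lrt(obesity_trait, Xm, A, target = "methylation")
  tibble::tibble(beta = res$beta, beta_std = res$beta_std,
                 lambda = res$lambda, df = res$df, p = res$p,
                 n_used = res$n_used)
}

#' Cis-mQTL scan over probes and proximal SNPs
#'
#' For every analyzed probe with coordinates, selects SNPs within `window`
#' bp and runs [measured_genotype_test()] for each.
#'
#' @param mm a QC'd [meth_set].
#' @param manifest probe manifest.
#' @param vs a QC'd [variant_set].
#' @param A relationship matrix / `relmat`.
#' @param covariates base covariates.
#' @param window cis window in bp (default 100000).
#' @return tibble with one row per probe-SNP pair: `probe_id`, `snp_id`,
#'   `maf`, `distance`, `beta`, `beta_std`, `p`, `n_used`.
#' @export
mqtl_scan <- function(mm, manifest, vs, A, covariates = NULL,
                      window = 100000) {
  manifest <- tibble::as_tibble(manifest)
  ids <- .pg_align_ids(NULL, A)
  out <- purrr::map_dfr(probes(mm), function(pid) {
    row <- manifest[manifest$probe_id == pid, ]
    if (nrow(row) == 0 || is.na(row$chrom) || is.na(row$cpg_pos)) {
      return(NULL)
    }
    prox <- suppressWarnings(select_proximal_snps(row, vs, window))
    if (nrow(prox) == 0) return(NULL)
    trait <- mm$beta[, pid]
    purrr::map_dfr(seq_len(nrow(prox)), function(k) {
      snp <- prox$snp_id[k]
      res <- measured_genotype_test(trait, vs$dosage[, snp],
                                    covariates, A)
      dplyr::bind_cols(tibble::tibble(probe_id = pid, snp_id = snp,
                                      maf = prox$maf[k] %||% NA_real_,
                                      distance = prox$distance[k]), res)
    })
  })
  out
}
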