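#' Methylation beta-value container
#'
#' Holds a samples-by-probes matrix of beta values (methylation fractions in
#' `[0, 1]`, or `NA`) and an optional matched matrix of detection p-values.
#' Row names are sample ids, column names probe ids.
#'
#' @param beta numeric matrix, samples x probes, values in `[0, 1]` or `NA`.
#' @param detection_p optional numeric matrix of detection p-values with the
#'   same shape and dimnames.
#' @param check_range if `FALSE`, beta values are not required to lie in
#'   `[0, 1]` (used for latent-scale simulated traits).
#' @return object of class `meth_set`.
#' @export
meth_set <- function(beta, detection_p = NULL, check_range = TRUE) {
  stopifnot(is.matrix(beta), is.numeric(beta))
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix needs sample row names and probe column names")
  }
  if (check_range && any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values outside [0, 1]")
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta))) {
      stop("detection_p and beta must share shape")
    }
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
      stop("detection p-values outside [0, 1]")
    }
    dimnames(detection_p) <- dimnames(beta)
  }
  structure(list(beta = beta, detection_p = detection_p,
                 bounded = isTRUE(check_range)),
            class = "meth_set")
}

#' @export
print.meth_set <- function(x, ...) {
  cat("meth_set:", nrow(x$beta), "samples x", ncol(x$beta), "probes",
      if (is.null(x$detection_p)) "(no detection p-values)" else "", "\n")
  invisible(x)
}

#' @export
dim.meth_set <- function(x) dim(x$beta)

samples <- function(mm) rownames(mm$beta)
probes <- function(mm) colnames(mm$beta)

subset_meth <- function(mm, samples = NULL, probes = NULL) {
  b <- mm$beta
  d <- mm$detection_p
  if (!is.null(samples)) {
    b <- b[samples, , drop = FALSE]
    if (!is.null(d)) d <- d[samples, , drop = FALSE]
  }
  if (!is.null(probes)) {
    b <- b[, probes, drop = FALSE]
    if (!is.null(d)) d <- d[, probes, drop = FALSE]
  }
  meth_set(b, d, check_range = mm$bounded)
}

qc_row <- function(filter, threshold, unit, n_before, n_excluded) {
  tibble::tibble(filter = filter, threshold = threshold, unit = unit,
                 n_before = as.integer(n_before),
                 n_excluded = as.integer(n_excluded),
                 n_after = as.integer(n_before - n_excluded))
}

as_qc_report <- function(x) {
  class(x) <- c("qc_report", class(x))
  x
}

#' Sample call-rate filter
#'
#' A sample's call rate is the fraction of probes whose detection p-value is
#' below `detect_alpha`; samples with call rate below `min_rate` are
#' removed.
#'
#' @param mm a [meth_set] with detection p-values.
#' @param detect_alpha detection p-value cutoff defining a called probe
#'   (default 0.05).
#' @param min_rate minimum call rate to retain a sample (default 0.90).
#' @return list with `data` (filtered [meth_set]) and `report` (one-row
#'   QC tibble).
#' @export
sample_call_rate_filter <- function(mm, detect_alpha = 0.05,
                                    min_rate = 0.90) {
  if (is.null(mm$detection_p)) stop("detection p-values required")
  called <- mm$detection_p < detect_alpha & !is.na(mm$detection_p)
  rate <- rowMeans(called)
  keep <- rate >= min_rate
  if (!any(keep)) stop("empty cohort: all samples fail the call-rate filter")
  rep <- qc_row("sample_call_rate", min_rate, "samples",
                nrow(mm$beta), sum(!keep))
  list(data = subset_meth(mm, samples = samples(mm)[keep]),
       report = as_qc_report(rep),
       call_rate = stats::setNames(rate, samples(mm)))
}

#' Sample coefficient-of-variation outlier filter
#'
#' Per sample, CV = sd(beta over probes) / mean(beta over probes) on
#' non-missing values; samples whose CV strictly exceeds the `upper_pct`
#' empirical percentile (linear-interpolation quantile, type 7) are removed.
#'
#' @param mm a [meth_set] with at least 2 samples.
#' @param upper_pct upper percentile cut (default 97.5).
#' @return list with `data`, `report`, and the per-sample `cv` vector.
#' @export
cv_outlier_filter <- function(mm, upper_pct = 97.5) {
  if (nrow(mm$beta) < 2) stop("need at least 2 samples")
  mu <- rowMeans(mm$beta, na.rm = TRUE)
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("undefined CV: sample(s) with non-positive mean beta: ",
         paste(samples(mm)[!is.finite(mu) | mu <= 0], collapse = ", "))
  }
  sdv <- apply(mm$beta, 1, stats::sd, na.rm = TRUE)
  cv <- sdv / mu
  cut <- stats::quantile(cv, probs = upper_pct / 100, type = 7, names = FALSE)
  keep <- cv <= cut
  rep <- qc_row("sample_cv_outlier", upper_pct, "samples",
                nrow(mm$beta), sum(!keep))
  list(data = subset_meth(mm, samples = samples(mm)[keep]),
       report = as_qc_report(rep),
       cv = stats::setNames(cv, samples(mm)))
}

#' Probe quality-control chain
#'
#' Applies, in order: (1) probe call rate `>= min_call` (fraction of samples
#' with detection p-value below `detect_alpha`); (2) beta-value variation
#' (max - min over non-missing samples) `>= min_range`; (3) Monte-Carlo
#' Lilliefors normality screen, probes retained when the
#' Benjamini-Hochberg-adjusted q-value is `>= lillie_fdr`; (4) autosomal
#' probes only. The report records each stage, so
#' `n_before - n_excluded = n_after` holds along the chain.
#'
#' @param mm a [meth_set] (sample filters already applied).
#' @param manifest probe manifest tibble with columns `probe_id`, `chrom`
#'   (and optionally `cpg_pos`, `strand`, `probe_start`, `probe_end`).
#'   Every probe in `mm` must appear.
#' @param min_call minimum probe call rate (default 0.97).
#' @param min_range minimum beta variation (default 0.17).
#' @param lillie_fdr FDR level of the normality screen (default 0.1).
#' @param detect_alpha detection p-value cutoff (default 0.05).
#' @param n_mc Monte-Carlo null size for the Lilliefors p-values.
#' @param seed seed for the Lilliefors null distribution.
#' @return list with `data` (filtered [meth_set]), `report` (4-row QC
#'   tibble) and `lilliefors` (per-probe D, p, q for the probes tested).
#' @export
probe_filters <- function(mm, manifest, min_call = 0.97, min_range = 0.17,
                          lillie_fdr = 0.1, detect_alpha = 0.05,
                          n_mc = 10000, seed = 1L) {
  manifest <- tibble::as_tibble(manifest)
  missing_probes <- setdiff(probes(mm), manifest$probe_id)
  if (length(missing_probes) > 0) {
    stop("probe(s) absent from manifest: ",
         paste(utils::head(missing_probes, 5), collapse = ", "),
         if (length(missing_probes) > 5) " ..." else "")
  }
  report <- list()

  # 1. probe call rate
  if (!is.null(mm$detection_p)) {
    rate <- colMeans(mm$detection_p < detect_alpha & !is.na(mm$detection_p))
  } else {
    rate <- colMeans(!is.na(mm$beta))
  }
  keep <- rate >= min_call
  report$call <- qc_row("probe_call_rate", min_call, "probes",
                        ncol(mm$beta), sum(!keep))
  mm <- subset_meth(mm, probes = probes(mm)[keep])

  # 2. beta variation (range)
  rng <- apply(mm$beta, 2, function(b) {
    b <- b[!is.na(b)]
    if (length(b) < 2) 0 else max(b) - min(b)
  })
  keep <- rng >= min_range
  report$range <- qc_row("beta_variation", min_range, "probes",
                         ncol(mm$beta), sum(!keep))
  mm <- subset_meth(mm, probes = probes(mm)[keep])

  # 3. Lilliefors normality screen (FDR-adjusted)
  lt <- apply_lilliefors(mm$beta, n_mc = n_mc, seed = seed)
  keep <- lt$q >= lillie_fdr & !is.na(lt$q)
  report$lillie <- qc_row("lilliefors_normality", lillie_fdr, "probes",
                          ncol(mm$beta), sum(!keep))
  mm <- subset_meth(mm, probes = probes(mm)[keep])

  # 4. autosomal probes only
  chrom <- normalize_chrom(manifest$chrom[match(probes(mm),
                                                manifest$probe_id)])
  keep <- !chrom %in% c("X", "Y")
  report$sex_chrom <- qc_row("x_linked", NA_real_, "probes",
                             ncol(mm$beta), sum(!keep))
  mm <- subset_meth(mm, probes = probes(mm)[keep])

  list(data = mm,
       report = as_qc_report(dplyr::bind_rows(report)),
       lilliefors = lt)
}

# Lilliefors over the columns of a beta matrix; shares the Monte-Carlo null
# distribution across probes with the same effective sample size.
apply_lilliefors <- function(beta, n_mc = 10000, seed = 1L) {
  stats_list <- lapply(seq_len(ncol(beta)), function(j) {
    b <- beta[, j]
    b <- b[is.finite(b)]
    if (length(b) < 4 || stats::sd(b) == 0) {
      return(c(D = NA_real_, n = length(b)))
    }
    c(D = lilliefors_D(b), n = length(b))
  })
  D <- vapply(stats_list, `[[`, numeric(1), "D")
  n <- vapply(stats_list, `[[`, numeric(1), "n")
  p <- rep(NA_real_, length(D))
  for (nn in unique(n[!is.na(D)])) {
    null <- lilliefors_null(nn, n_mc = n_mc, seed = seed)
    sel <- which(n == nn & !is.na(D))
    p[sel] <- vapply(D[sel], function(d) (1 + sum(null >= d)) / (n_mc + 1),
                     numeric(1))
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  # untestable probes (too few values / zero variance) are excluded
  q[!ok & !is.na(D)] <- 0
  q[is.na(D)] <- 0
  tibble::tibble(probe_id = colnames(beta), D = D, n = as.integer(n),
                 p = p, q = q)
}

normalize_chrom <- function(x) {
  x <- toupper(sub("^chr", "", as.character(x), ignore.case = TRUE))
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x
}

#' Full sample + probe QC chain
#'
#' Convenience wrapper running [sample_call_rate_filter()],
#' [cv_outlier_filter()] and [probe_filters()] in the canonical order and
#' concatenating the QC report.
#'
#' @inheritParams probe_filters
#' @inheritParams sample_call_rate_filter
#' @inheritParams cv_outlier_filter
#' @return list with `data` and the combined `report`.
#' @export
run_qc <- function(mm, manifest, detect_alpha = 0.05, min_rate = 0.90,
                   upper_pct = 97.5, min_call = 0.97, min_range = 0.17,
                   lillie_fdr = 0.1, n_mc = 10000, seed = 1L) {
  s1 <- sample_call_rate_filter(mm, detect_alpha, min_rate)
  s2 <- cv_outlier_filter(s1$data, upper_pct)
  s3 <- probe_filters(s2$data, manifest, min_call = min_call,
                      min_range = min_range, lillie_fdr = lillie_fdr,
                      detect_alpha = detect_alpha, n_mc = n_mc, seed = seed)
  list(data = s3$data,
       report = as_qc_report(dplyr::bind_rows(s1$report, s2$report,
                                              s3$report)),
       lilliefors = s3$lilliefors)
}

#' Annotate probes with overlapping sequence variants
#'
#' Counts supplied variants that fall inside each probe's interval
#' (1-based, closed), the minimum distance from an overlapping variant to
#' the CpG position, the maximum overlapping minor allele frequency, and a
#' flag for any overlapping variant with MAF above `maf_flag`. Chromosome
#' names are normalized (`chr1` vs `1`) before matching.
#'
#' @param manifest tibble with `probe_id`, `chrom`, `cpg_pos`,
#'   `probe_start`, `probe_end`.
#' @param variants tibble with `chrom`, `pos`, `maf`.
#' @param maf_flag MAF threshold for flagging (default 0.05).
#' @return tibble with `probe_id`, `n_variants`, `min_distance`, `max_maf`,
#'   `flag_common` per probe.
#' @export
annotate_probe_variants <- function(manifest, variants, maf_flag = 0.05) {
  manifest <- tibble::as_tibble(manifest)
  variants <- tibble::as_tibble(variants)
  mchrom <- normalize_chrom(manifest$chrom)
  vchrom <- normalize_chrom(variants$chrom)
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    hit <- vchrom == mchrom[i] &
      variants$pos >= manifest$probe_start[i] &
      variants$pos <= manifest$probe_end[i]
    hits <- variants[hit, ]
    tibble::tibble(
      probe_id = manifest$probe_id[i],
      n_variants = nrow(hits),
      min_distance = if (nrow(hits)) min(abs(hits$pos - manifest$cpg_pos[i]))
                     else NA_integer_,
      max_maf = if (nrow(hits)) max(hits$maf) else NA_real_,
      flag_common = any(hits$maf > maf_flag)
    )
  })
}
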