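#' Run the full family-methylation study pipeline
#'
#' Executes the canonical stage order on a synthetic or file-based study:
#' sample QC (call rate, CV outliers), probe QC (call rate, variation,
#' Lilliefors screen, autosomes), heritability scan, cis measured-genotype
#' scan with per-chromosome Li-Ji correction, age and sex covariate scans,
#' obesity (waist / BMI) covariate scans, and multiple-testing summaries
#' (Bonferroni threshold and tail-area FDR q-values per scan). Identical
#' config + seed gives identical results.
#'
#' @param config a [study_config()] (a synthetic study is generated), a
#'   `sim_study` from [simulate_study()], or a named list of input file
#'   paths (`ped`, `beta`, `detection_p`, `manifest`, `dosage`,
#'   `phenotypes`) read via the package readers.
#' @param seed RNG seed for generation and the Lilliefors null.
#' @param out_dir optional directory: result tables are written as TSV.
#' @param thresholds named list overriding QC / correction defaults
#'   (`detect_alpha`, `min_rate`, `upper_pct`, `min_call`, `min_range`,
#'   `lillie_fdr`, `snp_min_call`, `min_minor_carriers`, `hwe_alpha`,
#'   `window`, `alpha`).
#' @param quiet suppress stage messages.
#' @return object of class `scan_report`: list with `qc`, `heritability`,
#'   `mqtl`, `mqtl_top`, `age`, `sex`, `obesity`, `corrections`, `summary`,
#'   `n_analyzed`, `truth` (when synthetic), `seed`.
#' @export
run_study <- function(config = study_config(), seed = 1L, out_dir = NULL,
                      thresholds = list(), quiet = FALSE) {
  th <- utils::modifyList(list(
    detect_alpha = 0.05, min_rate = 0.90, upper_pct = 97.5,
    min_call = 0.97, min_range = 0.17, lillie_fdr = 0.1,
    snp_min_call = 0.95, min_minor_carriers = 10, hwe_alpha = 1e-4,
    window = 100000, alpha = 0.05, n_mc = 10000), thresholds)
  say <- function(...) if (!quiet) message(...)

  study <- if (inherits(config, "sim_study")) {
    config
  } else if (inherits(config, "study_config")) {
    say("generating synthetic study (seed ", seed, ")")
    simulate_study(config, seed = seed)
  } else if (is.list(config) && !is.null(config$beta)) {
    read_study_files(config)
  } else {
    stop("config must be a study_config, sim_study or input-file list")
  }
  check_alignment(study)

  # --- QC ------------------------------------------------------------
  say("QC: sample call rate >= ", th$min_rate, ", CV <= p",
      th$upper_pct, "; probe call rate >= ", th$min_call,
      ", variation >= ", th$min_range, ", Lilliefors FDR ", th$lillie_fdr)
  qc <- run_qc(study$meth, study$manifest,
               detect_alpha = th$detect_alpha, min_rate = th$min_rate,
               upper_pct = th$upper_pct, min_call = th$min_call,
               min_range = th$min_range, lillie_fdr = th$lillie_fdr,
               n_mc = th$n_mc, seed = seed)
  mm <- qc$data
  analyzed <- probes(mm)
  kept_samples <- samples(mm)
  say("QC: ", length(kept_samples), " samples, ", length(analyzed),
      " probes analyzed")

  A <- as.matrix(study$A)[kept_samples, kept_samples]
  eg <- eigen_relationship(A)
  phen <- study$phenotypes[match(kept_samples, study$phenotypes$id), ]
  covs <- default_covariates(phen)

  # --- heritability scan ---------------------------------------------
  say("heritability scan over ", length(analyzed), " probes")
  herit <- purrr::map_dfr(analyzed, function(pid) {
    res <- suppressWarnings(
      estimate_heritability(mm$beta[, pid], covs, A))
    dplyr::bind_cols(tibble::tibble(probe_id = pid), res)
  })
  herit$q <- tail_area_fdr(herit$p)$q_values

  # --- cis mQTL scan ---------------------------------------------------
  mq <- mqtl_top <- tibble::tibble()
  corr_mqtl <- NULL
  if (!is.null(study$variants)) {
    gqc <- genotype_qc(study$variants |> subset_variants(
                         samples = kept_samples),
                       study$ped, min_call = th$snp_min_call,
                       min_minor_carriers = th$min_minor_carriers,
                       hwe_alpha = th$hwe_alpha)
    say("SNP QC: ", ncol(gqc$data$dosage), " of ",
        ncol(study$variants$dosage), " SNPs retained")
    qc$report <- as_qc_report(dplyr::bind_rows(qc$report, gqc$report))
    mq <- suppressWarnings(
      mqtl_scan(mm, study$manifest, gqc$data, A, covs,
                window = th$window))
    if (nrow(mq) > 0) {
      corr_mqtl <- li_ji_correction(gqc$data, alpha = th$alpha)
      mq$q <- tail_area_fdr(mq$p)$q_values
      mqtl_top <- mq |>
        dplyr::group_by(.data$probe_id) |>
        dplyr::summarise(
          n_snps = dplyr::n(),
          n_significant = sum(.data$p < corr_mqtl$summary$threshold),
          top_snp = .data$snp_id[which.min(.data$p)],
          maf = .data$maf[which.min(.data$p)],
          distance = .data$distance[which.min(.data$p)],
          beta_std = .data$beta_std[which.min(.data$p)],
          p = min(.data$p), .groups = "drop")
    }
  }

  # --- age and sex scans ----------------------------------------------
  say("age / sex covariate scans")
  cov_scan <- function(target) {
    purrr::map_dfr(analyzed, function(pid) {
      res <- suppressWarnings(
        covariate_lrt(mm$beta[, pid], covs, A, target = target))
      dplyr::bind_cols(tibble::tibble(probe_id = pid), res)
    })
  }
  age_scan <- cov_scan("age")
  age_scan$q <- tail_area_fdr(age_scan$p)$q_values
  sex_scan <- cov_scan("sex")
  sex_scan$q <- tail_area_fdr(sex_scan$p)$q_values

  # --- obesity scans ---------------------------------------------------
  say("obesity covariate scans (waist, BMI)")
  obesity <- purrr::map_dfr(c("waist", "bmi"), function(tr) {
    y <- stats::setNames(phen[[tr]], phen$id)
    purrr::map_dfr(analyzed, function(pid) {
      res <- suppressWarnings(
        obesity_covariate_test(y, mm$beta[, pid], covs, A))
      dplyr::bind_cols(tibble::tibble(trait = tr, probe_id = pid), res)
    })
  })
  obesity <- obesity |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(q = tail_area_fdr(.data$p)$q_values) |>
    dplyr::ungroup()

  # --- corrections ------------------------------------------------------
  m_probes <- length(analyzed)
  thr_bonf <- bonferroni_threshold(th$alpha, m_probes)
  corrections <- tibble::tibble(
    scan = c("heritability", "age", "sex", "obesity"),
    m = m_probes, method = "bonferroni", threshold = thr_bonf)
  if (!is.null(corr_mqtl)) {
    corrections <- dplyr::bind_rows(corrections, tibble::tibble(
      scan = "mqtl", m = corr_mqtl$summary$m_total,
      method = paste0("li_ji_", corr_mqtl$summary$mode),
      threshold = corr_mqtl$summary$threshold))
  }

  report <- structure(list(
    qc = qc$report, heritability = herit, mqtl = mq, mqtl_top = mqtl_top,
    age = age_scan, sex = sex_scan, obesity = obesity,
    corrections = corrections, li_ji = corr_mqtl,
    n_analyzed = length(analyzed), samples = kept_samples,
    truth = study$truth, seed = seed, thresholds = th),
    class = "scan_report")
  report$summary <- summarize_proportions(report, alpha = th$alpha)
  if (!is.null(out_dir)) write_scan_report(report, out_dir)
  report
}

check_alignment <- function(study) {
  ms <- rownames(study$meth$beta)
  bad <- setdiff(ms, study$phenotypes$id)
  if (length(bad) > 0) {
    stop("samples missing from phenotypes: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(ms, study$ped$id)
  if (length(bad) > 0) {
    stop("samples missing from pedigree: ", paste(bad, collapse = ", "))
  }
  if (!is.null(study$variants)) {
    bad <- setdiff(ms, rownames(study$variants$dosage))
    if (length(bad) > 0) {
      stop("samples missing from dosages: ", paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.scan_report <- function(x, ...) {
  cat("scan_report:", x$n_analyzed, "probes analyzed,",
      length(x$samples), "samples\n")
  print(x$summary)
  invisible(x)
}

#' Tiered significance summary in the reporting style of the study
#'
#' Counts and percentages of probes significant at the nominal level, at an
#' FDR of 5% (tail-area q < 0.05) and after Bonferroni correction, per
#' scan; for the heritability scan also the mean heritability estimate
#' overall and within each tier. Percentages are rounded to one decimal
#' (27 of 393 gives 6.9).
#'
#' @param report a `scan_report` from [run_study()].
#' @param alpha nominal / family-wise level (default 0.05).
#' @return tibble: `scan`, `tier`, `n`, `total`, `percent`, `mean_h2`.
#' @export
summarize_proportions <- function(report, alpha = 0.05) {
  herit <- report$heritability
  if (is.null(herit) || nrow(herit) == 0) stop("empty report")
  scans <- list(heritability = report$heritability, age = report$age,
                sex = report$sex)
  if (!is.null(report$mqtl_top) && nrow(report$mqtl_top) > 0) {
    mq <- report$mqtl_top
    mq$q <- tail_area_fdr(mq$p)$q_values # per-probe top-hit q
    scans$mqtl <- mq
  }
  purrr::map_dfr(names(scans), function(sc) {
    d <- scans[[sc]]
    total <- nrow(d)
    bonf <- if (sc == "mqtl" && !is.null(report$li_ji)) {
      report$li_ji$summary$threshold
    } else {
      bonferroni_threshold(alpha, total)
    }
    tiers <- list(nominal = d$p < alpha, fdr5 = d$q < 0.05,
                  bonferroni = d$p < bonf)
    purrr::map_dfr(names(tiers), function(tn) {
      sel <- tiers[[tn]]
      tibble::tibble(
        scan = sc, tier = tn, n = sum(sel), total = total,
        percent = proportion_percent(sum(sel), total),
        mean_h2 = if (sc == "heritability" && sum(sel) > 0) {
          mean(d$h2[sel])
        } else if (sc == "heritability") NA_real_ else NA_real_)
    })
  })
}

#' Percentage of k out of m, rounded to one decimal
#' @param k count of significant probes.
#' @param m total probes.
#' @return percentage rounded to one decimal place.
#' @export
proportion_percent <- function(k, m) {
  if (m < 1) stop("empty denominator")
  round(100 * k / m, 1)
}

#' Write the scan report tables as TSV files
#' @param report a `scan_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scan_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("qc", "heritability", "mqtl", "mqtl_top", "age", "sex",
            "obesity", "corrections", "summary")
  for (tb in tabs) {
    d <- report[[tb]]
    if (!is.null(d) && is.data.frame(d) && nrow(d) > 0) {
      readr::write_tsv(d, file.path(out_dir, paste0(tb, ".tsv")))
    }
  }
  invisible(out_dir)
}
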