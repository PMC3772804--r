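#' Read a beta-value (and detection p-value) matrix from TSV
#'
#' Layout: header row of probe ids, first column `sample_id`, one row per
#' sample.
#'
#' @param beta_path TSV of beta values.
#' @param detection_path optional TSV of detection p-values (same layout).
#' @param check_range see [meth_set()].
#' @return a [meth_set].
#' @export
read_meth_tsv <- function(beta_path, detection_path = NULL,
                          check_range = TRUE) {
  as_mat <- function(path) {
    d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(d[, -1])
    rownames(m) <- as.character(d[[1]])
    storage.mode(m) <- "double"
    m
  }
  beta <- as_mat(beta_path)
  detp <- if (!is.null(detection_path)) as_mat(detection_path) else NULL
  meth_set(beta, detp, check_range = check_range)
}

#' Write a [meth_set] as TSV file(s)
#' @param mm a [meth_set].
#' @param beta_path output TSV for beta values.
#' @param detection_path optional output TSV for detection p-values.
#' @export
write_meth_tsv <- function(mm, beta_path, detection_path = NULL) {
  wr <- function(m, path) {
    d <- tibble::as_tibble(m, rownames = "sample_id")
    readr::write_tsv(d, path)
  }
  wr(mm$beta, beta_path)
  if (!is.null(detection_path) && !is.null(mm$detection_p)) {
    wr(mm$detection_p, detection_path)
  }
  invisible(beta_path)
}

#' Read a probe manifest TSV
#'
#' Columns: `probe_id`, `chrom`, `cpg_pos`, `strand`, `probe_start`,
#' `probe_end`.
#'
#' @param path TSV path.
#' @return manifest tibble.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a phenotype table TSV (`id`, `sex`, `age`, `bmi`, `waist`)
#' @param path TSV path.
#' @return tibble.
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  d$id <- as.character(d$id)
  d
}

#' Read variants from a dosage TSV or a VCF
#'
#' Dosage TSV layout: columns `snp_id`, `chrom`, `pos`, `allele_major`,
#' `allele_minor`, then one column per sample holding minor-allele dosages.
#' Files ending in `.vcf` / `.vcf.gz` are read via the vcfR package (DS
#' format field if present, otherwise GT hard calls).
#'
#' @param path input path.
#' @return a [variant_set].
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(read_variants_vcf(path))
  }
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- intersect(c("snp_id", "chrom", "pos", "allele_major",
                      "allele_minor", "maf"), names(d))
  samp_cols <- setdiff(names(d), meta)
  dosage <- t(as.matrix(d[, samp_cols]))
  colnames(dosage) <- d$snp_id
  storage.mode(dosage) <- "double"
  variant_set(d[, meta], dosage)
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(g) {
      vapply(strsplit(gsub("\\|", "/", g), "/"), function(a) {
        if (anyNA(a) || any(a == ".")) NA_real_ else sum(a != "0")
      }, numeric(1))
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(v@gt) - 0)
  }
  dosage <- t(ds)
  colnames(dosage) <- ids
  info <- tibble::tibble(snp_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         allele_major = fix[, "REF"],
                         allele_minor = fix[, "ALT"])
  variant_set(info, dosage)
}

#' Write a [variant_set] as a dosage TSV
#' @param vs a [variant_set].
#' @param path output path.
#' @export
write_variants <- function(vs, path) {
  d <- dplyr::bind_cols(
    vs$info[, intersect(c("snp_id", "chrom", "pos", "allele_major",
                          "allele_minor", "maf"), names(vs$info))],
    tibble::as_tibble(t(vs$dosage)))
  readr::write_tsv(d, path)
  invisible(path)
}

# read a study from files (pipeline input mode)
read_study_files <- function(paths) {
  need <- c("ped", "beta", "manifest", "phenotypes")
  miss <- setdiff(need, names(paths))
  if (length(miss) > 0) {
    stop("missing input file entries: ", paste(miss, collapse = ", "))
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  ped <- read_pedigree(paths$ped)
  meth <- read_meth_tsv(paths$beta, paths$detection_p)
  list(ped = ped,
       A = additive_relationship(ped),
       cohort = rownames(meth$beta),
       meth = meth,
       manifest = read_manifest(paths$manifest),
       phenotypes = read_phenotypes(paths$phenotypes),
       variants = if (!is.null(paths$dosage)) read_variants(paths$dosage)
                  else NULL,
       truth = NULL)
}

#' Write a full synthetic study in the pipeline's input formats
#'
#' Emits PED, beta/detection TSVs, manifest, phenotype table, dosage TSV
#' and the truth table of generating parameters.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named list of the written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    ped = file.path(dir, "study.ped"),
    beta = file.path(dir, "beta.tsv"),
    detection_p = file.path(dir, "detection_p.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    dosage = file.path(dir, "dosage.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_pedigree(study$ped, paths$ped)
  write_meth_tsv(study$meth, paths$beta, paths$detection_p)
  readr::write_tsv(study$manifest, paths$manifest)
  readr::write_tsv(study$phenotypes, paths$phenotypes)
  if (!is.null(study$variants)) write_variants(study$variants, paths$dosage)
  if (!is.null(study$truth)) readr::write_tsv(study$truth, paths$truth)
  paths
}
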