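#' Construct a validated pedigree
#'
#' A pedigree is a tibble with one row per individual and columns `fam`,
#' `id`, `father`, `mother`, `sex` and optionally `mz` (a label shared by
#' monozygotic-twin groups; `NA` otherwise). Missing parents are `NA`;
#' individuals must have either zero or two recorded parents, every parent
#' id must exist in the pedigree, and the parentage graph must be acyclic.
#'
#' @param df data frame with columns `fam`, `id`, `father`, `mother`, `sex`
#'   (coded `"male"`/`"female"`, `"M"`/`"F"`, or `1`/`2`) and optional `mz`.
#' @return a tibble of class `pedigree`.
#' @export
pedigree <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("fam", "id", "father", "mother", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  }
  ped <- tibble::as_tibble(df)
  ped$fam    <- as.character(ped$fam)
  ped$id     <- as.character(ped$id)
  ped$father <- normalize_parent(ped$father)
  ped$mother <- normalize_parent(ped$mother)
  ped$sex    <- normalize_sex(ped$sex)
  if (!"mz" %in% names(ped)) ped$mz <- NA_character_
  ped$mz <- as.character(ped$mz)
  ped <- ped[, c("fam", "id", "father", "mother", "sex", "mz")]

  if (anyDuplicated(ped$id)) {
    stop("duplicated individual ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  one_parent <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(one_parent)) {
    stop("individuals with exactly one known parent (need zero or two): ",
         paste(ped$id[one_parent], collapse = ", "))
  }
  parents <- stats::na.omit(c(ped$father, ped$mother))
  unknown <- setdiff(parents, ped$id)
  if (length(unknown) > 0) {
    stop("parent id(s) not present in pedigree: ",
         paste(unique(unknown), collapse = ", "))
  }
  chk <- topo_order(ped) # errors on cycles
  stopifnot(length(chk) == nrow(ped))
  class(ped) <- c("pedigree", class(ped))
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "" | x == ".")] <- NA_character_
  x
}

normalize_sex <- function(x) {
  if (is.numeric(x)) x <- as.character(x)
  x <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    x %in% c("1", "m", "male")   ~ "male",
    x %in% c("2", "f", "female") ~ "female",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    stop("unrecognized sex code(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read a PED-style pedigree file
#'
#' Whitespace-delimited columns FAM, IID, FATHER, MOTHER, SEX and an
#' optional sixth MZ-twin-group column; `0` denotes a missing parent, sex is
#' coded 1 = male, 2 = female (M/F also accepted). No header line.
#'
#' @param path path to the pedigree file.
#' @return a validated [pedigree] tibble. Founders are the individuals with
#'   both parents missing.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("fam", "id", "father", "mother",
                                         "sex", "mz")[1:count_ped_cols(path)],
                           fill = FALSE)
  pedigree(raw)
}

count_ped_cols <- function(path) {
  first <- readLines(path, n = 1L)
  n <- length(strsplit(trimws(first), "[ \t]+")[[1]])
  if (!n %in% 5:6) stop("expected 5 or 6 whitespace-delimited columns, got ", n)
  n
}

#' Write a pedigree to a PED-style file
#' @param ped a [pedigree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  out$sex <- ifelse(out$sex == "male", "1", "2")
  cols <- c("fam", "id", "father", "mother", "sex")
  if (any(!is.na(out$mz))) {
    out$mz[is.na(out$mz)] <- "0"
    cols <- c(cols, "mz")
  }
  utils::write.table(out[, cols], path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

# Topological order of individuals (parents before offspring).
# Errors with the offending cycle if parentage is cyclic.
topo_order <- function(ped) {
  n <- nrow(ped)
  if (n == 0) return(character(0))
  idx <- stats::setNames(seq_len(n), ped$id)
  placed <- rep(FALSE, n)
  order_ids <- character(0)
  repeat {
    ready <- !placed &
      (is.na(ped$father) | placed[match(ped$father, ped$id)]) &
      (is.na(ped$mother) | placed[match(ped$mother, ped$id)])
    if (!any(ready)) {
      if (all(placed)) break
      stop("cyclic parentage involving: ",
           paste(ped$id[!placed], collapse = ", "))
    }
    placed[ready] <- TRUE
    order_ids <- c(order_ids, ped$id[ready])
  }
  order_ids
}

#' The study's printed relationship-degree coefficients
#'
#' Reporting table of relationship-degree labels and the coefficients the
#' source study printed for them. The 3rd- to 6th-degree values do not
#' follow the standard halving series and are kept verbatim for reporting
#' only; the additive-relationship recursion is always exact.
#'
#' @return tibble with columns `degree` and `printed_coefficient`.
#' @export
relationship_degree_table <- function() {
  tibble::tibble(
    degree = c("mz", "1st", "2nd", "3rd", "4th", "5th", "6th"),
    printed_coefficient = c(1, 0.5, 0.25, 0.0078, 0.0020, 0.0005, 0.0001)
  )
}

#' Default coefficient-to-degree bins for the pair census
#'
#' The standard halving series of expected additive-relationship values:
#' monozygotic 1, 1st degree 0.5, 2nd 0.25, 3rd 0.125, 4th 0.0625,
#' 5th 0.03125, 6th 0.015625.
#'
#' @return named numeric vector mapping degree label to coefficient.
#' @export
degree_bins <- function() {
  c("mz" = 1, "1st" = 0.5, "2nd" = 0.25, "3rd" = 0.125,
    "4th" = 0.0625, "5th" = 0.03125, "6th" = 0.015625)
}

#' Additive genetic relationship matrix from a pedigree
#'
#' Computes the numerator relationship matrix A by the tabular recursion:
#' processing individuals so parents precede offspring,
#' `A[i, j] = (A[father(i), j] + A[mother(i), j]) / 2` for previously placed
#' `j`, and `A[i, i] = 1 + A[father(i), mother(i)] / 2`. Founders are
#' assumed non-inbred and mutually unrelated. Monozygotic twins (shared
#' `mz` label) are forced to coefficient 1 and identical relationships to
#' everyone else. A parent-offspring or full-sibling pair has coefficient
#' 0.5; grandparent-grandchild, avuncular, half-sib and double-first-cousin
#' pairs 0.25.
#'
#' @param ped a [pedigree].
#' @return object of class `relmat`: list with `ids`, the symmetric matrix
#'   `A` (dimnames = ids) and `degree_table` (see
#'   [relationship_degree_table()]).
#' @export
additive_relationship <- function(ped) {
  ped <- if (inherits(ped, "pedigree")) ped else pedigree(ped)
  ord <- topo_order(ped)
  n <- length(ord)
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  father <- stats::setNames(ped$father, ped$id)
  mother <- stats::setNames(ped$mother, ped$id)
  mz     <- stats::setNames(ped$mz, ped$id)
  for (k in seq_len(n)) {
    i <- ord[k]
    f <- father[[i]]; m <- mother[[i]]
    if (is.na(f)) {
      A[i, i] <- 1
      # founders unrelated: row already 0
    } else {
      if (k > 1) {
        prev <- ord[seq_len(k - 1)]
        A[i, prev] <- (A[f, prev] + A[m, prev]) / 2
        A[prev, i] <- A[i, prev]
      }
      A[i, i] <- 1 + A[f, m] / 2
    }
    if (!is.na(mz[[i]])) {
      prior_twins <- ord[seq_len(k - 1)][mz[ord[seq_len(k - 1)]] %in% mz[[i]]]
      for (tw in prior_twins) {
        A[i, ] <- A[tw, ]
        A[, i] <- A[, tw]
        A[i, tw] <- A[tw, i] <- 1
        A[i, i] <- A[tw, tw]
      }
    }
  }
  # restore the input order
  A <- A[ped$id, ped$id, drop = FALSE]
  structure(list(ids = ped$id, A = A,
                 degree_table = relationship_degree_table()),
            class = "relmat")
}

#' @export
as.matrix.relmat <- function(x, ...) x$A

#' @export
print.relmat <- function(x, ...) {
  cat("Additive relationship matrix:", length(x$ids), "individuals\n")
  invisible(x)
}

#' Write a relationship matrix as TSV (header row/column of ids)
#' @param rm a `relmat` or matrix.
#' @param path output path.
#' @export
write_relmat <- function(rm, path) {
  A <- as.matrix(rm)
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Census of relative pairs by relationship degree
#'
#' Counts pairs of distinct individuals in each relationship-degree bin.
#' Coefficients are matched to `bins` within `tol`; zero coefficients are
#' reported as `"unrelated"`, unmatched non-zero coefficients as `"other"`
#' (never dropped silently).
#'
#' @param A a `relmat` or relationship matrix.
#' @param bins named vector mapping degree label to coefficient
#'   (default [degree_bins()]).
#' @param ids optional subset of individuals to census (e.g. the phenotyped
#'   cohort inside a larger pedigree).
#' @param tol matching tolerance on the coefficient.
#' @return tibble with columns `degree` and `pairs`, ordered as `bins` then
#'   `unrelated`, then `other` (rows present even when the count is zero for
#'   bins; `other` only when non-empty).
#' @export
pair_degree_census <- function(A, bins = degree_bins(), ids = NULL,
                               tol = 1e-6) {
  A <- as.matrix(A)
  if (!is.null(ids)) A <- A[ids, ids, drop = FALSE]
  n <- nrow(A)
  if (n < 2) {
    return(tibble::tibble(degree = character(0), pairs = integer(0)))
  }
  vals <- A[upper.tri(A)]
  lab <- rep("other", length(vals))
  for (d in names(bins)) lab[abs(vals - bins[[d]]) <= tol] <- d
  lab[abs(vals) <= tol] <- "unrelated"
  counts <- table(factor(lab, levels = c(names(bins), "unrelated", "other")))
  out <- tibble::tibble(degree = names(counts),
                        pairs = as.integer(counts))
  out[out$degree != "other" | out$pairs > 0, ]
}
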