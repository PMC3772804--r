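#' Lilliefors test for normality with a Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' standard deviation estimated from the data,
#' `D = sup |F_n(x) - Phi((x - mean) / sd)|`. Because parameters are
#' estimated, the classical KS null does not apply; the p-value is taken
#' from a Monte-Carlo null distribution of D built from `n_mc`
#' standard-normal samples of the same size
#' (`p = (1 + #{D_null >= D}) / (n_mc + 1)`). The null distribution depends
#' on the sample size only, so it is cached per `(n, n_mc, seed)` and shared
#' across probes.
#'
#' @param x numeric vector, at least 4 finite values with nonzero variance.
#' @param n_mc number of Monte-Carlo null samples.
#' @param seed RNG seed for the null distribution (required for
#'   reproducibility).
#' @return list with `statistic` (D), `p.value` and `n`.
#' @export
lilliefors_test <- function(x, n_mc = 10000, seed = 1L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("Lilliefors test needs at least 4 finite values, got ", n)
  if (stats::sd(x) == 0) stop("degenerate input: zero variance")
  D <- lilliefors_D(x)
  null <- lilliefors_null(n, n_mc = n_mc, seed = seed)
  p <- (1 + sum(null >= D)) / (n_mc + 1)
  list(statistic = D, p.value = p, n = n)
}

# D statistic (parameters estimated from x)
lilliefors_D <- function(x) {
  n <- length(x)
  z <- sort(pnorm(x, mean = mean(x), sd = stats::sd(x)))
  dplus <- max(seq_len(n) / n - z)
  dminus <- max(z - (seq_len(n) - 1) / n)
  max(dplus, dminus)
}

.lillie_cache <- new.env(parent = emptyenv())

# Monte-Carlo null distribution of D for sample size n (cached)
lilliefors_null <- function(n, n_mc = 10000, seed = 1L) {
  key <- paste(n, n_mc, seed, sep = "_")
  hit <- .lillie_cache[[key]]
  if (!is.null(hit)) return(hit)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  d <- vapply(seq_len(n_mc), function(i) lilliefors_D(stats::rnorm(n)),
              numeric(1))
  .lillie_cache[[key]] <- d
  d
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
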