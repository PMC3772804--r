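# Independent oracles used across the suite. Each is deliberately naive:
# brute force or textbook definitions, no shared code with the package
# internals they check.

# --- gene-dropping Monte-Carlo estimate of the additive relationship ------
# Founders get unique allele labels; offspring inherit one random allele per
# parent. The additive relationship is 2x the kinship coefficient:
# A_ij = 2 * E[ P(random allele of i IBD to random allele of j) ].
# Vectorized over B independent drops.
gene_drop_relationship <- function(ped, B = 1e5, seed = 1) {
  set.seed(seed)
  ord <- methkin:::topo_order(ped)
  n <- length(ord)
  father <- stats::setNames(ped$father, ped$id)
  mother <- stats::setNames(ped$mother, ped$id)
  a1 <- matrix(NA_integer_, n, B, dimnames = list(ord, NULL))
  a2 <- a1
  lab <- 0L
  for (i in ord) {
    f <- father[[i]]
    if (is.na(f)) {
      a1[i, ] <- lab + 1L
      a2[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      m <- mother[[i]]
      pick <- stats::runif(B) < 0.5
      a1[i, ] <- ifelse(pick, a1[f, ], a2[f, ])
      pick <- stats::runif(B) < 0.5
      a2[i, ] <- ifelse(pick, a1[m, ], a2[m, ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
        (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
      A[i, j] <- A[j, i] <- 2 * mean(ibd) / 4
    }
  }
  A[ped$id, ped$id]
}

# --- dense multivariate-normal log-likelihood oracle ----------------------
# log N(y; X beta, s2 * (h2 A + (1 - h2) I)) via Cholesky, no rotation.
dense_mvn_loglik <- function(y, X, beta, s2, h2, A) {
  n <- length(y)
  V <- s2 * (h2 * A + (1 - h2) * diag(n))
  R <- chol(V)
  r <- y - X %*% beta
  z <- backsolve(R, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

# dense ML fit: profile beta and total variance by GLS at each h2, optimize
# h2 on [0, 1) by grid + optimize, all with dense solves.
dense_ml_fit <- function(y, X, A) {
  n <- length(y)
  prof <- function(h2) {
    V <- h2 * A + (1 - h2) * diag(n)
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) +
                    determinant(V)$modulus + n)
    list(ll = as.numeric(ll), beta = beta, s2 = s2)
  }
  grid <- seq(0, 1 - 1e-6, length.out = 64)
  ll <- vapply(grid, function(h) prof(h)$ll, numeric(1))
  k <- which.max(ll)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(64, k + 1)]
  opt <- stats::optimize(function(h) prof(h)$ll, lower = lo, upper = hi,
                         maximum = TRUE, tol = 1e-9)
  h2 <- opt$maximum
  cand <- c(lo, h2, hi)
  h2 <- cand[which.max(vapply(cand, function(h) prof(h)$ll, numeric(1)))]
  pr <- prof(h2)
  list(h2 = h2, loglik = pr$ll, beta = pr$beta, s2 = pr$s2)
}

# --- brute-force Benjamini-Hochberg step-up -------------------------------
# q_(i) = min_{j >= i} m * p_(j) / j on the sorted p-values, mapped back.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# --- small fixed pedigrees ------------------------------------------------
trio_ped <- function() {
  pedigree(data.frame(fam = "F1", id = c("P1", "P2", "C1"),
                      father = c(NA, NA, "P1"), mother = c(NA, NA, "P2"),
                      sex = c("M", "F", "M")))
}

# two founder parents, four children (6 members, 2 founders)
sixmember_ped <- function() {
  pedigree(data.frame(
    fam = "F1",
    id = c("P1", "P2", "C1", "C2", "C3", "C4"),
    father = c(NA, NA, "P1", "P1", "P1", "P1"),
    mother = c(NA, NA, "P2", "P2", "P2", "P2"),
    sex = c("M", "F", "M", "F", "M", "F")))
}

# double first cousins: children of two sibling pairs married crosswise
double_cousin_ped <- function() {
  pedigree(data.frame(
    fam = "F1",
    id = c("A1", "A2", "B1", "B2", "S1", "S2", "T1", "T2", "X", "Y"),
    father = c(NA, NA, NA, NA, "A1", "A1", "B1", "B1", "S1", "T1"),
    mother = c(NA, NA, NA, NA, "A2", "A2", "B2", "B2", "T2", "S2"),
    sex = c("M", "F", "M", "F", "M", "F", "M", "F", "M", "F")))
}

# three generations incl. grandparent-grandchild and avuncular pairs
threegen_ped <- function() {
  pedigree(data.frame(
    fam = "F1",
    id = c("G1", "G2", "P1", "U1", "S1", "K1", "K2"),
    father = c(NA, NA, "G1", "G1", NA, "P1", "P1"),
    mother = c(NA, NA, "G2", "G2", NA, "S1", "S1"),
    sex = c("M", "F", "M", "M", "F", "F", "M")))
}

# Mann-Whitney AUC: probability a true positive ranks ahead of a null
rank_auc <- function(p_pos, p_neg) {
  r <- rank(c(p_pos, p_neg))
  1 - (sum(r[seq_along(p_pos)]) -
         length(p_pos) * (length(p_pos) + 1) / 2) /
    (length(p_pos) * length(p_neg))
}

# n independent trios as a bare pedigree (no relationship matrix built):
# for Mendelian-consistency checks at scale
make_trio_ped <- function(n) {
  fams <- rep(sprintf("F%05d", seq_len(n)), each = 3)
  is_kid <- rep(c(FALSE, FALSE, TRUE), n)
  pedigree(tibble::tibble(
    fam = fams,
    id = paste0(fams, c("_P1", "_P2", "_C1")),
    father = ifelse(is_kid, paste0(fams, "_P1"), NA),
    mother = ifelse(is_kid, paste0(fams, "_P2"), NA),
    sex = rep(c("M", "F", "M"), n)))
}
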