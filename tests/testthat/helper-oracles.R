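# Independent brute-force oracles. These deliberately use naive O(n^2)
# pairwise loops and literal textbook constants, sharing no code with the
# package implementation.

# mean pairwise difference sum over sites (counts), complete-case per site
brute_pi_count <- function(a) {
  n <- nrow(a)
  total <- 0
  for (s in seq_len(ncol(a))) {
    col <- a[, s]
    col <- col[!is.na(col)]
    m <- length(col)
    if (m < 2) next
    diffs <- 0
    pairs <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      diffs <- diffs + as.integer(col[i] != col[j])
      pairs <- pairs + 1
    }
    total <- total + diffs / pairs
  }
  total
}

# cross-population mean pairwise difference sum over sites (counts)
brute_dxy_count <- function(a, b) {
  total <- 0
  for (s in seq_len(ncol(a))) {
    x <- a[, s]; y <- b[, s]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) next
    diffs <- 0
    for (i in seq_along(x)) for (j in seq_along(y))
      diffs <- diffs + as.integer(x[i] != y[j])
    total <- total + diffs / (length(x) * length(y))
  }
  total
}

# number of segregating sites (complete-case)
brute_S <- function(a) {
  S <- 0
  for (s in seq_len(ncol(a))) {
    col <- a[, s]
    col <- col[!is.na(col)]
    if (length(unique(col)) > 1) S <- S + 1
  }
  S
}

# Tajima's D from first principles (Tajima 1989 constants, coded literally)
brute_tajima_d <- function(a) {
  n <- nrow(a)
  S <- brute_S(a)
  if (S == 0 || n < 4) return(NA_real_)
  k_hat <- brute_pi_count(a)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# ABBA/BABA sums by an explicit per-site loop on frequencies
brute_abba_baba_sums <- function(p1, p2, p3, p4) {
  sa <- 0; sb <- 0
  for (s in seq_along(p1)) {
    sa <- sa + (1 - p1[s]) * p2[s] * p3[s] * (1 - p4[s])
    sb <- sb + p1[s] * (1 - p2[s]) * p3[s] * (1 - p4[s])
  }
  c(abba = sa, baba = sb)
}

# numeric quadrature of a 1-D Gaussian-mixture KDE density
brute_kde_mass <- function(centers, bw, lo, hi, n_grid = 20000) {
  x <- seq(lo, hi, length.out = n_grid)
  f <- vapply(x, function(xx) mean(stats::dnorm(xx, centers, bw)), 0)
  sum(f) * (hi - lo) / (n_grid - 1)
}
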