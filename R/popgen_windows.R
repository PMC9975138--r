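#' Window nucleotide diversity (pi)
#'
#' `pi = sum_sites [n/(n-1)] 2 p (1-p) / L`, with L the window length in bp
#' (positions without a SNP record are treated as monomorphic) and p the
#' complete-case ALT frequency per site.
#'
#' @param hm a [hap_matrix()].
#' @param samples sample ids of the population (>= 2 haplotypes).
#' @param window list/row with `first`, `last` (0-based half-open site
#'   indices), `start_bp`, `end_bp`.
#' @return pi per bp (`NA` if fewer than 2 haplotypes).
#' @export
window_pi <- function(hm, samples, window) {
  rows <- hm$sample %in% samples
  if (sum(rows) < 2) return(NA_real_)
  L <- window$end_bp - window$start_bp + 1
  if (is.na(window$first) || window$snp_count == 0) return(0)
  idx <- (window$first + 1L):window$last
  a <- hm$alleles[rows, idx, drop = FALSE]
  n <- colSums(!is.na(a))
  p <- colSums(a == 1L, na.rm = TRUE) / n
  w <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), 0)
  sum(w) / L
}

#' Window absolute divergence (Dxy)
#'
#' `Dxy = sum_sites [pA (1-pB) + pB (1-pA)] / L`. Sites with an undefined
#' frequency in either population are skipped.
#'
#' @param hm a [hap_matrix()].
#' @param samples_a,samples_b sample ids of the two populations.
#' @inheritParams window_pi
#' @return Dxy per bp.
#' @export
window_dxy <- function(hm, samples_a, samples_b, window) {
  L <- window$end_bp - window$start_bp + 1
  if (is.na(window$first) || window$snp_count == 0) return(0)
  idx <- (window$first + 1L):window$last
  fa <- pop_allele_freq(hm, samples_a)
  fb <- pop_allele_freq(hm, samples_b)
  pa <- fa$freq[idx]; pb <- fb$freq[idx]
  ok <- !fa$undefined[idx] & !fb$undefined[idx]
  sum((pa * (1 - pb) + pb * (1 - pa))[ok]) / L
}

#' Hudson window Fst
#'
#' `Fst = 1 - mean(piA, piB) / Dxy` as a ratio of window sums. Negative
#' estimates are floored at 0 (flagged via attribute `floored`);
#' `Dxy = 0` yields `NA`.
#'
#' @param pi_a,pi_b within-population diversity of the window (same scale as
#'   `dxy`).
#' @param dxy between-population divergence of the window.
#' @return Fst in \[0, 1\] or `NA`.
#' @export
window_fst_hudson <- function(pi_a, pi_b, dxy) {
  if (is.na(dxy) || dxy == 0) return(NA_real_)
  fst <- 1 - mean(c(pi_a, pi_b)) / dxy
  if (!is.na(fst) && fst < 0) {
    fst <- structure(0, floored = TRUE)
  }
  fst
}

#' Global pairwise Fst matrix
#'
#' Two estimators over all sites (per-pair complete-case):
#' `"wc84"` (default) is the Weir-Cockerham ratio-of-sums estimator adapted
#' to haploid samples; `"nei"` is the uncorrected ratio
#' `1 - Hw / Hb` with `Hw = mean(2 pA qA, 2 pB qB)` and
#' `Hb = pA qB + pB qA`, which is exactly 0 for populations with identical
#' allele frequencies.
#'
#' @param hm a [hap_matrix()].
#' @param pops named list mapping population label to sample ids (each with
#'   >= 2 haplotypes), or a [sample_table()].
#' @param estimator `"wc84"` or `"nei"`.
#' @return Symmetric matrix of pairwise Fst, diagonal 0.
#' @export
pairwise_fst_global <- function(hm, pops, estimator = c("wc84", "nei")) {
  estimator <- match.arg(estimator)
  if (is.data.frame(pops))
    pops <- split(pops$sample, pops$population)
  k <- length(pops)
  if (k < 2) stop("need >= 2 populations")
  freqs <- lapply(pops, function(ids) pop_allele_freq(hm, ids))
  out <- matrix(0, k, k, dimnames = list(names(pops), names(pops)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fi <- freqs[[i]]; fj <- freqs[[j]]
    ok <- !fi$undefined & !fj$undefined & fi$n_called >= 2 & fj$n_called >= 2
    p1 <- fi$freq[ok]; p2 <- fj$freq[ok]
    n1 <- fi$n_called[ok]; n2 <- fj$n_called[ok]
    if (estimator == "wc84") {
      nbar <- (n1 + n2) / 2
      nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))  # r - 1 = 1
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar  # / (r-1)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
      fst <- sum(a) / sum(a + b)
    } else {
      hw <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
      hb <- p1 * (1 - p2) + p2 * (1 - p1)
      fst <- 1 - sum(hw) / sum(hb)
    }
    out[i, j] <- out[j, i] <- fst
  }
  out
}

#' Tajima's D for a window
#'
#' Standard formulation: `D = (pi_count - S/a1) / sqrt(e1 S + e2 S (S-1))`
#' with `pi_count` the mean-pairwise-difference sum over sites (counts, not
#' per bp) and the usual constants a1, a2, b1, b2, c1, c2, e1, e2 for n
#' haplotypes. Undefined (`NA`) when `S = 0` or fewer than 4 haplotypes.
#'
#' @inheritParams window_pi
#' @return Tajima's D, or `NA`.
#' @export
tajimas_d <- function(hm, samples, window) {
  rows <- hm$sample %in% samples
  n <- sum(rows)
  if (n < 4) return(NA_real_)
  if (is.na(window$first) || window$snp_count == 0) return(NA_real_)
  idx <- (window$first + 1L):window$last
  a <- hm$alleles[rows, idx, drop = FALSE]
  nc <- colSums(!is.na(a))
  p <- colSums(a == 1L, na.rm = TRUE) / nc
  seg <- !is.na(p) & p > 0 & p < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_count <- sum((2 * p * (1 - p) * nc / (nc - 1))[seg])
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_count - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Sliding-window diversity scan
#'
#' Computes per-window nucleotide diversity, pairwise Dxy and Hudson Fst,
#' Tajima's D and segregating-site counts for every population over bp
#' windows. Windows with fewer than `min_snps` SNPs are flagged
#' `excluded` (statistics set to `NA`) but retained in the output.
#'
#' @param hm a [hap_matrix()].
#' @param pops named list of sample-id vectors, or a [sample_table()].
#' @param size,step window size and step in bp.
#' @param min_snps minimum SNPs for a window to be computed (a window with
#'   exactly `min_snps` SNPs is kept).
#' @return An object of class `window_stats`: a `data.frame` with one row
#'   per window and columns `pi_<pop>`, `tajd_<pop>`, `S_<pop>`,
#'   `dxy_<A>_<B>`, `fst_<A>_<B>`, `snp_count`, `excluded`.
#' @export
sliding_scan <- function(hm, pops, size = 100000L, step = 50000L,
                         min_snps = 10L) {
  if (is.data.frame(pops)) pops <- split(pops$sample, pops$population)
  win <- windows_by_bp(hm, size, step)
  res <- win[, c("chrom", "start_bp", "end_bp", "snp_count")]
  res$excluded <- win$snp_count < min_snps
  pn <- names(pops)
  for (p in pn) {
    res[[paste0("pi_", p)]] <- NA_real_
    res[[paste0("tajd_", p)]] <- NA_real_
    res[[paste0("S_", p)]] <- NA_integer_
  }
  pairs <- if (length(pn) >= 2) utils::combn(pn, 2, simplify = FALSE)
           else list()
  for (pr in pairs) {
    res[[paste0("dxy_", pr[1], "_", pr[2])]] <- NA_real_
    res[[paste0("fst_", pr[1], "_", pr[2])]] <- NA_real_
  }
  for (w in which(!res$excluded)) {
    wrow <- win[w, ]
    pis <- stats::setNames(numeric(length(pn)), pn)
    for (p in pn) {
      pis[p] <- window_pi(hm, pops[[p]], wrow)
      res[[paste0("pi_", p)]][w] <- pis[p]
      res[[paste0("tajd_", p)]][w] <- tajimas_d(hm, pops[[p]], wrow)
      idx <- (wrow$first + 1L):wrow$last
      a <- hm$alleles[hm$sample %in% pops[[p]], idx, drop = FALSE]
      f <- colMeans(a == 1L, na.rm = TRUE)
      res[[paste0("S_", p)]][w] <- sum(!is.na(f) & f > 0 & f < 1)
    }
    for (pr in pairs) {
      dxy <- window_dxy(hm, pops[[pr[1]]], pops[[pr[2]]], wrow)
      res[[paste0("dxy_", pr[1], "_", pr[2])]][w] <- dxy
      res[[paste0("fst_", pr[1], "_", pr[2])]][w] <-
        as.numeric(window_fst_hudson(pis[pr[1]], pis[pr[2]], dxy))
    }
  }
  class(res) <- c("window_stats", "data.frame")
  res
}

#' @export
print.window_stats <- function(x, ...) {
  cat("<window_stats> ", nrow(x), " windows (",
      sum(x$excluded), " excluded with < min_snps SNPs)\n", sep = "")
  NextMethod()
}
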