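#' Per-site quartet allele frequencies
#'
#' Builds the frequency table underlying the ABBA-BABA statistics: ALT-allele
#' frequencies in four populations P1 (sister of the recipient), P2
#' (recipient), P3 (donor) and P4 (outgroup). A site is usable when all four
#' frequencies are defined (complete-case per population).
#'
#' @param hm a [hap_matrix()].
#' @param samples a [sample_table()].
#' @param p1,p2,p3,p4 population labels in `samples`.
#' @return An object of class `quartet_freqs`: list with `p1..p4`
#'   (frequencies per site), `usable`, `chrom`, `pos`.
#' @export
quartet_freqs <- function(hm, samples, p1, p2, p3, p4) {
  f <- lapply(c(p1, p2, p3, p4), function(p) {
    ids <- pop_samples(samples, p)
    if (!length(ids)) stop("population not in sample table: ", p)
    pop_allele_freq(hm, ids)
  })
  freqs <- lapply(f, `[[`, "freq")
  usable <- !Reduce(`|`, lapply(f, `[[`, "undefined"))
  structure(list(p1 = freqs[[1]], p2 = freqs[[2]], p3 = freqs[[3]],
                 p4 = freqs[[4]], usable = usable,
                 chrom = hm$chrom, pos = hm$pos,
                 pops = c(p1, p2, p3, p4)),
            class = "quartet_freqs")
}

#' Frequency-weighted ABBA and BABA site patterns
#'
#' Durand-style frequency weights: `ABBA = (1-p1) p2 p3 (1-p4)` and
#' `BABA = p1 (1-p2) p3 (1-p4)`.
#'
#' @param qf a [quartet_freqs()] (only usable sites contribute).
#' @return A `data.frame` with columns `abba`, `baba` for usable sites, plus
#'   `chrom`, `pos`.
#' @export
site_patterns <- function(qf) {
  u <- qf$usable
  with(qf, data.frame(
    chrom = chrom[u], pos = pos[u],
    abba = (1 - p1[u]) * p2[u] * p3[u] * (1 - p4[u]),
    baba = p1[u] * (1 - p2[u]) * p3[u] * (1 - p4[u])))
}

#' Patterson's D from pattern sums
#'
#' `D = (sum(ABBA) - sum(BABA)) / (sum(ABBA) + sum(BABA))`. A zero
#' denominator yields `NA` (undefined), not 0.
#'
#' @param abba,baba per-site pattern weights (or their sums).
#' @return D in \[-1, 1\], or `NA` when undefined.
#' @export
d_statistic <- function(abba, baba) {
  sa <- sum(abba); sb <- sum(baba)
  if (sa + sb <= 0) return(NA_real_)
  (sa - sb) / (sa + sb)
}

#' Block-jackknife standard error and Z score for D
#'
#' Usable sites are partitioned into `n_blocks` contiguous blocks of (near-)
#' equal SNP count; D is recomputed with each block deleted in turn, and
#' `SE = sqrt((m-1)/m * sum((D_-i - mean(D_-i))^2))`, `Z = D / SE`. D is
#' conventionally called significant when |Z| > 3.
#'
#' @param qf a [quartet_freqs()].
#' @param n_blocks number of jackknife blocks (>= 20).
#' @return A list with `D`, `SE`, `Z`, `n_blocks`, `n_sites`, and the
#'   per-block `abba`/`baba` sums. `Z` is `Inf` (with a warning) when
#'   `SE == 0` with `D != 0`.
#' @export
block_jackknife <- function(qf, n_blocks = 379L) {
  if (n_blocks < 20) stop("n_blocks must be >= 20")
  pat <- site_patterns(qf)
  n <- nrow(pat)
  if (n < n_blocks) stop("fewer usable sites than blocks")
  block <- ceiling(seq_len(n) / (n / n_blocks))
  A <- as.numeric(tapply(pat$abba, block, sum))
  B <- as.numeric(tapply(pat$baba, block, sum))
  out <- d_jackknife_blocks(A, B)
  out$n_sites <- n
  out
}

#' Delete-one jackknife of D from per-block pattern sums
#'
#' @param block_abba,block_baba per-block sums of ABBA and BABA weights.
#' @return A list with `D`, `SE`, `Z`, `n_blocks`, `block_abba`,
#'   `block_baba`.
#' @export
d_jackknife_blocks <- function(block_abba, block_baba) {
  A <- block_abba; B <- block_baba
  m <- length(A)
  D <- d_statistic(A, B)
  d_del <- (sum(A) - A - (sum(B) - B)) / (sum(A) - A + sum(B) - B)
  se <- sqrt((m - 1) / m * sum((d_del - mean(d_del))^2))
  z <- if (se == 0) {
    if (is.na(D) || D == 0) 0 else {
      warning("jackknife SE is 0 with D != 0; Z reported as Inf")
      Inf
    }
  } else D / se
  list(D = D, SE = se, Z = z, n_blocks = m,
       block_abba = A, block_baba = B)
}

#' Admixture fraction f
#'
#' Ratio of the observed ABBA-BABA numerator to the numerator expected under
#' complete introgression, with the donor population P3 substituted into the
#' recipient slot of the denominator:
#' `f = S(P1, P2, P3, P4) / S(P1, P3, P3, P4)`, where `S` is the sum of
#' per-site `ABBA - BABA` weights.
#'
#' @param qf a [quartet_freqs()].
#' @return `f_hat` (typically in \[0, 1\]; values outside are returned
#'   unchanged with a warning), or `NA` when the denominator is 0.
#' @export
admixture_fraction_f <- function(qf) {
  u <- qf$usable
  p1 <- qf$p1[u]; p2 <- qf$p2[u]; p3 <- qf$p3[u]; p4 <- qf$p4[u]
  num <- sum((1 - p1) * p2 * p3 * (1 - p4) - p1 * (1 - p2) * p3 * (1 - p4))
  den <- sum((1 - p1) * p3 * p3 * (1 - p4) - p1 * (1 - p3) * p3 * (1 - p4))
  if (den == 0) return(NA_real_)
  f <- num / den
  if (!is.na(f) && (f < 0 || f > 1))
    warning("f estimate outside [0, 1]: ", signif(f, 4))
  f
}

#' Windowed D, fd and fdM
#'
#' Per-window introgression-fraction estimators. `fd` substitutes the
#' dynamic donor frequency `pD = max(p2, p3)` into both the recipient and
#' donor slots of the denominator and is reported only for windows with
#' `D >= 0` (`NA` otherwise). `fdM` extends `fd` symmetrically to
#' introgression into P1 (sign convention: positive means P3 -> P2).
#'
#' @param qf a [quartet_freqs()].
#' @param windows a `data.frame` from [windows_by_bp()] (site indices refer
#'   to the same matrix used to build `qf`).
#' @param min_sites minimum usable sites per window.
#' @return A `data.frame`: chrom, start_bp, end_bp, n_sites, D, fd, fdM;
#'   windows below `min_sites` carry `NA` statistics and `excluded = TRUE`.
#' @export
fd_fdM_windows <- function(qf, windows, min_sites = 20L) {
  res <- windows[, c("chrom", "start_bp", "end_bp")]
  n <- nrow(windows)
  res$n_sites <- 0L
  res$D <- res$fd <- res$fdM <- NA_real_
  res$excluded <- TRUE
  for (w in seq_len(n)) {
    if (windows$snp_count[w] == 0 || is.na(windows$first[w])) next
    idx <- (windows$first[w] + 1L):windows$last[w]
    idx <- idx[qf$usable[idx]]
    res$n_sites[w] <- length(idx)
    if (length(idx) < min_sites) next
    res$excluded[w] <- FALSE
    p1 <- qf$p1[idx]; p2 <- qf$p2[idx]; p3 <- qf$p3[idx]; p4 <- qf$p4[idx]
    abba <- (1 - p1) * p2 * p3 * (1 - p4)
    baba <- p1 * (1 - p2) * p3 * (1 - p4)
    num <- sum(abba - baba)
    res$D[w] <- d_statistic(abba, baba)
    pD <- pmax(p2, p3)
    den_fd <- sum((1 - p1) * pD * pD * (1 - p4) -
                  p1 * (1 - pD) * pD * (1 - p4))
    if (!is.na(res$D[w]) && res$D[w] >= 0 && den_fd != 0)
      res$fd[w] <- num / den_fd
    # fdM: dynamic donor on the P2 side when p2 >= p1, else on the P1 side
    pD2 <- pmax(p2, p3)
    pD1 <- pmax(p1, p3)
    den_site <- ifelse(
      p2 >= p1,
      (1 - p1) * pD2 * pD2 * (1 - p4) - p1 * (1 - pD2) * pD2 * (1 - p4),
      -((1 - pD1) * p2 * pD1 * (1 - p4) - pD1 * (1 - p2) * pD1 * (1 - p4)))
    den_fdM <- sum(den_site)
    if (den_fdM != 0) res$fdM[w] <- num / den_fdM
  }
  res
}

#' Genome-wide ABBA-BABA test
#'
#' Convenience wrapper: builds the quartet frequencies, computes Patterson's
#' D with its block-jackknife SE/Z, and the admixture fraction f.
#'
#' @inheritParams quartet_freqs
#' @param n_blocks jackknife blocks.
#' @return An object of class `dstat_test` with a print method: list with
#'   `D`, `SE`, `Z`, `f_hat`, `n_sites`, `n_blocks`, `pops`, `significant`.
#' @export
abba_baba_test <- function(hm, samples, p1, p2, p3, p4, n_blocks = 379L) {
  qf <- quartet_freqs(hm, samples, p1, p2, p3, p4)
  jk <- block_jackknife(qf, n_blocks)
  f <- admixture_fraction_f(qf)
  structure(list(D = jk$D, SE = jk$SE, Z = jk$Z, f_hat = f,
                 n_sites = jk$n_sites, n_blocks = jk$n_blocks,
                 pops = qf$pops,
                 significant = is.finite(jk$Z) && abs(jk$Z) > 3),
            class = "dstat_test")
}

#' @export
print.dstat_test <- function(x, ...) {
  cat("ABBA-BABA test  (P1,P2,P3,P4) = (",
      paste(x$pops, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  D = %.4f   SE = %.4f   Z = %.2f   (%s at |Z| > 3)\n",
              x$D, x$SE, x$Z,
              if (isTRUE(x$significant)) "significant" else "not significant"))
  cat(sprintf("  f = %.4f   over %d sites in %d jackknife blocks\n",
              x$f_hat, x$n_sites, x$n_blocks))
  invisible(x)
}
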