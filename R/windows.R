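#' SNP-count windows
#'
#' Half-overlapping windows of a fixed number of SNPs per chromosome. Full
#' windows start at site indices 0, `step`, `2*step`, ... (0-based, half-open
#' internally; reported bp bounds are 1-based inclusive). If trailing SNPs
#' remain uncovered after the last full window, a final short window starting
#' at the next grid index is appended when it holds at least `size/2` SNPs.
#' A chromosome with fewer than `size` SNPs yields no windows (warning).
#'
#' @param hm a [hap_matrix()].
#' @param size window size in SNPs (>= 2).
#' @param step step in SNPs, `1 <= step <= size`.
#' @return A `data.frame` with columns chrom, first, last (0-based half-open
#'   site indices into `hm`), start_bp, end_bp, snp_count.
#' @export
windows_by_snp_count <- function(hm, size = 150L, step = 75L) {
  if (size < 2) stop("size must be >= 2")
  if (step < 1 || step > size) stop("step must satisfy 1 <= step <= size")
  out <- list()
  for (ch in unique(hm$chrom)) {
    idx <- which(hm$chrom == ch)
    S <- length(idx)
    if (S < size) {
      warning("chromosome ", ch, " has fewer than ", size,
              " SNPs; no windows")
      next
    }
    n_full <- (S - size) %/% step + 1L
    starts <- (seq_len(n_full) - 1L) * step
    ends <- starts + size
    covered_to <- ends[n_full]
    if (covered_to < S) {
      cand <- starts[n_full] + step
      if (S - cand >= size / 2) {
        starts <- c(starts, cand)
        ends <- c(ends, S)
      }
    }
    off <- idx[1] - 1L
    out[[ch]] <- data.frame(
      chrom = ch, first = off + starts, last = off + ends,
      start_bp = hm$pos[off + starts + 1L], end_bp = hm$pos[off + ends],
      snp_count = ends - starts, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), first = integer(0),
                      last = integer(0), start_bp = integer(0),
                      end_bp = integer(0), snp_count = integer(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Base-pair windows
#'
#' Sliding windows on the bp scale whose grid is anchored at each
#' chromosome's first SNP position (so a constant offset added to all
#' positions shifts the grid with the data): starts are `p0, p0 + step, ...`
#' until the chromosome end (last SNP position) is covered. Windows
#' containing no SNPs are retained with `snp_count = 0`.
#'
#' @param hm a [hap_matrix()].
#' @param size window size in bp.
#' @param step step in bp, `step <= size`.
#' @return A `data.frame` with columns chrom, start_bp, end_bp (1-based
#'   inclusive), first, last (0-based half-open site indices; `NA` when
#'   empty) and snp_count.
#' @export
windows_by_bp <- function(hm, size = 100000L, step = 50000L) {
  if (size < step) stop("size must be >= step")
  out <- list()
  for (ch in unique(hm$chrom)) {
    idx <- which(hm$chrom == ch)
    p <- hm$pos[idx]
    chrom_end <- max(p)
    starts <- integer(0)
    s <- min(p)
    repeat {
      starts <- c(starts, s)
      if (s + size - 1L >= chrom_end) break
      s <- s + as.integer(step)
    }
    ends <- starts + as.integer(size) - 1L
    first <- findInterval(starts - 1L, p)        # sites with pos >= start
    last <- findInterval(ends, p)                # sites with pos <= end
    cnt <- last - first
    off <- idx[1] - 1L
    out[[ch]] <- data.frame(
      chrom = ch, start_bp = starts, end_bp = ends,
      first = ifelse(cnt > 0, off + first, NA_integer_),
      last = ifelse(cnt > 0, off + last, NA_integer_),
      snp_count = cnt, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' LD pruning by pairwise r-squared
#'
#' Scans windows of `window` SNPs advancing by `step`; within each window,
#' site pairs are examined in position order and when the squared Pearson
#' correlation of allele dosages exceeds `r2_max` the later site of the pair
#' is dropped. Monomorphic sites are excluded from correlations (and kept).
#' The procedure is deterministic and idempotent.
#'
#' @param hm a [hap_matrix()].
#' @param window window size in SNPs (>= 2).
#' @param step window advance in SNPs.
#' @param r2_max maximum allowed squared correlation.
#' @return Integer vector of kept site indices (1-based).
#' @export
ld_prune <- function(hm, window = 50L, step = 10L, r2_max = 0.2) {
  if (window < 2) stop("window must be >= 2")
  S <- ncol(hm$alleles)
  keep <- rep(TRUE, S)
  a <- hm$alleles
  for (ch in unique(hm$chrom)) {
    idx <- which(hm$chrom == ch)
    starts <- seq(1L, max(1L, length(idx)), by = step)
    for (s in starts) {
      w <- idx[s:min(s + window - 1L, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2) next
      x <- a[, w, drop = FALSE]
      v <- apply(x, 2, stats::var, na.rm = TRUE)
      poly <- which(!is.na(v) & v > 0)
      if (length(poly) < 2) next
      r2 <- suppressWarnings(
        stats::cor(x[, poly, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      for (i in seq_along(poly)) {
        if (!keep[w[poly[i]]]) next
        for (j in seq_along(poly)) {
          if (j <= i || !keep[w[poly[j]]]) next
          if (!is.na(r2[i, j]) && r2[i, j] > r2_max)
            keep[w[poly[j]]] <- FALSE
        }
      }
      if (s + window - 1L >= length(idx)) break
    }
  }
  which(keep)
}
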