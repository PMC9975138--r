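#' EHH decay around a focal site
#'
#' Extended haplotype homozygosity for one core allele: at distance x from
#' the focal site, `EHH(x) = sum_h C(n_h, 2) / C(n_core, 2)` over the
#' distinct extended haplotypes h spanning focal..x, computed outward SNP by
#' SNP on each flank. A flank is truncated when EHH drops below `ehh_min`,
#' at the chromosome end, or when the gap to the next SNP exceeds
#' `max_gap_bp`. Haplotypes missing the focal allele call are dropped;
#' missing alleles along the extension break haplotype sharing.
#'
#' @param hm a [hap_matrix()] (phased).
#' @param samples sample ids of the scanned population (default: all).
#' @param focal site index (1-based column of `hm`).
#' @param core_allele 0 (REF) or 1 (ALT).
#' @param ehh_min truncation threshold.
#' @param max_gap_bp maximum allowed inter-SNP gap (`Inf` to disable).
#' @return An object of class `ehh_curve`: list with `focal_pos`,
#'   `core_allele`, `left`/`right` (data.frames pos, ehh, focal first),
#'   `truncated` (logical per flank: hit the chromosome end with
#'   EHH >= ehh_min), `n_core`.
#' @export
ehh_decay <- function(hm, samples = NULL, focal, core_allele,
                      ehh_min = 0.05, max_gap_bp = Inf) {
  a <- if (is.null(samples)) hm$alleles else
    hm$alleles[hm$sample %in% samples, , drop = FALSE]
  core <- which(!is.na(a[, focal]) & a[, focal] == core_allele)
  n <- length(core)
  if (n < 2) return(NULL)
  ch <- hm$chrom[focal]
  pos <- hm$pos
  denom <- n * (n - 1) / 2
  walk <- function(dir) {
    res_pos <- pos[focal]
    res_ehh <- 1
    grp <- rep(1L, n)
    truncated <- FALSE
    j <- focal
    ehh <- 1
    repeat {
      nxt <- j + dir
      if (nxt < 1L || nxt > ncol(a) || hm$chrom[nxt] != ch) {
        truncated <- ehh >= ehh_min
        break
      }
      if (abs(pos[nxt] - pos[j]) > max_gap_bp) {
        truncated <- ehh >= ehh_min
        break
      }
      al <- a[core, nxt]
      al[is.na(al)] <- 2L + seq_len(sum(is.na(al)))  # missing breaks sharing
      key <- grp * (n + 3L) + al
      grp <- match(key, unique(key))
      cnt <- tabulate(grp)
      ehh <- sum(cnt * (cnt - 1) / 2) / denom
      res_pos <- c(res_pos, pos[nxt])
      res_ehh <- c(res_ehh, ehh)
      j <- nxt
      if (ehh < ehh_min) break
    }
    list(df = data.frame(pos = res_pos, ehh = res_ehh),
         truncated = truncated)
  }
  L <- walk(-1L)
  R <- walk(+1L)
  structure(list(focal_pos = pos[focal], core_allele = core_allele,
                 left = L$df, right = R$df,
                 truncated = c(left = L$truncated, right = R$truncated),
                 n_core = n),
            class = "ehh_curve")
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH curve over physical distance (bp), summed
#' over both flanks; integration stops at each flank's truncation point.
#'
#' @param curve an [ehh_decay()] result.
#' @return iHH in bp x EHH units (0 for a single-point curve).
#' @export
ihh <- function(curve) {
  if (is.null(curve)) return(NA_real_)
  trap <- function(df) {
    if (nrow(df) < 2) return(0)
    x <- abs(df$pos - df$pos[1])
    sum(diff(x) * (df$ehh[-1] + df$ehh[-nrow(df)]) / 2)
  }
  trap(curve$left) + trap(curve$right)
}

#' Unstandardized iHS at one site
#'
#' `iHS = ln(iHH_ref / iHH_alt)`, computed on unpolarised data (REF vs ALT
#' allele). Sites failing the MAF filter, with a zero iHH, or (by default)
#' with a flank truncated at the chromosome end are dropped with a reason
#' code.
#'
#' @param hm a [hap_matrix()].
#' @param samples scanned population sample ids (default all).
#' @param focal site index.
#' @param maf_min minimum minor-allele frequency.
#' @param ehh_min,max_gap_bp passed to [ehh_decay()].
#' @param discard_border drop sites whose EHH reaches the chromosome end
#'   before falling below `ehh_min`.
#' @return A list with `ihs` (`NA` when dropped), `reason` (`"ok"`,
#'   `"maf"`, `"zero_ihh"`, `"border"`, `"few_core"`), `ihh_ref`, `ihh_alt`,
#'   `alt_freq`.
#' @export
ihs_unstandardized <- function(hm, samples = NULL, focal, maf_min = 0.05,
                               ehh_min = 0.05, max_gap_bp = Inf,
                               discard_border = TRUE) {
  al <- if (is.null(samples)) hm$alleles[, focal] else
    hm$alleles[hm$sample %in% samples, focal]
  n <- sum(!is.na(al))
  p <- sum(al == 1L, na.rm = TRUE) / n
  out <- list(ihs = NA_real_, reason = "ok", ihh_ref = NA_real_,
              ihh_alt = NA_real_, alt_freq = p)
  if (is.nan(p) || min(p, 1 - p) < maf_min) {
    out$reason <- "maf"; return(out)
  }
  cr <- ehh_decay(hm, samples, focal, 0L, ehh_min, max_gap_bp)
  ca <- ehh_decay(hm, samples, focal, 1L, ehh_min, max_gap_bp)
  if (is.null(cr) || is.null(ca)) {
    out$reason <- "few_core"; return(out)
  }
  if (discard_border && (any(cr$truncated) || any(ca$truncated))) {
    out$reason <- "border"; return(out)
  }
  out$ihh_ref <- ihh(cr)
  out$ihh_alt <- ihh(ca)
  if (out$ihh_ref == 0 || out$ihh_alt == 0) {
    out$reason <- "zero_ihh"; return(out)
  }
  out$ihs <- log(out$ihh_ref / out$ihh_alt)
  out
}

#' Standardize iHS within allele-frequency bins
#'
#' Subtracts the bin mean and divides by the bin standard deviation within
#' ALT-frequency bins of width `bin_width`; bins with fewer than `min_bin`
#' sites are merged with their nearest populated neighbour. Sites in a
#' zero-variance bin are set to 0 and flagged.
#'
#' @param ihs numeric vector of unstandardized iHS.
#' @param alt_freq ALT allele frequency per site.
#' @param bin_width frequency bin width.
#' @param min_bin minimum sites per bin before merging.
#' @return A list with `std_ihs`, `bin` (final bin index per site) and
#'   `zero_sd` (logical per site).
#' @export
standardize_ihs <- function(ihs, alt_freq, bin_width = 0.025,
                            min_bin = 10L) {
  ok <- !is.na(ihs)
  if (sum(ok) < min_bin) stop("fewer than min_bin usable sites overall")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- findInterval(alt_freq, breaks, rightmost.closed = TRUE)
  bin[!ok] <- NA
  # merge sparse bins with the nearest populated neighbour (by bin centre)
  repeat {
    tab <- table(bin[ok])
    sparse <- names(tab)[tab < min_bin]
    if (!length(sparse) || length(tab) == 1) break
    b <- as.integer(sparse[1])
    others <- setdiff(as.integer(names(tab)), b)
    nearest <- others[which.min(abs(others - b))]
    bin[!is.na(bin) & bin == b] <- nearest
  }
  std <- rep(NA_real_, length(ihs))
  zero_sd <- rep(FALSE, length(ihs))
  for (b in unique(stats::na.omit(bin))) {
    i <- which(!is.na(bin) & bin == b & ok)
    mu <- mean(ihs[i]); sdv <- stats::sd(ihs[i])
    if (is.na(sdv) || sdv == 0) {
      std[i] <- 0
      zero_sd[i] <- TRUE
    } else std[i] <- (ihs[i] - mu) / sdv
  }
  list(std_ihs = std, bin = bin, zero_sd = zero_sd)
}

#' Gaussian p-value transform of standardized iHS
#'
#' Two-sided: `p = -log10(1 - 2 |Phi(iHS) - 0.5|)`, computed stably as
#' `-log10(2 Phi(-|iHS|))`.
#'
#' @param std_ihs standardized iHS value(s).
#' @return p on the -log10 scale (>= 0); symmetric in the sign of iHS.
#' @export
ihs_pvalue <- function(std_ihs) {
  -(log(2) + stats::pnorm(-abs(std_ihs), log.p = TRUE)) / log(10)
}

#' Genome scan: iHS at every eligible site
#'
#' Runs [ihs_unstandardized()] at every site, standardizes within frequency
#' bins and attaches -log10 p-values.
#'
#' @param hm a [hap_matrix()].
#' @param samples scanned population sample ids (default all).
#' @param maf_min,ehh_min,max_gap_bp,discard_border per-site scan
#'   parameters, see [ihs_unstandardized()].
#' @param bin_width,min_bin standardization parameters, see
#'   [standardize_ihs()].
#' @return An object of class `ihs_table`: `data.frame` with chrom, pos,
#'   alt_freq, ihh_ref, ihh_alt, ihs, std_ihs, p, reason.
#' @export
ihs_scan <- function(hm, samples = NULL, maf_min = 0.05, ehh_min = 0.05,
                     max_gap_bp = Inf, discard_border = TRUE,
                     bin_width = 0.025, min_bin = 10L) {
  if (!is.null(samples)) {
    hm <- hm_subset(hm, samples = intersect(hm$sample_ids, samples))
    samples <- NULL
  }
  S <- ncol(hm$alleles)
  res <- data.frame(chrom = hm$chrom, pos = hm$pos,
                    alt_freq = NA_real_, ihh_ref = NA_real_,
                    ihh_alt = NA_real_, ihs = NA_real_,
                    std_ihs = NA_real_, p = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (s in seq_len(S)) {
    r <- ihs_unstandardized(hm, samples, s, maf_min, ehh_min, max_gap_bp,
                            discard_border)
    res$alt_freq[s] <- r$alt_freq
    res$ihh_ref[s] <- r$ihh_ref
    res$ihh_alt[s] <- r$ihh_alt
    res$ihs[s] <- r$ihs
    res$reason[s] <- r$reason
  }
  if (sum(!is.na(res$ihs)) >= min_bin) {
    st <- standardize_ihs(res$ihs, res$alt_freq, bin_width, min_bin)
    res$std_ihs <- st$std_ihs
    res$p <- ihs_pvalue(res$std_ihs)
  }
  class(res) <- c("ihs_table", "data.frame")
  res
}

#' Call outlier (candidate-selection) sites
#'
#' A site is significant when its -log10 p-value strictly exceeds
#' `threshold`. Each outlier is annotated with the driving allele: ALT when
#' iHS < 0 (extended ALT homozygosity), REF when iHS > 0.
#'
#' @param table an [ihs_scan()] result.
#' @param threshold -log10 p threshold (default 5).
#' @return The significant rows with an extra `driving_allele` column.
#' @export
call_outliers <- function(table, threshold = 5) {
  sig <- which(!is.na(table$p) & table$p > threshold)
  out <- table[sig, , drop = FALSE]
  out$driving_allele <- ifelse(out$std_ihs < 0, "alt", "ref")
  class(out) <- "data.frame"
  out
}

#' Map outlier SNPs to candidate genes
#'
#' A gene is a candidate when its interval intersects
#' `[pos - flank, pos + flank]` for any outlier SNP on the same chromosome.
#' Hits are deduplicated per gene; the distance to the nearest outlier SNP
#' is reported (0 when a SNP falls inside the gene).
#'
#' @param outliers a [call_outliers()] result (needs chrom, pos).
#' @param genes a [read_gene_annotations()] table.
#' @param flank flanking distance in bp on each side (default 30 kb).
#' @return A `data.frame`: gene_id, chrom, start_bp, end_bp, name,
#'   nearest_snp_pos, distance_bp.
#' @export
candidate_genes <- function(outliers, genes, flank = 30000L) {
  hits <- list()
  for (g in seq_len(nrow(genes))) {
    snps <- outliers[outliers$chrom == genes$chrom[g], , drop = FALSE]
    if (!nrow(snps)) next
    d <- pmax(0, pmax(genes$start_bp[g] - snps$pos,
                      snps$pos - genes$end_bp[g]))
    i <- which.min(d)
    if (d[i] <= flank) {
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = genes$gene_id[g], chrom = genes$chrom[g],
        start_bp = genes$start_bp[g], end_bp = genes$end_bp[g],
        name = genes$name[g], nearest_snp_pos = snps$pos[i],
        distance_bp = d[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      name = character(0), nearest_snp_pos = integer(0),
                      distance_bp = integer(0)))
  do.call(rbind, c(hits, make.row.names = FALSE))
}

#' @export
print.ihs_table <- function(x, ...) {
  done <- sum(x$reason == "ok", na.rm = TRUE)
  cat("<ihs_table> ", nrow(x), " sites; iHS computed at ", done, "\n",
      sep = "")
  if (any(!is.na(x$p)))
    cat("  max -log10 p = ", signif(max(x$p, na.rm = TRUE), 4),
        " at pos ", x$pos[which.max(x$p)], "\n", sep = "")
  tab <- table(x$reason)
  drop <- tab[setdiff(names(tab), "ok")]
  if (length(drop))
    cat("  dropped: ", paste(names(drop), drop, sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Manhattan-style plot of an iHS scan
#'
#' @param x an [ihs_scan()] result.
#' @param threshold -log10 p significance line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ihs_table <- function(x, threshold = 5, ...) {
  ok <- !is.na(x$p)
  graphics::plot(x$pos[ok] / 1e6, x$p[ok], pch = 20, cex = 0.5,
                 xlab = "position (Mb)", ylab = expression(-log[10] ~ p),
                 ...)
  graphics::abline(h = threshold, col = "orange", lwd = 2)
  invisible(x)
}
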