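#' Read phased haplotypes from a VCF
#'
#' Parses a VCF v4.x with GT fields into a [hap_matrix()]. Only biallelic SNP
#' records are used; multiallelic or indel records are skipped and counted
#' (attribute `n_skipped`, with a warning). Unphased genotypes are accepted
#' only when homozygous, unless `random_phase = TRUE`, in which case
#' heterozygous unphased genotypes are assigned a random (seeded) phase.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param region optional `"chrom:start-end"` filter (1-based inclusive).
#' @param random_phase allow unphased heterozygotes, phased at random.
#' @param seed seed for random phase assignment.
#' @return A [hap_matrix()]; attribute `n_skipped` counts skipped records.
#' @export
read_vcf <- function(path, region = NULL, random_phase = FALSE, seed = 1L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  gt_fmt <- v@gt
  if (is.null(gt_fmt) || ncol(gt_fmt) < 2L)
    stop("VCF has no genotype (GT) data")
  if (!all(grepl("(^|:)GT(:|$)", gt_fmt[, "FORMAT"])))
    stop("GT field missing from FORMAT")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    warning(n_skipped, " non-biallelic-SNP record(s) skipped")
  keep <- snp
  if (!is.null(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    keep <- keep & chrom == m[2] & pos >= as.integer(m[3]) &
      pos <= as.integer(m[4])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  n_samp <- ncol(gt)
  if (nrow(gt) == 0L) stop("no usable biallelic SNP records")
  a1c <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2c <- substr(gt, 3, 3)
  to_allele <- function(ch) {
    out <- rep(NA_integer_, length(ch))
    out[ch == "0"] <- 0L
    out[ch == "1"] <- 1L
    out
  }
  a1 <- to_allele(a1c); a2 <- to_allele(a2c)
  miss <- is.na(gt) | gt == "."
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  unphased_het <- !miss & sep == "/" & !is.na(a1) & !is.na(a2) & a1 != a2
  if (any(unphased_het)) {
    if (!random_phase)
      stop("unphased heterozygous genotypes present; ",
           "set random_phase = TRUE to assign phase at random")
    with_seed(seed, {
      flip <- stats::rbinom(sum(unphased_het), 1L, 0.5) == 1L
      i <- which(unphased_het)[flip]
      tmp <- a1[i]; a1[i] <- a2[i]; a2[i] <- tmp
    })
  }
  # gt is sites x samples; build haplotypes x sites with 2 rows per sample
  alleles <- matrix(NA_integer_, 2L * n_samp, length(pos))
  alleles[seq(1L, 2L * n_samp, 2L), ] <- t(matrix(a1, nrow = length(pos)))
  alleles[seq(2L, 2L * n_samp, 2L), ] <- t(matrix(a2, nrow = length(pos)))
  ord <- order(chrom, pos)
  out <- hap_matrix(alleles[, ord, drop = FALSE], colnames(gt),
                    chrom[ord], pos[ord], ref[ord], alt[ord])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a haplotype matrix as a phased VCF
#'
#' @param hm a [hap_matrix()].
#' @param path output path.
#' @param phased write `|`-separated genotypes (default); `FALSE` writes `/`.
#' @param seed optional seed recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(hm, path, phased = TRUE, seed = NULL) {
  sep <- if (phased) "|" else "/"
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=introPaint-", utils::packageVersion("introPaint"),
           if (!is.null(seed)) paste0(";seed=", seed)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    vapply(unique(hm$chrom), function(ch)
      sprintf("##contig=<ID=%s>", ch), ""),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hm$sample_ids), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  n_sites <- ncol(hm$alleles)
  if (n_sites > 0) {
    ch1 <- hm$alleles[seq(1L, nrow(hm$alleles), 2L), , drop = FALSE]
    ch2 <- hm$alleles[seq(2L, nrow(hm$alleles), 2L), , drop = FALSE]
    f <- function(x) ifelse(is.na(x), ".", as.character(x))
    gt <- matrix(paste0(f(ch1), sep, f(ch2)), nrow = nrow(ch1))
    lines <- paste(hm$chrom, hm$pos, ".", hm$ref, hm$alt, ".", "PASS", ".",
                   "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a population table
#'
#' Tab-separated file with columns sample, population and (optionally) role.
#'
#' @param path TSV path.
#' @return A [sample_table()].
#' @export
read_population_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("population table needs >= 2 columns")
  role <- if (ncol(df) >= 3) df[[3]] else rep("reference", nrow(df))
  sample_table(df[[1]], df[[2]], role)
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3: only `gene` features are kept (a file with none yields an empty
#' table with a warning). BED intervals (0-based half-open) are converted to
#' 1-based inclusive coordinates. Output is sorted by (chrom, start).
#'
#' @param path annotation file path.
#' @param format `"gff3"` or `"bed"`.
#' @return A `data.frame` with columns gene_id, chrom, start_bp, end_bp,
#'   name (1-based inclusive coordinates).
#' @export
read_gene_annotations <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) {
      warning("no 'gene' features found in GFF3")
      return(data.frame(gene_id = character(0), chrom = character(0),
                        start_bp = integer(0), end_bp = integer(0),
                        name = character(0)))
    }
    id <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
    nm <- if (!is.null(gr$Name)) gr$Name else id
    df <- data.frame(gene_id = as.character(id),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start_bp = GenomicRanges::start(gr),
                     end_bp = GenomicRanges::end(gr),
                     name = as.character(nm), stringsAsFactors = FALSE)
  } else {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    nm <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
      paste0("gene", seq_len(nrow(bed)))
    df <- data.frame(gene_id = nm, chrom = as.character(bed[[1]]),
                     start_bp = as.integer(bed[[2]]) + 1L,  # 0-based -> 1-based
                     end_bp = as.integer(bed[[3]]),
                     name = nm, stringsAsFactors = FALSE)
  }
  if (any(df$start_bp > df$end_bp)) stop("gene with start > end")
  df[order(df$chrom, df$start_bp), , drop = FALSE]
}
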