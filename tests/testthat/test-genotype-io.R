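test_that("VCF write/read round-trips alleles, coordinates and missing data", {
  a <- matrix(c(0L, 1L, NA, 1L,
                1L, 0L, 1L, 0L,
                0L, 0L, 1L, 1L), nrow = 4, byrow = FALSE)
  hm <- hap_matrix(a, c("sA", "sB"), "chr1", c(10L, 200L, 3000L),
                   ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  f <- tempfile(fileext = ".vcf")
  write_vcf(hm, f, seed = 7)
  expect_true(any(grepl("seed=7", readLines(f, n = 3))))
  back <- read_vcf(f)
  expect_identical(back$alleles, hm$alleles)
  expect_identical(back$pos, hm$pos)
  expect_identical(back$chrom, hm$chrom)
  expect_identical(back$ref, hm$ref)
  expect_identical(back$alt, hm$alt)
  expect_identical(back$sample_ids, hm$sample_ids)
})

test_that("read_vcf skips multiallelic and indel records with a count", {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
             "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1",
             "chr1\t200\t.\tA\tC,T\t.\tPASS\t.\tGT\t0|1\t0|2",
             "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0|0\t0|1",
             "chr1\t400\t.\tG\tC\t.\tPASS\t.\tGT\t1|0\t0|0")
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  expect_warning(hm <- read_vcf(f), "skipped")
  expect_equal(attr(hm, "n_skipped"), 2)
  expect_equal(ncol(hm$alleles), 2)
  expect_equal(hm$pos, c(100L, 400L))
})

test_that("unphased heterozygotes need the random-phase flag, and it is seeded", {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
             "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",
             "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t1/1")
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  expect_error(read_vcf(f), "unphased")
  h1 <- read_vcf(f, random_phase = TRUE, seed = 5)
  h2 <- read_vcf(f, random_phase = TRUE, seed = 5)
  expect_identical(h1$alleles, h2$alleles)
  # homozygous unphased is fine either way
  expect_equal(sort(h1$alleles[, 1]), c(0L, 1L))
  expect_equal(h1$alleles[, 2], c(1L, 1L))
})

test_that("SNP-count windows follow the half-overlap grid and trailing rule", {
  w300 <- windows_by_snp_count(random_hm(4, 300), 150, 75)
  expect_equal(nrow(w300), 3)
  expect_equal(w300$first, c(0, 75, 150))
  expect_equal(w300$last, c(150, 225, 300))
  w150 <- windows_by_snp_count(random_hm(4, 150), 150, 75)
  expect_equal(nrow(w150), 1)
  w310 <- windows_by_snp_count(random_hm(4, 310), 150, 75)
  expect_equal(nrow(w310), 4)
  expect_equal(w310$first[4], 225)
  expect_equal(w310$last[4], 310)
  expect_equal(w310$snp_count[4], 85)
  expect_warning(w99 <- windows_by_snp_count(random_hm(4, 99), 150, 75),
                 "fewer than")
  expect_equal(nrow(w99), 0)
})

test_that("every SNP index is covered at most twice at half-overlap", {
  hm <- random_hm(4, 287, seed = 9)
  w <- windows_by_snp_count(hm, 150, 75)
  cover <- integer(287)
  for (i in seq_len(nrow(w)))
    cover[(w$first[i] + 1):w$last[i]] <- cover[(w$first[i] + 1):w$last[i]] + 1
  expect_true(all(cover >= 1))
  expect_true(all(cover <= 2))
})

test_that("bp windows tile the chromosome and retain empty windows", {
  hm <- random_hm(4, 250, bp_per_site = 1000)  # positions 1..249001
  hm$pos[250] <- 250000L
  hm <- hap_matrix(hm$alleles, hm$sample_ids, hm$chrom, hm$pos)
  w <- windows_by_bp(hm, 100000, 50000)
  expect_equal(w$start_bp, c(1, 50001, 100001, 150001))
  expect_equal(w$end_bp, c(100000, 150000, 200000, 250000))
  # a SNP at exactly 100,000 falls in the first two windows
  hm2 <- hm_from_matrix(matrix(0:1, 2, 3), pos = c(1, 100000, 250000))
  w2 <- windows_by_bp(hm2, 100000, 50000)
  in_w <- function(i, j) w2$start_bp[i] <= hm2$pos[j] &
    w2$end_bp[i] >= hm2$pos[j]
  expect_true(in_w(1, 2) && in_w(2, 2))
  expect_false(in_w(3, 2))
  # windows with no SNPs are retained with snp_count 0
  expect_true(any(w2$snp_count == 0))
})

test_that("population allele frequencies are complete-case with undefined flag", {
  a <- matrix(c(0L, 1L, 1L, 1L,
                0L, NA, 1L, 1L,
                NA, NA, NA, NA), nrow = 4)
  hm <- hm_from_matrix(a)
  f <- pop_allele_freq(hm, c("s01", "s02"))
  expect_equal(f$freq[1], 0.75)
  expect_equal(f$freq[2], 2 / 3)
  expect_true(f$undefined[3])
  expect_equal(f$n_called, c(4L, 3L, 0L))
  expect_error(pop_allele_freq(hm, "nope"), "unknown sample")
})

test_that("LD pruning drops the later of a correlated pair, keeps independents, is idempotent", {
  withr::with_seed(11, {
    x <- rbinom(1000, 1, 0.5)
    y <- rbinom(1000, 1, 0.5)   # independent of x
    a <- cbind(x, x, y, rep(0L, 1000))  # duplicate pair + independent + monomorphic
  })
  hm <- hm_from_matrix(a)
  kept <- ld_prune(hm)
  expect_equal(kept, c(1L, 3L, 4L))     # 2nd dropped (r2=1); mono kept
  # independent columns both kept (r2 ~ 0 < 0.2)
  expect_true(all(c(1L, 3L) %in% kept))
  # r2_max = 1 keeps everything
  expect_equal(ld_prune(hm, r2_max = 1), 1:4)
  # idempotent
  hm2 <- hm_subset(hm, sites = kept)
  expect_equal(length(ld_prune(hm2)), length(kept))
})

test_that("gene annotations parse from BED (coordinate shift) and GFF3", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr6\t17899999\t18000000\tgeneB",
               "chr1\t99\t200\tgeneA"), bed)
  g <- read_gene_annotations(bed, "bed")
  expect_equal(g$start_bp, c(100L, 17900000L))  # sorted by (chrom, start)
  expect_equal(g$end_bp, c(200L, 18000000L))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t500\t900\t.\t+\t.\tID=g1;Name=G1",
               "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g2;Name=G2"), gff)
  g2 <- read_gene_annotations(gff, "gff3")
  expect_equal(g2$gene_id, c("g2", "g1"))
  expect_equal(g2$start_bp, c(100L, 500L))
  gff_mrna <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t500\t900\t.\t+\t.\tID=m1"), gff_mrna)
  expect_warning(g3 <- read_gene_annotations(gff_mrna, "gff3"),
                 "no 'gene'")
  expect_equal(nrow(g3), 0)
})
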