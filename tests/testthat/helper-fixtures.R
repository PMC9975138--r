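# Small in-code fixtures shared across test files.

# hap_matrix from a plain matrix (one row per haplotype; even row count)
hm_from_matrix <- function(a, pos = NULL, chrom = "chr1", prefix = "s") {
  n <- nrow(a)
  stopifnot(n %% 2 == 0)
  if (is.null(pos)) pos <- seq_len(ncol(a))
  hap_matrix(a, sprintf("%s%02d", prefix, seq_len(n / 2)), chrom, pos)
}

# seeded random biallelic panel
random_hm <- function(n_hap, n_sites, seed = 42, maf = NULL,
                      bp_per_site = 1) {
  withr::with_seed(seed, {
    p <- if (is.null(maf)) stats::runif(n_sites, 0.05, 0.95) else
      rep(maf, n_sites)
    a <- matrix(stats::rbinom(n_hap * n_sites, 1, rep(p, each = n_hap)),
                nrow = n_hap)
    hm_from_matrix(a, pos = 1 + (seq_len(n_sites) - 1) * bp_per_site)
  })
}

# a full-span window row for a hap_matrix
whole_window <- function(hm) {
  list(chrom = hm$chrom[1], first = 0L, last = ncol(hm$alleles),
       start_bp = min(hm$pos), end_bp = max(hm$pos),
       snp_count = ncol(hm$alleles))
}
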