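#' Phased haplotype matrix
#'
#' The central data container: a matrix of phased biallelic alleles with one
#' row per haplotype (two consecutive rows per sample) and one column per SNP.
#' Allele values are 0 (REF), 1 (ALT) or `NA` (missing). Positions are 1-based
#' base-pair coordinates, strictly increasing within each chromosome.
#'
#' @param alleles integer matrix, haplotypes x sites, values in \{0, 1, NA\}.
#' @param sample_ids character vector of sample names, one per diploid sample;
#'   row `2i-1` and `2i` of `alleles` are the two haplotypes of sample `i`.
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, one per site; strictly
#'   increasing within each chromosome.
#' @param ref,alt single-character REF and ALT alleles per site.
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(alleles, sample_ids, chrom, pos, ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_sites <- ncol(alleles)
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("alleles must have exactly 2 rows per sample")
  if (length(chrom) == 1L) chrom <- rep(chrom, n_sites)
  if (length(chrom) != n_sites || length(pos) != n_sites)
    stop("chrom/pos length must equal the number of sites")
  bad <- !(alleles %in% c(0L, 1L, NA))
  if (any(bad)) stop("alleles must be 0, 1 or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  structure(
    list(
      alleles = alleles,
      sample_ids = sample_ids,
      sample = rep(sample_ids, each = 2L),
      hap = rep(1:2, times = length(sample_ids)),
      chrom = as.character(chrom),
      pos = as.integer(pos),
      ref = as.character(ref),
      alt = as.character(alt)
    ),
    class = "hap_matrix"
  )
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("<hap_matrix> ", nrow(x$alleles), " haplotypes (",
      length(x$sample_ids), " samples) x ", ncol(x$alleles), " sites; ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$alleles))
  cat("  positions ", x$pos[1], "-", x$pos[length(x$pos)],
      "; missing fraction ", signif(miss, 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)

n_haps <- function(x) nrow(x$alleles)
n_sites <- function(x) ncol(x$alleles)

#' Subset a haplotype matrix
#'
#' @param x a [hap_matrix()].
#' @param samples optional character vector of sample ids to keep.
#' @param sites optional integer vector of site (column) indices to keep.
#' @return A `hap_matrix` restricted to the requested samples/sites.
#' @export
hm_subset <- function(x, samples = NULL, sites = NULL) {
  rows <- seq_len(nrow(x$alleles))
  ids <- x$sample_ids
  if (!is.null(samples)) {
    unknown <- setdiff(samples, ids)
    if (length(unknown))
      stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    keep <- ids %in% samples
    ids <- ids[keep]
    rows <- which(x$sample %in% samples)
  }
  if (is.null(sites)) sites <- seq_len(ncol(x$alleles))
  hap_matrix(x$alleles[rows, sites, drop = FALSE], ids,
             x$chrom[sites], x$pos[sites], x$ref[sites], x$alt[sites])
}

#' Combine haplotype matrices over the same sites
#'
#' Stacks the haplotype rows of several matrices that describe the same sites
#' (identical chromosome, position, REF and ALT vectors).
#'
#' @param ... `hap_matrix` objects.
#' @return A single `hap_matrix`.
#' @export
hm_bind <- function(...) {
  xs <- list(...)
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!identical(x$pos, ref$pos) || !identical(x$chrom, ref$chrom))
      stop("hap_matrix objects describe different sites")
  }
  hap_matrix(do.call(rbind, lapply(xs, `[[`, "alleles")),
             unlist(lapply(xs, `[[`, "sample_ids")),
             ref$chrom, ref$pos, ref$ref, ref$alt)
}

#' Per-site population allele frequency
#'
#' ALT-allele frequency in a set of samples, computed per site from
#' non-missing haplotypes (complete-case).
#'
#' @param x a [hap_matrix()].
#' @param samples character vector of sample ids defining the population.
#' @return A list with `freq` (ALT frequency per site; `NaN` where all
#'   haplotypes are missing), `n_called` (non-missing haplotype count per
#'   site) and `undefined` (logical flag per site).
#' @export
pop_allele_freq <- function(x, samples) {
  unknown <- setdiff(samples, x$sample_ids)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  rows <- x$sample %in% samples
  if (!any(rows)) stop("no haplotypes selected")
  a <- x$alleles[rows, , drop = FALSE]
  n_called <- colSums(!is.na(a))
  freq <- colSums(a == 1L, na.rm = TRUE) / n_called
  list(freq = freq, n_called = n_called, undefined = n_called == 0L)
}

#' Population sample table
#'
#' @param sample character vector of unique sample ids.
#' @param population population label per sample.
#' @param role one of `"reference"`, `"target"`, `"outgroup"` per sample.
#' @return A `data.frame` with columns sample, population, role.
#' @export
sample_table <- function(sample, population,
                         role = rep("reference", length(sample))) {
  if (anyDuplicated(sample)) stop("sample ids must be unique")
  if (!all(role %in% c("reference", "target", "outgroup")))
    stop("role must be reference, target or outgroup")
  data.frame(sample = as.character(sample),
             population = as.character(population),
             role = as.character(role), stringsAsFactors = FALSE)
}

#' Samples belonging to a population
#' @param samples a [sample_table()].
#' @param pop population label.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(samples, pop) {
  samples$sample[samples$population == pop]
}

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
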