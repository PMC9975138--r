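#' Population model for the Balding-Nichols simulator
#'
#' Describes a set of diverged gene pools. Per site an ancestral ALT frequency
#' p is drawn uniformly from `ancestral_freq_range`; each population's
#' frequency is then drawn from Beta(p(1-F)/F, (1-p)(1-F)/F), where F is that
#' population's drift coefficient, and haplotype alleles are Bernoulli draws
#' from the population frequency.
#'
#' @param pop_labels character vector of population names.
#' @param drift_F per-population drift coefficient, strictly in (0, 1).
#' @param n_haplotypes per-population haplotype count (>= 2).
#' @param ancestral_freq_range length-2 numeric, 0 < low < high < 1.
#' @return An object of class `pop_model`.
#' @export
pop_model <- function(pop_labels, drift_F, n_haplotypes,
                      ancestral_freq_range = c(0.1, 0.9)) {
  k <- length(pop_labels)
  drift_F <- rep_len(drift_F, k)
  n_haplotypes <- rep_len(as.integer(n_haplotypes), k)
  if (any(drift_F <= 0 | drift_F >= 1))
    stop("drift_F must be strictly between 0 and 1")
  if (any(n_haplotypes < 2L)) stop("n_haplotypes must be >= 2 per population")
  r <- ancestral_freq_range
  if (length(r) != 2 || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1)
    stop("ancestral_freq_range must satisfy 0 < low < high < 1")
  structure(list(pop_labels = pop_labels, drift_F = drift_F,
                 n_haplotypes = n_haplotypes, ancestral_freq_range = r),
            class = "pop_model")
}

#' Introgression tract specification
#'
#' A contiguous donor segment planted on target haplotypes; coordinates are
#' 1-based inclusive.
#'
#' @param chrom chromosome name.
#' @param start_bp,end_bp 1-based inclusive bounds, `start_bp <= end_bp`.
#' @param donor_pop donor population name.
#' @param carrier_fraction probability in \[0, 1\] that a target sample
#'   carries the tract (both haplotypes of a carrier sample carry it).
#' @return An object of class `tract_spec`.
#' @export
tract_spec <- function(chrom, start_bp, end_bp, donor_pop,
                       carrier_fraction = 0.5) {
  if (start_bp > end_bp) stop("start_bp must be <= end_bp")
  if (carrier_fraction < 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in [0, 1]")
  structure(list(chrom = chrom, start_bp = as.integer(start_bp),
                 end_bp = as.integer(end_bp), donor_pop = donor_pop,
                 carrier_fraction = carrier_fraction),
            class = "tract_spec")
}

#' Partial-sweep specification (founder-copy model)
#'
#' @param focal_bp position of the focal (selected) site.
#' @param q carrier fraction, strictly in (0, 1).
#' @param lambda_bp expected one-sided length (bp) of the founder-copied
#'   haplotype; copying extends an Exponential(mean = lambda_bp) distance on
#'   each side of the focal site.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(focal_bp, q, lambda_bp) {
  if (q <= 0 || q >= 1) stop("q must be strictly in (0, 1)")
  if (lambda_bp <= 0) stop("lambda_bp must be > 0")
  structure(list(focal_bp = as.integer(focal_bp), q = q,
                 lambda_bp = lambda_bp), class = "sweep_spec")
}

# Balding-Nichols population frequency draws around ancestral frequencies p.
bn_freq <- function(p, F) {
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# Bernoulli haplotype draws: n_hap x n_sites matrix from per-site frequencies.
draw_haps <- function(n_hap, freq) {
  matrix(stats::rbinom(n_hap * length(freq), 1L, rep(freq, each = n_hap)),
         nrow = n_hap)
}

#' Simulate diverged reference panels
#'
#' Draws one haplotype panel per population under the Balding-Nichols model
#' (see [pop_model()]). Sites are statistically independent; positions are
#' evenly spaced at `bp_per_site`. Sites that come out monomorphic across the
#' union of all panels are made biallelic by flipping one randomly chosen
#' haplotype allele (seeded, so still deterministic).
#'
#' @param model a [pop_model()].
#' @param n_sites number of SNPs (>= 1).
#' @param bp_per_site spacing in bp; positions are 1, 1 + bp_per_site, ...
#' @param seed integer RNG seed.
#' @param chrom chromosome name for all sites.
#' @return A list with `panel` (a [hap_matrix()] holding all populations;
#'   sample ids are `<pop>_<i>`), `samples` (a [sample_table()]), `freqs`
#'   (sites x populations matrix of drawn Balding-Nichols frequencies) and
#'   `p_anc` (ancestral frequencies).
#' @export
simulate_reference_panels <- function(model, n_sites, bp_per_site = 1000L,
                                      seed = 1L, chrom = "chr1") {
  stopifnot(inherits(model, "pop_model"))
  if (n_sites < 1) stop("n_sites must be >= 1")
  with_seed(seed, {
    r <- model$ancestral_freq_range
    p_anc <- stats::runif(n_sites, r[1], r[2])
    k <- length(model$pop_labels)
    freqs <- matrix(NA_real_, n_sites, k,
                    dimnames = list(NULL, model$pop_labels))
    blocks <- vector("list", k)
    ids <- character(0)
    pops <- character(0)
    for (j in seq_len(k)) {
      freqs[, j] <- bn_freq(p_anc, model$drift_F[j])
      nh <- model$n_haplotypes[j]
      if (nh %% 2L != 0L)
        stop("n_haplotypes must be even (2 per diploid sample)")
      blocks[[j]] <- draw_haps(nh, freqs[, j])
      ns <- nh %/% 2L
      ids <- c(ids, sprintf("%s_%02d", model$pop_labels[j], seq_len(ns)))
      pops <- c(pops, rep(model$pop_labels[j], ns))
    }
    alleles <- do.call(rbind, blocks)
    # force biallelic in the union of populations
    mono <- which(colSums(alleles) %in% c(0L, nrow(alleles)))
    if (length(mono)) {
      rows <- sample.int(nrow(alleles), length(mono), replace = TRUE)
      for (i in seq_along(mono))
        alleles[rows[i], mono[i]] <- 1L - alleles[rows[i], mono[i]]
    }
    pos <- 1L + (seq_len(n_sites) - 1L) * as.integer(bp_per_site)
    nuc <- c("A", "C", "G", "T")
    ref <- sample(nuc, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(nuc, b), 1L), "")
    list(panel = hap_matrix(alleles, ids, chrom, pos, ref, alt),
         samples = sample_table(ids, pops),
         freqs = freqs, p_anc = p_anc)
  })
}

#' Simulate admixed target genomes with planted donor tracts
#'
#' Target haplotypes are mosaics: alleles are drawn from the background
#' population's frequencies everywhere except inside planted tracts on
#' carrier samples, where they are drawn from the donor population's
#' frequencies. Carrier status is Bernoulli(`carrier_fraction`) per sample;
#' both haplotypes of a carrier sample carry the tract, and every carried
#' tract is recorded in the returned truth set.
#'
#' @param panels result of [simulate_reference_panels()] (its `freqs`, site
#'   coordinates and chromosome are used).
#' @param background_pop name of the background population.
#' @param tracts list of [tract_spec()]; tracts on one target must not
#'   overlap.
#' @param n_targets number of target samples to simulate.
#' @param seed integer RNG seed.
#' @param prefix sample-name prefix for targets.
#' @return A list with `targets` (a [hap_matrix()]) and `truth` (a
#'   `data.frame` with one row per carried tract: sample, hap, chrom,
#'   start_bp, end_bp, donor).
#' @export
simulate_admixed_targets <- function(panels, background_pop, tracts,
                                     n_targets, seed = 1L,
                                     prefix = "target") {
  freqs <- panels$freqs
  hm <- panels$panel
  if (!background_pop %in% colnames(freqs))
    stop("unknown background population: ", background_pop)
  tracts <- if (inherits(tracts, "tract_spec")) list(tracts) else tracts
  for (tr in tracts) {
    if (!tr$donor_pop %in% colnames(freqs))
      stop("unknown donor population: ", tr$donor_pop)
    if (tr$start_bp < min(hm$pos) || tr$end_bp > max(hm$pos))
      stop("tract outside the simulated region")
  }
  if (length(tracts) > 1) {
    iv <- t(vapply(tracts, function(t) c(t$start_bp, t$end_bp), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping tracts on one target")
  }
  with_seed(seed, {
    bg <- freqs[, background_pop]
    n_hap <- 2L * n_targets
    alleles <- draw_haps(n_hap, bg)
    ids <- sprintf("%s_%02d", prefix, seq_len(n_targets))
    truth <- list()
    for (tr in tracts) {
      carriers <- which(stats::rbinom(n_targets, 1L, tr$carrier_fraction) == 1L)
      in_tract <- which(hm$chrom == tr$chrom &
                        hm$pos >= tr$start_bp & hm$pos <= tr$end_bp)
      donor <- freqs[in_tract, tr$donor_pop]
      for (s in carriers) {
        for (h in 1:2) {
          row <- 2L * (s - 1L) + h
          alleles[row, in_tract] <-
            stats::rbinom(length(in_tract), 1L, donor)
          truth[[length(truth) + 1L]] <- data.frame(
            sample = ids[s], hap = h, chrom = tr$chrom,
            start_bp = tr$start_bp, end_bp = tr$end_bp,
            donor = tr$donor_pop, stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(sample = character(0), hap = integer(0),
                 chrom = character(0), start_bp = integer(0),
                 end_bp = integer(0), donor = character(0))
    list(targets = hap_matrix(alleles, ids, hm$chrom, hm$pos, hm$ref, hm$alt),
         truth = truth)
  })
}

#' Simulate a four-population quartet with gene flow
#'
#' P1 and P2 are sister pools derived from a common Balding-Nichols lineage,
#' P3 is a diverged donor pool and P4 an outgroup lineage. Gene flow from P3
#' into P2 is implemented as contiguous blocks of sites covering a fraction
#' `f_true` of the genome, inside which P2 haplotypes are drawn from P3's
#' population frequencies.
#'
#' @param f_true true admixture fraction in \[0, 1\].
#' @param n_per_pop diploid samples per population (>= 2 haplotypes each).
#' @param n_sites number of SNPs.
#' @param seed integer RNG seed.
#' @param bp_per_site spacing in bp.
#' @param block_sites sites per introgression block.
#' @param drift per-branch drift coefficients: `split` (ancestor of P1/P2),
#'   `sister` (P1 and P2 around that ancestor), `p3` and `p4` (from the root).
#' @param chrom chromosome name.
#' @return A list with `quartet` (a [hap_matrix()] with populations
#'   P1..P4), `samples` (a [sample_table()]; P4 has role outgroup) and
#'   `truth` (list with `f_true` and the introgressed site indices).
#' @export
simulate_quartet <- function(f_true, n_per_pop = 30L, n_sites = 30000L,
                             seed = 1L, bp_per_site = 1000L,
                             block_sites = 200L,
                             drift = c(split = 0.2, sister = 0.1,
                                       p3 = 0.3, p4 = 0.5),
                             chrom = "chr1") {
  if (f_true < 0 || f_true > 1) stop("f_true must be in [0, 1]")
  if (n_per_pop < 2) stop("n_per_pop must be >= 2")
  with_seed(seed, {
    p_anc <- stats::runif(n_sites, 0.1, 0.9)
    p12 <- bn_freq(p_anc, drift[["split"]])
    fr <- cbind(P1 = bn_freq(p12, drift[["sister"]]),
                P2 = bn_freq(p12, drift[["sister"]]),
                P3 = bn_freq(p_anc, drift[["p3"]]),
                P4 = bn_freq(p_anc, drift[["p4"]]))
    # contiguous introgression blocks: P2 frequencies replaced by P3's
    n_blocks_total <- n_sites %/% block_sites
    n_intro <- round(f_true * n_blocks_total)
    intro_sites <- integer(0)
    if (n_intro > 0) {
      picked <- sample.int(n_blocks_total, n_intro)
      intro_sites <- sort(unlist(lapply(picked, function(b)
        ((b - 1L) * block_sites + 1L):(b * block_sites))))
      fr[intro_sites, "P2"] <- fr[intro_sites, "P3"]
    }
    nh <- 2L * n_per_pop
    alleles <- do.call(rbind, lapply(colnames(fr), function(p)
      draw_haps(nh, fr[, p])))
    ids <- as.vector(vapply(colnames(fr), function(p)
      sprintf("%s_%02d", p, seq_len(n_per_pop)), character(n_per_pop)))
    pops <- rep(colnames(fr), each = n_per_pop)
    pos <- 1L + (seq_len(n_sites) - 1L) * as.integer(bp_per_site)
    list(quartet = hap_matrix(alleles, ids, chrom, pos),
         samples = sample_table(ids, pops,
                                ifelse(pops == "P4", "outgroup", "reference")),
         truth = list(f_true = f_true, intro_sites = intro_sites))
  })
}

#' Plant a partial selective sweep in a panel (founder-copy model)
#'
#' Picks one founder haplotype carrying the focal ALT allele; a fraction `q`
#' of haplotypes then copy the founder's alleles outward from the focal site
#' for an Exponential(mean `lambda_bp`) distance on each side, producing the
#' long shared haplotypes around a partially swept allele that EHH-based
#' statistics detect. The focal allele frequency is set to approximately `q`.
#'
#' @param panel a [hap_matrix()].
#' @param spec a [sweep_spec()]; `focal_bp` must match a site position.
#' @param seed integer RNG seed.
#' @return The modified `hap_matrix` with attribute `focal_index`.
#' @export
simulate_sweep_region <- function(panel, spec, seed = 1L) {
  stopifnot(inherits(spec, "sweep_spec"))
  focal <- match(spec$focal_bp, panel$pos)
  if (is.na(focal)) stop("focal_bp is not a site position in the panel")
  a <- panel$alleles
  n <- nrow(a)
  cnt <- sum(a[, focal] == 1L, na.rm = TRUE)
  if (cnt == 0L || cnt == n) stop("focal site is monomorphic in the panel")
  with_seed(seed, {
    n_carriers <- round(spec$q * n)
    if (n_carriers >= 1L) {
      founder <- sample(which(a[, focal] == 1L), 1L)
      # carriers: the founder plus a random draw of other haplotypes
      others <- sample(setdiff(seq_len(n), founder), n_carriers - 1L)
      carriers <- c(founder, others)
      a[, focal] <- 0L
      a[carriers, focal] <- 1L
      pos <- panel$pos
      for (h in carriers) {
        if (h == founder) next
        d_right <- stats::rexp(1, 1 / spec$lambda_bp)
        d_left <- stats::rexp(1, 1 / spec$lambda_bp)
        idx <- which(pos >= pos[focal] - d_left & pos <= pos[focal] + d_right)
        a[h, idx] <- a[founder, idx]
      }
    }
    out <- hap_matrix(a, panel$sample_ids, panel$chrom, panel$pos,
                      panel$ref, panel$alt)
    attr(out, "focal_index") <- focal
    out
  })
}

#' Write a simulated dataset to disk
#'
#' Emits a phased VCF, a population TSV (`sample<TAB>population<TAB>role`), a
#' BED4 file of truth tracts (0-based half-open; name column
#' `sample|hap|donor`) and a truth JSON. The VCF round-trips losslessly
#' through [read_vcf()].
#'
#' @param hm a [hap_matrix()] (typically references and targets combined via
#'   [hm_bind()]).
#' @param samples a [sample_table()] covering every sample in `hm`.
#' @param truth optional truth `data.frame` as returned by
#'   [simulate_admixed_targets()].
#' @param outdir output directory (created if needed).
#' @param seed seed recorded in the VCF header and truth JSON.
#' @return Invisibly, a named character vector of the files written.
#' @export
emit_dataset <- function(hm, samples, truth = NULL, outdir, seed = NULL) {
  if (!all(hm$sample_ids %in% samples$sample))
    stop("sample table does not cover every emitted sample")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(vcf = file.path(outdir, "genotypes.vcf"),
             pops = file.path(outdir, "populations.tsv"),
             bed = file.path(outdir, "truth_tracts.bed"),
             json = file.path(outdir, "truth.json"))
  write_vcf(hm, files[["vcf"]], seed = seed)
  utils::write.table(samples, files[["pops"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(truth) && nrow(truth)) {
    bed <- data.frame(chrom = truth$chrom,
                      start = truth$start_bp - 1L,  # 0-based half-open
                      end = truth$end_bp,
                      name = paste(truth$sample, truth$hap, truth$donor,
                                   sep = "|"))
    utils::write.table(bed, files[["bed"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(files[["bed"]])
  }
  jsonlite::write_json(
    list(seed = seed,
         tracts = if (is.null(truth)) list() else truth),
    files[["json"]], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
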