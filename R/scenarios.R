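#' Default chromosome-painting scenario
#'
#' Three strongly diverged reference panels (drift F = 0.3, 60 haplotypes
#' each) plus an outgroup lineage (F = 0.5), a 30 Mb pseudo-chromosome at
#' 1 SNP/kb, and 20 target genomes on a GJ (japonica-like) background
#' carrying a planted 3.8 Mb cAus-like donor tract (17.9-21.7 Mb, carrier
#' fraction 0.5). This mirrors the structure in which a large adaptive
#' introgression was described in upland rice.
#'
#' @param seed integer RNG seed.
#' @param n_sites SNP count (default 30,000 = 30 Mb at 1 SNP/kb).
#' @param n_targets number of admixed target samples.
#' @param carrier_fraction probability a target carries the tract.
#' @param tract a [tract_spec()] (default chr6:17,900,001-21,700,000 from
#'   the cAus-like pool).
#' @return A list with `panels` (reference simulation), `targets`, `truth`,
#'   `combined` (references + targets + outgroup in one [hap_matrix()]),
#'   `samples` (roles set for painting) and `tract`.
#' @export
scenario_painting <- function(seed = 1L, n_sites = 30000L, n_targets = 20L,
                              carrier_fraction = 0.5, tract = NULL) {
  model <- pop_model(c("GJ", "XI", "cAus", "OUT"),
                     drift_F = c(0.3, 0.3, 0.3, 0.5),
                     n_haplotypes = c(60L, 60L, 60L, 20L))
  panels <- simulate_reference_panels(model, n_sites, 1000L, seed,
                                      chrom = "chr6")
  if (is.null(tract))
    tract <- tract_spec("chr6", 17900001L, 21700000L, "cAus",
                        carrier_fraction)
  tg <- simulate_admixed_targets(panels, "GJ", list(tract), n_targets,
                                 seed + 1L)
  combined <- hm_bind(panels$panel, tg$targets)
  roles <- panels$samples
  roles$role[roles$population == "OUT"] <- "outgroup"
  samples <- rbind(roles,
                   sample_table(tg$targets$sample_ids,
                                rep("admixed", n_targets),
                                rep("target", n_targets)))
  list(panels = panels, targets = tg$targets, truth = tg$truth,
       combined = combined, samples = samples, tract = tract)
}

#' Default sweep scenario
#'
#' A single 5 Mb region at 1 SNP/kb, 200 haplotypes drawn from one
#' Balding-Nichols pool (F = 0.1), with (optionally) a founder-copy partial
#' sweep at the centre: carrier fraction q = 0.5 and mean one-sided copied
#' length 150 kb.
#'
#' @param seed integer RNG seed.
#' @param sweep plant the sweep (`FALSE` gives the neutral control).
#' @param n_hap haplotypes in the panel (must be even).
#' @param n_sites SNP count (default 5,000 = 5 Mb at 1 SNP/kb).
#' @param q carrier fraction.
#' @param lambda_bp mean one-sided copied length in bp.
#' @return A list with `panel` (a [hap_matrix()]), `focal_bp`,
#'   `focal_index` and `spec` (`NULL` for neutral runs).
#' @export
scenario_sweep <- function(seed = 1L, sweep = TRUE, n_hap = 200L,
                           n_sites = 5000L, q = 0.5,
                           lambda_bp = 150000L) {
  model <- pop_model("POP", 0.1, n_hap)
  sim <- simulate_reference_panels(model, n_sites, 1000L, seed,
                                   chrom = "chr1")
  focal_index <- (n_sites %/% 2L) + 1L
  focal_bp <- sim$panel$pos[focal_index]
  if (!sweep)
    return(list(panel = sim$panel, focal_bp = focal_bp,
                focal_index = focal_index, spec = NULL))
  spec <- sweep_spec(focal_bp, q, lambda_bp)
  panel <- simulate_sweep_region(sim$panel, spec, seed + 1L)
  list(panel = panel, focal_bp = focal_bp, focal_index = focal_index,
       spec = spec)
}
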