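#' Validate pipeline inputs
#'
#' Checks a VCF and population table (and optionally a gene annotation file)
#' for the properties the pipeline assumes: GT present and phased,
#' biallelic SNPs, sorted positions, and every population represented in
#' the VCF. Per-population haplotype counts are printed.
#'
#' @param vcf path to the VCF.
#' @param pops path to the population TSV.
#' @param genes optional path to a GFF3/BED annotation
#'   (format guessed from the extension).
#' @param quiet suppress the per-population summary.
#' @return Invisibly, a list with `findings` (character vector; empty when
#'   clean), `hm` and `samples`. Fatal problems raise an error.
#' @export
validate_inputs <- function(vcf, pops, genes = NULL, quiet = FALSE) {
  for (f in c(vcf, pops, genes))
    if (!file.exists(f)) stop("file not found: ", f)
  # sortedness is checked on the raw records before hap_matrix sorts them
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  if (length(body)) {
    ch <- sub("\t.*", "", body)
    po <- as.numeric(vapply(strsplit(body, "\t", fixed = TRUE),
                            `[[`, "", 2))
    for (cc in unique(ch)) {
      p <- po[ch == cc]
      if (is.unsorted(p, strictly = TRUE)) {
        first_bad <- which(diff(p) <= 0)[1] + 1L
        stop("unsorted positions in ", cc, ": record at line ",
             which(ch == cc)[first_bad] + sum(startsWith(lines, "#")),
             " (pos ", p[first_bad], ")")
      }
    }
  }
  hm <- read_vcf(vcf)
  samples <- read_population_table(pops)
  findings <- character(0)
  missing_pop <- setdiff(samples$sample, hm$sample_ids)
  if (length(missing_pop))
    stop("population-table sample(s) absent from VCF: ",
         paste(missing_pop, collapse = ", "))
  extra <- setdiff(hm$sample_ids, samples$sample)
  if (length(extra))
    findings <- c(findings, paste0("VCF sample(s) not in population table: ",
                                   paste(extra, collapse = ", ")))
  nsk <- attr(hm, "n_skipped")
  if (!is.null(nsk) && nsk > 0)
    findings <- c(findings, paste0(nsk, " non-biallelic-SNP records skipped"))
  if (!is.null(genes)) {
    fmt <- if (grepl("\\.bed$", genes, ignore.case = TRUE)) "bed" else "gff3"
    invisible(read_gene_annotations(genes, fmt))
  }
  if (!quiet) {
    cnt <- table(samples$population[match(hm$sample, samples$sample)])
    cat("haplotypes per population:\n")
    for (p in names(cnt)) cat(sprintf("  %-12s %d\n", p, cnt[[p]]))
    if (length(findings)) cat("findings:\n ",
                              paste(findings, collapse = "\n  "), "\n")
    else cat("no findings\n")
  }
  invisible(list(findings = findings, hm = hm, samples = samples))
}

# Fixed ideogram colour map: three reference groups in sorted order get
# blue/red/yellow; pairs blend to purple/green/orange.
ideogram_colors <- function(groups) {
  groups <- sort(groups)
  base <- c("blue", "red", "gold")[seq_along(groups)]
  names(base) <- groups
  cols <- base
  if (length(groups) >= 2) {
    pair_col <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "+")
      mix <- c("blue+red" = "purple", "blue+gold" = "green",
               "gold+red" = "orange")
      m <- paste(sort(c(base[a], base[b])), collapse = "+")
      unname(mix[m])
    }
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i < j) {
        nm <- paste(sort(c(groups[i], groups[j])), collapse = "+")
        cols[nm] <- pair_col(groups[i], groups[j])
      }
    }
  }
  cols["unspecific"] <- "grey"
  cols["absent"] <- "black"
  cols
}

#' Render a painting ideogram
#'
#' One horizontal bar per painted haplotype, coloured by slice label:
#' single-group labels in blue/red/yellow, shared (dual) labels in the
#' blended colours (purple/green/orange), unspecific in grey and absent in
#' black. Layout is deterministic.
#'
#' @param painting a [paint_genome()] result.
#' @param outfile optional PNG path; when `NULL`, draws on the active
#'   device.
#' @param width,height device size in pixels when writing a PNG.
#' @return Invisibly, the label-to-colour map used.
#' @export
render_ideogram <- function(painting, outfile = NULL, width = 900,
                            height = 600) {
  sl <- painting$slices
  if (is.null(sl) || !nrow(sl)) stop("empty painting: nothing to render")
  cols <- ideogram_colors(painting$groups)
  if (!is.null(outfile)) {
    grDevices::png(outfile, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  haps <- unique(sl[, c("sample", "hap")])
  haps <- haps[order(haps$sample, haps$hap), ]
  n <- nrow(haps)
  graphics::plot(NULL, xlim = range(c(sl$start_bp, sl$end_bp)) / 1e6,
                 ylim = c(0, n + 1), xlab = "position (Mb)", ylab = "",
                 yaxt = "n", main = "Local haplotype assignment")
  graphics::axis(2, at = seq_len(n),
                 labels = paste0(haps$sample, "/", haps$hap),
                 las = 2, cex.axis = 0.6)
  for (i in seq_len(n)) {
    s <- sl[sl$sample == haps$sample[i] & sl$hap == haps$hap[i], ]
    col <- cols[s$label]
    col[is.na(col)] <- "grey"
    graphics::rect(s$start_bp / 1e6, i - 0.4, s$end_bp / 1e6, i + 0.4,
                   col = col, border = NA)
  }
  invisible(cols)
}

#' One-command synthetic end-to-end demo
#'
#' Generates the default painting, quartet and sweep scenarios, runs every
#' pipeline stage (painting, ABBA-BABA D/f, windowed Fst/fdM localization,
#' iHS scan with candidate genes) and writes a summary report with
#' pass/fail checks of the expected recoveries. Deterministic for a given
#' seed.
#'
#' @param outdir output directory.
#' @param seed integer RNG seed.
#' @return An object of class `demo_report` (list of per-stage results and
#'   `checks`, a named logical vector); written to `outdir/report.json`
#'   alongside the emitted dataset and figures.
#' @export
run_demo <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  checks <- c()
  ## painting scenario: emit to disk, validate, read back, paint
  sc <- scenario_painting(seed)
  files <- emit_dataset(sc$combined, sc$samples, sc$truth,
                        file.path(outdir, "dataset"), seed = seed)
  val <- validate_inputs(files[["vcf"]], files[["pops"]], quiet = TRUE)
  checks["inputs_valid"] <- length(val$findings) == 0
  pg <- paint_genome(val$hm, val$samples)
  ev <- evaluate_painting(pg, sc$truth, background = "GJ")
  checks["painting_accuracy_ge_0.90"] <- ev$accuracy >= 0.90
  render_ideogram(pg, file.path(outdir, "ideogram.png"))
  ## quartet scenarios: null and f = 0.2
  q0 <- simulate_quartet(0, seed = seed)
  # a null quartet routinely gives a small negative f estimate
  t0 <- suppressWarnings(
    abba_baba_test(q0$quartet, q0$samples, "P1", "P2", "P3", "P4"))
  qa <- simulate_quartet(0.2, seed = seed)
  ta <- abba_baba_test(qa$quartet, qa$samples, "P1", "P2", "P3", "P4")
  checks["null_quartet_not_significant"] <- abs(t0$Z) < 3
  checks["admixed_quartet_significant"] <- ta$Z > 3
  checks["f_recovered_within_0.05"] <- abs(ta$f_hat - 0.2) <= 0.05
  ## windowed localization on the painting scenario
  carriers <- unique(sc$truth$sample)
  non_carriers <- setdiff(sc$targets$sample_ids, carriers)
  loc <- list(fst_peak_in_tract = NA, fdm_peak_in_tract = NA)
  if (length(carriers) >= 2 && length(non_carriers) >= 2) {
    scan <- sliding_scan(sc$combined,
                         list(car = carriers, non = non_carriers))
    fst <- scan$fst_car_non
    peak <- which.max(ifelse(is.na(fst), -Inf, fst))
    loc$fst_peak_in_tract <-
      scan$end_bp[peak] >= sc$tract$start_bp &&
      scan$start_bp[peak] <= sc$tract$end_bp
    st <- sc$samples
    st$population[st$sample %in% sc$targets$sample_ids] <- "TGT"
    qf <- quartet_freqs(sc$combined, st, "GJ", "TGT", "cAus", "OUT")
    fw <- fd_fdM_windows(qf, windows_by_bp(sc$combined))
    pk <- which.max(ifelse(is.na(fw$fdM), -Inf, fw$fdM))
    loc$fdm_peak_in_tract <-
      fw$end_bp[pk] >= sc$tract$start_bp &&
      fw$start_bp[pk] <= sc$tract$end_bp
  }
  checks["fst_peak_in_tract"] <- isTRUE(loc$fst_peak_in_tract)
  checks["fdm_peak_in_tract"] <- isTRUE(loc$fdm_peak_in_tract)
  ## sweep scenario: iHS localization and candidate genes
  sw <- scenario_sweep(seed)
  scan <- ihs_scan(sw$panel)
  top <- which.max(ifelse(is.na(scan$std_ihs), -Inf, abs(scan$std_ihs)))
  checks["sweep_detected_near_focal"] <-
    any(!is.na(scan$p) & scan$p > 5 &
          abs(scan$pos - sw$focal_bp) <= 50000)
  outl <- call_outliers(scan, 5)
  genes <- data.frame(gene_id = "toy_gene", chrom = "chr1",
                      start_bp = sw$focal_bp - 5000L,
                      end_bp = sw$focal_bp + 5000L, name = "toy_gene")
  cand <- candidate_genes(outl, genes)
  report <- structure(
    list(seed = seed,
         painting = list(accuracy = ev$accuracy,
                         boundaries = ev$boundaries),
         quartet = list(null = t0[c("D", "SE", "Z", "f_hat")],
                        admixed = ta[c("D", "SE", "Z", "f_hat")]),
         localization = loc,
         sweep = list(focal_bp = sw$focal_bp,
                      peak_pos = scan$pos[top],
                      peak_p = scan$p[top],
                      n_outliers = nrow(outl),
                      n_candidate_genes = nrow(cand)),
         checks = checks),
    class = "demo_report")
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' @export
print.demo_report <- function(x, ...) {
  cat("introgression pipeline demo (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  painting accuracy: %.3f\n", x$painting$accuracy))
  cat(sprintf("  null quartet:    D = %+.3f  Z = %+.2f\n",
              x$quartet$null$D, x$quartet$null$Z))
  cat(sprintf("  admixed quartet: D = %+.3f  Z = %+.2f  f = %.3f\n",
              x$quartet$admixed$D, x$quartet$admixed$Z,
              x$quartet$admixed$f_hat))
  cat(sprintf("  sweep: focal %d, iHS peak at %d (-log10 p = %.2f)\n",
              x$sweep$focal_bp, x$sweep$peak_pos, x$sweep$peak_p))
  cat("  checks:\n")
  for (nm in names(x$checks))
    cat(sprintf("    [%s] %s\n", if (x$checks[[nm]]) "PASS" else "FAIL", nm))
  cat(if (all(x$checks)) "ALL CHECKS PASSED\n" else "SOME CHECKS FAILED\n")
  invisible(x)
}
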