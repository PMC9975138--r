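test_that("pop_model and tract/sweep specs validate their invariants", {
  expect_error(pop_model("A", 0, 10), "drift_F")
  expect_error(pop_model("A", 1, 10), "drift_F")
  expect_error(pop_model("A", 0.2, 1), "n_haplotypes")
  expect_error(pop_model("A", 0.2, 10, c(0.9, 0.1)), "ancestral_freq_range")
  expect_error(tract_spec("chr1", 100, 50, "A"), "start_bp")
  expect_error(tract_spec("chr1", 1, 2, "A", 1.5), "carrier_fraction")
  expect_error(sweep_spec(100, 0, 1000), "q must")
  expect_error(sweep_spec(100, 0.5, -1), "lambda")
  expect_error(simulate_reference_panels(pop_model("A", 0.2, 10), 0), "n_sites")
})

test_that("reference panels are seeded-deterministic with the stated geometry", {
  m <- pop_model(c("A", "B"), c(0.3, 0.3), c(10, 10))
  s1 <- simulate_reference_panels(m, 500, 1000, seed = 7)
  s2 <- simulate_reference_panels(m, 500, 1000, seed = 7)
  expect_identical(s1$panel$alleles, s2$panel$alleles)
  expect_identical(s1$freqs, s2$freqs)
  expect_equal(s1$panel$pos, 1L + (0:499) * 1000L)
  # biallelic in the union of populations
  cs <- colSums(s1$panel$alleles)
  expect_true(all(cs > 0 & cs < nrow(s1$panel$alleles)))
})

test_that("drift F -> 0 makes population frequencies track the ancestral ones", {
  s <- simulate_reference_panels(pop_model("P", 1e-6, 10), 10000, 1, seed = 3)
  expect_lt(mean(abs(s$freqs[, 1] - s$p_anc)), 0.01)
})

test_that("empirical panel frequencies recover the drawn frequencies", {
  s <- simulate_reference_panels(pop_model("P", 0.2, 1000), 2000, 1, seed = 8)
  emp <- colMeans(s$panel$alleles)
  expect_gte(mean(abs(emp - s$freqs[, 1]) < 0.05), 0.99)
})

test_that("Hudson Fst between panels grows with drift and sits in the pinned band", {
  fst_at <- function(F) {
    m <- pop_model(c("A", "B"), c(F, F), c(60, 60))
    p <- simulate_reference_panels(m, 10000, 1000, seed = 4)
    w <- whole_window(p$panel)
    A <- pop_samples(p$samples, "A"); B <- pop_samples(p$samples, "B")
    as.numeric(window_fst_hudson(window_pi(p$panel, A, w),
                                 window_pi(p$panel, B, w),
                                 window_dxy(p$panel, A, B, w)))
  }
  f <- vapply(c(0.05, 0.15, 0.3), fst_at, 0)
  expect_true(all(diff(f) > 0))
  # 3 pops at F = 0.3: pairwise Fst in the calibrated band [0.15, 0.45]
  expect_gt(f[3], 0.15)
  expect_lt(f[3], 0.45)
})

test_that("admixed targets are background mosaics with recorded donor tracts", {
  m <- pop_model(c("A", "B"), c(0.3, 0.3), c(20, 20))
  p <- simulate_reference_panels(m, 3000, 1000, seed = 2)
  tr <- tract_spec("chr1", 1000001, 1800000, "B", 0.5)
  tg <- simulate_admixed_targets(p, "A", list(tr), 20, seed = 5)
  # binomial(20, 0.5) carrier draw at this seed gives 9 carrier samples
  expect_equal(length(unique(tg$truth$sample)), 9)
  expect_equal(nrow(tg$truth), 18)  # both haplotypes per carrier
  # carrier_fraction = 0: no truth, targets look like background
  tg0 <- simulate_admixed_targets(
    p, "A", list(tract_spec("chr1", 1000001, 1800000, "B", 0)), 20,
    seed = 5)
  expect_equal(nrow(tg0$truth), 0)
  expect_lt(mean(abs(colMeans(tg0$targets$alleles) - p$freqs[, "A"])),
            0.06)
  # carrier_fraction = 1 over the whole region: frequencies match the donor
  tg1 <- simulate_admixed_targets(
    p, "A", list(tract_spec("chr1", 1, 2999001, "B", 1)), 30, seed = 5)
  expect_equal(length(unique(tg1$truth$sample)), 30)
  expect_lt(mean(abs(colMeans(tg1$targets$alleles) - p$freqs[, "B"])),
            0.05)
  # overlapping tracts rejected
  expect_error(simulate_admixed_targets(
    p, "A", list(tract_spec("chr1", 1, 1000, "B"),
                 tract_spec("chr1", 500, 2000, "B")), 5, seed = 1),
    "overlapping")
})

test_that("quartet simulation hits its degenerate limits", {
  expect_error(simulate_quartet(0.5, n_per_pop = 1, n_sites = 100), "n_per_pop")
  expect_error(simulate_quartet(1.5), "f_true")
  # f_true = 1: P2 == P3 in distribution, f-hat ~ 1
  q1 <- simulate_quartet(1, n_per_pop = 30, n_sites = 5000, seed = 2)
  qf <- quartet_freqs(q1$quartet, q1$samples, "P1", "P2", "P3", "P4")
  expect_lt(abs(admixture_fraction_f(qf) - 1), 0.05)
  expect_equal(q1$truth$f_true, 1)
  # gene flow is laid down in contiguous blocks
  q <- simulate_quartet(0.2, n_per_pop = 5, n_sites = 2000, seed = 3)
  expect_equal(length(q$truth$intro_sites), 0.2 * 2000)
  runs <- rle(diff(q$truth$intro_sites))
  expect_gte(max(runs$lengths[runs$values == 1]), 199)
})

test_that("founder-copy sweeps respect their degenerate limits", {
  hm <- random_hm(20, 200, seed = 6, bp_per_site = 1000)
  focal_bp <- hm$pos[100]
  # q below 1/n: nothing changes
  sw0 <- simulate_sweep_region(hm, sweep_spec(focal_bp, 0.02, 1e5), seed = 1)
  expect_identical(sw0$alleles, hm$alleles)
  # lambda -> Inf: all carriers identical to the founder; EHH stays 1
  sw <- simulate_sweep_region(hm, sweep_spec(focal_bp, 0.5, 1e12), seed = 1)
  carriers <- which(sw$alleles[, 100] == 1L)
  expect_equal(length(carriers), 10)
  for (h in carriers)
    expect_identical(sw$alleles[h, ], sw$alleles[carriers[1], ])
  curve <- ehh_decay(sw, focal = 100, core_allele = 1L)
  expect_true(all(curve$left$ehh == 1))
  expect_true(all(curve$right$ehh == 1))
  expect_true(all(curve$truncated))
  # monomorphic focal rejected
  hm2 <- hm
  hm2$alleles[, 50] <- 0L
  expect_error(simulate_sweep_region(hm2, sweep_spec(hm$pos[50], 0.5, 1e5)),
               "monomorphic")
})

test_that("emitted datasets round-trip and truth BED uses 0-based half-open intervals", {
  m <- pop_model(c("A", "B"), c(0.3, 0.3), c(10, 10))
  p <- simulate_reference_panels(m, 200, 1000, seed = 2)
  tr <- tract_spec("chr1", 50001, 120000, "B", 0.6)
  tg <- simulate_admixed_targets(p, "A", list(tr), 5, seed = 4)
  combined <- hm_bind(p$panel, tg$targets)
  st <- rbind(p$samples,
              sample_table(tg$targets$sample_ids, rep("adm", 5),
                           rep("target", 5)))
  out <- file.path(tempdir(), "emit-test")
  files <- emit_dataset(combined, st, tg$truth, out, seed = 4)
  expect_true(all(file.exists(files)))
  back <- read_vcf(files[["vcf"]])
  expect_identical(back$alleles, combined$alleles)
  expect_identical(back$pos, combined$pos)
  st_back <- read_population_table(files[["pops"]])
  expect_equal(st_back, st, ignore_attr = TRUE)
  bed <- read.table(files[["bed"]], sep = "\t")
  expect_equal(nrow(bed), nrow(tg$truth))
  expect_equal(bed[[2]], tg$truth$start_bp - 1L)
  expect_equal(bed[[3]], tg$truth$end_bp)
  expect_match(bed[[4]][1], "^target_\\d+\\|[12]\\|B$")
})
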