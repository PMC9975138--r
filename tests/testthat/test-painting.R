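# small three-pool scenario reused across painting tests
make_panels <- function(seed = 21, n_sites = 1500, n_hap = 30) {
  m <- pop_model(c("A", "B", "C"), 0.3, n_hap)
  simulate_reference_panels(m, n_sites, 1000, seed = seed)
}

test_that("reference selection applies the inclusive ancestry cutoff", {
  props <- data.frame(sample = c("r1", "t1", "r2"),
                      c1 = c(0.85, 0.60, 0.80),
                      c2 = c(0.10, 0.30, 0.20),
                      c3 = c(0.05, 0.10, 0.00))
  st <- select_references(props, cutoff = 0.8)
  expect_equal(st$role, c("reference", "target", "reference"))
  expect_equal(st$population, c("c1", "admixed", "c1"))
  expect_error(select_references(props, cutoff = 0.5), "cutoff")
  bad <- props; bad$c1[1] <- 0.5
  expect_error(select_references(bad), "sum to 1")
})

test_that("window PCA separates diverged pools and respects duplicates/constant sites", {
  withr::with_seed(31, {
    a <- rbind(matrix(rbinom(30 * 20, 1, 0.1), 30),
               matrix(rbinom(30 * 20, 1, 0.9), 30))
  })
  hm <- hm_from_matrix(a)
  coords <- fit_window_pca(hm, 1:20, painting_config(n_pcs = 5))
  between <- abs(mean(coords[1:30, 1]) - mean(coords[31:60, 1]))
  within <- max(sd(coords[1:30, 1]), sd(coords[31:60, 1]))
  expect_gt(between, within)
  # duplicate haplotype rows get identical coordinates
  a2 <- rbind(a, a[1, ], a[1, ])
  hm2 <- hm_from_matrix(a2)
  c2 <- fit_window_pca(hm2, 1:20, painting_config())
  expect_equal(c2[61, ], c2[62, ], tolerance = 1e-12)
  # adding a constant site leaves coordinates unchanged
  hm3 <- hm_from_matrix(cbind(a, 1L))
  c3 <- fit_window_pca(hm3, 1:21, painting_config())
  expect_equal(abs(c3), abs(coords), tolerance = 1e-8)
  # too few polymorphic sites -> absent
  mono <- hm_from_matrix(cbind(a[, 1:3], matrix(0L, 60, 10)))
  expect_null(fit_window_pca(mono, 1:13, painting_config(n_pcs = 5)))
})

test_that("reference KDEs are proper densities with floored bandwidths", {
  withr::with_seed(5, {
    coords <- matrix(rnorm(40, sd = 2), ncol = 1)
  })
  kde <- fit_reference_kde(coords, rep("G", 40),
                           painting_config(n_pcs = 1))$G
  # Scott's rule bandwidth and mixture mass ~ 1 (quadrature oracle)
  expect_equal(kde$bw, max(sd(coords) * 40^(-1 / 5), 1e-3),
               tolerance = 1e-12)
  mass <- brute_kde_mass(kde$centers[, 1], kde$bw, -30, 30)
  expect_lt(abs(mass - 1), 1e-2)
  # density at the centroid beats a point 10 bandwidths away
  ld_c <- introPaint:::kde_log_density(kde, mean(coords))
  ld_far <- introPaint:::kde_log_density(kde, mean(coords) + 10 * kde$bw +
                                           max(abs(coords)))
  expect_gt(ld_c, ld_far)
  # zero-variance dimension: bandwidth floored, density finite
  flat <- matrix(c(rnorm(20), rep(1, 20)), ncol = 2)
  kde2 <- fit_reference_kde(flat, rep("G", 20),
                            painting_config(n_pcs = 2))$G
  expect_equal(kde2$bw[2], 1e-3)
  expect_true(is.finite(introPaint:::kde_log_density(kde2, c(0, 1))))
  # undersized group flagged absent
  expect_null(fit_reference_kde(flat, c(rep("G", 4), rep(NA, 16)),
                                painting_config())$G)
})

test_that("haplotype assignment follows the single/dual/unspecific thresholds", {
  cfg <- painting_config()
  mk <- function(center, m = 10, d = 2, bw = 0.5)
    list(centers = matrix(rep(center, each = m), m, d), bw = rep(bw, d))
  # far-separated groups: confident single label
  kdes <- list(A = mk(0), B = mk(20), C = mk(-20))
  a <- assign_haplotype(c(0, 0), kdes, cfg)
  expect_equal(a$label, "A")
  expect_gt(a$posterior[["A"]], 0.99)
  expect_equal(sum(a$posterior), 1)
  # equidistant between identical A and B, C remote: dual label
  kdes2 <- list(A = mk(-1), B = mk(1), C = mk(50))
  a2 <- assign_haplotype(c(0, 0), kdes2, cfg)
  expect_equal(a2$label, "A+B")
  expect_equal(unname(a2$posterior[c("A", "B")]), c(0.5, 0.5),
               tolerance = 1e-9)
  # three identical densities: 1/3 each, unspecific
  kdes3 <- list(A = mk(0), B = mk(0), C = mk(0))
  a3 <- assign_haplotype(c(0, 0), kdes3, cfg)
  expect_equal(a3$label, "unspecific")
  expect_equal(unname(a3$posterior), rep(1 / 3, 3), tolerance = 1e-9)
  # fewer than two densities: absent
  a4 <- assign_haplotype(c(0, 0), list(A = mk(0), B = NULL, C = NULL), cfg)
  expect_equal(a4$label, "absent")
})

test_that("posteriors sum to one across random assignment cases", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      kdes <- lapply(1:3, function(i)
        list(centers = matrix(rnorm(20, mean = runif(1, -5, 5)), 10, 2),
             bw = runif(2, 0.1, 1)))
      names(kdes) <- c("A", "B", "C")
      a <- assign_haplotype(rnorm(2, sd = 3), kdes, painting_config())
      expect_equal(sum(a$posterior), 1, tolerance = 1e-9)
    }
  })
})

test_that("painting recovers a planted donor tract and leaves non-carriers clean", {
  p <- make_panels()
  tr <- tract_spec("chr1", 500001, 1000000, "C", 1)
  tg <- simulate_admixed_targets(p, "A", list(tr), 3, seed = 22)
  # plus one non-carrier target
  tg0 <- simulate_admixed_targets(
    p, "A", list(tract_spec("chr1", 500001, 1000000, "C", 0)), 1,
    seed = 23, prefix = "clean")
  hm <- hm_bind(p$panel, tg$targets, tg0$targets)
  st <- rbind(p$samples,
              sample_table(c(tg$targets$sample_ids, "clean_01"),
                           rep("admixed", 4), rep("target", 4)))
  pg <- paint_genome(hm, st)
  ev <- evaluate_painting(pg, tg$truth, background = "A")
  expect_gte(ev$accuracy, 0.9)
  # carrier haplotypes have a C-labelled tract overlapping the truth
  expect_true(all(!is.na(ev$boundaries$start_err)))
  # the non-carrier has no C-labelled tract longer than 2 windows
  ctr <- pg$tracts[pg$tracts$sample == "clean_01" &
                     pg$tracts$label == "C", , drop = FALSE]
  if (nrow(ctr))
    expect_true(all(ctr$last - ctr$first <= 2 * 150))
  # determinism: identical inputs give identical paintings
  pg2 <- paint_genome(hm, st)
  expect_identical(pg$slices, pg2$slices)
})

test_that("a target identical to a reference haplotype paints as one tract", {
  p <- make_panels(seed = 40, n_sites = 600)
  dup <- p$panel$alleles[1, , drop = FALSE]
  tgt <- hap_matrix(rbind(dup, dup), "twin", p$panel$chrom, p$panel$pos)
  hm <- hm_bind(p$panel, tgt)
  st <- rbind(p$samples, sample_table("twin", "admixed", "target"))
  pg <- paint_genome(hm, st)
  tw <- pg$tracts[pg$tracts$sample == "twin" & pg$tracts$hap == 1, ]
  expect_equal(nrow(tw), 1)
  expect_equal(tw$label, "A")
})

test_that("painting is equivariant under permuting reference group names", {
  p <- make_panels(seed = 25, n_sites = 600)
  tr <- tract_spec("chr1", 200001, 400000, "C", 1)
  tg <- simulate_admixed_targets(p, "A", list(tr), 2, seed = 26)
  hm <- hm_bind(p$panel, tg$targets)
  st <- rbind(p$samples,
              sample_table(tg$targets$sample_ids, c("admixed", "admixed"),
                           c("target", "target")))
  pg <- paint_genome(hm, st)
  # rename A -> Z (and keep everything else); labels must follow
  st2 <- st
  st2$population[st2$population == "A"] <- "Z"
  pg2 <- paint_genome(hm, st2)
  relabel <- function(l) {
    parts <- strsplit(l, "+", fixed = TRUE)
    vapply(parts, function(p)
      paste(sort(ifelse(p == "A", "Z", p)), collapse = "+"), "")
  }
  keep <- !pg$slices$label %in% c("unspecific", "absent")
  expect_equal(relabel(pg$slices$label[keep]), pg2$slices$label[keep])
})

test_that("evaluation flags an all-unspecific painting", {
  p <- make_panels(seed = 27, n_sites = 600)
  tg <- simulate_admixed_targets(
    p, "A", list(tract_spec("chr1", 1, 2, "C", 0)), 1, seed = 28)
  hm <- hm_bind(p$panel, tg$targets)
  st <- rbind(p$samples,
              sample_table(tg$targets$sample_ids, "admixed", "target"))
  pg <- paint_genome(hm, st)
  pg$slices$label <- "unspecific"
  ev <- evaluate_painting(pg, tg$truth, background = "A")
  expect_equal(ev$accuracy, 0)
  expect_true(ev$all_unspecific)
})
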