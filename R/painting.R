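#' Painting configuration
#'
#' Parameters of the supervised chromosome-painting classifier: window
#' geometry, number of principal components retained, and the posterior
#' thresholds that map kernel-density posteriors to single, dual ("shared"),
#' unspecific or absent labels.
#'
#' @param window_size window size in SNPs.
#' @param window_step window step in SNPs.
#' @param n_pcs number of principal components used for density estimation.
#' @param single_label_min_posterior minimum posterior for a single-group
#'   label.
#' @param dual_label_min_joint minimum joint posterior of the top two groups
#'   for a dual label.
#' @param dual_label_min_each minimum individual posterior of each of the top
#'   two groups for a dual label.
#' @param absent_max_missing_fraction a window is "absent" for a reference
#'   group when more than this fraction of its SNPs is missing in the group.
#' @param min_group_haplotypes minimum reference haplotypes per group for a
#'   usable density.
#' @return An object of class `painting_config`.
#' @export
painting_config <- function(window_size = 150L, window_step = 75L,
                            n_pcs = 5L,
                            single_label_min_posterior = 0.8,
                            dual_label_min_joint = 0.8,
                            dual_label_min_each = 0.1,
                            absent_max_missing_fraction = 0.5,
                            min_group_haplotypes = 5L) {
  thr <- c(single_label_min_posterior, dual_label_min_joint,
           dual_label_min_each)
  if (any(thr <= 0 | thr > 1)) stop("thresholds must be in (0, 1]")
  if (n_pcs < 1) stop("n_pcs must be >= 1")
  if (window_step > window_size) stop("window_step must be <= window_size")
  structure(list(window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 n_pcs = as.integer(n_pcs),
                 single_label_min_posterior = single_label_min_posterior,
                 dual_label_min_joint = dual_label_min_joint,
                 dual_label_min_each = dual_label_min_each,
                 absent_max_missing_fraction = absent_max_missing_fraction,
                 min_group_haplotypes = as.integer(min_group_haplotypes)),
            class = "painting_config")
}

#' Select reference accessions from global ancestry proportions
#'
#' A sample is a reference for a cluster when its ancestry fraction for that
#' cluster is at least `cutoff` (inclusive); all other samples are targets
#' (admixed). A cutoff at or below 0.5 would allow two clusters to claim the
#' same sample and is rejected.
#'
#' @param props `data.frame`/matrix of per-sample ancestry fractions, one
#'   column per cluster (columns named by cluster), rows named or carrying a
#'   `sample` column; fractions must sum to 1 (tolerance 1e-6).
#' @param cutoff minimum pure-ancestry fraction, > 0.5.
#' @return A [sample_table()]: references labelled by their cluster, others
#'   `role = "target"` with population `"admixed"`.
#' @export
select_references <- function(props, cutoff = 0.8) {
  if (cutoff <= 0.5) stop("cutoff must be > 0.5")
  if (is.data.frame(props) && "sample" %in% names(props)) {
    ids <- props$sample
    m <- as.matrix(props[setdiff(names(props), "sample")])
  } else {
    m <- as.matrix(props)
    ids <- rownames(m)
    if (is.null(ids)) stop("sample ids required (rownames or column)")
  }
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stop("ancestry fractions must sum to 1")
  top <- max.col(m, ties.method = "first")
  topval <- m[cbind(seq_len(nrow(m)), top)]
  is_ref <- topval >= cutoff
  sample_table(ids,
               ifelse(is_ref, colnames(m)[top], "admixed"),
               ifelse(is_ref, "reference", "target"))
}

#' Per-window PCA of haplotypes
#'
#' Fits a PCA on all haplotypes (references and targets jointly) of one SNP
#' window. Sites are mean-centred; missing alleles are mean-imputed per site;
#' components are ordered by decreasing variance with the sign convention
#' that the largest-magnitude loading of each component is positive. Windows
#' with fewer than `n_pcs + 1` polymorphic sites are flagged absent.
#'
#' @param hm a [hap_matrix()].
#' @param window one row of [windows_by_snp_count()] (list or data.frame row
#'   with `first`, `last`), or an integer vector of site indices.
#' @param config a [painting_config()].
#' @return Haplotypes x `n_pcs` coordinate matrix, or `NULL` (absent window).
#' @export
fit_window_pca <- function(hm, window, config = painting_config()) {
  idx <- if (is.numeric(window)) as.integer(window) else
    (window$first + 1L):window$last
  x <- hm$alleles[, idx, drop = FALSE]
  storage.mode(x) <- "double"
  cm <- colMeans(x, na.rm = TRUE)
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- cm[nas[, 2]]
  poly <- sum(apply(x, 2, function(col) stats::var(col) > 0))
  if (poly < config$n_pcs + 1L) return(NULL)
  k <- min(config$n_pcs, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, rank. = k)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) coords[, j] <- -coords[, j]
  }
  if (k < config$n_pcs)
    coords <- cbind(coords, matrix(0, nrow(coords), config$n_pcs - k))
  rownames(coords) <- paste(hm$sample, hm$hap, sep = "|")
  coords
}

#' Fit per-reference kernel density models in PC space
#'
#' One Gaussian product-kernel density per reference group, with
#' per-dimension bandwidths from Scott's rule (`sd * m^(-1/(d+4))`, m group
#' size, d number of PCs), floored at 1e-3. Groups with fewer than
#' `min_group_haplotypes` members are flagged absent (`NULL` entry).
#'
#' @param coords coordinate matrix from [fit_window_pca()].
#' @param groups character/factor vector over rows of `coords`; `NA` for
#'   haplotypes (targets) not in any reference group.
#' @param config a [painting_config()].
#' @return Named list (one per group level) of `list(centers, bw)` models,
#'   `NULL` where the group is absent.
#' @export
fit_reference_kde <- function(coords, groups, config = painting_config()) {
  groups <- as.factor(groups)
  d <- ncol(coords)
  out <- stats::setNames(vector("list", nlevels(groups)), levels(groups))
  for (g in levels(groups)) {
    rows <- which(!is.na(groups) & groups == g)
    m <- length(rows)
    if (m < config$min_group_haplotypes) next
    centers <- coords[rows, , drop = FALSE]
    bw <- pmax(apply(centers, 2, stats::sd) * m^(-1 / (d + 4)), 1e-3)
    out[[g]] <- list(centers = centers, bw = bw)
  }
  out
}

# Log density of a product-Gaussian KDE at point x (length d).
kde_log_density <- function(kde, x) {
  lp <- sweep(kde$centers, 2, x)             # centers - x
  ll <- rowSums(stats::dnorm(lp, sd = rep(kde$bw, each = nrow(lp)),
                             log = TRUE))
  M <- max(ll)
  M + log(mean(exp(ll - M)))
}

#' Classify one haplotype in one window
#'
#' Posteriors are the per-group KDE densities normalised to sum to one
#' (equal priors). The label is the top group if its posterior reaches the
#' single-label threshold; otherwise the top two groups combined
#' (`"A+B"`) if their joint posterior reaches the dual threshold and each
#' reaches the per-group minimum; otherwise `"unspecific"`. If fewer than
#' two group densities are defined the label is `"absent"`.
#'
#' @param point numeric vector of PC coordinates.
#' @param kdes list from [fit_reference_kde()].
#' @param config a [painting_config()].
#' @return A list with `label`, `posterior` (named numeric, sums to 1) and
#'   `top_log_density` (the winning group's log density at the point; a
#'   saturation-proof confidence measure).
#' @export
assign_haplotype <- function(point, kdes, config = painting_config()) {
  ok <- !vapply(kdes, is.null, TRUE)
  if (sum(ok) < 2)
    return(list(label = "absent",
                posterior = stats::setNames(rep(NA_real_, length(kdes)),
                                            names(kdes)),
                top_log_density = -Inf))
  logd <- vapply(kdes[ok], kde_log_density, 0, x = point)
  M <- max(logd)
  w <- exp(logd - M)
  post <- stats::setNames(rep(0, length(kdes)), names(kdes))
  if (!all(is.finite(w)) || sum(w) == 0) {
    label <- "unspecific"
    post[] <- NA_real_
    return(list(label = label, posterior = post,
                top_log_density = -Inf))
  }
  post[names(logd)] <- w / sum(w)
  ord <- order(post, decreasing = TRUE)
  top <- ord[1]; second <- ord[2]
  if (post[top] >= config$single_label_min_posterior) {
    label <- names(post)[top]
  } else if (post[top] + post[second] >= config$dual_label_min_joint &&
             post[top] >= config$dual_label_min_each &&
             post[second] >= config$dual_label_min_each) {
    pair <- sort(names(post)[c(top, second)])
    label <- paste(pair, collapse = "+")
  } else {
    label <- "unspecific"
  }
  list(label = label, posterior = post, top_log_density = max(logd))
}

#' Paint target genomes against reference panels
#'
#' For every SNP window a PCA is fitted on references and targets jointly,
#' reference-group kernel densities are estimated on the retained PCs, and
#' every target haplotype is classified ([assign_haplotype()]). Overlapping
#' windows are reconciled per step-sized slice by keeping the covering
#' window whose top posterior is larger; posteriors that saturate to 1 in
#' double precision are tied, and ties are broken by the winning group's
#' log density at the point, then by window order (earlier wins). Adjacent
#' equal-label slices are merged into tracts whose bp bounds come from the
#' first and last SNP of the run.
#'
#' @param hm a [hap_matrix()] holding references and targets.
#' @param samples a [sample_table()]; rows with `role == "reference"` define
#'   the groups, rows with `role == "target"` are painted.
#' @param config a [painting_config()].
#' @return An object of class `painting`: list with `slices` (data.frame:
#'   sample, hap, chrom, first, last, start_bp, end_bp, label, posterior),
#'   `tracts` (merged runs), `windows`, `groups` and `config`.
#' @export
paint_genome <- function(hm, samples, config = painting_config()) {
  refs <- samples[samples$role == "reference", , drop = FALSE]
  tgts <- samples[samples$role == "target", , drop = FALSE]
  groups_lv <- sort(unique(refs$population))
  if (length(groups_lv) < 2) stop("references must span >= 2 groups")
  hap_pop <- refs$population[match(hm$sample, refs$sample)]
  hap_group <- factor(hap_pop, levels = groups_lv)
  target_rows <- which(hm$sample %in% tgts$sample)
  if (!length(target_rows)) stop("no target haplotypes to paint")
  win <- windows_by_snp_count(hm, config$window_size, config$window_step)
  if (!nrow(win)) {
    warning("no polymorphic windows; empty painting")
    return(structure(list(slices = NULL, tracts = NULL, windows = win,
                          groups = groups_lv, config = config),
                     class = "painting"))
  }
  nw <- nrow(win)
  lab <- matrix(NA_character_, length(target_rows), nw)
  top_post <- matrix(NA_real_, length(target_rows), nw)
  top_logd <- matrix(-Inf, length(target_rows), nw)
  post_arr <- array(NA_real_, c(length(target_rows), nw, length(groups_lv)),
                    dimnames = list(NULL, NULL, groups_lv))
  for (w in seq_len(nw)) {
    idx <- (win$first[w] + 1L):win$last[w]
    coords <- fit_window_pca(hm, idx, config)
    if (is.null(coords)) {
      lab[, w] <- "absent"
      next
    }
    # per-group missingness rule for the absent label
    kdes <- fit_reference_kde(coords, hap_group, config)
    for (g in groups_lv) {
      rows_g <- which(!is.na(hap_group) & hap_group == g)
      mf <- mean(is.na(hm$alleles[rows_g, idx]))
      if (mf > config$absent_max_missing_fraction) kdes[g] <- list(NULL)
    }
    if (sum(!vapply(kdes, is.null, TRUE)) < 2) {
      lab[, w] <- "absent"
      next
    }
    for (i in seq_along(target_rows)) {
      a <- assign_haplotype(coords[target_rows[i], ], kdes, config)
      lab[i, w] <- a$label
      top_post[i, w] <- suppressWarnings(max(a$posterior, na.rm = TRUE))
      top_logd[i, w] <- a$top_log_density
      post_arr[i, w, ] <- a$posterior
    }
  }
  # reconcile overlapping windows per step-sized slice, chromosome-wise
  slices <- list()
  step <- config$window_step
  for (ch in unique(win$chrom)) {
    wch <- which(win$chrom == ch)
    lo <- min(win$first[wch]); hi <- max(win$last[wch])
    bnd <- unique(c(seq(lo, hi, by = step), hi))
    for (k in seq_len(length(bnd) - 1L)) {
      s0 <- bnd[k]; s1 <- bnd[k + 1L]
      cover <- wch[win$first[wch] <= s0 & win$last[wch] >= s1]
      if (!length(cover)) next
      for (i in seq_along(target_rows)) {
        tp <- top_post[i, cover]
        tp[is.na(tp)] <- -Inf
        # larger top posterior; posteriors within 1e-6 are treated as
        # saturated ties (a point deep between clusters underflows to
        # exactly 1.0 while a point at a cluster centre reports 1 - 1e-8)
        # and broken by the winning group's absolute density at the
        # point; remaining ties -> earlier window
        cand <- which(tp >= max(tp) - 1e-6)
        best <- cover[cand[which.max(top_logd[i, cover][cand])]]
        slices[[length(slices) + 1L]] <- data.frame(
          sample = hm$sample[target_rows[i]],
          hap = hm$hap[target_rows[i]],
          chrom = ch, first = s0, last = s1,
          start_bp = hm$pos[s0 + 1L], end_bp = hm$pos[s1],
          label = lab[i, best],
          posterior = if (is.finite(top_post[i, best]))
            top_post[i, best] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  slices <- do.call(rbind, c(slices, make.row.names = FALSE))
  slices <- slices[order(slices$sample, slices$hap, slices$chrom,
                         slices$first), , drop = FALSE]
  tracts <- merge_slices(slices)
  structure(list(slices = slices, tracts = tracts, windows = win,
                 groups = groups_lv, config = config),
            class = "painting")
}

# Merge adjacent equal-label slices into tracts per haplotype.
merge_slices <- function(slices) {
  out <- list()
  key <- paste(slices$sample, slices$hap, slices$chrom)
  for (k in unique(key)) {
    s <- slices[key == k, , drop = FALSE]
    runs <- rle(s$label)
    stop_i <- cumsum(runs$lengths)
    start_i <- stop_i - runs$lengths + 1L
    out[[k]] <- data.frame(
      sample = s$sample[1], hap = s$hap[1], chrom = s$chrom[1],
      start_bp = s$start_bp[start_i], end_bp = s$end_bp[stop_i],
      first = s$first[start_i], last = s$last[stop_i],
      label = runs$values, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
print.painting <- function(x, ...) {
  cat("<painting> ", length(unique(paste(x$slices$sample, x$slices$hap))),
      " haplotypes, ", nrow(x$windows), " windows, groups: ",
      paste(x$groups, collapse = ", "), "\n", sep = "")
  tab <- sort(table(x$slices$label), decreasing = TRUE)
  cat("  slice labels:\n")
  for (nm in names(tab))
    cat(sprintf("    %-14s %6d (%.1f%%)\n", nm, tab[[nm]],
                100 * tab[[nm]] / nrow(x$slices)))
  invisible(x)
}

#' Compare a painting against truth tracts
#'
#' A slice counts as correct when its label equals the truth ancestry at the
#' slice midpoint, or (for dual labels) contains it. Boundary errors are
#' reported for each carried truth tract as the distance, in SNP indices,
#' between the truth tract bounds and the painted donor run that overlaps it.
#'
#' @param painting a [paint_genome()] result.
#' @param truth truth `data.frame` (sample, hap, chrom, start_bp, end_bp,
#'   donor) as produced by [simulate_admixed_targets()].
#' @param background ancestry label expected outside truth tracts.
#' @return A list with `accuracy`, `confusion` (truth x painted label
#'   table), and `boundaries` (per carried tract: start/end error in SNP
#'   indices, `NA` when no overlapping donor run was painted).
#' @export
evaluate_painting <- function(painting, truth, background) {
  sl <- painting$slices
  if (is.null(sl)) stop("empty painting")
  if (nrow(truth) && !all(truth$sample %in% sl$sample))
    stop("truth contains samples that were not painted")
  mid <- (sl$start_bp + sl$end_bp) / 2
  truth_lab <- rep(background, nrow(sl))
  if (nrow(truth)) {
    for (r in seq_len(nrow(truth))) {
      hit <- sl$sample == truth$sample[r] & sl$hap == truth$hap[r] &
        sl$chrom == truth$chrom[r] &
        mid >= truth$start_bp[r] & mid <= truth$end_bp[r]
      truth_lab[hit] <- truth$donor[r]
    }
  }
  contains <- function(label, anc)
    vapply(strsplit(label, "+", fixed = TRUE),
           function(p) anc %in% p, TRUE) & label != "unspecific"
  correct <- mapply(function(l, a) l == a || contains(l, a),
                    sl$label, truth_lab)
  confusion <- table(truth = truth_lab, painted = sl$label)
  boundaries <- NULL
  if (nrow(truth)) {
    rows <- lapply(seq_len(nrow(truth)), function(r) {
      s <- sl[sl$sample == truth$sample[r] & sl$hap == truth$hap[r] &
                sl$chrom == truth$chrom[r], , drop = FALSE]
      s <- s[order(s$first), , drop = FALSE]
      # contiguous runs of slices whose label contains the donor ancestry
      mark <- contains(s$label, truth$donor[r])
      runs <- rle(mark)
      stop_i <- cumsum(runs$lengths)
      start_i <- stop_i - runs$lengths + 1L
      keep <- which(runs$values)
      if (!length(keep))
        return(data.frame(sample = truth$sample[r], hap = truth$hap[r],
                          start_err = NA_integer_, end_err = NA_integer_))
      ov <- vapply(keep, function(k)
        max(0, min(s$end_bp[stop_i[k]], truth$end_bp[r]) -
              max(s$start_bp[start_i[k]], truth$start_bp[r])), 0)
      if (max(ov) <= 0)
        return(data.frame(sample = truth$sample[r], hap = truth$hap[r],
                          start_err = NA_integer_, end_err = NA_integer_))
      k <- keep[which.max(ov)]
      data.frame(sample = truth$sample[r], hap = truth$hap[r],
                 start_err = abs(s$start_bp[start_i[k]] - truth$start_bp[r]),
                 end_err = abs(s$end_bp[stop_i[k]] - truth$end_bp[r]))
    })
    boundaries <- do.call(rbind, rows)
  }
  list(accuracy = mean(correct), confusion = confusion,
       boundaries = boundaries,
       all_unspecific = all(sl$label == "unspecific"))
}
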