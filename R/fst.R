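#' @name diffscan
#' @title Hudson F_ST: per-site components, sliding windows, outliers
#' @description Pairwise differentiation from called genotypes using the
#'   Hudson estimator in its Bhatia ratio-of-sums form: per-site
#'   numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#'   denominator `p1(1-p2) + p2(1-p1)`, aggregated by summing components
#'   before dividing (never by averaging per-site ratios). Windows are
#'   10 kb with a 5-kb step by default, anchored at position 0 of each
#'   scaffold; outlier windows above 0.5 are merged into maximal
#'   candidate regions.
NULL

#' Per-site Hudson F_ST components
#'
#' @param p1,p2 allele frequencies in the two populations (the estimator
#'   is invariant to which allele is counted, applied consistently).
#' @param n1,n2 called chromosomes (>= 2; sites below are excluded with
#'   a warning by the callers).
#' @return data.frame with `num` and `den`; sites with `den = 0`
#'   (fixed identical alleles) carry no information and are excluded
#'   from ratio-of-sums aggregates.
#' @export
site_fst <- function(p1, n1, p2, n2) {
  .assert(all(n1 >= 2 & n2 >= 2, na.rm = TRUE),
          "site_fst requires at least 2 chromosomes per population")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(num = num, den = den)
}

# assemble the per-site component table for one population pair
.pair_site_table <- function(freqs, pop1, pop2) {
  f1 <- freqs[[pop1]]; f2 <- freqs[[pop2]]
  keep <- !is.na(f1$freq) & !is.na(f2$freq) & f1$n_chrom >= 2 & f2$n_chrom >= 2
  comp <- site_fst(f1$freq[keep], f1$n_chrom[keep],
                   f2$freq[keep], f2$n_chrom[keep])
  data.frame(scaffold = f1$scaffold[keep], pos = f1$pos[keep],
             num = comp$num, den = comp$den, stringsAsFactors = FALSE)
}

#' Sliding-window F_ST (ratio of sums)
#'
#' @param sites data.frame with `scaffold`, `pos` (1-based), `num`,
#'   `den`, sorted by scaffold then position.
#' @param scaffold_lengths named vector of scaffold lengths in bp.
#' @param window,step window size and step in bp.
#' @param min_snps windows with fewer informative SNPs are reported with
#'   `NA` (stabilizes ratios on sparse data).
#' @param comparison optional label attached to every row.
#' @return data.frame of windows: `scaffold`, `start`, `end` (0-based
#'   half-open), `n_snps`, `fst`, `partial` (terminal short window),
#'   `comparison`.
#' @export
windowed_fst <- function(sites, scaffold_lengths, window = 10000, step = 5000,
                         min_snps = 5, comparison = NA_character_) {
  if (step > window) warning("step exceeds window size; gaps between windows")
  out <- list()
  for (scaf in names(scaffold_lengths)) {
    d <- sites[sites$scaffold == scaf, , drop = FALSE]
    if (nrow(d) && is.unsorted(d$pos)) stop("sites must be sorted by position")
    L <- scaffold_lengths[[scaf]]
    starts <- seq(0, max(0, L - 1), by = step)
    starts <- starts[starts < L]
    ends <- pmin(starts + window, L)
    n <- numeric(length(starts)); fs <- numeric(length(starts))
    for (w in seq_along(starts)) {
      # window [start, end) in 0-based bp = positions start+1 .. end 1-based
      sel <- d$pos > starts[w] & d$pos <= ends[w]
      den_sum <- sum(d$den[sel])
      keep <- sel & d$den > 0
      n[w] <- sum(keep)
      fs[w] <- if (n[w] >= min_snps && den_sum > 0)
        sum(d$num[keep]) / sum(d$den[keep]) else NA_real_
    }
    out[[scaf]] <- data.frame(scaffold = scaf, start = starts, end = ends,
                              n_snps = as.integer(n), fst = fs,
                              partial = (ends - starts) < window,
                              comparison = comparison, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge outlier windows into candidate regions
#'
#' Overlapping or abutting windows exceeding the threshold are merged
#' into maximal regions whose bounds are the union of member windows.
#'
#' @param windows data.frame from [windowed_fst()] (one comparison).
#' @param threshold F_ST outlier threshold (0.5 in the scan this
#'   implements).
#' @return data.frame of regions: `scaffold`, `start`, `end`,
#'   `peak_fst`, `n_windows`, `comparison`.
#' @export
merge_outliers <- function(windows, threshold = 0.5) {
  sel <- windows[!is.na(windows$fst) & windows$fst > threshold, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), peak_fst = numeric(0),
                      n_windows = integer(0), comparison = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (scaf in unique(sel$scaffold)) {
    d <- sel[sel$scaffold == scaf, ]
    ir <- IRanges::IRanges(start = d$start + 1, end = d$end)  # 1-based closed
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    peak <- tapply(d$fst[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov), max)
    cnt <- tapply(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov), length)
    out[[scaf]] <- data.frame(
      scaffold = scaf,
      start = IRanges::start(red) - 1, end = IRanges::end(red),
      peak_fst = as.numeric(peak), n_windows = as.integer(cnt),
      comparison = d$comparison[1], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide F_ST point estimate
#'
#' Ratio of summed Hudson components over all retained sites, with
#' scaffold exclusion (the Z is excluded by default in genome-wide
#' estimates because of uneven sex sampling) and optional restriction
#' to a degeneracy class.
#'
#' @param sites per-site component table (`scaffold`, `pos`, `num`, `den`).
#' @param exclude scaffolds to drop.
#' @param class_map optional data.frame (`scaffold`, `pos`, `class`).
#' @param class site class to retain when `class_map` is given.
#' @return scalar F_ST.
#' @export
genome_wide_fst <- function(sites, exclude = character(0),
                            class_map = NULL, class = NULL) {
  d <- sites[!(sites$scaffold %in% exclude), , drop = FALSE]
  if (!is.null(class_map) && !is.null(class)) {
    key <- paste(class_map$scaffold, class_map$pos)[class_map$class == class]
    d <- d[paste(d$scaffold, d$pos) %in% key, , drop = FALSE]
  }
  d <- d[d$den > 0, , drop = FALSE]
  .assert(nrow(d) > 0, "no informative sites retained")
  sum(d$num) / sum(d$den)
}

#' Pairwise F_ST scan over a dataset
#'
#' Convenience driver: polarizes, computes per-site components for each
#' population pair, windows them, and merges outliers.
#'
#' @param ds an `hs_dataset`.
#' @param decisions optional precomputed polarization decisions.
#' @param window,step,threshold scan parameters.
#' @param min_snps minimum informative SNPs per window.
#' @return list with `site_components` (per pair), `windows`,
#'   `outliers`, `genome_wide` (Z excluded), and `pairs`.
#' @export
fst_scan <- function(ds, decisions = NULL, window = 10000, step = 5000,
                     threshold = 0.5, min_snps = 5) {
  freqs <- population_frequencies(ds, decisions)
  pops <- unique(ds$samples$population)
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  lens <- setNames(ds$scaffolds$length, ds$scaffolds$name)
  z_scafs <- ds$scaffolds$name[ds$scaffolds$is_z]
  site_components <- list(); windows <- list(); outliers <- list()
  genome_wide <- list()
  for (pr in pairs) {
    lab <- paste(pr, collapse = "-")
    st <- .pair_site_table(freqs, pr[1], pr[2])
    site_components[[lab]] <- st
    w <- windowed_fst(st, lens, window, step, min_snps, comparison = lab)
    windows[[lab]] <- w
    outliers[[lab]] <- merge_outliers(w, threshold)
    genome_wide[[lab]] <- genome_wide_fst(st, exclude = z_scafs)
  }
  list(site_components = site_components, windows = windows,
       outliers = outliers, genome_wide = genome_wide,
       pairs = vapply(pairs, paste, character(1), collapse = "-"))
}

#' Genotype PCA of sample structure
#'
#' Principal components of the column-centered genotype dosage matrix
#' (samples x sites), excluding the Z by default. Missing dosages are
#' imputed with the site mean; monomorphic sites are dropped. Component
#' signs are fixed by forcing each component's largest-magnitude
#' loading positive, making coordinates deterministic.
#'
#' @param geno dosage matrix (sites x samples).
#' @param sites site table aligned with `geno`.
#' @param exclude scaffolds to drop (e.g. the Z, or an inversion
#'   scaffold for leave-one-out structure checks).
#' @param n_components components to return.
#' @return list with `scores` (samples x components), `sdev`, and
#'   `prop_var`.
#' @export
genotype_pca <- function(geno, sites, exclude = character(0), n_components = 4) {
  keep <- !(sites$scaffold %in% exclude)
  m <- t(geno[keep, , drop = FALSE])
  .assert(nrow(m) >= 2, "need at least 2 samples")
  # impute missing with site means
  for (j in which(colSums(is.na(m)) > 0)) {
    m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  }
  v <- apply(m, 2, stats::var)
  m <- m[, v > 0, drop = FALSE]
  .assert(ncol(m) >= 2, "need at least 2 variable sites")
  k <- min(n_components, nrow(m) - 1, ncol(m))
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  list(scores = scores, sdev = pc$sdev[seq_len(k)],
       prop_var = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2))
}
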