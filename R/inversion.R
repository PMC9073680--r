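#' @name inversion
#' @title Inversion detection and genotyping from allele-frequency tracts
#' @description Loci inside a segregating inversion cannot recombine
#'   with the non-inverted orientation, so they share one derived-allele
#'   frequency across distances far longer than background linkage
#'   allows. The detector finds maximal runs of SNPs dominated by a
#'   single non-trivial lattice frequency k/T (T sampled chromosomes),
#'   genotypes each sample from the fraction of tract-defining alleles
#'   it carries (respecting Z hemizygosity), and checks co-segregation
#'   of focal variants with the inversion.
NULL

#' Detect modal allele-frequency tracts in one population
#'
#' @param freqs data.frame with `scaffold`, `pos` (1-based, sorted) and
#'   `freq` (derived-allele frequency); masked/NA sites are dropped.
#' @param total_chromosomes T, the frequency-lattice denominator
#'   (2 x diploids + hemizygous samples); must be >= 4, below which the
#'   lattice is too coarse to be informative.
#' @param min_span minimum tract span in bp.
#' @param min_modal_fraction minimum fraction of SNPs in the run sharing
#'   the modal frequency.
#' @param min_snps minimum modal SNPs per tract.
#' @param max_gap_snps maximum number of consecutive non-modal SNPs the
#'   run may bridge (defaults to `ceiling(3 / min_modal_fraction)`);
#'   keeps sparse background sites that happen to hit the modal lattice
#'   value from dragging a tract past its true boundary.
#' @param population optional label.
#' @return data.frame of tracts: `scaffold`, `start`, `end` (0-based
#'   half-open), `modal_k`, `modal_freq`, `n_modal`, `n_snps`,
#'   `population`; non-overlapping, preferring tracts with more modal
#'   SNPs.
#' @export
detect_tracts <- function(freqs, total_chromosomes, min_span = 1e5,
                          min_modal_fraction = 0.6, min_snps = 10,
                          max_gap_snps = NULL, population = NA_character_) {
  if (is.null(max_gap_snps)) max_gap_snps <- ceiling(3 / min_modal_fraction)
  T <- as.integer(total_chromosomes)
  if (T < 4) stop("total chromosomes < 4: frequency lattice too coarse to scan")
  d <- freqs[!is.na(freqs$freq), , drop = FALSE]
  d$k <- as.integer(round(d$freq * T))
  d <- d[d$k > 0 & d$k < T, , drop = FALSE]   # fixed classes carry no signal
  out <- list()
  for (scaf in unique(d$scaffold)) {
    s <- d[d$scaffold == scaf, , drop = FALSE]
    s <- s[order(s$pos), ]
    cand <- list()
    for (k in unique(s$k)) {
      idx <- which(s$k == k)
      if (length(idx) < min_snps) next
      # greedy chaining: extend a run over the next modal site only while
      # the modal fraction within the enclosing site interval holds
      run_start <- idx[1]; last <- idx[1]; n_modal <- 1L
      close_run <- function(run_start, last, n_modal) {
        span <- s$pos[last] - s$pos[run_start]
        n_tot <- last - run_start + 1L
        if (span >= min_span && n_modal >= min_snps &&
            n_modal / n_tot >= min_modal_fraction) {
          data.frame(scaffold = scaf, start = s$pos[run_start] - 1,
                     end = s$pos[last], modal_k = k, modal_freq = k / T,
                     n_modal = n_modal, n_snps = n_tot,
                     population = population, stringsAsFactors = FALSE)
        } else NULL
      }
      for (j in idx[-1]) {
        if (j - last - 1L <= max_gap_snps &&
            (n_modal + 1L) / (j - run_start + 1L) >= min_modal_fraction) {
          last <- j; n_modal <- n_modal + 1L
        } else {
          cand[[length(cand) + 1L]] <- close_run(run_start, last, n_modal)
          run_start <- j; last <- j; n_modal <- 1L
        }
      }
      cand[[length(cand) + 1L]] <- close_run(run_start, last, n_modal)
    }
    cand <- do.call(rbind, Filter(Negate(is.null), cand))
    if (is.null(cand) || nrow(cand) == 0) next
    # resolve overlaps: keep tracts with the most modal SNPs
    cand <- cand[order(-cand$n_modal), ]
    kept <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      clash <- kept & (cand$start < cand$end[i]) & (cand$end > cand$start[i])
      if (!any(clash)) kept[i] <- TRUE
    }
    out[[scaf]] <- cand[kept, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), modal_k = integer(0),
                      modal_freq = numeric(0), n_modal = integer(0),
                      n_snps = integer(0), population = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[order(res$scaffold, res$start), , drop = FALSE]
}

#' Genotype samples for an inversion tract
#'
#' Each sample's fraction of tract-defining derived alleles carried
#' (over its called tract SNPs and ploidy) maps to a genotype class:
#' below 0.25 homozygous ancestral, 0.25-0.75 heterozygous, above 0.75
#' homozygous inverted; hemizygous samples (one Z) are carrier /
#' non-carrier at 0.5. Samples missing more than half the tract SNPs
#' are `unknown` and excluded from the frequency.
#'
#' @param tract one tract row from [detect_tracts()].
#' @param freqs the same population frequency table the tract was
#'   detected from (identifies tract-defining SNPs: sites in the span at
#'   the modal lattice value).
#' @param derived derived-allele dosage matrix aligned with `sites`.
#' @param sites site table (`scaffold`, `pos`).
#' @param ploidy per-sample ploidy vector on the tract's scaffold.
#' @return an `inversion_call`: list with `tract`, `genotype` (named
#'   character), `carrier_chromosomes` (named integer), `carriers`,
#'   `total`, `frequency`.
#' @export
genotype_samples <- function(tract, freqs, derived, sites, ploidy) {
  T <- round(tract$modal_k / tract$modal_freq)
  in_span <- freqs$scaffold == tract$scaffold &
    freqs$pos > tract$start & freqs$pos <= tract$end & !is.na(freqs$freq)
  def <- in_span & as.integer(round(freqs$freq * T)) == tract$modal_k
  .assert(any(def), "tract has no defining SNPs")
  key_def <- paste(freqs$scaffold[def], freqs$pos[def])
  rows <- match(key_def, paste(sites$scaffold, sites$pos))
  m <- derived[rows, , drop = FALSE]
  n_sites <- nrow(m)
  genotype <- character(ncol(m)); carriers_chr <- integer(ncol(m))
  names(genotype) <- names(carriers_chr) <- colnames(m)
  for (s in seq_len(ncol(m))) {
    called <- !is.na(m[, s])
    if (sum(called) < n_sites / 2) {
      genotype[s] <- "unknown"; carriers_chr[s] <- NA_integer_
      next
    }
    frac <- sum(m[called, s]) / (sum(called) * ploidy[s])
    if (ploidy[s] == 1L) {
      genotype[s] <- if (frac > 0.5) "carrier" else "non_carrier"
      carriers_chr[s] <- as.integer(frac > 0.5)
    } else {
      genotype[s] <- if (frac > 0.75) "hom_inverted"
        else if (frac >= 0.25) "het" else "hom_ancestral"
      carriers_chr[s] <- c(hom_ancestral = 0L, het = 1L, hom_inverted = 2L)[genotype[s]]
    }
  }
  ok <- genotype != "unknown"
  carriers <- sum(carriers_chr[ok])
  total <- sum(ploidy[ok])
  structure(list(tract = tract, genotype = genotype,
                 carrier_chromosomes = carriers_chr,
                 carriers = carriers, total = total,
                 frequency = carriers / total),
            class = "inversion_call")
}

#' @export
print.inversion_call <- function(x, ...) {
  cat(sprintf("<inversion_call> %s:[%d,%d) modal %s\n", x$tract$scaffold,
              x$tract$start, x$tract$end,
              format_fraction(x$tract$modal_k,
                              round(x$tract$modal_k / x$tract$modal_freq))))
  tb <- table(factor(x$genotype, levels = c("hom_inverted", "het",
                                            "hom_ancestral", "carrier",
                                            "non_carrier", "unknown")))
  cat("  genotypes:", paste(sprintf("%s=%d", names(tb)[tb > 0], tb[tb > 0]),
                            collapse = ", "), "\n")
  cat("  frequency:", format_fraction(x$carriers, x$total), "\n")
  invisible(x)
}

#' Carrier-state concordance between an inversion and a focal variant
#'
#' Fraction of genotyped samples whose variant carrier state (derived
#' dosage) matches their inversion genotype; 1.0 means perfect
#' co-segregation (the pseudogene stop-loss pattern).
#'
#' @param call an `inversion_call`.
#' @param variant_dosage named derived-allele dosage vector at one site.
#' @param ploidy named per-sample ploidy vector.
#' @return fraction in `[0, 1]`.
#' @export
concordance <- function(call, variant_dosage, ploidy) {
  common <- intersect(names(call$genotype)[call$genotype != "unknown"],
                      names(variant_dosage)[!is.na(variant_dosage)])
  .assert(length(common) > 0, "no overlapping genotyped samples")
  inv_carr <- call$carrier_chromosomes[common]
  var_carr <- as.integer(variant_dosage[common])
  mean(inv_carr == var_carr)
}

#' Windowed linkage-disequilibrium (r^2) profile
#'
#' Mean squared genotype-dosage correlation over SNP pairs within
#' nonoverlapping windows. Monomorphic SNPs are skipped; windows with
#' no pair are reported missing. Inside an inversion the profile is
#' elevated in every population, carrier or not.
#'
#' @param geno dosage matrix (sites x samples) for the samples of one
#'   population.
#' @param sites aligned site table (one scaffold).
#' @param window window size in bp (50-bp nonoverlapping windows in the
#'   scan this mirrors).
#' @return data.frame: `start`, `end`, `n_snps`, `n_pairs`, `mean_r2`.
#' @export
tract_ld_profile <- function(geno, sites, window = 50) {
  .assert(length(unique(sites$scaffold)) == 1, "one scaffold at a time")
  L <- max(sites$pos)
  starts <- seq(0, L - 1, by = window)
  out <- data.frame(start = starts, end = pmin(starts + window, L),
                    n_snps = 0L, n_pairs = 0L, mean_r2 = NA_real_)
  for (w in seq_along(starts)) {
    sel <- which(sites$pos > out$start[w] & sites$pos <= out$end[w])
    if (length(sel) < 2) { out$n_snps[w] <- length(sel); next }
    g <- geno[sel, , drop = FALSE]
    v <- apply(g, 1, stats::var, na.rm = TRUE)
    g <- g[!is.na(v) & v > 0, , drop = FALSE]
    out$n_snps[w] <- nrow(g)
    if (nrow(g) < 2) next
    cc <- suppressWarnings(cor(t(g), use = "pairwise.complete.obs"))
    r2 <- cc[upper.tri(cc)]^2
    r2 <- r2[!is.na(r2)]
    out$n_pairs[w] <- length(r2)
    if (length(r2)) out$mean_r2[w] <- mean(r2)
  }
  out
}
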