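#' @name polarize
#' @title Ancestral-allele polarization by outgroup parsimony
#' @description Infers the ancestral allele at each focal polymorphic
#'   site from congener (outgroup) variation. Four parsimony rules:
#'   (1) outgroup invariant at the site -> the reference allele is
#'   ancestral; (2) an outgroup alternate allele matches the focal
#'   alternate -> the alternate is ancestral (the reference is derived);
#'   (3) a heterozygous outgroup carrying an allele outside the focal
#'   set but sharing exactly one allele with it -> the shared allele is
#'   ancestral; (4) no shared resolution -> the site is masked to N and
#'   dropped from polarized analyses. Without polarization, frequencies
#'   collapse onto [0, 0.5] and derived-allele information is lost.
NULL

#' Classify one site's ancestral allele
#'
#' @param focal list or one-row data.frame with `scaffold`, `pos`,
#'   `ref`, and `alt` (character vector; multi-allelic records are
#'   decomposed per alternate and masked on disagreement).
#' @param outgroup `NULL` when the outgroup is invariant at the site,
#'   else a list with `alleles`: the alleles observed in the outgroup
#'   genotype (reference included if carried).
#' @return a `polarization_decision`: list with `scaffold`, `pos`,
#'   `ref`, `alt`, `outgroup_alleles`, `verdict` (one of
#'   `reference_ancestral`, `alternate_ancestral`,
#'   `shared_allele_ancestral`, `masked`) and `ancestral` (base, or "N"
#'   iff masked).
#' @export
classify_site <- function(focal, outgroup = NULL) {
  ref <- as.character(focal$ref)
  alts <- unlist(strsplit(as.character(focal$alt), ",", fixed = TRUE))
  .assert(length(alts) >= 1 && !any(alts == ref), "focal site must be polymorphic")
  if (!is.null(outgroup) && !is.null(outgroup$pos)) {
    .assert(identical(as.integer(outgroup$pos), as.integer(focal$pos)) &&
              identical(as.character(outgroup$scaffold %||% focal$scaffold),
                        as.character(focal$scaffold)),
            "focal/outgroup coordinates do not match")
  }
  og <- unique(as.character(outgroup$alleles %||% character(0)))

  decide_one <- function(alt) {
    focal_set <- c(ref, alt)
    if (length(og) == 0 || identical(og, ref)) {
      return(list(verdict = "reference_ancestral", ancestral = ref))
    }
    outside <- setdiff(og, focal_set)
    shared <- intersect(og, focal_set)
    if (length(outside) == 0 && alt %in% og) {
      # outgroup alleles all within the focal set and the alternate is
      # carried: the alternate is ancestral (homozygous-alt outgroups
      # folded in with heterozygous ref/alt ones)
      return(list(verdict = "alternate_ancestral", ancestral = alt))
    }
    if (length(og) >= 2 && length(shared) == 1) {
      # heterozygous outgroup sharing exactly one allele (e.g. focal
      # T->C with outgroup G/C: C is ancestral)
      return(list(verdict = "shared_allele_ancestral", ancestral = shared))
    }
    list(verdict = "masked", ancestral = "N")
  }

  per_alt <- lapply(alts, decide_one)
  anc <- unique(vapply(per_alt, `[[`, character(1), "ancestral"))
  if (length(anc) > 1) {
    verdict <- "masked"; ancestral <- "N"
  } else {
    verdict <- per_alt[[1]]$verdict; ancestral <- anc
  }
  structure(list(scaffold = as.character(focal$scaffold),
                 pos = as.integer(focal$pos), ref = ref, alt = alts,
                 outgroup_alleles = og, verdict = verdict,
                 ancestral = ancestral),
            class = "polarization_decision")
}

# outgroup table row -> allele set implied by its GT string
.outgroup_alleles <- function(ref, alt, gt) {
  alleles <- c(ref, unlist(strsplit(alt, ",", fixed = TRUE)))
  idx <- suppressWarnings(as.integer(unlist(strsplit(gt, "[/|]")))) + 1L
  idx <- idx[!is.na(idx)]
  unique(alleles[idx])
}

#' Polarize a table of focal sites against outgroup records
#'
#' Vectorized driver for [classify_site()].
#'
#' @param sites data.frame with `scaffold`, `pos`, `ref`, `alt`.
#' @param outgroup data.frame with `scaffold`, `pos`, `ref`, `alt`
#'   (comma-separated) and `gt`; sites absent from it are treated as
#'   outgroup-invariant.
#' @return data.frame of decisions: `scaffold`, `pos`, `ref`, `alt`,
#'   `verdict`, `ancestral`.
#' @export
polarize_sites <- function(sites, outgroup = NULL) {
  key_f <- paste(sites$scaffold, sites$pos)
  m <- if (is.null(outgroup) || nrow(outgroup) == 0) rep(NA_integer_, nrow(sites))
       else match(key_f, paste(outgroup$scaffold, outgroup$pos))
  verdict <- character(nrow(sites)); ancestral <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    og <- NULL
    if (!is.na(m[i])) {
      r <- outgroup[m[i], ]
      og <- list(alleles = .outgroup_alleles(r$ref, r$alt, r$gt))
    }
    d <- classify_site(sites[i, ], og)
    verdict[i] <- d$verdict; ancestral[i] <- d$ancestral
  }
  data.frame(scaffold = sites$scaffold, pos = sites$pos, ref = sites$ref,
             alt = sites$alt, verdict = verdict, ancestral = ancestral,
             stringsAsFactors = FALSE)
}

#' Build the ancestral reference sequence
#'
#' Substitutes the inferred ancestral base where the alternate (or a
#' shared tri-allelic allele) is ancestral, masks unresolvable sites to
#' N, and leaves reference-ancestral sites untouched.
#'
#' @param ref [Biostrings::DNAStringSet].
#' @param decisions data.frame from [polarize_sites()].
#' @return list with `ancestral` (DNAStringSet) and `counts`
#'   (`unchanged`, `updated`, `masked`; they sum to `nrow(decisions)`).
#' @export
build_ancestral_reference <- function(ref, decisions) {
  seqs <- lapply(names(ref), function(s) .scaffold_bases(ref, s))
  names(seqs) <- names(ref)
  updated <- 0L; masked <- 0L
  for (i in seq_len(nrow(decisions))) {
    d <- decisions[i, ]
    .assert(d$scaffold %in% names(seqs), "decision on unknown scaffold")
    .assert(d$pos >= 1 && d$pos <= length(seqs[[d$scaffold]]),
            "decision position out of scaffold bounds")
    if (d$verdict == "masked") {
      seqs[[d$scaffold]][d$pos] <- "N"
      masked <- masked + 1L
    } else if (d$verdict %in% c("alternate_ancestral", "shared_allele_ancestral")) {
      .assert(d$ancestral != "N", "non-masked verdict with ancestral N")
      seqs[[d$scaffold]][d$pos] <- d$ancestral
      updated <- updated + 1L
    }
  }
  anc <- Biostrings::DNAStringSet(vapply(seqs, paste0, character(1), collapse = ""))
  names(anc) <- names(ref)
  list(ancestral = anc,
       counts = list(unchanged = nrow(decisions) - updated - masked,
                     updated = updated, masked = masked))
}

#' Derived-allele frequency at a polarized site
#'
#' @param alt_count observed alternate-allele count.
#' @param n_chrom called chromosomes at the site.
#' @param decision one decision row (or `polarization_decision`).
#' @return derived-allele frequency in `[0, 1]`, or `NA` for masked
#'   sites (excluded downstream) and for sites with no called
#'   chromosomes (flagged by warning).
#' @examples
#' d <- list(verdict = "reference_ancestral", ref = "T", alt = "C", ancestral = "T")
#' polarized_frequency(11, 16, d)  # 0.6875
#' @export
polarized_frequency <- function(alt_count, n_chrom, decision) {
  if (decision$verdict == "masked") return(NA_real_)
  if (n_chrom == 0) {
    warning("no called chromosomes at site; frequency undefined")
    return(NA_real_)
  }
  p_alt <- alt_count / n_chrom
  if (decision$ancestral == decision$ref) p_alt else 1 - p_alt
}

#' Derived-allele dosage matrix under a set of polarization decisions
#'
#' Flips ALT dosages at sites where the alternate (or shared) allele is
#' ancestral, and sets masked sites to `NA` so they drop out of every
#' downstream statistic.
#'
#' @param geno ALT dosage matrix (sites x samples).
#' @param decisions data.frame aligned row-by-row with `geno`.
#' @param ploidy ploidy matrix of the same shape (see [ploidy_matrix()]).
#' @return derived-allele dosage matrix.
#' @export
derived_dosage <- function(geno, decisions, ploidy) {
  .assert(nrow(geno) == nrow(decisions), "geno/decisions row mismatch")
  out <- geno
  flip <- decisions$verdict %in% c("alternate_ancestral", "shared_allele_ancestral")
  out[flip, ] <- ploidy[flip, , drop = FALSE] - geno[flip, , drop = FALSE]
  out[decisions$verdict == "masked", ] <- NA_integer_
  out
}

#' Per-population derived-allele frequencies
#'
#' Complete-case frequencies: per site and population, the derived
#' dosage summed over called samples divided by their summed ploidy.
#'
#' @param ds an `hs_dataset`.
#' @param decisions decisions aligned with `ds$sites` (defaults to
#'   polarizing against the dataset's own outgroup records).
#' @return list per population: data.frame `scaffold`, `pos`, `freq`,
#'   `n_chrom` (masked sites carry `NA` freq).
#' @export
population_frequencies <- function(ds, decisions = NULL) {
  if (is.null(decisions)) decisions <- polarize_sites(ds$sites, ds$outgroup)
  pl <- ploidy_matrix(ds)
  dd <- derived_dosage(ds$geno, decisions, pl)
  out <- list()
  for (pn in unique(ds$samples$population)) {
    cols <- which(ds$samples$population == pn)
    sub <- dd[, cols, drop = FALSE]
    pls <- pl[, cols, drop = FALSE]
    pls[is.na(sub)] <- 0L
    n_chrom <- rowSums(pls)
    freq <- rowSums(sub, na.rm = TRUE) / ifelse(n_chrom == 0, NA, n_chrom)
    freq[decisions$verdict == "masked"] <- NA_real_
    out[[pn]] <- data.frame(scaffold = ds$sites$scaffold, pos = ds$sites$pos,
                            freq = freq, n_chrom = n_chrom,
                            stringsAsFactors = FALSE)
  }
  out
}
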