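#' @name anchoring
#' @title Synteny-vote chromosome anchoring of assembly scaffolds
#' @description Assigns unanchored scaffolds of a new assembly to
#'   chromosomes by tabulating syntenic alignments against an older,
#'   anchored assembly and taking the highest-scoring chromosome. Votes
#'   are weighted by aligned bases (scaffold counts are reported
#'   alongside for audit); near-ties are flagged, and spatially
#'   partitioned two-chromosome patterns (the fusion/chimera signature)
#'   are flagged `split_synteny` rather than discarded. Manual overrides
#'   (e.g. external BAC-FISH evidence) are applied with provenance.
NULL

#' Tabulate synteny votes
#'
#' @param alignments data.frame with `old_scaffold`, `old_chrom`,
#'   `new_scaffold`, `new_start`, `new_end` (0-based half-open on the
#'   new scaffold).
#' @return data.frame of votes: `new_scaffold`, `chrom`,
#'   `aligned_bases`, `n_old_scaffolds`, plus the contributing interval
#'   list in attribute-free long form via `intervals`.
#' @export
tabulate_votes <- function(alignments) {
  if (nrow(alignments) == 0) {
    return(list(votes = data.frame(new_scaffold = character(0),
                                   chrom = character(0),
                                   aligned_bases = numeric(0),
                                   n_old_scaffolds = integer(0),
                                   stringsAsFactors = FALSE),
                intervals = alignments))
  }
  .assert(all(alignments$new_end > alignments$new_start),
          "alignment intervals must have positive width")
  key <- paste(alignments$new_scaffold, alignments$old_chrom, sep = "\r")
  bases <- tapply(alignments$new_end - alignments$new_start, key, sum)
  scafs <- tapply(alignments$old_scaffold, key, function(x) length(unique(x)))
  parts <- do.call(rbind, strsplit(names(bases), "\r", fixed = TRUE))
  votes <- data.frame(new_scaffold = parts[, 1], chrom = parts[, 2],
                      aligned_bases = as.numeric(bases),
                      n_old_scaffolds = as.integer(scafs),
                      stringsAsFactors = FALSE)
  votes <- votes[order(votes$new_scaffold, -votes$aligned_bases), ]
  rownames(votes) <- NULL
  list(votes = votes, intervals = alignments)
}

# Minimal interleaving fraction when splitting two chromosomes' aligned
# intervals at a single point on the new scaffold: the fraction of
# aligned bases on the "wrong" side under the better orientation.
.interleaving_fraction <- function(intervals, chrom_a, chrom_b) {
  d <- intervals[intervals$old_chrom %in% c(chrom_a, chrom_b), ]
  cuts <- sort(unique(c(d$new_start, d$new_end)))
  total <- sum(d$new_end - d$new_start)
  best <- Inf
  for (s in cuts) {
    left <- pmax(0, pmin(d$new_end, s) - d$new_start)
    right <- (d$new_end - d$new_start) - left
    a <- d$old_chrom == chrom_a
    mis1 <- sum(right[a]) + sum(left[!a])   # A left of cut, B right
    mis2 <- sum(left[a]) + sum(right[!a])   # mirrored
    best <- min(best, mis1, mis2)
  }
  best / total
}

#' Assign scaffolds to chromosomes from votes
#'
#' Argmax by aligned bases. A runner-up within `ambiguity_ratio` of the
#' top vote flags the call: `split_synteny` when the two chromosomes'
#' intervals partition the scaffold spatially (interleaving fraction
#' below 0.1 — a fusion or chimera), otherwise the scaffold is
#' `ambiguous`. Exact ties are ambiguous; scaffolds under `min_bases`
#' are unassigned.
#'
#' @param votes result of [tabulate_votes()].
#' @param ambiguity_ratio runner-up/top vote ratio above which a call
#'   is flagged.
#' @param min_bases minimum top-vote aligned bases for any assignment.
#' @param interleaving_threshold spatial-partition test threshold.
#' @return data.frame: `new_scaffold`, `chromosome` (or `"ambiguous"` /
#'   `"unassigned"`), `confidence` (top vote / total votes), `flags`.
#' @export
assign_chromosomes <- function(votes, ambiguity_ratio = 0.2, min_bases = 10000,
                               interleaving_threshold = 0.1) {
  v <- votes$votes
  out <- list()
  for (scaf in unique(v$new_scaffold)) {
    d <- v[v$new_scaffold == scaf, ]
    d <- d[order(-d$aligned_bases), ]
    top <- d[1, ]
    conf <- top$aligned_bases / sum(d$aligned_bases)
    flags <- character(0)
    chrom <- top$chrom
    if (top$aligned_bases < min_bases) {
      chrom <- "unassigned"
    } else if (nrow(d) > 1) {
      runner <- d[2, ]
      if (runner$aligned_bases == top$aligned_bases) {
        chrom <- "ambiguous"
      } else if (runner$aligned_bases / top$aligned_bases > ambiguity_ratio) {
        inter <- .interleaving_fraction(votes$intervals, top$chrom, runner$chrom)
        if (inter <= interleaving_threshold) {
          flags <- "split_synteny"
        } else {
          chrom <- "ambiguous"
        }
      }
    }
    out[[scaf]] <- data.frame(new_scaffold = scaf, chromosome = chrom,
                              confidence = conf,
                              flags = paste(flags, collapse = ";"),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply manual chromosome-assignment overrides
#'
#' @param assignments data.frame from [assign_chromosomes()].
#' @param overrides data.frame with `new_scaffold`, `chromosome`,
#'   `reason`.
#' @return assignments with overridden rows flagged `manual_override`;
#'   the pre-override call is preserved in `previous`.
#' @export
apply_overrides <- function(assignments, overrides) {
  assignments$previous <- NA_character_
  if (is.null(overrides) || nrow(overrides) == 0) return(assignments)
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    j <- match(o$new_scaffold, assignments$new_scaffold)
    if (is.na(j)) {
      warning(sprintf("override for unknown scaffold '%s' ignored",
                      o$new_scaffold))
      next
    }
    assignments$previous[j] <- assignments$chromosome[j]
    assignments$chromosome[j] <- o$chromosome
    fl <- setdiff(strsplit(assignments$flags[j], ";")[[1]], "")
    assignments$flags[j] <- paste(c(fl, "manual_override"), collapse = ";")
  }
  assignments
}
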