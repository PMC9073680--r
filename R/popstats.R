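#' @name popstats
#' @title Coding-site degeneracy, variant effects, and diversity statistics
#' @description Classification of 0-fold/4-fold degenerate coding sites
#'   from gene models, a minimal variant-effect annotator (synonymous /
#'   missense / stop gain / stop loss), per-gene pN and pS with
#'   population medians, and nucleotide diversity with Tajima's D.
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_translate <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

#' Degeneracy class of every position of every codon
#'
#' For each of the 64 codons and each within-codon offset, a position is
#' `four_fold` if all four nucleotides encode the same amino acid,
#' `zero_fold` if every substitution changes it, and `other` otherwise
#' (stop codons are treated as a 21st "amino acid").
#'
#' @return 64 x 3 character matrix, rownames are codons.
#' @export
codon_degeneracy_table <- function() {
  nts <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE)[, 3:1],
                  1, paste0, collapse = "")
  out <- matrix("other", nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  for (cod in codons) {
    aa <- .codon_translate(cod)
    for (off in 1:3) {
      variants <- vapply(nts, function(n) {
        x <- strsplit(cod, "")[[1]]; x[off] <- n; paste0(x, collapse = "")
      }, character(1))
      aas <- .codon_translate(variants)
      alt_aas <- aas[variants != cod]
      if (all(aas == aa)) out[cod, off] <- "four_fold"
      else if (all(alt_aas != aa)) out[cod, off] <- "zero_fold"
    }
  }
  out
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
  paste(rev(.COMP[strsplit(x, "")[[1]]]), collapse = "")
}

# Genomic positions of a gene's CDS in coding (5'->3') order.
# `cds` rows for one gene, exon_rank in coding order; coordinates
# 1-based inclusive.
cds_positions <- function(cds_gene) {
  cds_gene <- cds_gene[order(cds_gene$exon_rank), , drop = FALSE]
  unlist(lapply(seq_len(nrow(cds_gene)), function(i) {
    if (cds_gene$strand[i] == "+") seq(cds_gene$start[i], cds_gene$end[i])
    else seq(cds_gene$end[i], cds_gene$start[i])
  }), use.names = FALSE)
}

.scaffold_bases <- function(ref, scaf) {
  strsplit(as.character(ref[[scaf]]), "")[[1]]
}

#' Classify 0-fold and 4-fold degenerate sites
#'
#' Walks every gene's CDS (exons joined in coding order, strand
#' respected) and assigns each genomic position a degeneracy class from
#' the standard nuclear codon table. Genes whose joined CDS is not a
#' multiple of 3, lacks a terminal stop, or contains an internal stop
#' are flagged and excluded. Positions covered by several genes with
#' conflicting classes are demoted to `other` in the genome-level map.
#'
#' @param genes gene-model list with data.frames `genes` and `cds`
#'   (1-based inclusive coordinates, `exon_rank` in coding order).
#' @param ref reference [Biostrings::DNAStringSet].
#' @return object of class `degeneracy_map`: `by_gene` per-position
#'   data.frame, `genome` deduplicated map, `site_counts` per-gene 0-fold
#'   and 4-fold totals, `excluded` gene ids.
#' @export
classify_degeneracy <- function(genes, ref) {
  tab <- codon_degeneracy_table()
  per_gene <- list()
  excluded <- character(0)
  base_cache <- list()
  for (gid in genes$genes$gene_id) {
    cg <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    scaf <- cg$scaffold[1]
    if (is.null(base_cache[[scaf]])) base_cache[[scaf]] <- .scaffold_bases(ref, scaf)
    bases <- base_cache[[scaf]]
    pos <- cds_positions(cg)
    seqv <- bases[pos]
    if (cg$strand[1] == "-") seqv <- unname(.COMP[seqv])
    n <- length(seqv)
    if (n %% 3 != 0) { excluded <- c(excluded, gid); next }
    codons <- vapply(seq_len(n / 3), function(i)
      paste0(seqv[(3 * i - 2):(3 * i)], collapse = ""), character(1))
    aas <- .codon_translate(codons)
    if (aas[length(aas)] != "*" || any(aas[-length(aas)] == "*")) {
      excluded <- c(excluded, gid); next
    }
    cls <- tab[cbind(match(rep(codons, each = 3), rownames(tab)),
                     rep(1:3, length(codons)))]
    per_gene[[gid]] <- data.frame(
      gene_id = gid, scaffold = scaf, pos = pos,
      cds_pos = seq_len(n), strand = cg$strand[1],
      codon = rep(codons, each = 3), codon_offset = rep(1:3, length(codons)),
      class = cls, stringsAsFactors = FALSE)
  }
  by_gene <- if (length(per_gene)) do.call(rbind, per_gene) else
    data.frame(gene_id = character(0), scaffold = character(0),
               pos = integer(0), cds_pos = integer(0), strand = character(0),
               codon = character(0), codon_offset = integer(0),
               class = character(0))
  rownames(by_gene) <- NULL
  # genome-level map: conflicting classes at shared positions -> other
  key <- paste(by_gene$scaffold, by_gene$pos)
  cls_by_key <- tapply(by_gene$class, key, function(x)
    if (length(unique(x)) == 1) x[1] else "other")
  first <- !duplicated(key)
  genome <- data.frame(scaffold = by_gene$scaffold[first],
                       pos = by_gene$pos[first],
                       class = unname(cls_by_key[key[first]]),
                       stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(split(by_gene, by_gene$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1],
               zero_fold = sum(d$class == "zero_fold"),
               four_fold = sum(d$class == "four_fold"),
               stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  structure(list(by_gene = by_gene, genome = genome,
                 site_counts = counts, excluded = excluded),
            class = "degeneracy_map")
}

#' Annotate the coding effect of SNPs
#'
#' Resolves each SNP against the gene models: substitutions within a CDS
#' are classified from the codon change (`synonymous`, `missense`,
#' `stop_gain`, or `stop_loss` when a canonical stop codon becomes a
#' sense codon); positions inside a gene span but outside its CDS, or
#' outside all genes, are `non_coding`.
#'
#' @param sites data.frame with `scaffold`, `pos` (1-based), `ref`, `alt`.
#' @param genes gene-model list (see [classify_degeneracy()]).
#' @param ref reference [Biostrings::DNAStringSet].
#' @return data.frame, one row per (site, overlapping gene): columns
#'   `scaffold`, `pos`, `ref`, `alt`, `gene_id`, `effect`,
#'   `codon_ref`, `codon_alt`.
#' @export
annotate_effect <- function(sites, genes, ref) {
  deg <- classify_degeneracy(genes, ref)
  bg <- deg$by_gene
  key_sites <- paste(sites$scaffold, sites$pos)
  key_cds <- paste(bg$scaffold, bg$pos)
  uk <- unique(key_cds)
  idx_by_key <- split(seq_along(key_cds), factor(key_cds, levels = uk))
  site_slot <- match(key_sites, uk)
  out <- vector("list", nrow(sites))
  gene_span <- genes$genes
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    hits <- if (is.na(site_slot[i])) integer(0) else idx_by_key[[site_slot[i]]]
    if (length(hits) == 0) {
      g <- gene_span[gene_span$scaffold == s$scaffold &
                     gene_span$start <= s$pos & gene_span$end >= s$pos, ]
      out[[i]] <- data.frame(scaffold = s$scaffold, pos = s$pos, ref = s$ref,
                             alt = s$alt,
                             gene_id = if (nrow(g)) g$gene_id[1] else NA_character_,
                             effect = "non_coding",
                             codon_ref = NA_character_, codon_alt = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    rows <- lapply(hits, function(h) {
      b <- bg[h, ]
      ref_c <- b$codon
      sub_base <- if (b$strand == "+") s$alt else unname(.COMP[s$alt])
      alt_chars <- strsplit(ref_c, "")[[1]]
      alt_chars[b$codon_offset] <- sub_base
      alt_c <- paste0(alt_chars, collapse = "")
      ref_stop <- ref_c %in% .STOP_CODONS
      alt_stop <- alt_c %in% .STOP_CODONS
      effect <- if (ref_stop && !alt_stop) "stop_loss"
        else if (!ref_stop && alt_stop) "stop_gain"
        else if (.codon_translate(ref_c) == .codon_translate(alt_c)) "synonymous"
        else "missense"
      data.frame(scaffold = s$scaffold, pos = s$pos, ref = s$ref, alt = s$alt,
                 gene_id = b$gene_id, effect = effect,
                 codon_ref = ref_c, codon_alt = alt_c, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene pN and pS with population medians
#'
#' pN is the count of nonsynonymous segregating SNPs (missense, stop
#' gain, stop loss) per 0-fold degenerate site of the gene; pS the count
#' of synonymous SNPs per 4-fold site. Medians across genes are reported
#' (robust to outlier genes); per-gene pN/pS is defined only where
#' pS > 0.
#'
#' @param effects data.frame from [annotate_effect()] restricted to SNPs
#'   segregating in the population of interest.
#' @param degeneracy a `degeneracy_map` from [classify_degeneracy()].
#' @return list with `per_gene` data.frame and `medians` (pN, pS, pNpS).
#' @export
gene_polymorphism <- function(effects, degeneracy) {
  counts <- degeneracy$site_counts
  nonsyn <- c("missense", "stop_gain", "stop_loss")
  per_gene <- counts
  per_gene$n_nonsyn <- vapply(per_gene$gene_id, function(g)
    sum(effects$gene_id == g & effects$effect %in% nonsyn, na.rm = TRUE), numeric(1))
  per_gene$n_syn <- vapply(per_gene$gene_id, function(g)
    sum(effects$gene_id == g & effects$effect == "synonymous", na.rm = TRUE),
    numeric(1))
  per_gene$pN <- ifelse(per_gene$zero_fold > 0,
                        per_gene$n_nonsyn / per_gene$zero_fold, NA_real_)
  per_gene$pS <- ifelse(per_gene$four_fold > 0,
                        per_gene$n_syn / per_gene$four_fold, NA_real_)
  per_gene$pNpS <- ifelse(!is.na(per_gene$pS) & per_gene$pS > 0,
                          per_gene$pN / per_gene$pS, NA_real_)
  medians <- list(pN = median(per_gene$pN, na.rm = TRUE),
                  pS = median(per_gene$pS, na.rm = TRUE),
                  pNpS = median(per_gene$pNpS, na.rm = TRUE))
  list(per_gene = per_gene, medians = medians)
}

# Standard Tajima (1989) normalizing constants for n sampled chromosomes
tajima_constants <- function(n) {
  stopifnot(n >= 4)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Nucleotide diversity and Tajima's D for one site class
#'
#' Computes pairwise diversity from derived (or minor; the statistic is
#' symmetric) allele counts at segregating sites, the number of
#' segregating sites S, and Tajima's D with the standard normalizing
#' constants. Per-site heterozygosity uses the unbiased factor
#' `n/(n-1)`: a site at frequency p contributes `2p(1-p) n/(n-1)`.
#'
#' @param k integer vector of derived-allele counts at segregating sites
#'   (0 < k < n); monomorphic sites contribute only through `n_sites`.
#' @param n number of sampled chromosomes (>= 4).
#' @param n_sites total sites of the class surveyed (denominator for the
#'   per-site pi); defaults to `length(k)`.
#' @return list with `pi` (per site), `pi_sum`, `S`, `D`, and
#'   `D_defined` (FALSE when S = 0, where D is reported as 0).
#' @export
pi_and_tajimas_d <- function(k, n, n_sites = length(k)) {
  if (n < 4) stop("n < 4: variance terms of Tajima's D are unstable")
  k <- k[k > 0 & k < n]
  S <- length(k)
  p <- k / n
  pi_sum <- sum(2 * p * (1 - p) * n / (n - 1))
  if (S == 0) {
    return(list(pi = 0, pi_sum = 0, S = 0L, D = 0, D_defined = FALSE))
  }
  cst <- tajima_constants(n)
  D <- (pi_sum - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  list(pi = pi_sum / max(n_sites, 1L), pi_sum = pi_sum, S = S,
       D = D, D_defined = TRUE)
}
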