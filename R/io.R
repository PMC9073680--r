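#' @name io
#' @title Fixture-bundle input/output
#' @description Writers and readers for the standard interchange formats
#'   the analysis chain consumes: VCF 4.2 (diploid GT fields, haploid GT
#'   for female Z records), FASTA, GFF3, and TSV tables for metadata,
#'   expression, synteny summaries and simulation truth. Re-reading a
#'   written bundle reproduces the in-memory objects exactly.
NULL

.dosage_to_gt <- function(dosage, ploidy) {
  ifelse(is.na(dosage),
         ifelse(ploidy == 1L, ".", "./."),
         ifelse(ploidy == 1L, as.character(dosage),
                c("0/0", "0/1", "1/1")[dosage + 1L]))
}

.gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  d <- nchar(gsub("[^1]", "", gt))
  d[gt %in% c(".", "./.", ".|.")] <- NA_integer_
  as.integer(d)
}

.vcf_meta <- function(scaffolds) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", scaffolds$name,
            as.integer(scaffolds$length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
}

#' Write focal variant calls as VCF 4.2
#'
#' Pooled across populations (population labels live in the metadata
#' TSV); female Z records carry haploid GT fields.
#'
#' @param ds an `hs_dataset`.
#' @param path output path (`.vcf.gz`).
#' @export
write_focal_vcf <- function(ds, path) {
  pl <- ploidy_matrix(ds)
  gt <- matrix(NA_character_, nrow = nrow(ds$sites), ncol = nrow(ds$samples))
  for (s in seq_len(ncol(gt))) gt[, s] <- .dosage_to_gt(ds$geno[, s], pl[, s])
  colnames(gt) <- ds$samples$sample
  gt <- cbind(FORMAT = "GT", gt)
  fix <- cbind(CHROM = ds$sites$scaffold, POS = as.character(ds$sites$pos),
               ID = ".", REF = ds$sites$ref, ALT = ds$sites$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  v <- new("vcfR", meta = .vcf_meta(ds$scaffolds), fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write outgroup variant calls as VCF 4.2
#'
#' One outgroup sample; sites invariant in the outgroup are simply
#' absent, which is how the polarizer recognizes rule 1.
#'
#' @param ds an `hs_dataset`.
#' @param path output path (`.vcf.gz`).
#' @export
write_outgroup_vcf <- function(ds, path) {
  og <- ds$outgroup
  fix <- cbind(CHROM = og$scaffold, POS = as.character(og$pos), ID = ".",
               REF = og$ref, ALT = og$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt <- cbind(FORMAT = "GT", OUT = og$gt)
  v <- new("vcfR", meta = .vcf_meta(ds$scaffolds), fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a focal VCF back into site table and dosage matrix
#'
#' @param path VCF path.
#' @return list with `sites` (`scaffold`, `pos`, `ref`, `alt`) and
#'   `geno` (ALT dosage matrix, `NA` for missing).
#' @export
read_focal_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  sites <- data.frame(scaffold = v@fix[, "CHROM"],
                      pos = as.integer(v@fix[, "POS"]),
                      ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                      stringsAsFactors = FALSE)
  gtm <- v@gt[, -1, drop = FALSE]
  geno <- apply(gtm, 2, .gt_to_dosage)
  list(sites = sites, geno = geno)
}

#' Read an outgroup VCF into the polarizer's record table
#'
#' @param path VCF path.
#' @return data.frame with `scaffold`, `pos`, `ref`, `alt`, `gt`.
#' @export
read_outgroup_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  data.frame(scaffold = v@fix[, "CHROM"], pos = as.integer(v@fix[, "POS"]),
             ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
             gt = sub(":.*$", "", v@gt[, 2]), stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' @param genes gene-model list (`genes`, `cds`).
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  g <- genes$genes
  gr_gene <- GenomicRanges::GRanges(
    seqnames = g$scaffold,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand, type = "gene", ID = g$gene_id)
  cd <- genes$cds
  # GFF3 phase: bases to skip before the first complete codon of each exon
  phase <- integer(nrow(cd))
  for (g in unique(cd$gene_id)) {
    i <- which(cd$gene_id == g)
    i <- i[order(cd$exon_rank[i])]
    before <- cumsum(c(0, (cd$end[i] - cd$start[i] + 1)))[seq_along(i)]
    phase[i] <- (3 - before %% 3) %% 3
  }
  gr_cds <- GenomicRanges::GRanges(
    seqnames = cd$scaffold,
    ranges = IRanges::IRanges(start = cd$start, end = cd$end),
    strand = cd$strand, type = "CDS", phase = phase,
    ID = paste0(cd$gene_id, ".cds", cd$exon_rank))
  S4Vectors::mcols(gr_cds)$Parent <- as.character(cd$gene_id)
  rtracklayer::export(c(gr_gene, gr_cds), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Exon ranks are reconstructed in coding order (ascending start on the
#' plus strand, descending on the minus strand).
#'
#' @param path GFF3 path.
#' @return gene-model list (`genes`, `cds`).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gg <- gr[gr$type == "gene"]
  genes <- data.frame(gene_id = as.character(gg$ID),
                      scaffold = as.character(GenomicRanges::seqnames(gg)),
                      strand = as.character(GenomicRanges::strand(gg)),
                      start = GenomicRanges::start(gg),
                      end = GenomicRanges::end(gg), stringsAsFactors = FALSE)
  cc <- gr[gr$type == "CDS"]
  parent <- vapply(cc$Parent, function(x) as.character(x)[1], character(1))
  cds <- data.frame(gene_id = parent,
                    scaffold = as.character(GenomicRanges::seqnames(cc)),
                    strand = as.character(GenomicRanges::strand(cc)),
                    start = GenomicRanges::start(cc),
                    end = GenomicRanges::end(cc), stringsAsFactors = FALSE)
  parts <- split(seq_len(nrow(cds)), cds$gene_id)
  cds$exon_rank <- NA_integer_
  for (g in names(parts)) {
    i <- parts[[g]]
    o <- order(cds$start[i], decreasing = cds$strand[i][1] == "-")
    cds$exon_rank[i[o]] <- seq_along(i)
  }
  cds <- cds[order(match(cds$gene_id, genes$gene_id), cds$exon_rank), ]
  rownames(cds) <- NULL
  genes_sorted <- genes[order(match(genes$gene_id, unique(genes$gene_id))), ]
  list(genes = genes_sorted, cds = cds)
}

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write a complete simulated fixture bundle
#'
#' Emits the dataset as standard files: focal and outgroup VCFs,
#' reference FASTA, gene-model GFF3, and TSVs for sample metadata,
#' expression (matrix + design), scaffold table, and the truth tables.
#'
#' @param ds an `hs_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named file set.
#' @export
write_fixture_bundle <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(dir), "cannot create output directory")
  paths <- list(
    focal = file.path(dir, "focal.vcf.gz"),
    outgroup = file.path(dir, "outgroup.vcf.gz"),
    reference = file.path(dir, "reference.fa"),
    genes = file.path(dir, "genes.gff3"),
    samples = file.path(dir, "samples.tsv"),
    scaffolds = file.path(dir, "scaffolds.tsv"),
    expression = file.path(dir, "expression.tsv"),
    expr_design = file.path(dir, "expression_design.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_inversions = file.path(dir, "truth_inversions.tsv"))
  write_focal_vcf(ds, paths$focal)
  write_outgroup_vcf(ds, paths$outgroup)
  Biostrings::writeXStringSet(ds$ref, paths$reference)
  write_gff3(ds$genes, paths$genes)
  .write_tsv(ds$samples, paths$samples)
  .write_tsv(ds$scaffolds, paths$scaffolds)
  expr <- data.frame(gene_id = rownames(ds$expr), ds$expr,
                     check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(expr, paths$expression)
  .write_tsv(ds$expr_design, paths$expr_design)
  .write_tsv(ds$truth$sites, paths$truth_sites)
  .write_tsv(ds$truth$genes, paths$truth_genes)
  inv_rows <- do.call(rbind, lapply(ds$truth$inversions, function(iv)
    data.frame(inversion = iv$id, scaffold = iv$scaffold, start = iv$start,
               end = iv$end, sample = names(iv$sample_genotypes),
               inverted_chromosomes = as.integer(iv$sample_genotypes),
               stringsAsFactors = FALSE)))
  .write_tsv(inv_rows, paths$truth_inversions)
  invisible(paths)
}

#' Read a fixture bundle back into a dataset object
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @return an `hs_dataset` (without the generating `config`; truth
#'   tables are returned in their on-disk tabular form).
#' @export
read_fixture_bundle <- function(dir) {
  focal <- read_focal_vcf(file.path(dir, "focal.vcf.gz"))
  samples <- .read_tsv(file.path(dir, "samples.tsv"))
  scaffolds <- .read_tsv(file.path(dir, "scaffolds.tsv"))
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(ref) <- sub(" .*$", "", names(ref))
  genes <- read_gff3(file.path(dir, "genes.gff3"))
  exprd <- .read_tsv(file.path(dir, "expression.tsv"))
  expr <- as.matrix(exprd[, -1, drop = FALSE])
  rownames(expr) <- exprd$gene_id
  sites <- focal$sites
  sites$is_z <- scaffolds$is_z[match(sites$scaffold, scaffolds$name)]
  truth_sites <- .read_tsv(file.path(dir, "truth_sites.tsv"))
  truth_genes <- .read_tsv(file.path(dir, "truth_genes.tsv"))
  truth_inv <- .read_tsv(file.path(dir, "truth_inversions.tsv"))
  structure(list(config = NULL, samples = samples, scaffolds = scaffolds,
                 ref = ref, genes = genes, sites = sites, geno = focal$geno,
                 outgroup = read_outgroup_vcf(file.path(dir, "outgroup.vcf.gz")),
                 expr = expr,
                 expr_design = .read_tsv(file.path(dir, "expression_design.tsv")),
                 truth = list(sites = truth_sites, genes = truth_genes,
                              inversions = truth_inv)),
            class = "hs_dataset")
}

#' Read a synteny alignment summary TSV
#'
#' Columns: `old_scaffold`, `old_chrom`, `new_scaffold`, `new_start`,
#' `new_end` (0-based half-open).
#'
#' @param path TSV path.
#' @return data.frame of alignment records.
#' @export
read_synteny_tsv <- function(path) {
  d <- .read_tsv(path)
  .assert(all(c("old_scaffold", "old_chrom", "new_scaffold",
                "new_start", "new_end") %in% names(d)),
          "synteny TSV missing required columns")
  d
}
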