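# Shared simulated dataset, built once per test run. The default
# configuration IS the emulated study design (NC 12, KS 1M/3F, AZ 6M/2F;
# chr12-analog inversion at 11/16 in AZ; Z-analog at 13/14; linked
# stop-loss pseudogene), so most tests interrogate the same object.
.hs_cache <- new.env(parent = emptyenv())

.hs_full_run <- function() {
  if (is.null(.hs_cache$run)) {
    env <- shared_run()
    .hs_cache$run <- run_full(env$ds)
  }
  .hs_cache$run
}

shared_run <- function() {
  if (is.null(.hs_cache$ds)) {
    .hs_cache$cfg <- sim_config(seed = 42)
    .hs_cache$ds <- simulate_dataset(.hs_cache$cfg)
    .hs_cache$dec <- polarize_sites(.hs_cache$ds$sites, .hs_cache$ds$outgroup)
    .hs_cache$freqs <- population_frequencies(.hs_cache$ds, .hs_cache$dec)
  }
  .hs_cache
}

# Tiny neutral configuration (no inversions, drift only) for estimator
# calibration: >= 5000 background SNPs across three 1-Mb autosomes.
neutral_config <- function(seed = 7) {
  sim_config(
    seed = seed,
    scaffolds = data.frame(name = c("sc1", "sc2", "sc3"),
                           length = rep(1e6, 3),
                           chromosome = c("chr1", "chr2", "chr3"),
                           is_z = FALSE, stringsAsFactors = FALSE),
    n_snps_per_scaffold = 2000,
    inversions = list(), pseudogene = NULL,
    zero_fold_factor = 1)
}

# A toy plus-strand single-exon gene written into a fresh reference;
# used by the degeneracy / effect-annotation oracles.
toy_gene <- function(cds_len = 300, strand = "+", seed = 11) {
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  sense <- setdiff(rownames(hornscan::codon_degeneracy_table()),
                   c("TAA", "TAG", "TGA"))
  coding <- c("A", "T", "G",
              unlist(strsplit(sample(sense, cds_len / 3 - 2, replace = TRUE), "")),
              "T", "A", "A")
  L <- cds_len + 200
  bases <- sample(nts, L, replace = TRUE)
  start <- 101
  put <- if (strand == "+") coding else rev(unname(c(A = "T", C = "G", G = "C",
                                                     T = "A")[coding]))
  bases[start:(start + cds_len - 1)] <- put
  ref <- Biostrings::DNAStringSet(paste0(bases, collapse = ""))
  names(ref) <- "toy_scaf"
  genes <- list(
    genes = data.frame(gene_id = "toy_gene", scaffold = "toy_scaf",
                       strand = strand, start = start,
                       end = start + cds_len - 1, stringsAsFactors = FALSE),
    cds = data.frame(gene_id = "toy_gene", scaffold = "toy_scaf",
                     strand = strand, start = start,
                     end = start + cds_len - 1, exon_rank = 1L,
                     stringsAsFactors = FALSE))
  list(ref = ref, genes = genes, coding = coding, bases = bases, start = start)
}

jaccard <- function(a1, a2, b1, b2) {
  i <- max(0, min(a2, b2) - max(a1, b1))
  i / ((a2 - a1) + (b2 - b1) - i)
}
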