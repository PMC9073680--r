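#' Default three-population sampling design
#'
#' The study design the generator emulates: 12 North Carolina males,
#' 4 Kansas moths (1 male, 3 females), and 8 Arizona moths (6 males,
#' 2 females). Females are hemizygous on the Z.
#'
#' @return data.frame with columns `name`, `n`, `males`, `females`.
#' @export
default_populations <- function() {
  data.frame(name = c("NC", "KS", "AZ"),
             n = c(12L, 4L, 8L),
             males = c(12L, 1L, 6L),
             females = c(0L, 3L, 2L),
             stringsAsFactors = FALSE)
}

#' Default desk-scale genome
#'
#' Two 1-Mb autosomal scaffolds (a chr12 analog carrying the large
#' autosomal inversion, and a neutral chr5 analog) plus a 500-kb Z
#' scaffold carrying the smaller sex-linked inversion. Mirrors the real
#' layout (an ~8 Mb inversion spanning roughly half of chromosome 12 and
#' an ~1 Mb inversion on the Z) at 1/16 scale.
#'
#' @return data.frame with columns `name`, `length`, `chromosome`, `is_z`.
#' @export
default_scaffolds <- function() {
  data.frame(name = c("scaffold_12", "scaffold_05", "scaffold_Z"),
             length = c(1e6, 1e6, 5e5),
             chromosome = c("chr12", "chr5", "chrZ"),
             is_z = c(FALSE, FALSE, TRUE),
             stringsAsFactors = FALSE)
}

#' Describe a segregating inversion for the simulator
#'
#' @param id label, e.g. `"inv12"`.
#' @param scaffold scaffold name; must exist in the config's scaffold set.
#' @param start,end inverted interval, 0-based half-open bp.
#' @param marker_per_kb density of SNPs fixed on the inverted haplotype.
#' @param genotypes named list, population -> integer vector of per-sample
#'   inverted-chromosome counts (0/1/2 for diploids; 0/1 for hemizygous
#'   females on the Z), in metadata sample order. Populations absent from
#'   the list carry no inverted chromosomes.
#' @return object of class `inversion_spec`.
#' @export
inversion_spec <- function(id, scaffold, start, end, marker_per_kb = 3,
                           genotypes = list()) {
  .assert(end > start, "inversion end must exceed start")
  structure(list(id = id, scaffold = scaffold, start = start, end = end,
                 marker_per_kb = marker_per_kb, genotypes = genotypes),
            class = "inversion_spec")
}

#' Describe the inversion-linked pseudogene variant set
#'
#' A gene inside the linked inversion receives `n_linked_snps` coding
#' SNPs whose per-sample genotypes copy the inversion genotype exactly,
#' optionally including a stop-loss variant in the final codon.
#'
#' @param inversion id of the inversion the variants co-segregate with.
#' @param n_linked_snps number of linked coding SNPs (61 in the study
#'   population this emulates).
#' @param stop_loss include a stop-loss variant in the terminal codon.
#' @return object of class `pseudogene_spec`.
#' @export
pseudogene_spec <- function(inversion = "inv12", n_linked_snps = 61,
                            stop_loss = TRUE) {
  .assert(n_linked_snps >= 1, "need at least one linked SNP")
  structure(list(inversion = inversion, n_linked_snps = n_linked_snps,
                 stop_loss = stop_loss), class = "pseudogene_spec")
}

# Default per-sample inversion genotypes matching the study pattern:
# chr12 analog in AZ distributed as hom, hom, het, het, hom, hom, het,
# hom-ancestral (11/16 carrier chromosomes); Z analog carried on every
# sampled AZ Z chromosome except one (a heterozygous male): 13/14.
.default_inversions <- function() {
  list(
    inversion_spec("inv12", "scaffold_12", 250000, 750000, marker_per_kb = 3,
                   genotypes = list(AZ = c(2L, 2L, 1L, 1L, 2L, 2L, 1L, 0L))),
    inversion_spec("invZ", "scaffold_Z", 150000, 350000, marker_per_kb = 3,
                   # AZ metadata order is males 1-6 then hemizygous females
                   # 7-8: five ZZ homozygotes, one heterozygous male (the
                   # single non-carrier chromosome), two carrier females
                   genotypes = list(AZ = c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L)))
  )
}

#' Default expression-profiling design
#'
#' Conditions (stage x tissue x sex availability) reconstructed from the
#' RNA-seq metadataset design: head, midgut and fat body in all three
#' stages (the tissues the stage dimension is computed on), sexed gonad
#' libraries in pupa and adult, sexed antennal libraries in adults, plus
#' pooled muscle and Malpighian-tube libraries where sampled.
#'
#' @return data.frame with columns `condition`, `stage`, `tissue`, `sex`.
#' @export
default_expression_design <- function() {
  rows <- rbind(
    c("larva_head",      "larva", "head",       "pooled"),
    c("larva_midgut",    "larva", "midgut",     "pooled"),
    c("larva_fat",       "larva", "fat",        "pooled"),
    c("larva_muscle",    "larva", "muscle",     "pooled"),
    c("larva_malpighian","larva", "malpighian", "pooled"),
    c("pupa_head",       "pupa",  "head",       "pooled"),
    c("pupa_midgut",     "pupa",  "midgut",     "pooled"),
    c("pupa_fat",        "pupa",  "fat",        "pooled"),
    c("pupa_gonad_M",    "pupa",  "gonad",      "M"),
    c("pupa_gonad_F",    "pupa",  "gonad",      "F"),
    c("adult_antenna_M", "adult", "antenna",    "M"),
    c("adult_antenna_F", "adult", "antenna",    "F"),
    c("adult_head",      "adult", "head",       "pooled"),
    c("adult_midgut",    "adult", "midgut",     "pooled"),
    c("adult_fat",       "adult", "fat",        "pooled"),
    c("adult_muscle",    "adult", "muscle",     "pooled"),
    c("adult_gonad_M",   "adult", "gonad",      "M"),
    c("adult_gonad_F",   "adult", "gonad",      "F"))
  out <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(out) <- c("condition", "stage", "tissue", "sex")
  out
}

#' Build a simulation configuration
#'
#' Defines the study conditions the generator emulates: the three-state
#' sampling design, background pairwise differentiation, two segregating
#' inversions (autosomal 11/16 and Z-linked 13/14 in the AZ-like
#' population), and a linked pseudogene variant set.
#'
#' @param populations data.frame as [default_populations()].
#' @param scaffolds data.frame as [default_scaffolds()].
#' @param background_fst named vector of pairwise F_ST targets,
#'   names `"POP1-POP2"`. Per-population Balding-Nichols F values are
#'   solved from these via `E[FST_ij] = (F_i + F_j)/2`.
#' @param n_snps_per_scaffold background SNP count per Mb of scaffold.
#' @param inversions list of [inversion_spec()] objects.
#' @param pseudogene [pseudogene_spec()] or `NULL`.
#' @param expression_design data.frame as [default_expression_design()].
#' @param genes_per_mb density of simulated protein-coding genes.
#' @param zero_fold_factor multiplicative suppression of ancestral derived
#'   allele frequencies at 0-fold degenerate sites (1 = drift only;
#'   the default mimics purifying selection so that pi_0 < pi_4).
#' @param polarization_mix probabilities of the four outgroup
#'   configurations at background SNPs (reference-ancestral /
#'   alternate-ancestral / shared-allele tri-allelic / unresolvable).
#' @param missing_rate named per-population genotype missingness.
#' @param seed master integer seed; fans out to named substreams.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(populations = default_populations(),
                       scaffolds = default_scaffolds(),
                       background_fst = c("NC-KS" = 0.064,
                                          "NC-AZ" = 0.090,
                                          "KS-AZ" = 0.041),
                       n_snps_per_scaffold = 2000,
                       inversions = .default_inversions(),
                       pseudogene = pseudogene_spec(),
                       expression_design = default_expression_design(),
                       genes_per_mb = 40,
                       zero_fold_factor = 0.15,
                       polarization_mix = c(reference = 0.80, alternate = 0.10,
                                            shared = 0.05, masked = 0.05),
                       missing_rate = NULL,
                       seed = 1) {
  .assert(all(populations$males + populations$females == populations$n),
          "males + females must equal n for every population")
  .assert(all(populations$n >= 1), "n_diploids must be >= 1")
  .assert(all(background_fst > 0 & background_fst < 1),
          "target F_ST values must lie in (0, 1)")
  .assert(abs(sum(polarization_mix) - 1) < 1e-8,
          "polarization_mix must sum to 1")
  if (is.null(missing_rate)) {
    missing_rate <- setNames(rep(0, nrow(populations)), populations$name)
  }
  cfg <- structure(list(populations = populations, scaffolds = scaffolds,
                        background_fst = background_fst,
                        n_snps_per_scaffold = n_snps_per_scaffold,
                        inversions = inversions, pseudogene = pseudogene,
                        expression_design = expression_design,
                        genes_per_mb = genes_per_mb,
                        zero_fold_factor = zero_fold_factor,
                        polarization_mix = polarization_mix,
                        missing_rate = missing_rate, seed = seed),
                   class = "sim_config")
  validate_config(cfg)
  cfg
}

# Total sampled chromosomes for one population on one scaffold class
pop_chromosomes <- function(pop_row, is_z) {
  if (is_z) 2L * pop_row$males + pop_row$females else 2L * pop_row$n
}

validate_config <- function(cfg) {
  scafs <- cfg$scaffolds
  for (inv in cfg$inversions) {
    i <- match(inv$scaffold, scafs$name)
    .assert(!is.na(i), sprintf("inversion %s on unknown scaffold", inv$id))
    .assert(inv$start >= 0 && inv$end <= scafs$length[i],
            sprintf("inversion %s interval outside scaffold", inv$id))
    for (pn in names(inv$genotypes)) {
      p <- cfg$populations[cfg$populations$name == pn, ]
      .assert(nrow(p) == 1, sprintf("inversion %s names unknown population", inv$id))
      g <- inv$genotypes[[pn]]
      .assert(length(g) == p$n,
              sprintf("inversion %s genotype vector length != n for %s", inv$id, pn))
      is_z <- scafs$is_z[i]
      ploidy <- .sample_ploidy(p, is_z)
      .assert(all(g >= 0 & g <= ploidy),
              sprintf("inversion %s genotypes exceed ploidy in %s", inv$id, pn))
      .assert(sum(g) <= pop_chromosomes(p, is_z),
              sprintf("inversion %s carrier count exceeds sampled chromosomes in %s",
                      inv$id, pn))
    }
  }
  if (!is.null(cfg$pseudogene)) {
    ids <- vapply(cfg$inversions, function(x) x$id, character(1))
    .assert(cfg$pseudogene$inversion %in% ids,
            "pseudogene linked to unknown inversion")
  }
  invisible(cfg)
}

# Per-sample ploidy vector for one population (metadata order: males first)
.sample_ploidy <- function(pop_row, is_z) {
  if (!is_z) return(rep(2L, pop_row$n))
  c(rep(2L, pop_row$males), rep(1L, pop_row$females))
}

# Solve per-population Balding-Nichols F from pairwise targets.
# E[FST_ij] = (F_i + F_j)/2 under independent BN draws, so the pairwise
# map is a linear system in the per-population F values.
solve_population_F <- function(populations, background_fst) {
  pops <- populations$name
  pairs <- strsplit(names(background_fst), "-", fixed = TRUE)
  A <- matrix(0, nrow = length(pairs), ncol = length(pops),
              dimnames = list(names(background_fst), pops))
  for (k in seq_along(pairs)) {
    .assert(all(pairs[[k]] %in% pops), "background_fst names unknown population")
    A[k, pairs[[k]]] <- 0.5
  }
  f <- qr.solve(A, background_fst)
  setNames(pmin(pmax(as.numeric(f), 1e-4), 0.5), pops)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  populations:",
      paste(sprintf("%s (n=%d, %dM/%dF)", x$populations$name, x$populations$n,
                    x$populations$males, x$populations$females),
            collapse = ", "), "\n")
  cat("  scaffolds:",
      paste(sprintf("%s (%.0f kb%s)", x$scaffolds$name, x$scaffolds$length / 1e3,
                    ifelse(x$scaffolds$is_z, ", Z", "")), collapse = ", "), "\n")
  cat("  inversions:",
      paste(vapply(x$inversions, function(i)
        sprintf("%s [%d,%d) on %s", i$id, i$start, i$end, i$scaffold),
        character(1)), collapse = "; "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
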