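#' @name synthetic_data
#' @title Balding-Nichols three-population simulator
#' @description Generates a miniature resequencing dataset with the
#'   statistical structure the analysis chain assumes: background
#'   differentiation calibrated to pairwise F_ST targets, two
#'   non-recombining inversion haplotypes (autosomal and Z-linked, with
#'   female Z hemizygosity), a linked pseudogene variant set including a
#'   stop-loss, outgroup variation for polarization, gene models with
#'   classifiable degeneracy, and an expression matrix with known
#'   specificity classes. A truth table records every generated signal
#'   for parameter-recovery tests.
NULL

.NTS <- c("A", "C", "G", "T")

# vectorized "sample a base different from ref"
.sample_other_base <- function(ref_bases, exclude2 = NULL) {
  n <- length(ref_bases)
  out <- character(n)
  for (i in seq_len(n)) {
    pool <- setdiff(.NTS, c(ref_bases[i], exclude2[i]))
    out[i] <- pool[sample.int(length(pool), 1)]
  }
  out
}

.build_samples <- function(populations) {
  rows <- lapply(seq_len(nrow(populations)), function(i) {
    p <- populations[i, ]
    data.frame(sample = sprintf("%s%02d", p$name, seq_len(p$n)),
               population = p$name,
               sex = c(rep("M", p$males), rep("F", p$females)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Random reference with ORFs written in at the gene coordinates
.sim_genome <- function(config) {
  scafs <- config$scaffolds
  .set_stream(config$seed, "reference")
  bases <- lapply(seq_len(nrow(scafs)), function(i)
    sample(.NTS, scafs$length[i], replace = TRUE))
  names(bases) <- scafs$name

  .set_stream(config$seed, "genes")
  stops <- .STOP_CODONS
  all_codons <- rownames(codon_degeneracy_table())
  sense <- setdiff(all_codons, stops)
  gene_rows <- list(); cds_rows <- list()
  gi <- 0
  for (i in seq_len(nrow(scafs))) {
    L <- scafs$length[i]
    G <- max(1L, round(config$genes_per_mb * L / 1e6))
    w <- floor(L / G)
    for (g in seq_len(G)) {
      gi <- gi + 1
      cds_len <- sample(c(300, 450, 600, 900), 1)
      two_exon <- g %% 3 == 0
      intron <- if (two_exon) 120L else 0L
      span <- cds_len + intron
      lo <- (g - 1) * w + 50
      hi <- g * w - span - 50
      if (hi <= lo) { two_exon <- FALSE; intron <- 0L; span <- cds_len; hi <- g * w - span - 50 }
      if (hi <= lo) next
      start <- lo + sample.int(hi - lo, 1)
      strand <- if (gi %% 2 == 0) "-" else "+"
      gid <- sprintf("gene_%s_%03d", scafs$chromosome[i], g)
      if (two_exon) {
        s1 <- floor(cds_len * 0.4)  # deliberately off codon boundary
        e1 <- c(start, start + s1 - 1)
        e2 <- c(start + s1 + intron, start + cds_len + intron - 1)
        ex <- rbind(e1, e2)
      } else {
        ex <- rbind(c(start, start + cds_len - 1))
      }
      gene_rows[[gi]] <- data.frame(gene_id = gid, scaffold = scafs$name[i],
                                    strand = strand, start = min(ex),
                                    end = max(ex), stringsAsFactors = FALSE)
      rank_order <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
      cds_rows[[gi]] <- data.frame(gene_id = gid, scaffold = scafs$name[i],
                                   strand = strand,
                                   start = ex[rank_order, 1],
                                   end = ex[rank_order, 2],
                                   exon_rank = seq_len(nrow(ex)),
                                   stringsAsFactors = FALSE)
      # write the ORF: ATG + sense codons + TAA on the coding strand
      n_mid <- cds_len / 3 - 2
      coding <- c("A", "T", "G",
                  unlist(strsplit(sample(sense, n_mid, replace = TRUE), "")),
                  "T", "A", "A")
      pos <- cds_positions(cds_rows[[gi]])
      put <- if (strand == "+") coding else unname(.COMP[coding])
      bases[[scafs$name[i]]][pos] <- put
    }
  }
  genes <- list(genes = do.call(rbind, gene_rows), cds = do.call(rbind, cds_rows))
  rownames(genes$genes) <- rownames(genes$cds) <- NULL
  for (col in c("start", "end")) {
    genes$genes[[col]] <- as.integer(genes$genes[[col]])
    genes$cds[[col]] <- as.integer(genes$cds[[col]])
  }
  ref <- Biostrings::DNAStringSet(vapply(bases, paste0, character(1), collapse = ""))
  names(ref) <- scafs$name
  list(ref = ref, genes = genes, ref_bases = bases)
}

# per-sample inverted-chromosome counts for one inversion (0 for
# populations without a genotype entry)
.inv_sample_counts <- function(inv, samples) {
  counts <- setNames(rep(0L, nrow(samples)), samples$sample)
  for (pn in names(inv$genotypes)) {
    idx <- which(samples$population == pn)
    counts[idx] <- as.integer(inv$genotypes[[pn]])
  }
  counts
}

# Haplotype-structured dosages inside an inversion interval. The
# non-recombining region segregates as whole haplotypes: one shared
# inverted haplotype plus a small pool of ancestral haplotypes common
# to all populations (drawn once from the ancestral frequency).
# Populations differ only in haplotype composition, so linkage is
# elevated inside the interval in every population while non-carrier
# populations show no artificial divergence there. Marker sites are
# fixed derived on the inverted haplotype only, so their
# within-population frequency is exactly carriers/total.
.sim_inversion_dosage <- function(n_bg_sites, n_marker_sites, p_anc, samples,
                                  populations, inv_counts, ploidy, n_anc_hap = 3) {
  n_samp <- nrow(samples)
  D_bg <- matrix(0L, nrow = n_bg_sites, ncol = n_samp)
  D_mk <- matrix(0L, nrow = n_marker_sites, ncol = n_samp)
  K <- n_anc_hap
  H <- if (n_bg_sites > 0) {
    # col 1 = inverted haplotype, cols 2..K+1 = shared ancestral pool
    matrix(rbinom((K + 1) * n_bg_sites, 1L, rep(p_anc, K + 1)),
           nrow = n_bg_sites)
  } else NULL
  for (pi in seq_len(nrow(populations))) {
    pn <- populations$name[pi]
    idx <- which(samples$population == pn)
    chrom_sample <- rep(idx, times = ploidy[idx])
    n_chrom <- length(chrom_sample)
    # inverted chromosomes first within each sample
    inv_flag <- unlist(lapply(idx, function(s) {
      g <- inv_counts[s]
      c(rep(TRUE, g), rep(FALSE, ploidy[s] - g))
    }))
    hap_of_chrom <- integer(n_chrom)       # 0 = inverted haplotype
    hap_of_chrom[!inv_flag] <- sample.int(K, sum(!inv_flag), replace = TRUE)
    if (n_bg_sites > 0) {
      for (ci in seq_len(n_chrom)) {
        col <- hap_of_chrom[ci] + 1L
        D_bg[, chrom_sample[ci]] <- D_bg[, chrom_sample[ci]] + H[, col]
      }
    }
    if (n_marker_sites > 0) {
      for (s in idx) D_mk[, s] <- inv_counts[s]
    }
  }
  list(bg = D_bg, markers = D_mk)
}

# One scaffold's sites, derived dosages, outgroup records and truth rows
.sim_scaffold_sites <- function(config, scaf_i, samples, popF, ref_bases,
                                forbidden, zero_fold_pos, genes, degmap) {
  scafs <- config$scaffolds
  scaf <- scafs$name[scaf_i]
  L <- scafs$length[scaf_i]
  is_z <- scafs$is_z[scaf_i]
  pops <- config$populations
  ploidy <- unlist(lapply(seq_len(nrow(pops)),
                          function(i) .sample_ploidy(pops[i, ], is_z)))
  names(ploidy) <- samples$sample

  .set_stream(config$seed, paste0("sites:", scaf))
  invs <- Filter(function(x) x$scaffold == scaf, config$inversions)

  # --- pseudogene plan (if its inversion lives on this scaffold)
  pg <- config$pseudogene
  pg_plan <- NULL
  if (!is.null(pg)) {
    inv_ids <- vapply(invs, function(x) x$id, character(1))
    if (pg$inversion %in% inv_ids) {
      inv <- invs[[match(pg$inversion, inv_ids)]]
      cand <- genes$genes[genes$genes$scaffold == scaf &
                          genes$genes$start >= inv$start + 1 &
                          genes$genes$end <= inv$end, ]
      cand <- cand[cand$gene_id %in% degmap$site_counts$gene_id, ]
      .assert(nrow(cand) > 0, "no intact gene inside the linked inversion")
      centre <- (inv$start + inv$end) / 2
      gid <- cand$gene_id[which.min(abs((cand$start + cand$end) / 2 - centre))]
      bg <- degmap$by_gene[degmap$by_gene$gene_id == gid, ]
      n_cds <- max(bg$cds_pos)
      body_pos <- bg$pos[bg$cds_pos > 3 & bg$cds_pos <= n_cds - 3]
      stop_row <- bg[bg$cds_pos == n_cds - 1, ]    # middle base of TAA
      # TAA -> TCA: coding-strand A->C at codon offset 2
      stop_alt <- if (stop_row$strand == "+") "C" else unname(.COMP["C"])
      pg_plan <- list(gene_id = gid, inversion = pg$inversion,
                      body_pos = body_pos, stop_pos = stop_row$pos,
                      stop_alt = stop_alt,
                      n_body = pg$n_linked_snps - as.integer(pg$stop_loss),
                      stop_loss = pg$stop_loss)
      .assert(length(body_pos) >= pg_plan$n_body,
              "pseudogene CDS too short for requested linked SNP count")
    }
  }

  allowed <- setdiff(seq_len(L), forbidden[[scaf]])
  if (!is.null(pg_plan)) {
    gspan <- genes$genes[genes$genes$gene_id == pg_plan$gene_id, ]
    allowed <- allowed[allowed < gspan$start | allowed > gspan$end]
  }

  n_bg <- round(config$n_snps_per_scaffold * L / 1e6)
  bg_pos <- sort(sample(allowed, n_bg))
  used <- bg_pos

  # --- background frequencies: Balding-Nichols around uniform ancestral p
  p_anc <- runif(n_bg, 0.05, 0.95)
  zf <- bg_pos %in% zero_fold_pos[[scaf]]
  p_anc[zf] <- p_anc[zf] * config$zero_fold_factor
  P <- matrix(NA_real_, nrow = n_bg, ncol = nrow(pops),
              dimnames = list(NULL, pops$name))
  for (pn in pops$name) {
    f <- popF[[pn]]
    P[, pn] <- rbeta(n_bg, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }

  # --- outside-inversion dosages: independent binomial per sample
  inside <- rep(FALSE, n_bg)
  for (inv in invs) inside <- inside | (bg_pos > inv$start & bg_pos <= inv$end)
  D <- matrix(0L, nrow = n_bg, ncol = nrow(samples))
  out_idx <- which(!inside)
  if (length(out_idx)) {
    for (s in seq_len(nrow(samples))) {
      pn <- samples$population[s]
      D[out_idx, s] <- rbinom(length(out_idx), ploidy[s], P[out_idx, pn])
    }
  }

  # --- inversion interiors: haplotype-structured + marker sites
  marker_sites <- list()
  for (inv in invs) {
    in_idx <- which(bg_pos > inv$start & bg_pos <= inv$end)
    inv_counts <- .inv_sample_counts(inv, samples)
    n_mk <- round(inv$marker_per_kb * (inv$end - inv$start) / 1000)
    pool <- setdiff(allowed[allowed > inv$start & allowed <= inv$end], used)
    mk_pos <- sort(sample(pool, min(n_mk, length(pool))))
    used <- c(used, mk_pos)
    sim <- .sim_inversion_dosage(length(in_idx), length(mk_pos),
                                 p_anc[in_idx], samples, pops,
                                 inv_counts, ploidy)
    if (length(in_idx)) D[in_idx, ] <- sim$bg
    marker_sites[[inv$id]] <- list(pos = mk_pos, dosage = sim$markers,
                                   inversion = inv$id)
  }

  # --- pseudogene linked SNPs copy the inversion genotype exactly
  pg_sites <- NULL
  if (!is.null(pg_plan)) {
    inv_ids <- vapply(invs, function(x) x$id, character(1))
    inv <- invs[[match(pg_plan$inversion, inv_ids)]]
    inv_counts <- .inv_sample_counts(inv, samples)
    body <- sort(sample(setdiff(pg_plan$body_pos, used), pg_plan$n_body))
    pos <- c(body, if (pg_plan$stop_loss) pg_plan$stop_pos)
    o <- order(pos)
    dos <- matrix(rep(as.integer(inv_counts), each = length(pos)),
                  nrow = length(pos))
    pg_sites <- list(pos = pos[o], dosage = dos[o, , drop = FALSE],
                     is_stop = (pos == pg_plan$stop_pos)[o],
                     inversion = pg_plan$inversion, gene_id = pg_plan$gene_id)
  }

  # --- assemble site table in position order
  all_pos <- bg_pos
  site_type <- rep("background", n_bg)
  inv_of_site <- rep(NA_character_, n_bg)
  for (inv in invs) {
    ii <- which(bg_pos > inv$start & bg_pos <= inv$end)
    inv_of_site[ii] <- inv$id
  }
  D_all <- D
  for (mk in marker_sites) {
    all_pos <- c(all_pos, mk$pos)
    site_type <- c(site_type, rep("marker", length(mk$pos)))
    inv_of_site <- c(inv_of_site, rep(mk$inversion, length(mk$pos)))
    D_all <- rbind(D_all, mk$dosage)
  }
  if (!is.null(pg_sites)) {
    all_pos <- c(all_pos, pg_sites$pos)
    site_type <- c(site_type,
                   ifelse(pg_sites$is_stop, "pseudogene_stop_loss", "pseudogene"))
    inv_of_site <- c(inv_of_site, rep(pg_sites$inversion, length(pg_sites$pos)))
    D_all <- rbind(D_all, pg_sites$dosage)
  }
  o <- order(all_pos)
  all_pos <- all_pos[o]; site_type <- site_type[o]
  inv_of_site <- inv_of_site[o]
  D_all <- D_all[o, , drop = FALSE]
  n_sites <- length(all_pos)

  # --- polarization truth: outgroup configuration per site
  .set_stream(config$seed, paste0("polarize:", scaf))
  classes <- rep("reference", n_sites)
  is_bg <- site_type == "background"
  classes[is_bg] <- sample(names(config$polarization_mix), sum(is_bg),
                           replace = TRUE, prob = config$polarization_mix)
  ref_allele <- ref_bases[[scaf]][all_pos]
  alt_allele <- .sample_other_base(ref_allele)
  stop_i <- which(site_type == "pseudogene_stop_loss")
  if (length(stop_i)) alt_allele[stop_i] <- pg_plan$stop_alt
  third <- rep(NA_character_, n_sites)
  need3 <- classes %in% c("shared", "masked")
  third[need3] <- .sample_other_base(ref_allele[need3], alt_allele[need3])

  # ancestral truth: reference/masked -> ref is ancestral (derived = alt);
  # alternate/shared -> alt is ancestral (derived = ref)
  anc <- ifelse(classes %in% c("alternate", "shared"), alt_allele, ref_allele)

  # stored genotypes are ALT dosages; flip where the derived allele is REF
  ploidy_m <- matrix(rep(ploidy, each = n_sites), nrow = n_sites)
  A <- D_all
  flip <- classes %in% c("alternate", "shared")
  A[flip, ] <- ploidy_m[flip, ] - D_all[flip, , drop = FALSE]

  # --- outgroup VCF records (absent row = outgroup invariant)
  og <- NULL
  og_idx <- which(classes != "reference")
  if (length(og_idx)) {
    og <- data.frame(scaffold = scaf, pos = all_pos[og_idx],
                     ref = ref_allele[og_idx],
                     alt = NA_character_, gt = NA_character_,
                     stringsAsFactors = FALSE)
    for (j in seq_along(og_idx)) {
      i <- og_idx[j]
      if (classes[i] == "alternate") {
        og$alt[j] <- alt_allele[i]
        og$gt[j] <- sample(c("1/1", "0/1"), 1)
      } else if (classes[i] == "shared") {
        og$alt[j] <- paste(third[i], alt_allele[i], sep = ",")
        og$gt[j] <- "1/2"
      } else {                                   # masked: private outgroup allele
        og$alt[j] <- third[i]
        og$gt[j] <- "1/1"
      }
    }
  }

  sites <- data.frame(scaffold = scaf, pos = all_pos, ref = ref_allele,
                      alt = alt_allele, is_z = is_z, stringsAsFactors = FALSE)
  truth <- data.frame(scaffold = scaf, pos = all_pos, ref = ref_allele,
                      alt = alt_allele, ancestral = anc,
                      outgroup_case = classes, site_type = site_type,
                      inversion = inv_of_site, stringsAsFactors = FALSE)
  list(sites = sites, geno = A, outgroup = og, truth = truth, ploidy = ploidy)
}

.sim_expression <- function(config, genes, degmap, pg_gene) {
  .set_stream(config$seed, "expression")
  design <- config$expression_design
  gdf <- genes$genes
  n_g <- nrow(gdf)
  stages <- c("larva", "pupa", "adult")
  tissues <- unique(design$tissue)
  invZ <- Filter(function(x) x$id == "invZ",
                 config$inversions)
  in_invz <- rep(FALSE, n_g)
  if (length(invZ)) {
    iv <- invZ[[1]]
    in_invz <- gdf$scaffold == iv$scaffold & gdf$start >= iv$start + 1 &
      gdf$end <= iv$end
  }
  stage_class <- sample(c(stages, "unbiased"), n_g, replace = TRUE,
                        prob = c(0.15, 0.10, 0.20, 0.55))
  tissue_class <- sample(c(tissues, "unbiased"), n_g, replace = TRUE,
                         prob = c(rep(0.45 / length(tissues), length(tissues)), 0.55))
  # sex: genes inside the Z inversion are seeded with an excess of
  # unbiased genes relative to the genomic background
  sex_class <- ifelse(in_invz,
                      sample(c("M", "F", "unbiased"), n_g, replace = TRUE,
                             prob = c(0.05, 0.05, 0.90)),
                      sample(c("M", "F", "unbiased"), n_g, replace = TRUE,
                             prob = c(0.25, 0.25, 0.50)))
  if (!is.null(pg_gene)) {
    i <- match(pg_gene, gdf$gene_id)
    stage_class[i] <- "larva"; tissue_class[i] <- "antenna"
    sex_class[i] <- "unbiased"
  }
  w_of <- function(class_vec, cats, member) {
    # weight for one condition attribute: specific class concentrates 90%
    ifelse(class_vec == "unbiased", 1,
           ifelse(class_vec == member, 0.9 * (length(cats)) / 1,
                  0.1 * length(cats) / (length(cats) - 1)))
  }
  expr <- matrix(0, nrow = n_g, ncol = nrow(design),
                 dimnames = list(gdf$gene_id, design$condition))
  total <- exp(rnorm(n_g, 3, 1))
  for (ci in seq_len(nrow(design))) {
    cond <- design[ci, ]
    sw <- w_of(stage_class, stages, cond$stage)
    tw <- w_of(tissue_class, tissues, cond$tissue)
    xw <- if (cond$sex == "pooled") 1 else
      ifelse(sex_class == "unbiased", 1,
             ifelse(sex_class == cond$sex, 1.8, 0.2))
    expr[, ci] <- sw * tw * xw * exp(rnorm(n_g, 0, 0.1))
  }
  expr <- expr / rowSums(expr) * total
  expr <- round(expr, 6)
  truth_genes <- data.frame(gene_id = gdf$gene_id, scaffold = gdf$scaffold,
                            start = gdf$start, end = gdf$end,
                            stage_class = stage_class,
                            tissue_class = tissue_class,
                            sex_class = sex_class,
                            in_z_inversion = in_invz,
                            is_pseudogene = gdf$gene_id %in% pg_gene,
                            stringsAsFactors = FALSE)
  list(expr = expr, truth = truth_genes)
}

#' Simulate a three-population resequencing dataset
#'
#' Draws per-population allele frequencies from a Balding-Nichols
#' construction calibrated to the configured pairwise F_ST targets,
#' genotypes each sample binomially given its ploidy (females carry one
#' Z), overlays non-recombining inversion haplotypes whose marker SNPs
#' sit at exactly carriers/total frequency in the carrier population,
#' plants an inversion-linked pseudogene variant set with an optional
#' stop-loss, and emits outgroup variation encoding a known parsimony
#' configuration at every site.
#'
#' @param config a [sim_config()].
#' @return object of class `hs_dataset` with components `sites`, `geno`
#'   (ALT-allele dosage matrix, sites x samples), `samples`, `scaffolds`,
#'   `ref`, `genes`, `outgroup`, `expr`, `expr_design`, and `truth`.
#' @export
simulate_dataset <- function(config) {
  validate_config(config)
  samples <- .build_samples(config$populations)
  popF <- solve_population_F(config$populations, config$background_fst)
  genome <- .sim_genome(config)
  degmap <- classify_degeneracy(genome$genes, genome$ref)

  # positions never hit by background/marker SNPs: start + stop codons
  forbidden <- list(); zero_fold_pos <- list()
  bg <- degmap$by_gene
  n_by_gene <- tapply(bg$cds_pos, bg$gene_id, max)
  terminal <- bg$cds_pos <= 3 | bg$cds_pos > (n_by_gene[bg$gene_id] - 3)
  for (scaf in config$scaffolds$name) {
    sel <- bg$scaffold == scaf
    forbidden[[scaf]] <- unique(bg$pos[sel & terminal])
    gsel <- degmap$genome$scaffold == scaf & degmap$genome$class == "zero_fold"
    zero_fold_pos[[scaf]] <- degmap$genome$pos[gsel]
  }

  parts <- lapply(seq_len(nrow(config$scaffolds)), function(i)
    .sim_scaffold_sites(config, i, samples, popF, genome$ref_bases,
                        forbidden, zero_fold_pos, genome$genes, degmap))
  sites <- do.call(rbind, lapply(parts, `[[`, "sites"))
  geno <- do.call(rbind, lapply(parts, `[[`, "geno"))
  outgroup <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(parts, `[[`, "outgroup")))
  truth_sites <- do.call(rbind, lapply(parts, `[[`, "truth"))
  rownames(sites) <- rownames(truth_sites) <- NULL
  colnames(geno) <- samples$sample

  # missing genotypes, if configured
  .set_stream(config$seed, "missing")
  for (pn in names(config$missing_rate)) {
    r <- config$missing_rate[[pn]]
    if (r > 0) {
      cols <- which(samples$population == pn)
      mask <- matrix(runif(nrow(geno) * length(cols)) < r,
                     nrow = nrow(geno))
      geno[, cols][mask] <- NA_integer_
    }
  }

  # pseudogene gene id (recomputed as in the scaffold pass)
  pg_gene <- truth_sites$inversion[match("pseudogene", truth_sites$site_type)]
  pg_gene_id <- NULL
  if (!is.na(pg_gene) && !is.null(config$pseudogene)) {
    pg_pos <- truth_sites$pos[truth_sites$site_type == "pseudogene"][1]
    pg_scaf <- truth_sites$scaffold[truth_sites$site_type == "pseudogene"][1]
    gdf <- genome$genes$genes
    hit <- gdf[gdf$scaffold == pg_scaf & gdf$start <= pg_pos & gdf$end >= pg_pos, ]
    pg_gene_id <- hit$gene_id[1]
  }

  ex <- .sim_expression(config, genome$genes, degmap, pg_gene_id)

  inv_truth <- lapply(config$inversions, function(inv) {
    counts <- .inv_sample_counts(inv, samples)
    scaf_i <- match(inv$scaffold, config$scaffolds$name)
    is_z <- config$scaffolds$is_z[scaf_i]
    ploidy <- unlist(lapply(seq_len(nrow(config$populations)), function(i)
      .sample_ploidy(config$populations[i, ], is_z)))
    carrier_pops <- names(inv$genotypes)
    per_pop <- lapply(carrier_pops, function(pn) {
      idx <- which(samples$population == pn)
      list(carriers = sum(counts[idx]), total = sum(ploidy[idx]),
           frequency = sum(counts[idx]) / sum(ploidy[idx]))
    })
    names(per_pop) <- carrier_pops
    list(id = inv$id, scaffold = inv$scaffold, start = inv$start, end = inv$end,
         sample_genotypes = counts, by_population = per_pop)
  })
  names(inv_truth) <- vapply(config$inversions, `[[`, character(1), "id")

  structure(list(config = config, samples = samples,
                 scaffolds = config$scaffolds, ref = genome$ref,
                 genes = genome$genes, degeneracy = degmap,
                 sites = sites, geno = geno, outgroup = outgroup,
                 expr = ex$expr, expr_design = config$expression_design,
                 truth = list(sites = truth_sites, inversions = inv_truth,
                              genes = ex$truth, population_F = popF,
                              pseudogene = pg_gene_id)),
            class = "hs_dataset")
}

#' Per-site, per-sample ploidy matrix
#'
#' Two chromosomes everywhere except Z-scaffold sites in females, which
#' carry a single Z.
#'
#' @param ds an `hs_dataset`.
#' @return integer matrix, sites x samples.
#' @export
ploidy_matrix <- function(ds) {
  female <- ds$samples$sex == "F"
  m <- matrix(2L, nrow = nrow(ds$sites), ncol = nrow(ds$samples),
              dimnames = list(NULL, ds$samples$sample))
  if (any(female) && any(ds$sites$is_z)) {
    m[ds$sites$is_z, female] <- 1L
  }
  m
}

#' @export
print.hs_dataset <- function(x, ...) {
  cat("<hs_dataset>\n")
  cat(sprintf("  %d sites x %d samples on %d scaffolds; %d genes\n",
              nrow(x$sites), nrow(x$samples), nrow(x$scaffolds),
              nrow(x$genes$genes)))
  cat("  populations:", paste(sprintf("%s (n=%d)",
      unique(x$samples$population),
      as.integer(table(x$samples$population)[unique(x$samples$population)])),
      collapse = ", "), "\n")
  invisible(x)
}
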