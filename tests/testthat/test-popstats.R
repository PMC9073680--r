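test_that("degeneracy classes follow the codon table", {
  tab <- codon_degeneracy_table()
  expect_equal(unname(tab["GGG", 3]), "four_fold")
  expect_equal(unname(tab["ATG", ]), rep("zero_fold", 3))
  # oracle: enumeration of the codon table gives 32 four-fold third positions
  expect_equal(sum(tab[, 3] == "four_fold"), 32)
  expect_equal(sum(tab[, 3] == "four_fold") / nrow(tab), 0.5)
})

test_that("strand is respected: a minus-strand gene classifies like its plus twin", {
  tgp <- toy_gene(300, "+", seed = 21)
  tgm <- toy_gene(300, "-", seed = 21)
  dp <- classify_degeneracy(tgp$genes, tgp$ref)
  dm <- classify_degeneracy(tgm$genes, tgm$ref)
  expect_equal(dp$by_gene$class[order(dp$by_gene$cds_pos)],
               dm$by_gene$class[order(dm$by_gene$cds_pos)])
  expect_equal(dp$site_counts$zero_fold, dm$site_counts$zero_fold)
  expect_equal(dp$site_counts$four_fold, dm$site_counts$four_fold)
})

test_that("broken CDS models are flagged and excluded", {
  tg <- toy_gene(300, "+")
  bad <- tg$genes
  bad$cds$end <- bad$cds$end - 1   # length no longer divisible by 3
  d <- classify_degeneracy(bad, tg$ref)
  expect_true("toy_gene" %in% d$excluded)
  expect_equal(nrow(d$by_gene), 0)
})

test_that("effect annotation matches a brute-force translate-and-compare oracle", {
  tg <- toy_gene(300, "+", seed = 31)
  gc <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  pos_all <- tg$start:(tg$start + 299)
  sites <- do.call(rbind, lapply(pos_all, function(p) {
    ref_b <- tg$bases[p]
    data.frame(scaffold = "toy_scaf", pos = p, ref = ref_b,
               alt = setdiff(c("A", "C", "G", "T"), ref_b),
               stringsAsFactors = FALSE)
  }))
  eff <- annotate_effect(sites, tg$genes, tg$ref)
  # oracle: substitute into the coding sequence, translate both, compare
  oracle_one <- function(pos, alt) {
    cds_i <- pos - tg$start + 1
    coding <- tg$coding
    coding2 <- coding; coding2[cds_i] <- alt
    ci <- (cds_i - 1) %/% 3 + 1
    ref_c <- paste0(coding[(3 * ci - 2):(3 * ci)], collapse = "")
    alt_c <- paste0(coding2[(3 * ci - 2):(3 * ci)], collapse = "")
    if (ref_c %in% stops && !(alt_c %in% stops)) "stop_loss"
    else if (!(ref_c %in% stops) && alt_c %in% stops) "stop_gain"
    else if (gc[ref_c] == gc[alt_c]) "synonymous"
    else "missense"
  }
  expected <- mapply(oracle_one, eff$pos, eff$alt)
  expect_equal(eff$effect, unname(expected))
  expect_gte(sum(eff$effect == "stop_loss"), 1)  # terminal codon is TAA
})

test_that("canonical stop substitutions are named", {
  tg <- toy_gene(300, "+", seed = 31)
  stop_mid <- tg$start + 298   # middle base of the terminal TAA (CDS pos 299)
  eff <- annotate_effect(data.frame(scaffold = "toy_scaf", pos = stop_mid,
                                    ref = "A", alt = "C"), tg$genes, tg$ref)
  expect_equal(eff$effect, "stop_loss")
  expect_equal(eff$codon_ref, "TAA")
  expect_equal(eff$codon_alt, "TCA")
  out <- annotate_effect(data.frame(scaffold = "toy_scaf", pos = 5,
                                    ref = tg$bases[5], alt = "A"),
                         tg$genes, tg$ref)
  expect_equal(out$effect, "non_coding")
})

test_that("degeneracy classes and effects are mutually consistent", {
  run <- shared_run()
  ds <- run$ds
  deg <- ds$degeneracy
  key <- paste(deg$genome$scaffold, deg$genome$pos)
  in_cds <- paste(ds$sites$scaffold, ds$sites$pos) %in% key
  sub <- ds$sites[in_cds, ][1:200, ]
  eff <- annotate_effect(sub, ds$genes, ds$ref)
  cls <- deg$genome$class[match(paste(eff$scaffold, eff$pos), key)]
  nonsyn <- c("missense", "stop_gain", "stop_loss")
  expect_true(all(eff$effect[cls == "zero_fold"] %in% nonsyn))
  expect_true(all(eff$effect[cls == "four_fold"] == "synonymous"))
})

test_that("pN and pS tally per gene and scale linearly", {
  deg <- list(site_counts = data.frame(gene_id = "g1", zero_fold = 600,
                                       four_fold = 200,
                                       stringsAsFactors = FALSE))
  eff <- data.frame(gene_id = "g1",
                    effect = c(rep("missense", 6), rep("synonymous", 10)),
                    stringsAsFactors = FALSE)
  gp <- gene_polymorphism(eff, deg)
  expect_equal(gp$per_gene$pN, 6 / 600)
  expect_equal(gp$per_gene$pS, 10 / 200)
  expect_equal(gp$per_gene$pNpS, (6 / 600) / (10 / 200))
  gp2 <- gene_polymorphism(rbind(eff, eff), deg)
  expect_equal(gp2$per_gene$pN, 2 * gp$per_gene$pN)
  expect_equal(gp2$per_gene$pS, 2 * gp$per_gene$pS)
  # no SNPs -> zero rates
  gp0 <- gene_polymorphism(eff[0, ], deg)
  expect_equal(gp0$per_gene$pN, 0)
  expect_equal(gp0$per_gene$pS, 0)
})

test_that("pi and Tajima's D match direct formula evaluation", {
  r <- pi_and_tajimas_d(integer(0), 16, n_sites = 100)
  expect_equal(r$pi, 0)
  expect_equal(r$D, 0)
  expect_false(r$D_defined)
  r1 <- pi_and_tajimas_d(8, 16, n_sites = 1)
  expect_equal(r1$pi, 0.5 * 16 / 15)
  expect_error(pi_and_tajimas_d(2, 3), "n < 4")
  # hand-checked constants at n = 10
  cst <- tajima_constants(10)
  expect_equal(cst$a1, sum(1 / 1:9))
  expect_equal(cst$b1, 11 / 27)
})

test_that("Tajima's D centers on zero under the neutral frequency spectrum", {
  set.seed(77)
  n <- 16; S <- 60
  reps <- 200
  d <- replicate(reps, {
    k <- sample(1:(n - 1), S, replace = TRUE, prob = 1 / (1:(n - 1)))
    pi_and_tajimas_d(k, n)$D
  })
  expect_lt(abs(mean(d)), 0.15)
})

test_that("purifying pressure at zero-fold sites depresses pi0 below pi4", {
  run <- shared_run()
  ds <- run$ds
  auto <- ds$scaffolds$name[!ds$scaffolds$is_z]
  gmap <- ds$degeneracy$genome
  class_sites <- table(gmap$class[gmap$scaffold %in% auto])
  fq <- run$freqs$NC
  keep <- fq$scaffold %in% auto & !is.na(fq$freq)
  n <- max(fq$n_chrom[keep])
  keep <- keep & fq$n_chrom == n
  cls <- gmap$class[match(paste(fq$scaffold, fq$pos)[keep],
                          paste(gmap$scaffold, gmap$pos))]
  k <- round(fq$freq[keep] * n)
  pi0 <- pi_and_tajimas_d(k[!is.na(cls) & cls == "zero_fold"], n,
                          as.integer(class_sites["zero_fold"]))$pi
  pi4 <- pi_and_tajimas_d(k[!is.na(cls) & cls == "four_fold"], n,
                          as.integer(class_sites["four_fold"]))$pi
  expect_lt(pi0, pi4)

  # drift-only generator: the two classes are statistically equivalent
  cfg <- sim_config(seed = 55, zero_fold_factor = 1, inversions = list(),
                    pseudogene = NULL, n_snps_per_scaffold = 3000,
                    genes_per_mb = 80)
  ds2 <- simulate_dataset(cfg)
  dec2 <- polarize_sites(ds2$sites, ds2$outgroup)
  fq2 <- population_frequencies(ds2, dec2)$NC
  gmap2 <- ds2$degeneracy$genome
  keep2 <- !is.na(fq2$freq) & fq2$n_chrom == max(fq2$n_chrom)
  cls2 <- gmap2$class[match(paste(fq2$scaffold, fq2$pos)[keep2],
                            paste(gmap2$scaffold, gmap2$pos))]
  k2 <- round(fq2$freq[keep2] * max(fq2$n_chrom))
  cs2 <- table(gmap2$class)
  p0 <- pi_and_tajimas_d(k2[!is.na(cls2) & cls2 == "zero_fold"],
                         max(fq2$n_chrom), as.integer(cs2["zero_fold"]))$pi
  p4 <- pi_and_tajimas_d(k2[!is.na(cls2) & cls2 == "four_fold"],
                         max(fq2$n_chrom), as.integer(cs2["four_fold"]))$pi
  expect_lt(abs(p0 - p4) / p4, 0.5)
})
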