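test_that("uniform lattice frequencies yield no tracts", {
  set.seed(4)
  T <- 16
  freqs <- data.frame(scaffold = "s", pos = sort(sample(1e6, 2000)),
                      freq = sample(seq_len(T - 1), 2000, replace = TRUE) / T)
  tr <- detect_tracts(freqs, T, min_span = 1e5)
  expect_equal(nrow(tr), 0)
  expect_error(detect_tracts(freqs, 3), "too coarse")
})

test_that("tract detection is invariant to a constant coordinate shift", {
  run <- shared_run()
  fq <- run$freqs$AZ
  rows <- fq$scaffold == "scaffold_12"
  t1 <- detect_tracts(fq[rows, ], 16)
  fq2 <- fq[rows, ]; fq2$pos <- fq2$pos + 12345L
  t2 <- detect_tracts(fq2, 16)
  expect_equal(t2$start, t1$start + 12345)
  expect_equal(t2$end, t1$end + 12345)
  expect_equal(t2$modal_k, t1$modal_k)
})

test_that("the autosomal inversion tract is recovered at 11/16 with high overlap", {
  run <- shared_run()
  fq <- run$freqs$AZ
  rows <- fq$scaffold == "scaffold_12"
  tr <- detect_tracts(fq[rows, ], 16, population = "AZ")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$modal_freq, 11 / 16)
  iv <- run$ds$truth$inversions$inv12
  expect_gte(jaccard(tr$start, tr$end, iv$start, iv$end), 0.8)
})

test_that("the Z inversion tract is recovered at 13/14 under hemizygosity", {
  run <- shared_run()
  fq <- run$freqs$AZ
  rows <- fq$scaffold == "scaffold_Z"
  tr <- detect_tracts(fq[rows, ], 14, population = "AZ")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$modal_freq, 13 / 14)
  iv <- run$ds$truth$inversions$invZ
  expect_gte(jaccard(tr$start, tr$end, iv$start, iv$end), 0.8)
})

test_that("samples are genotyped from tract-allele fractions with correct ploidy tally", {
  run <- shared_run()
  ds <- run$ds
  pl <- ploidy_matrix(ds)
  dec <- run$dec
  dd <- derived_dosage(ds$geno, dec, pl)
  az <- which(ds$samples$population == "AZ")
  fq <- run$freqs$AZ
  r12 <- which(ds$sites$scaffold == "scaffold_12")
  tr <- detect_tracts(fq[r12, ], 16, population = "AZ")
  cl <- genotype_samples(tr[1, ], fq, dd[, az], ds$sites, pl[r12[1], az])
  truth <- ds$truth$inversions$inv12$sample_genotypes[ds$samples$sample[az]]
  expect_equal(unname(cl$carrier_chromosomes), unname(truth))
  expect_equal(sum(cl$genotype == "hom_inverted"), 4)
  expect_equal(sum(cl$genotype == "het"), 3)
  expect_equal(sum(cl$genotype == "hom_ancestral"), 1)
  expect_equal(cl$frequency, 0.6875)
  # frequency sits on the tract's lattice value within half a lattice step
  expect_lte(abs(cl$frequency - tr$modal_freq[1]), 1 / (2 * cl$total))

  # Z: hemizygous females are carrier/non-carrier and contribute one
  # chromosome; total respects ploidy
  rz <- which(ds$sites$scaffold == "scaffold_Z")
  trz <- detect_tracts(fq[rz, ], 14, population = "AZ")
  clz <- genotype_samples(trz[1, ], fq, dd[, az], ds$sites, pl[rz[1], az])
  sex <- ds$samples$sex[az]
  expect_true(all(clz$genotype[sex == "F"] %in% c("carrier", "non_carrier")))
  expect_equal(clz$total, 2 * sum(sex == "M") + sum(sex == "F"))
  expect_equal(clz$carriers, 13)
  expect_equal(clz$frequency, 13 / 14)
})

test_that("a sample carrying the derived allele on every tract haplotype is hom_inverted", {
  freqs <- data.frame(scaffold = "s", pos = seq(1000, 200000, by = 1000),
                      freq = 0.5)
  tr <- data.frame(scaffold = "s", start = 0, end = 200000, modal_k = 8L,
                   modal_freq = 0.5, n_modal = 200L, n_snps = 200L,
                   population = "X")
  n_sites <- nrow(freqs)
  dd <- cbind(full = rep(2L, n_sites), none = rep(0L, n_sites),
              half = rep(1L, n_sites))
  cl <- genotype_samples(tr, freqs, dd, freqs[, c("scaffold", "pos")],
                         c(full = 2L, none = 2L, half = 2L))
  expect_equal(unname(cl$genotype), c("hom_inverted", "hom_ancestral", "het"))
})

test_that("inversion frequency survives 5% genotype missingness within a lattice step", {
  cfg <- sim_config(seed = 101, missing_rate = c(NC = 0.05, KS = 0.05, AZ = 0.05))
  ds <- simulate_dataset(cfg)
  dec <- polarize_sites(ds$sites, ds$outgroup)
  pl <- ploidy_matrix(ds)
  dd <- derived_dosage(ds$geno, dec, pl)
  fq <- population_frequencies(ds, dec)$AZ
  az <- which(ds$samples$population == "AZ")
  r12 <- which(ds$sites$scaffold == "scaffold_12")
  tr <- detect_tracts(fq[r12, ], 16, population = "AZ")
  expect_equal(tr$modal_freq[1], 11 / 16)
  cl <- genotype_samples(tr[1, ], fq, dd[, az], ds$sites, pl[r12[1], az])
  expect_lte(abs(cl$frequency - 11 / 16), 1 / (2 * cl$total))
})

test_that("carrier-state concordance counts matching samples", {
  run <- shared_run()
  ds <- run$ds
  pl <- ploidy_matrix(ds)
  dd <- derived_dosage(ds$geno, run$dec, pl)
  az <- which(ds$samples$population == "AZ")
  fq <- run$freqs$AZ
  r12 <- which(ds$sites$scaffold == "scaffold_12")
  tr <- detect_tracts(fq[r12, ], 16, population = "AZ")
  cl <- genotype_samples(tr[1, ], fq, dd[, az], ds$sites, pl[r12[1], az])
  # variant copied from the inversion genotypes co-segregates perfectly
  v <- cl$carrier_chromosomes
  expect_equal(concordance(cl, v, setNames(pl[r12[1], az], names(v))), 1.0)
  # shuffling breaks co-segregation; oracle = exhaustive matching count
  set.seed(2)
  perm <- sample(seq_along(v))
  v2 <- setNames(v[perm], names(v))
  expected <- mean(v2[names(v)] == v)
  expect_equal(concordance(cl, v2, setNames(pl[r12[1], az], names(v))), expected)
  expect_lt(expected, 1)
  # single-sample input with matching state
  cl1 <- cl; cl1$genotype <- cl$genotype[1]; cl1$carrier_chromosomes <- cl$carrier_chromosomes[1]
  expect_equal(concordance(cl1, v[1], c(AZ01 = 2L)), 1.0)
})

test_that("LD r^2 behaves at its limits and is elevated inside inversions", {
  # perfectly co-segregating pair
  g <- rbind(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2))
  sites <- data.frame(scaffold = "s", pos = c(10, 20))
  ld <- tract_ld_profile(g, sites, window = 50)
  expect_equal(ld$mean_r2[1], 1)
  # independent SNPs: mean r^2 ~ 1/(n-1)
  set.seed(6)
  n <- 120
  gi <- matrix(rbinom(40 * n, 2, 0.5), nrow = 40)
  ldi <- tract_ld_profile(gi, data.frame(scaffold = "s", pos = 1:40),
                          window = 40)
  expect_lt(abs(ldi$mean_r2[1] - 1 / (n - 1)), 0.01)
  # elevated inside the inversion in every population, carriers or not
  run <- shared_run()
  ds <- run$ds
  iv <- ds$truth$inversions$inv12
  r12 <- which(ds$sites$scaffold == "scaffold_12")
  for (p in c("NC", "KS", "AZ")) {
    cols <- which(ds$samples$population == p)
    ld <- tract_ld_profile(ds$geno[r12, cols], ds$sites[r12, ], window = 10000)
    ins <- ld$start >= iv$start & ld$end <= iv$end
    expect_gt(mean(ld$mean_r2[ins], na.rm = TRUE),
              mean(ld$mean_r2[!ins], na.rm = TRUE))
  }
})

test_that("printed breakpoints give the reported inversion lengths", {
  expect_equal(breakpoint_span(5414046, 13233866), 7819820)
  expect_equal(round(breakpoint_span(5414046, 13233866) / 1e6, 2), 7.82)
  expect_equal(breakpoint_span(13706400, 14710588), 1004188)
})

test_that("carrier tallies follow from genotype class counts", {
  cf <- carrier_frequency(hom_inverted = 4, het = 3, hom_ancestral = 1)
  expect_identical(cf$carriers, 11)
  expect_identical(cf$total, 16)
  expect_equal(cf$frequency, 0.6875)
  cfz <- carrier_frequency(hom_inverted = 5, het = 1, hemi_carrier = 2)
  expect_equal(cfz$frequency, 13 / 14)
})
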