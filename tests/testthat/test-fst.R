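test_that("Hudson components match direct evaluation of the formulas", {
  # oracle: hand evaluation
  comp <- site_fst(0.5, 16, 0, 24)
  expect_equal(comp$num, 0.25 - 0.25 / 15)
  expect_equal(comp$den, 0.5)
  # fixed difference drives the ratio to 1 at large n
  comp <- site_fst(1, 1e6, 0, 1e6)
  expect_equal(comp$num / comp$den, 1, tolerance = 1e-5)
  # identical fixed alleles are uninformative (0/0)
  comp <- site_fst(1, 10, 1, 10)
  expect_equal(comp$den, 0)
  expect_error(site_fst(0.5, 1, 0.5, 10), "at least 2 chromosomes")
})

test_that("windowed F_ST is a ratio of sums", {
  sites <- data.frame(scaffold = "s", pos = c(100, 200, 300),
                      num = c(0.2, 0.1, 0.0), den = c(0.5, 0.5, 0.2))
  w <- windowed_fst(sites, c(s = 1000), window = 1000, step = 1000,
                    min_snps = 1)
  expect_equal(nrow(w), 1)
  expect_equal(w$fst, 0.3 / 1.2)
  # identical frequencies across populations give ~0
  comp <- site_fst(rep(0.3, 50), 20, rep(0.3, 50), 20)
  sites0 <- data.frame(scaffold = "s", pos = seq(10, 500, by = 10),
                       num = comp$num, den = comp$den)
  w0 <- windowed_fst(sites0, c(s = 500), window = 500, step = 500, min_snps = 1)
  # identical sample frequencies leave only the (negative) finite-sample
  # correction terms: -p(1-p)(1/(n1-1) + 1/(n2-1)) per site
  expect_lt(abs(w0$fst), 0.06)
  expect_error(windowed_fst(data.frame(scaffold = "s", pos = c(5, 2),
                                       num = 0, den = 1), c(s = 10)),
               "sorted")
})

test_that("ratio-of-sums aggregation is invariant to splitting the site list", {
  set.seed(9)
  n <- 200
  p1 <- runif(n); p2 <- runif(n)
  comp <- site_fst(p1, 16, p2, 24)
  whole <- sum(comp$num) / sum(comp$den)
  idx <- sample(rep(1:4, length.out = n))
  parts <- lapply(1:4, function(k)
    c(num = sum(comp$num[idx == k]), den = sum(comp$den[idx == k])))
  split_sum <- sum(vapply(parts, `[[`, numeric(1), "num")) /
    sum(vapply(parts, `[[`, numeric(1), "den"))
  expect_equal(whole, split_sum)
})

test_that("windows tile each scaffold with the expected multiplicity", {
  empty_sites <- data.frame(scaffold = character(0), pos = integer(0),
                            num = numeric(0), den = numeric(0))
  w <- windowed_fst(empty_sites, c(s = 50000), window = 10000, step = 5000,
                    min_snps = 1)
  # every interior bp is covered by window/step windows
  probe <- c(17000, 25000, 33000)
  for (bp in probe) {
    expect_equal(sum(w$start < bp & w$end >= bp), 2)
  }
  expect_true(all(w$end <= 50000))
  # terminal partial windows flagged
  w2 <- windowed_fst(empty_sites, c(s = 12000), window = 10000, step = 5000,
                     min_snps = 1)
  expect_true(any(w2$partial))
})

test_that("outlier windows merge into maximal regions", {
  none <- merge_outliers(data.frame(scaffold = "s", start = 0, end = 10000,
                                    n_snps = 10L, fst = 0.3, partial = FALSE,
                                    comparison = "a-b"))
  expect_equal(nrow(none), 0)
  w <- data.frame(scaffold = "s", start = c(0, 5000), end = c(10000, 15000),
                  n_snps = 10L, fst = c(0.6, 0.7), partial = FALSE,
                  comparison = "a-b")
  r <- merge_outliers(w)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 0)
  expect_equal(r$end, 15000)
  expect_equal(r$peak_fst, 0.7)
})

test_that("genome-wide estimate degenerates to the single-site ratio", {
  s <- data.frame(scaffold = "s", pos = 1, num = 0.2, den = 0.5)
  expect_equal(genome_wide_fst(s), 0.4)
})

test_that("a population split in half shows no differentiation against itself", {
  run <- shared_run()
  ds <- run$ds
  nc <- which(ds$samples$population == "NC")
  set.seed(1)
  half <- sample(nc, length(nc) / 2)
  auto <- !ds$sites$is_z
  bg <- run$ds$truth$sites$site_type == "background"
  sel <- auto & bg
  freq_of <- function(cols) {
    d <- ds$geno[sel, cols, drop = FALSE]
    rowSums(d) / (2 * length(cols))
  }
  p1 <- freq_of(half); p2 <- freq_of(setdiff(nc, half))
  keep <- (p1 + p2) > 0 & (p1 + p2) < 2
  comp <- site_fst(p1[keep], 2 * length(half), p2[keep], 2 * length(half))
  fst <- sum(comp$num) / sum(comp$den)
  expect_lt(abs(fst), 0.03)
})

test_that("Hudson estimates recover the Balding-Nichols targets within 0.02", {
  cfg <- neutral_config()
  ds <- simulate_dataset(cfg)
  expect_gte(nrow(ds$sites), 5000)
  dec <- polarize_sites(ds$sites, ds$outgroup)
  scan <- fst_scan(ds, dec)
  for (pr in names(cfg$background_fst)) {
    expect_lt(abs(scan$genome_wide[[pr]] - cfg$background_fst[[pr]]), 0.02)
  }
})

test_that("genotype PCA matches a direct covariance eigendecomposition", {
  g <- matrix(c(0, 1, 2, 0,
                2, 1, 0, 1,
                1, 2, 0, 2,
                0, 0, 2, 2,
                1, 1, 1, 0), nrow = 5, byrow = TRUE)  # 5 sites x 4 samples
  sites <- data.frame(scaffold = "s", pos = 1:5)
  pc <- genotype_pca(g, sites, n_components = 2)
  m <- scale(t(g), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(m))
  scores_oracle <- m %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    expect_equal(abs(pc$scores[, j]), abs(scores_oracle[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # duplicated samples land on identical coordinates
  g2 <- cbind(g, g[, 2])
  pc2 <- genotype_pca(g2, sites, n_components = 2)
  expect_equal(pc2$scores[2, ], pc2$scores[5, ], ignore_attr = TRUE)
  # sign convention makes coordinates deterministic
  pc3 <- genotype_pca(g, sites, n_components = 2)
  expect_identical(pc$scores, pc3$scores)
})

test_that("inversion-poor AZ samples drift toward KS only when the inversion scaffold is present", {
  run <- shared_run()
  ds <- run$ds
  z <- ds$scaffolds$name[ds$scaffolds$is_z]
  pc_in <- genotype_pca(ds$geno, ds$sites, exclude = z)
  pc_ex <- genotype_pca(ds$geno, ds$sites, exclude = c(z, "scaffold_12"))
  pop <- ds$samples$population
  g12 <- ds$truth$inversions$inv12$sample_genotypes[ds$samples$sample]
  rel_ks <- function(pc) {
    s <- pc$scores[, 1:2]
    ks_c <- colMeans(s[pop == "KS", , drop = FALSE])
    hom_c <- colMeans(s[pop == "AZ" & g12 == 2, , drop = FALSE])
    idx <- which(pop == "AZ" & g12 <= 1)
    dk <- sqrt(colSums((t(s[idx, , drop = FALSE]) - ks_c)^2))
    dh <- sqrt(colSums((t(s[idx, , drop = FALSE]) - hom_c)^2))
    setNames(dk / (dk + dh), ds$samples$sample[idx])
  }
  r_in <- rel_ks(pc_in); r_ex <- rel_ks(pc_ex)
  # every het/non-carrier sample moves toward KS when the inversion is in
  expect_true(all(r_in < r_ex))
  # the non-carrier sits closer to KS than to inverted homozygotes only
  # with the inversion included
  non_carrier <- which(names(r_in) == "AZ08")
  expect_lt(r_in[non_carrier], 0.5)
  expect_gt(r_ex[non_carrier], 0.5)
})
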