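# Independent rule-table oracle: a literal re-statement of the four
# parsimony rules over explicit allele sets, written without reference
# to the implementation's set algebra.
oracle_polarize <- function(ref, alt, og_alleles) {
  if (length(og_alleles) == 0 || identical(sort(og_alleles), ref)) {
    return(list(verdict = "reference_ancestral", ancestral = ref))
  }
  focal <- c(ref, alt)
  if (all(og_alleles %in% focal) && alt %in% og_alleles) {
    return(list(verdict = "alternate_ancestral", ancestral = alt))
  }
  if (length(og_alleles) >= 2) {
    shared <- og_alleles[og_alleles %in% focal]
    if (length(shared) == 1) {
      return(list(verdict = "shared_allele_ancestral", ancestral = shared))
    }
  }
  list(verdict = "masked", ancestral = "N")
}

test_that("parsimony rules reproduce the documented worked cases", {
  # outgroup invariant: reference ancestral
  d <- classify_site(list(scaffold = "s", pos = 10, ref = "T", alt = "C"), NULL)
  expect_equal(d$verdict, "reference_ancestral")
  expect_equal(d$ancestral, "T")
  # tri-allelic with shared alternate: shared allele ancestral
  d <- classify_site(list(scaffold = "s", pos = 10, ref = "T", alt = "C"),
                     list(alleles = c("G", "C")))
  expect_equal(d$verdict, "shared_allele_ancestral")
  expect_equal(d$ancestral, "C")
  # outgroup alternate matches focal alternate: alternate ancestral
  d <- classify_site(list(scaffold = "s", pos = 10, ref = "T", alt = "C"),
                     list(alleles = "C"))
  expect_equal(d$verdict, "alternate_ancestral")
  expect_equal(d$ancestral, "C")
  # conflicting outgroup allele: no most-parsimonious solution
  d <- classify_site(list(scaffold = "s", pos = 10, ref = "T", alt = "C"),
                     list(alleles = "G"))
  expect_equal(d$verdict, "masked")
  expect_equal(d$ancestral, "N")
})

test_that("classifier agrees with the exhaustive rule-table oracle", {
  nts <- c("A", "C", "G", "T")
  og_configs <- c(list(character(0)),
                  lapply(nts, identity),
                  combn(nts, 2, simplify = FALSE))
  n_checked <- 0
  for (ref in nts) for (alt in setdiff(nts, ref)) for (og in og_configs) {
    d <- classify_site(list(scaffold = "s", pos = 1, ref = ref, alt = alt),
                       if (length(og)) list(alleles = og) else NULL)
    o <- oracle_polarize(ref, alt, og)
    expect_equal(d$verdict, o$verdict,
                 info = sprintf("ref=%s alt=%s og={%s}", ref, alt,
                                paste(og, collapse = ",")))
    expect_equal(d$ancestral, o$ancestral)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 4 * 3 * 11)
})

test_that("masked verdict and ancestral N are equivalent, ancestral stays in the allele set", {
  run <- shared_run()
  dec <- run$dec
  expect_true(all((dec$verdict == "masked") == (dec$ancestral == "N")))
  ok <- dec$verdict != "masked"
  expect_true(all(dec$ancestral[ok] == dec$ref[ok] |
                    dec$ancestral[ok] == dec$alt[ok]))
})

test_that("ancestral reference is rebuilt with correct counts, verified by base-level diff", {
  set.seed(3)
  L <- 60
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  ref <- Biostrings::DNAStringSet(paste0(bases, collapse = ""))
  names(ref) <- "s"
  pos <- seq(3, 57, by = 6)[1:10]
  alt <- vapply(bases[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1))
  verdict <- c(rep("alternate_ancestral", 4), rep("shared_allele_ancestral", 3),
               rep("masked", 3))
  dec <- data.frame(scaffold = "s", pos = pos, ref = bases[pos], alt = alt,
                    verdict = verdict,
                    ancestral = ifelse(verdict == "masked", "N", alt),
                    stringsAsFactors = FALSE)
  out <- build_ancestral_reference(ref, dec)
  expect_equal(out$counts$updated, 7)
  expect_equal(out$counts$masked, 3)
  expect_equal(out$counts$unchanged, 0)
  # oracle: character-level diff of the two sequences
  new_bases <- strsplit(as.character(out$ancestral[[1]]), "")[[1]]
  diff_pos <- which(new_bases != bases)
  expect_setequal(diff_pos, pos)
  expect_equal(sum(new_bases == "N"), 3)
  expect_true(all(new_bases[dec$pos[dec$verdict == "masked"]] == "N"))
})

test_that("zero decisions leave the reference untouched", {
  ref <- Biostrings::DNAStringSet(c(s = "ACGTACGT"))
  dec <- data.frame(scaffold = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    verdict = character(0), ancestral = character(0))
  out <- build_ancestral_reference(ref, dec)
  expect_equal(as.character(out$ancestral), as.character(ref))
  expect_equal(unlist(out$counts), c(unchanged = 0, updated = 0, masked = 0))
})

test_that("polarized frequencies flip with the ancestral assignment", {
  d_ref <- list(verdict = "reference_ancestral", ref = "T", alt = "C",
                ancestral = "T")
  d_alt <- list(verdict = "alternate_ancestral", ref = "T", alt = "C",
                ancestral = "C")
  expect_equal(polarized_frequency(11, 16, d_ref), 0.6875)
  expect_equal(polarized_frequency(11, 16, d_alt), 5 / 16)
  expect_equal(polarized_frequency(0, 16, d_ref), 0)
  expect_true(is.na(polarized_frequency(
    3, 8, list(verdict = "masked", ref = "T", alt = "C", ancestral = "N"))))
  expect_warning(polarized_frequency(0, 0, d_ref), "no called chromosomes")
})

test_that("inferred ancestral alleles match simulation truth at non-masked sites", {
  run <- shared_run()
  tr <- run$ds$truth$sites
  ok <- run$dec$verdict != "masked"
  expect_gte(mean(run$dec$ancestral[ok] == tr$ancestral[ok]), 0.99)
  # the generator's outgroup cases map onto the verdicts
  expect_true(all(run$dec$verdict[tr$outgroup_case == "masked"] == "masked"))
})
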