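---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models each
module implements, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a
choice had to be made.

## The study system

The package implements the inference chain for a three-population
resequencing design in the tobacco hornworm: 12 North Carolina males,
4 Kansas moths (1 male, 3 females), and 8 Arizona moths (6 males,
2 females). Lepidopteran females are ZW, so a female contributes one Z
chromosome to allele counts; on the autosomes every diploid contributes
two. The biological signals of interest are two segregating inversions
nearly private to the Arizona-like population — a large autosomal one
carried on 11 of 16 sampled chromosomes and a Z-linked one on 13 of 14 —
and a stop-loss variant inside the autosomal inversion that
co-segregates perfectly with it, the signature of a pseudogenizing
olfactory gene riding a locally adaptive rearrangement.

## Polarization by outgroup parsimony

`classify_site()` applies four rules against a single outgroup
genotype: (1) outgroup invariant → reference ancestral; (2) outgroup
alternate equals the focal alternate → alternate ancestral; (3) a
heterozygous outgroup carrying an allele outside the focal pair but
sharing exactly one allele with it → the shared allele ancestral;
(4) otherwise masked to N and dropped downstream.

Open points resolved here:

- **Homozygous-alternate outgroups** are folded into rule 2 together
  with heterozygous reference/alternate outgroups: in both cases the
  focal alternate is observed in the outgroup and parsimony favors it
  as ancestral. Rule 3 is reserved for genotypes carrying a third
  allele.
- **Multi-allelic focal records** are decomposed per alternate; if the
  per-alternate verdicts disagree about the ancestral base the site is
  masked — the conservative reading of rule 4.
- **Indels** are not polarized (the chain analyzes SNPs); they pass
  through untouched.
- Coordinates are 1-based (VCF convention) throughout this module;
  0-based half-open intervals appear only at window/region construction.

An exhaustive rule-table oracle over every reference/alternate/outgroup
allele combination backs the implementation in the test suite.

## F_ST: estimator choice

The scan uses the Hudson estimator (Bhatia et al. ratio-of-sums form)
computed from called genotypes: per site the numerator is
$(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$ and
the denominator $p_1(1-p_2)+p_2(1-p_1)$; windows, scaffolds, and
genome-wide values are always sums of numerators over sums of
denominators, never means of per-site ratios. This is a deliberate
divergence from genotype-likelihood/SFS machinery (ANGSD-style): at the
coverages this design assumes (14–26×), hard calls are a faithful
desk-scale substitute, but absolute values can differ slightly from
SFS-based estimates; the estimator is therefore documented prominently
and the package never claims numeric equivalence with likelihood-based
scans on real data.

Window parameters: 10 kb windows, 5 kb step, anchored at position 0 of
each scaffold; terminal partial windows are retained and flagged.
Windows with fewer than 5 informative SNPs are reported missing — on
sparse simulations the ratio is otherwise unstable. The outlier
threshold is F_ST > 0.5, and super-threshold windows merge
(overlapping or abutting) into maximal regions.

The genotype PCA used for structure checks fixes component signs by
forcing each component's largest-magnitude loading positive, so
coordinates are deterministic; the Z is excluded by default because
unequal sex sampling between populations would masquerade as structure.

## Inversion detection and genotyping

The detector looks for the frequency-lattice signature of a
non-recombining haplotype: runs of SNPs sharing one modal frequency
k/T. Parameters and their rationale:

- `min_span` = 100 kb. The real signals span ~8 Mb and ~1 Mb on 21–14 Mb
  chromosomes; at the package's 1/16 desk scale (1 Mb autosomes, 500 kb
  Z) the seeded tracts span 500 kb and 200 kb, and 100 kb keeps the
  detector sensitive without admitting background runs.
- `min_modal_fraction` = 0.6: inside a real inversion most, but not
  all, polymorphic sites sit at the modal value (new mutations on
  either orientation dilute it).
- `max_gap_snps` (default `ceiling(3/min_modal_fraction)`): a local
  gap cap, without which isolated background sites that happen to hit
  the modal lattice value drag the tract boundary outward — the global
  fraction decays too slowly to stop them.
- Runs at frequency 0 or 1 are ignored (no information), and
  populations with fewer than 4 sampled chromosomes are refused: the
  lattice is too coarse to distinguish a tract from noise.

Genotype classes come from the fraction of tract-defining derived
alleles a sample carries: < 0.25 homozygous ancestral, 0.25–0.75
heterozygous, > 0.75 homozygous inverted (hemizygous samples split at
0.5). The wide heterozygote band is robust to sporadic genotyping error
across hundreds of tract SNPs. Samples missing more than half the
tract SNPs are reported unknown and excluded from the frequency.

Breakpoint arithmetic on printed coordinates uses `end − start` of the
1-based breakpoints (so 5,414,046–13,233,866 → 7,819,820 bp ≈ 7.82 Mb
and 13,706,400–14,710,588 → 1,004,188 bp), matching how such intervals
are conventionally reported. Read-pair breakpoint detection itself is
out of scope; printed breakpoints are treated as interval inputs only.

## Population summary statistics

Degeneracy classes come from the standard nuclear codon table: a CDS
position is 4-fold if every substitution preserves the amino acid,
0-fold if none does, `other` otherwise (stops act as a 21st residue).
Genes whose joined CDS is not a multiple of three, lacks a terminal
stop, or contains an internal stop are flagged and excluded. Positions
covered by overlapping genes with conflicting classes are dropped from
the genome-level map but kept per gene.

π uses the unbiased per-site heterozygosity $2p(1-p)\frac{n}{n-1}$ and
is reported per site of the class (monomorphic sites count in the
denominator). Tajima's D follows the standard 1989 constants, computed
from called genotypes at complete-case sites with a fixed n per
population — again a documented divergence from likelihood-based
estimates. D is reported as 0 and flagged undefined when S = 0; n < 4
is refused because the variance terms are unstable.

pN and pS are per-gene counts of nonsynonymous/synonymous segregating
SNPs over 0-fold/4-fold site counts, with medians across genes (robust
to outlier genes); pN/pS is only defined where pS > 0. On sparse
simulated data most genes carry no SNPs and the medians sit at zero —
the per-gene table is the informative output there.

## Anchoring by synteny votes

Votes are weighted by aligned bases rather than raw counts of aligned
old scaffolds; tiny fragmented scaffolds otherwise dominate. Both
tallies are emitted so either rule can be audited. A runner-up
chromosome within 0.2 of the top vote flags the call; if the two
chromosomes' intervals occupy disjoint parts of the scaffold
(interleaving fraction ≤ 0.1 at the best single cut) the pattern is a
fusion or chimera and the call keeps the top chromosome with a
`split_synteny` flag, otherwise it is ambiguous. External evidence
(e.g. cytogenetic mapping) enters only through the override table,
which preserves the pre-override call and adds a `manual_override`
flag.

## Expression specificity

SPM for a category is implemented as the linear proportion of category
means — this matches the "proportion of a gene's expression" definition
and its worked example (a gene with adult SPM 0.90 shows 90% of its
expression in adults). The squared-expression form found elsewhere in
the specificity literature is available via `squared = TRUE` but is not
the default. The stage dimension is restricted to tissues sampled in
all three stages (head, midgut, fat body); the sex dimension uses only
sexed libraries. Labels use the 70% threshold. Enrichment tests are
plain Pearson χ² on the 2 × k region-by-class table with df = k − 1
(sex 3 classes → df 2, stage 4 → df 3, tissue 8 → df 7); p-values are
reported raw, matching a design with a handful of planned tests, with
no multiple-testing correction by default.

The availability design shipped as the default reconstructs the
emulated RNA-seq compendium from its description: head/midgut/fat in
all stages, sexed gonads in pupa and adult, sexed adult antennae, a
pooled larval antenna library, pooled muscle and Malpighian tubes where
sampled. It is a reconstruction, not a copy of any published table.

## The synthetic-data generator

The generator's defaults are the study conditions: the sample design
above; pairwise background F_ST targets 0.064 (NC–KS), 0.090 (NC–AZ),
0.041 (KS–AZ); the autosomal inversion at genotypes
(4 hom, 3 het, 1 ancestral) = 11/16; the Z inversion with a single
non-carrier chromosome = 13/14; and a 61-SNP linked pseudogene variant
set including a stop-loss in the terminal codon.

Key constructions and their rationale:

- **Balding–Nichols calibration.** Each site draws an ancestral
  frequency p ~ U(0.05, 0.95) and population frequencies from
  Beta(p(1−F)/F, (1−p)(1−F)/F). With independent draws,
  E[Hudson F_ST] between two populations is (F_i + F_j)/2, so
  per-population F values are solved from the pairwise targets by a
  linear system (exact for three populations). Arbitrary per-pair
  targets cannot be realized by per-pair draws with three populations,
  which is why the solve replaces a literal per-pair construction.
- **Inversion interiors.** The non-recombining interval segregates as
  whole haplotypes: one shared inverted haplotype plus a pool of three
  ancestral haplotypes *common to all populations*, drawn once from
  the ancestral frequency. Populations differ only in haplotype
  composition. This yields (i) marker SNPs at exactly carriers/total
  in the carrier population, (ii) elevated linkage disequilibrium
  inside the interval in every population, and (iii) no artificial
  divergence between non-carrier populations — a single shared
  ancestral haplotype per population would instead create constant
  frequency tracts and spurious F_ST in populations that do not carry
  the inversion at all.
- **Scaled genome.** 1 Mb autosomes and a 500 kb Z, with the autosomal
  inversion spanning 50% of its scaffold (mirroring roughly half of
  the real chromosome) and the Z inversion 40%. Background density is
  2 SNPs/kb, marker density 3/kb — enough that the modal fraction
  inside a tract clears the 0.6 detector floor.
- **Polarization cases.** Each background SNP is assigned an outgroup
  configuration (80% reference-ancestral, 10% alternate-ancestral, 5%
  tri-allelic shared, 5% unresolvable) and the outgroup VCF encodes
  it; the truth table stores the real ancestral base, so polarization
  accuracy is measurable (it is 1.0 by construction — the generator
  plants no homoplasy).
- **Selection proxy.** Derived frequencies at 0-fold sites are scaled
  by 0.15, producing the π₀ < π₄ pattern; setting the factor to 1
  gives the drift-only control where π₀ ≈ π₄.
- **Seeding.** One master seed fans out to named substreams (a string
  hash added to a multiplied seed), so adding a component never shifts
  another component's draws and every run is reproducible.
- **Expression.** Each gene gets a true class per dimension;
  condition-level means are products of per-dimension weights
  (specific classes concentrate ~90% of expression) with mild
  log-normal noise, rounded to 6 decimals so file round-trips are
  exact. Genes inside the Z inversion are seeded with an excess of
  sex-unbiased genes (90% vs 50% background), mirroring the
  feminization-shelter hypothesis the enrichment test probes; the
  pseudogene is forced to larval/antennal expression.

What the generator does **not** emulate: coalescent genealogies,
recombination maps or gene conversion, sequencing reads, base-calling
or mapping error, reference bias, indels and structural variants other
than the two inversions, and real linkage outside inversion intervals
(background SNPs are independent given their frequencies). Passing
tests therefore demonstrate estimator and detector correctness under
the assumed statistical structure, not robustness to artifacts of real
pipelines. Counts that depend on the real data (genome-wide site
tallies, the exact per-population summary values) are not reproducible
here and are not claimed.

One deliberate asymmetry: in the real system the pseudogene carries a
handful of coding polymorphisms even in the non-carrier populations;
the generator plants none (all 61 linked SNPs copy the inversion
genotype). The modeled feature is the perfect co-segregation, not the
exact minor counts.

At this scale the two inversions are a large fraction of the simulated
genome, so *genome-wide* F_ST for comparisons involving the carrier
population is visibly inflated relative to the background targets; the
calibration property is therefore stated (and tested) on inversion-free
configurations.

## Numerical choices and degenerate inputs

- Frequencies are mapped to the lattice by `round(freq * T)`; with 5%
  missingness the recovered inversion frequency stays within half a
  lattice step of truth.
- `site_fst` excludes sites with fewer than 2 chromosomes per
  population; windows below the SNP floor are missing, not zero.
- PCA imputes missing dosages with site means and drops monomorphic
  sites; a constant matrix is refused.
- χ² classes with zero total count are collapsed with a warning
  (reducing df) rather than producing NaN.
- The Z heterozygous-male default for the single non-carrier Z
  chromosome is arbitrary — a non-carrier female gives the same 13/14 —
  and is documented rather than hidden.

## Problem sizes

The shipped tests and the acceptance script run on the desk-scale
defaults: ~7,200 SNPs × 24 samples across 2.5 Mb and 100 genes, with
calibration checks on ~6,000 neutral SNPs and 200-replicate null
distributions for Tajima's D. These sizes were chosen so the full
chain exercises every code path in seconds while keeping Monte-Carlo
error well inside the stated tolerances (±0.02 on F_ST calibration,
±0.15 on the null mean of D).
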