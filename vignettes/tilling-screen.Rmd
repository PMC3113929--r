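---
title: "Modeling TILLING screens in an allotetraploid"
author: "tillploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TILLING screens in an allotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillploid)
```

# The problem

TILLING identifies induced point mutations in a mutagenized population by
CEL1 cleavage of heteroduplexes formed between mutant and wild-type PCR
products. In an allotetraploid, every gene of interest exists as two
homeologous copies, one per ancestral subgenome, typically >95% identical.
Screening them together is hopeless — every fixed inter-copy difference
would cleave — so the screen must first achieve single-copy resolution:
an unlabeled outer PCR enriches the gene family, and a labeled inner PCR
with primers anchored on copy-discriminating indels amplifies exactly one
homeolog. `tillploid` implements the downstream computation of such a
screen end to end, together with a synthetic-data generator that stands in
for a real mutagenized population.

This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic data do and do
not capture.

# Coordinate systems

All mutation arithmetic is anchored at the start codon. A `GeneModel`
stores the locus sequence (always on the plus strand; reverse-strand genes
are reverse-complemented at load, which removes a whole class of strand
errors), the number of bases 5' of the ATG (`upstream_len`), and the CDS
exon intervals. Three coordinate systems are interconverted:

* *locus*: 1-based on the stored sequence;
* *ATG-anchored*: position 1 is the A of ATG; upstream positions are
  negative with **no position 0** (−1 abuts +1), so `atgToLocus(-315, gm)`
  with 400 bp of upstream sequence is locus 86;
* *CDS*: 1-based offsets in the concatenated coding sequence, the system
  in which codon numbers live (`codonIndex(p)` is `ceiling(p / 3)`).

For intron-bearing genes, catalogued coordinates larger than the CDS
position implied by the residue number are interpreted as ATG-anchored
*locus* coordinates with introns included; for intronless genes the two
systems coincide. This is the only reading under which a change at
position 1392 can fall in codon 333 (1392 − 333·3 + 3 = 395 intronic bases
precede it) while a change at 448 falls in codon 150 of an intronless ORF.

# The mutagenesis model

`simulateM2(loci, n, params, seed)` draws, per M1 plant and locus, a
Poisson number of induced mutations with mean `density × locus length`.

* `density` (mutations/bp/M1 plant) defaults to `4 / (3 × 966000)`
  ≈ 1.38 × 10⁻⁶: under Mendelian transmission 3/4 of induced mutations
  survive into the single sampled M2 descendant (1/4 homozygous, 1/2
  heterozygous, 1/4 lost), so the *retained* M2 density is 1 per
  966,000 bp — the study condition the package models. EMS densities in
  crop TILLING populations span roughly 1/25 kb to 1/2500 kb, so the
  parameter is fully tunable.
* `canonical_fraction` (default 1) is the probability that a mutation is a
  canonical EMS G:C→A:T transition, placed uniformly over G/C sites of the
  stored strand (G→A at G sites, C→T at C sites). The remainder are random
  substitutions at any site. No local sequence-context model is applied
  beyond the G/C requirement, because none is warranted by the data the
  package emulates.
* `contaminants` models non-mutagenic impurity alleles segregating in the
  seed stock (e.g. a desaturase A-insertion and an A→G reversion, the two
  classic high-oleic alleles); each individual carries each contaminant
  heterozygously with its stated frequency, independently of EMS density.

M1 plants are treated as fully heterozygous carriers with no chimera
modeling: one pod harvested per M1 plant is the sampling design this
reflects. Two alleles can never occupy one site in one individual; a
colliding draw is re-drawn with a warning. The simulation is reproducible
from `seed` and restores the caller's RNG state; the seed is a function
argument rather than a stored parameter so that one parameter set can
drive many replicates.

# The screening engine

`runScreen()` chains the stages per gene:

1. **Nested amplification** — the inner amplicon is computed on the outer
   product and mapped back to template coordinates; it equals direct inner
   amplification whenever the inner sites are unique. Primer matching is
   ungapped and exact by default (`max_mismatch = 0`), with a 3-bp
   exact 3'-anchor when mismatches are allowed: homeolog specificity comes
   from indel-spanning primers, and thermodynamics is deliberately out of
   scope. Products are capped at 5,000 bp (all real screen amplicons here
   are < 2.3 kb; the cap only blocks pathological site pairings).
2. **Pooling** — individuals are partitioned in input order into four-fold
   pools in 96-well plate-major order (`pool_size = 1` is individual
   screening).
3. **Heteroduplex formation** — reduced to a set rule: a site is cleavable
   iff ≥ 2 distinct alleles occur among the pooled haplotypes (het
   carriers contribute both alleles, hom carriers the alternate only,
   non-carriers the reference). Partial digestion and band intensity are
   not modeled; detection is binary, as on a gel image.
4. **Dual-channel cleavage** — a cut at amplicon offset `d` yields a
   `d`-bp fragment in the 700 channel (5' label) and `L − d` in the 800
   channel; the two always sum to `L`.
5. **Detection** — a call requires a 700/800 size pair summing exactly to
   `L` (a tolerance is applied only when Gaussian sizing noise
   `size_noise > 0` is switched on; the default is noise-free) with the
   cut strictly inside the analyzable window: `edge < d < L − edge`,
   `edge = 100` bp. Calls at identical cut positions co-migrate and are
   merged with a warning — a gel cannot resolve equal sizes, and whether
   two symmetric cuts (`d` and `L − d`) were ever distinguishable in
   practice is unknowable, so merging is a policy choice.
6. **Deconvolution** — each member of a positive pool is re-screened alone
   and mixed 1:1 with wild type: positive/positive is heterozygous,
   negative/positive homozygous (a pure mutant homoduplex is not
   cleavable), negative/negative wild type. A pool hit that no member
   explains raises an inconsistency error rather than a silent drop,
   because in a simulation it can only be a bookkeeping bug.

Edge exclusion implies a detectable fraction of `(L − 200)/L` for
uniformly placed mutations, which is exactly the correction the kb/SNP
statistic applies (below); the package's tests verify both the
completeness of detection inside the window and the expected loss outside
it.

# Effect annotation

`classifyMutation()` classifies against the gene model: `upstream`,
`intron`, `downstream`; coding substitutions via translation of the
wild-type and mutant codon (`silent`, `missense`, `nonsense`,
`start_loss`); indels by length mod 3 (`frameshift` with the truncated
length found by re-translating the shifted CDS to its first stop, or
`inframe`). Conventions worth stating:

* Translation uses the standard code with no alternative initiators
  (CTG is Leu even at codon 1 of a fragment).
* `truncated_length` for a nonsense change counts residues *strictly
  before* the premature stop: a stop at codon 102 leaves 101 residues.
  Informal usage often quotes the codon number itself ("a truncated
  protein of 102 amino acids"); the strict convention is unambiguous and
  testable, and the codon number is retained in `codon_index`.
* `start_loss` notes whether any downstream in-frame ATG could reinitiate.
* Upstream changes are never scored against promoter motifs.
* Epitope intervals are closed, in the protein coordinates the user
  supplies; no signal-peptide renumbering is attempted.

A property test enumerates all 61 sense codons and confirms that no
substitution at codon position 2 can be silent; a second one checks
`classifyMutation` against an independent full-CDS translate-and-diff
oracle.

# Restriction tools

Recognition sites are IUPAC-degenerate strings matched on the top strand
only (all built-ins — EcoRI, HindIII, AseI, BslI — are palindromic or
N-padded palindromic, so a double-strand scan would double-count). BslI is
CCNNNNNNNGG cutting after the seventh base (CCNNNNN^NNGG). `capsDesign()`
digests both alleles and reports the *largest* allele-unique fragment of
each digest as the diagnostic — the tie-break mirrors what is actually
scored on an agarose gel, where the largest divergent band is read.
`probeFragmentCount()` applies a 100-bp detectability floor (tiny
inter-site fragments run off the blot), a 50-bp minimum probe overlap, and
flags fragments within 5% relative size as co-migrating ("nearly
overlapping" bands; no sharper number is defensible). All three values are
arguments.

# Density estimation

Each amplicon contributes `L − 200` effectively screened bp per individual
(100 bp lost at each gel edge); `kbPerSnp(lengths, N, n)` is the total
effective bp divided by the confirmed mutation count, reported rounded to
the nearest kb with the unrounded value retained. Zero mutations give an
`NA` density, not an error. Rounding to integer kb is the convention of
the screening-summary table `table1Report()` reproduces; note that
966,467 bp rounds to 966 kb while casual rounding of "0.97 Mb" might print
967 — the table convention is the one implemented. Group labels are free
text; no dose–response model is fitted between treatments.

# The synthetic fixtures

`referenceFixtures()` builds, deterministically (internal fixed seed,
bit-stable, caller's RNG untouched), three homeolog pairs whose only
non-random content is what the worked examples require:

* every catalogued codon context (codon 49 CTT, 55 CGT, 62 CGA/CGG, 70
  GAT, 102 CGA, 150 AAT, 254 CCA, …), including the reference bases of
  three catalogued rows whose *printed* interpretations are internally
  inconsistent (a codon-position-3 change reported as missense and two
  codon-position-2 changes reported as silent) — those rows are flagged
  `anomalous`, kept as screenable variants, and excluded from effect-class
  concordance;
* the six-BslI-site amplicon whose wild-type digest contains adjacent 230-
  and 63-bp fragments separated by the site a C→T nonsense mutation
  destroys (the 293-bp CAPS diagnostic);
* the 19-bp indel 80 bp upstream of the desaturase start codons, on which
  the gene-specific primers anchor;
* intron placements that make the intron-inclusive coordinates of the
  vicilin-like copies come out at the catalogued residue numbers, an EcoRI
  site in each copy's first intron, two adjacent AseI sites in one copy's
  second intron, and no HindIII site in either gene (the Southern
  configurations assembled by `southernLayout()`).

Everything else — upstream, intron, downstream and filler CDS sequence —
is random, then scrubbed of stray restriction sites that would perturb the
layouts. The fixtures are synthetic stand-ins, not database sequences:
passing tests demonstrate that the *computation* is correct under the
documented contexts, not that any real gene has these sequences. Real data
additionally contain polymorphism between individuals, PCR artifacts,
incomplete digestion, sizing error (available as `size_noise`, default
off) and failed wells, none of which the generator emulates.

# Problem sizes

The test suite and acceptance script use: the full 3,420-plant
two-treatment reference screen (deterministic closure of the summary
table); 5,000 individuals over a 10-kb locus for the segregation and
density distribution checks; 2,000 uniformly placed mutations for the
edge-loss check; and 2,000 (tests) / 8,000 (acceptance script) individuals
over the six fixture amplicons for end-to-end density recovery, asserted
within three standard errors of the Poisson expectation. These sizes keep
every distributional assertion comfortably powered while the whole suite
runs in well under a minute.

# Known limitations

* Detection is binary and noise-free by default; there is no band
  intensity, partial digestion or background model, so sensitivity is 100%
  inside the analyzable window by construction.
* Primer matching is ungapped with no melting-temperature model; a primer
  that would mis-prime thermodynamically but mismatches textually is
  called non-binding.
* M1 chimerism and germination/lethality are not modeled; population size
  means *screened* M2 individuals.
* Southern counting predicts probe-visible fragment counts, not
  hybridization intensities or blot chemistry.
* The catalog transcription treats each confirmed mutation as
  heterozygous in its M2 plant, which is sufficient for count closure but
  ignores the occasional homozygous M2.
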