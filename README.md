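# tillploid

Simulation and analysis of **TILLING** (Targeting Induced Local Lesions IN
Genomes) mutation screens in **allotetraploid** species, where every target
gene exists as a homeologous pair contributed by the two ancestral
subgenomes.

TILLING screens an EMS-mutagenized M2 population for induced point
mutations in genes of interest: pooled DNAs are PCR-amplified with
end-labeled primers, heteroduplexes are formed and cleaved by CEL1 nuclease
at mismatches, and cleavage products are sized on a gel. In a polyploid the
first obstacle is amplifying *one* gene copy at a time — co-amplified
homeologs would bury real mutations under fixed inter-copy differences — so
the screen uses nested PCR with gene-specific inner primers anchored on
copy-discriminating indels. `tillploid` implements this whole computation
as testable code, for people designing, simulating or re-analyzing such
screens:

* **Gene models** with exact arithmetic between locus, ATG-anchored and CDS
  coordinates (`GeneModel`, `atgToLocus`, `locusToCds`, `cdsToLocus`).
* A **population simulator**: Poisson-distributed EMS mutations
  (G:C→A:T transitions at G/C sites), Mendelian 1 hom : 2 het : 1 lost
  transmission from M1 to M2, and non-EMS seed-stock contaminant alleles
  (`simulateM2`, `MutagenesisParams`).
* **In-silico nested PCR** with homeolog-specificity validation
  (`amplify`, `nestedAmplify`, `checkSpecificity`).
* The **screening engine**: four-fold pooling, heteroduplex enumeration,
  dual-channel CEL1 cleavage signals, the both-channels-sum detection rule
  with 100-bp edge exclusion, and pool deconvolution with zygosity calling
  — homozygotes are invisible alone and positive when mixed 1:1 with wild
  type (`runScreen`, `detectCalls`, `deconvolutePool`).
* **Effect annotation** with codon bookkeeping, epitope overlap and
  EMS-spectrum summaries (`classifyMutation`, `codonIndex`,
  `spectrumSummary`).
* **Restriction tools**: degenerate IUPAC site mapping, CAPS marker design
  and genotyping, and Southern probe-fragment counting
  (`restrictionSites`, `capsDesign`, `capsGenotype`,
  `probeFragmentCount`).
* **Density estimation** with the edge-corrected kb/SNP statistic and the
  standard screening-summary table (`kbPerSnp`, `table1Report`).

## The core statistic

A mutation is only detectable if its cleavage fragments fall inside the
analyzable gel window, which excludes ~100 bp at each amplicon end. The
screening-effort density over amplicons of lengths `L_g`, `N` individuals
and `n` confirmed mutations is therefore

```
kb/SNP = sum_g (L_g − 200) × N / n / 1000
```

reported rounded to the nearest integer kb, with the unrounded value
retained.

## Worked example

The package ships deterministic synthetic fixture genes (three homeolog
pairs with every documented mutation context planted; see
`?referenceFixtures`) and a curated 27-mutation catalog. Running the whole
pipeline over the reconstructed two-treatment M2 population:

```r
library(tillploid)
fx  <- referenceFixtures()
pop <- referenceScreenPopulation(fx)     # 3,420 M2 individuals
res <- runScreen(pop, primers = fx$primers)
table1Report(res$tally)
```

```
     gene amplicon_bp effective_bp 0.4% EMS/12 hr. 1.2% EMS/4.5 hr. total
 arah1.01        2211         2011               2                2     4
 arah1.02        1666         1466               1                0     1
 arah2.01        1278         1078               7                2     9
 arah2.02        1226         1026               2                3     5
  ahfad2A        1228         1028               5                0     5
  ahfad2B        1221         1021               3                0     3
    Total        8830         7630              20                7    27
Plants screened: 0.4% EMS/12 hr.: 2441; 1.2% EMS/4.5 hr.: 979 (total 3420)
kb/SNP: 0.4% EMS/12 hr.:  931; 1.2% EMS/4.5 hr.: 1067; overall:  966
```

Each plant contributes 7,630 effectively screened bp over the six
amplicons; 27 confirmed mutations over 3,420 plants give one mutation per
966 kb (931 and 1067 kb per group). Restricting to canonical EMS
transitions (22 of 27) gives 1 per 1,186 kb.

Designing a CAPS marker for the nonsense mutation in the vicilin-like
copy (`C304>T`, a destroyed BslI site):

```r
amp   <- nestedAmplify(fx$loci$arah1.02, fx$primers$arah1.02$outer,
                       fx$primers$arah1.02$inner)
assay <- capsDesign(amp, 704 - amp@start + 1, "C", "T", candidates = "BslI")
assay
```

```
CapsAssay (BslI): mutant-diagnostic 293 bp, wt-diagnostic 230 bp
  wt fragments: 480, 450, 284, 230, 122, 63, 37
  mut fragments: 480, 450, 293, 284, 122, 37
```

The mutation destroys the site separating the adjacent 230- and 63-bp
wild-type fragments; their 293-bp fusion indicates the mutant allele, and a
digest lacking the 230-bp fragment is a homozygous mutant
(`capsGenotype`).

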