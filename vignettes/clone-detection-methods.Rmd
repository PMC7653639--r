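---
title: "Detecting clones and inferring ploidy from reduced-representation genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clones and inferring ploidy from reduced-representation genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonekit)
```

## The problem

Apomixis — asexual reproduction through seed — is hard to observe directly in
tropical plants: flowering is sporadic, male inflorescences are ephemeral, and
embryological work is rarely feasible. clonekit implements an indirect route:
if the same multilocus genotype recurs across geographically distinct
localities in a plant that cannot spread vegetatively, the seeds must be
clonal. The package takes ddRAD-style per-locus allele read depths and
diploidized genotype matrices, finds clones, infers ploidy from allele
balance (gametophytic apomicts are typically of odd ploidy), and combines
both lines of evidence with field observations (growth habit, male sightings)
into a sexual/apomictic call per taxon. The motivating system is *Hanguana*
(Hanguanaceae), a dioecious tropical herb genus in which most Singapore
species turn out to be single widespread female clones.

## Genotype calling from read depths

A locus in a sample is called from its per-allele read counts with three
nested fractions of the total depth:

* minor fraction strictly above 10 % → heterozygote (the top two alleles);
* minor fraction in (5 %, 10 %] → the call is discarded as ambiguous;
* minor fraction at or below 5 % → homozygote; the minor reads are treated
  as sequencing error.

A locus with fewer than 30 reads yields no call, and both `DISCARDED` and
`NO_CALL` become missing cells in the genotype matrix. The band boundaries
are deliberately closed downward: exactly 5 % is a homozygote, exactly 10 %
a discard. The source rules leave exactly-5 % formally ambiguous ("fewer
than 5 %" vs. "5–10 %"); a single deterministic convention matters more than
the direction chosen, and both thresholds are arguments of `call_params()`.
Loci where more than two alleles each exceed the heterozygote threshold do
not fit a single-SNP model at any ploidy and are discarded. Calls are
*diploidized*: a triploid carrying one or two copies of the minor allele is
recorded as the same unordered heterozygous pair. True dosage is only
visible through depths, which is exactly what the ploidy stage exploits.

## Partitioning samples into comparable data sets

Heterozygous-locus similarity is only meaningful among closely related
samples, so the samples are first partitioned with an overall p-distance:
per pair, over loci called in both samples (pairwise deletion), each locus
contributes 0, 1 or 2 allele differences (identical unordered pair / one
shared allele / none), divided by twice the number of shared loci. A
het-vs-hom comparison therefore counts as half a substitution; this dosage
convention is symmetric and reduces to the haploid p-distance on
homozygotes, but it is a declared convention — distance tools differ in how
they weigh ambiguous diploid calls, and no claim is made of bit-for-bit
agreement with any of them. Loci missing in more than 30 % of samples are
dropped first; groups are single-linkage components at 99.78 % similarity
(both defaults are `pipeline_config()` arguments; complete linkage is
available by flag). Within each group, loci are refiltered to zero
missingness before clonality, mirroring the two-pass data-set construction
of the original workflow. One practical consequence of the dosage
convention: truly sexual families segregate at enough loci that sibs often
fall below the 99.78 % cutoff and land in singleton groups. That
over-splitting is harmless for clone detection — it can separate clones,
never merge them — and the per-group zero-missingness refilter keeps each
group's comparisons clean.

## The clone statistic

For samples A and B, every heterozygous locus of A that is called in B is
compared; the percentage of identical unordered genotype matches is the
directional similarity A→B. Both directions are computed and averaged
(`het_similarity()` keeps the raw directions for audit; a configurable
`match = "allele"` mode scores any shared allele instead of full genotype
identity). Sexually produced individuals — even full sibs — differ at a
large fraction of their heterozygous loci (about half, by Mendelian
segregation), while technical duplicates of one DNA sample differ only
through library error (about 1 %). Sorted pairwise values therefore show a
dense low block, an empty interval, and a high block. `calibrate_threshold()`
finds the widest empty interval below the weakest known duplicate pair and
puts the threshold at its midpoint; if no interval is at least 5 points wide
it falls back to 85 % with a warning, and any duplicate pair below the final
threshold is an error (the signature of a contaminated library). Clones are
connected components of the at-or-above-threshold graph; components holding
an internal below-threshold pair are kept but reported as transitivity
violations. Pairs with fewer than 20 compared heterozygous loci are flagged
unreliable rather than dropped — the floor is a package choice, as the
source method states none.

## Allele-balance ploidy inference

At ploidy $p$, a heterozygous locus carrying $d$ copies of the minor allele
contributes that allele at depth fraction $d/p$, so the *minor-allele depth
fraction* piles up at $\min(d, p-d)/p$: 1/2 for diploids, 1/3 for triploids,
1/4 (and 1/2) for tetraploids, 1/5 and 2/5 for pentaploids. `minor_fraction()`
uses the top-two passing alleles (alleles at ≥ 5 % of reads, total coverage
≥ 20) and a top-two denominator, mirroring normalized kmer-pair ratios; a
total-depth denominator is available by flag. Only the fraction axis is
interpreted — locus counts reflect the heavily skewed coverage of
reduced-representation data, which is why the kmer-based equivalent's
coverage axis is meaningless here.

`build_spectrum()` histograms the fractions over (0, 0.5] in 0.01 bins (the
source does not state a bin width or smoothing; both are declared package
choices and arguments). `detect_peaks()` takes local maxima of a 3-bin
moving average, suppresses the weaker of two maxima closer than 8 bins
(genuine allele-balance positions are never closer than 12 bins for ploidy
up to 8, while sampling shoulders on one smudge sit within a few bins), and
keeps maxima whose raw mass within ±2 bins exceeds 10 % of the spectrum.
The reported position is the mass-weighted centroid of that window, which
tracks the smudge centre under realistic depth dispersion better than the
modal bin. `infer_ploidy()` returns the smallest ploidy whose allowed set
$\{\min(d, p-d)/p\}$ covers every peak within a tolerance of 0.03 — small
enough to separate 1/3 from 1/4 and from 2/5 — and whose $1/p$ matches the
lowest peak; the smallest-$p$ rule is a parsimony tie-break (a lone 0.25
peak is a tetraploid, not an octoploid; in the original study chromosome
counts played this arbitration role). If nothing fits, the closest ploidy is
returned with `consistent = FALSE` rather than an error.

Two numerical caveats are worth knowing. First, the diploid smudge is
*folded* at 0.5 — the minor fraction cannot exceed 1/2 — so at finite depth
its centroid sits a little below 50 % (about 48–49 % at 100× mean coverage);
the 0.03 tolerance absorbs this. Second, `merge_stability()`, which checks
that pooling putatively clonal libraries does not move the peaks, compares
each library's centroid inside the *union* spectrum's peak windows. Windows
placed independently per library jitter by a bin or two on wide smudges,
which would fail honest clonal libraries; anchoring the windows makes the
one-bin-width agreement criterion reflect genuine allele-balance shifts.

## Genome-size arithmetic

Flow-cytometry replicate series are accepted when at least three
measurements from different days vary by at most 2 % (max/min), or, failing
that, once the standard error of the mean drops below 1 % of the mean
(`qc_fcm_replicates()`; the SEM is the sample standard deviation over
$\sqrt{n}$, a package choice as the source does not define its estimator).
Monoploid values are 2C/ploidy rounded *half-up* to 3 decimals
(`monoploid_size()`); half-up rather than banker's rounding is required to
reproduce the conventional printed picogram values (e.g. 2.290/4 = 0.573,
not 0.572). `theoretical_2c_range()` multiplies the measured diploid 1Cx
anchors by a ploidy to give the 2C window expected without genome size
evolution; a measured 2C below its window flags genome downsizing, as in
the tetraploid here. The bundled `hanguana_survey()` table carries the
published per-taxon evidence (sample, locality and clone counts, habit,
male records, ploidy, 2C and 1Cx), and these conversions reproduce its
printed genome-size columns exactly.

## Classifying the sexual system

`classify_sexual_system()` codifies the inference chain used for the survey
table; the source never formalizes it, so the rule order is a constructed —
and documented — reading of its reasoning:

1. recorded males imply sexual reproduction (a male cannot be apomictic);
2. with clonality testable (≥ 2 samples from ≥ 2 known localities),
   multiple clones imply sexual reproduction;
3. a single clone across several localities in a solitary plant implies
   apomixis; the same pattern in a stoloniferous plant is called apomictic
   but flagged, because vegetative spread can produce it;
4. otherwise the call is inferred from ploidy parity — odd (3x, 5x) →
   apomictic, even → sexual — and labelled `inferred`.

Rule 4's even-ploidy default is deliberately soft: even-ploidy apomicts
exist, so the inferred label marks these calls as downgradeable. The
`inferred` flag is attached exactly when rule 4 decides, which is what
reproduces the starred entries of the published table (a taxon tested at a
single locality with males present is *not* starred: rule 1 decided).

## The synthetic generator

`simulate_dataset()` exists so that every stage is testable without raw
reads. Each taxon gets a homozygous backbone genotype; a fraction of loci
(default 30 %) segregates within the taxon, with per-locus allele
frequencies from a Beta(1, 1) prior and founder dosages Binomial(p, q).
Sexual taxa are full-sib families from two simulated diploid parents via
Mendelian gamete union. Locus coverage is negative binomial with mean 100×
and dispersion 0.3; the gamma depth factor is drawn per locus and shared
across libraries, so low-coverage loci drop out consistently across samples
— the dominant missingness structure of real RAD data, and the reason a
zero-missingness within-group filter retains loci at all. Reads then flip
alleles at a 0.1 % substitution rate, and emitted heterozygous calls
collapse to the deeper allele's homozygote with 1 % probability (allelic
dropout, the dominant RAD genotyping error; substitution-style miscalls are
not modelled in the emitted calls). Duplicate libraries (default: 15 % of
samples, about the survey's 20 in 137) share the biological genotype but
draw depths and errors independently. Defaults give 500–1100 heterozygous
loci per library depending on ploidy.

At these defaults the full pipeline recovers simulated clone structure with
pairwise precision and recall of 1.0, and allele-balance ploidy recovery at
2000 loci and 100× coverage succeeds in ≥ 99 % of seeded replicates for
2x–5x. What the generator does *not* emulate — linkage, shared ancestry
between taxa, restriction-site polymorphism as such, reference bias,
index-hopping-style contamination — bounds what those green tests mean for
real data: they validate the statistics and their thresholds under the
stated error model, not the wet-lab pipeline upstream of it.

## Problem sizes and determinism

The bundled analysis scripts (`analysis/01`–`04`) simulate a survey of the
published shape — 10 taxa, 18 true clones, 152 libraries including 20
duplicates, 6000 loci — and run end to end in about a minute. The test
suite works on smaller instances (typically 2 taxa, ~20 libraries, 6000
loci; 2000-locus spectra) chosen to exercise the same conditions. All
randomness flows through explicit seeds: `sim_config()` makes the seed
mandatory, and the pipeline itself is deterministic, so a fixed seed gives
byte-identical reports.

## Known limitations

* The p-distance dosage convention is declared, not matched to any external
  tool; cutoffs tuned elsewhere (e.g. the 99.78 % grouping similarity) may
  partition differently here.
* Threshold calibration needs either duplicate libraries or a visible gap;
  a data set of one large clone plus nothing else has no low block, and the
  85 % fallback then does the work.
* Ploidy calls flatten above ~6x: peaks crowd together faster than the 0.03
  tolerance separates them, and high polyploids would need relaxed allele
  calling and deeper coverage.
* Genotype matrices are held dense in memory; hundreds of samples by tens
  of thousands of loci is comfortable, biobank scale is not the target.
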