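---
title: "Super-barcoding methods: variant scanning, marker design and cytonuclear hybrid detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-barcoding methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models
and conventions behind each stage, the tunable parameters and why their
defaults are what they are, what the simulator does and does not
emulate, and the judgement calls made where the design was genuinely
open.

## The inheritance model

Two genomic compartments carry complementary signals. The plastome is
maternally inherited in most angiosperms, so its genotype names a
sample's maternal lineage. The 45S nuclear ribosomal cistron
(18S–ITS1–5.8S–ITS2–26S) is biparentally inherited, so a hybrid carries
both parental haplotypes and shows two bases at every site where the
parents differ. The classifier is the direct product of these two
facts:

| plastome type | nrDNA state          | call                                |
|---------------|----------------------|-------------------------------------|
| resolved      | HOM, same lineage    | pure species (= plastome type)      |
| resolved      | HET                  | HYBRID, maternal = plastome type    |
| resolved      | HOM, other lineage   | DISCORDANT                          |
| ambiguous     | any                  | UNCLASSIFIED (reason retained)      |

Because the AM and AO nrDNA sequences are identical, nrDNA can never
separate those two species; that split is carried entirely by the
plastome markers, and when a hybrid's nrDNA implicates the AM/AO
lineage as the non-maternal contributor the output names AM and notes
in the rationale that AO is not excluded. Cross notation is a known
source of confusion (A×B is written both mother-first and
father-first in the literature), so hybrids are always reported with
explicit roles — `HYBRID(maternal = AM, paternal = AU)` — and the
rationale string prints both orderings.

Stem colour, where present in genotype tables, is carried through as
annotation only; it never enters the classification.

## Variant scanning conventions

Positions are 1-based in the ungapped coordinate of a designated
reference record; alignment columns are 1-based. An InDel's `ref_pos`
is the last reference base before the event (0 at the sequence start).

* **SNP**: any alignment column where at least two of the records
  carrying a base there disagree. Records gapped at that column get the
  allele `-`.
* **InDel event**: a maximal run of adjacent columns with an identical
  non-empty gap pattern. One event per run, whatever its length — a
  15-bp gap is one InDel, not fifteen. This convention makes event
  lengths meaningful (the marker-design rule "longer than 10 bp"
  operates on event lengths) and keeps counts auditable. Published
  InDel counts can differ between groups using different event-merging
  conventions; SNP counts are convention-robust.
* A column that mixes a gap run with a base difference among the
  non-gap records contributes to **both** tallies (the gap run as one
  event, the base difference as a SNP restricted to the non-gap
  records), keeping the two counts independent.
* Columns that are gap in every record are dropped. Columns containing
  ambiguity codes among the bases are excluded from SNP calling and
  counted in an attribute, since the downstream assays are built on
  unambiguous primers and probes.
* Inverted-repeat handling: the full alignment is scanned by default; a
  `mask` argument excludes alignment-column intervals (e.g. one IR
  copy) when a single-copy count is wanted.

Group-diagnostic sites are those where, for at least one pair of
groups, each group is internally fixed and the two group alleles
differ; sites polymorphic within every group are excluded and counted.

## Marker design

Primer placement is a transparent rule-based search rather than a
re-implementation of an interactive design tool: the properties that
matter downstream are (i) both primers sit in alignment windows
conserved across *all* references, so one pair amplifies every species,
and (ii) the product sizes (or product presence, or amplicon alleles)
discriminate the allele classes.

Constraints, with defaults: primer length 18–27 nt; melting temperature
57–63 °C by the GC-count approximation `Tm = 64.9 + 41·(GC − 16.4)/N`
(chosen over nearest-neighbour thermodynamics for transparency; the Tm
is recorded in the output so users can re-filter); GC 35–65 %; product
100–300 bp; ≥150 bp of flank per side of the target. Product sizes are
quoted outer-edge to outer-edge, including both primer footprints — the
convention under which gel sizes are reported.

Determinism: candidate pairs whose 3′-terminal bases are G or C are
preferred when any exist; ties are broken by maximising the distance of
the 3′ ends from any inter-reference variant column, then minimising
|Tm − 60| summed over the pair, then taking the leftmost forward
window. The chosen pair is verified by in-silico PCR against every
reference (exactly one product each, matching the predicted size);
failing pairs are discarded and the next-ranked pair tried.

* **Codominant InDel markers** target diagnostic events with length
  ≥ 11 (strictly "longer than 10 bp"); the class product sizes then
  differ by exactly the event length.
* The **dominant SNP marker** puts the forward primer's 3′-terminal
  base exactly on the SNP, carrying the amplifying class's allele; with
  3′-anchored matching the other class yields no product.
* **HRM markers** are modelled at the sequence level: amplicons of at
  most 120 bp containing 1–3 diagnostic nrDNA SNPs, with the product
  size required to be identical in every sample (so no InDel hides in
  the amplicon). A sample's call derives from which allele strings are
  present — in its sequences, or in its read pool via the allele-depth
  machinery — not from melt-curve physics: the melt peaks of a real HRM
  assay encode exactly allele presence and heterozygosity, which is
  what is reproduced. External panels load without re-validation of
  designer constraints (one published HRM primer is 17 nt).

## Read-based heterozygosity calling

Instead of full read mapping, each diagnostic site gets two probes: the
two group alleles embedded in `k` = 10 bp of reference flank per side.
A read supports an allele iff the probe (or its reverse complement) is
an exact substring. This is appropriate for a short reference (a ~5.9-kb
cistron) with well-separated sites, avoids a mapper dependency, and is
fully auditable; a hook (`as_site_depths()`) accepts externally mapped
counts for real data. The 1-bp InDel site uses the same machinery with
presence/absence alleles. Probes are dropped (with a message) when not
unique in the reference or too close to its ends, and the flank is
shrunk per-site down to `min_k` = 6 when a neighbouring variant
intrudes.

Costs of this choice: a read with a sequencing error inside the probe
window is silently unassigned, so the effective depth at 1 % per-base
error is about `(1 − 0.01)^21` ≈ 81 % of the covering reads — fractions
are unbiased, depth is modestly reduced.

Calling thresholds (all configurable): a site qualifies at total depth
≥ 20; it is heterozygous when the minor fraction is ≥ 0.2 (real hybrid
compartments sit at minor fractions ≈ 0.28–0.48, sequencing noise far
below; 0.2 separates them with margin); the compartment is HET or HOM
when ≥ 80 % of qualifying sites agree, else NO_CALL. The summary
statistic is the mean of per-site minor fractions over qualifying
sites — a stated stand-in, since how published "about 7:3 overall"
ratios were aggregated is typically not specified. Raising the
minor-fraction threshold can only move sites from heterozygous to
fixed, so a HOM call never becomes HET (regression-tested).

## The simulator: what it emulates and what it does not

`simulate_references()` draws an ancestor uniformly over {A,C,G,T} with
homopolymer runs capped at 4 (long homopolymers would make planted
events ambiguous to place), then derives the three species by planting
exactly the configured per-branch events on the topology AU | (AM, AO).
Defaults: branch SNP counts 145/25/35, giving pairwise totals 170
(AU–AM), 60 (AM–AO) and 180 (AU–AO) that mirror the real magnitudes;
per-branch InDel sets including events of 15/15/17/12/11 bp (AU), 12 bp
(AM) and 23 bp (AO) so each marker type is designable; an nrDNA
contrast of 20 SNPs plus one 1-bp InDel with AM ≡ AO. Events longer
than 10 bp are placed with ≥450 variant-free bp on each side
(guaranteeing conserved primer windows); other events keep ≥40 bp
spacing so probe flanks stay clean. The default "mini" plastome is
20 kb — chosen so a complete pipeline run takes well under two minutes —
and `full_scale = TRUE` plants the same structure on 154 kb with 80/40
branch-InDel totals at the real scale. One root seed feeds per-stream
derived seeds (references, nrDNA, per-sample reads), so adding a stage
never perturbs earlier streams and equal seeds give byte-identical
output.

`simulate_sample()` copies the maternal plastome verbatim and draws
nrDNA reads from the maternal haplotype with probability *f* (default
0.65, matching the ≈7:3 and 6:4 depth regimes of real hybrid
collections), uniform starts, both strands equiprobable, independent
per-base substitution errors.

Deliberately **not** emulated: realistic Illumina error profiles
(quality ramps, adapter read-through), rDNA array copy-number
variation, IR duplication (available as an option is out of scope; the
multi-product code path is exercised with synthetic duplications in
tests), recombination, and within-species polymorphism beyond the
planted events. Passing the closure tests therefore demonstrates that
the algorithms are internally correct and mutually consistent — scan
recovers exactly what was planted, designed markers reproduce their own
expected sizes, the classifier inverts the generative model — not that
real assemblies or real read pools are this clean. Real data adds
alignment ambiguity around tandem repeats, unequal rDNA copy
conversion, and coverage fluctuations that the thresholds above absorb
but the simulator does not generate.

## Numerical and degenerate-input choices

* FASTA output wraps at 70 columns (arbitrary, fixed for
  reproducibility); residues are uppercased on ingest; `-` survives
  round-trips so MAFFT output can be re-read.
* Genotyping uses exact primer matching (`max_mismatch = 0`) by
  default — samples are assumed conspecific with the panel's design
  references; the binding-site search exposes a mismatch budget (with
  the dominant marker's 3′ base always exact) for divergent material.
* Multiple convergent site pairs report every product; genotype
  matching uses the full multiset and any unexplained size demotes the
  call to `NULL` with a warning and the evidence retained.
* An empty diagnostic set, a sample with no qualifying depth, or an
  unresolvable plastome pattern degrade to `NO_CALL`/`ambiguous`/
  `UNCLASSIFIED` with a reason string, never to a silent guess; a
  corrupted single call can only move a pure pattern to `ambiguous`,
  never to the wrong species (enumerated in tests).
* Published product sizes given as a range ("233–236") are accepted in
  the panel TSV and matched as an inclusive interval.

## Problem sizes used in the checks

The automated checks run the mini scale (20-kb plastome, full-length
5,878-bp nrDNA, 500× hybrid coverage for mixture recovery at
*f* ∈ {0.60, 0.65}, a 10-sample end-to-end panel at 300×) plus a
full-scale (154-kb) reference simulation and scan; these sizes are the
package's own choice of a regime large enough to exercise every code
path while keeping a complete run near a minute.

## Known limitations

* Heterozygosity calling assumes two and only two contributing
  haplotype classes per compartment; three-way mixtures are not
  modelled.
* The generation of hybridity (F1 versus backcross) is not estimated;
  the mean minor fraction is exposed and interpretation stops there.
* The dominant-marker model treats any 3′-matched primer as productive;
  real allele-specific PCR can leak at high cycle numbers.
* GC-count Tm is a coarse screen; primer secondary structure
  (hairpins, dimers) is not checked.
* De novo assembly, annotation, phylogeny construction and wet-lab
  thermodynamics are upstream/downstream of this package's scope.
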