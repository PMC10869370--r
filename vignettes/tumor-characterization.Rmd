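---
title: "Characterizing tumors from paired germline/tumor calls: LOH, signatures, HRD and pedigree criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing tumors from paired germline/tumor calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohsig)
```

This vignette is the package's account of its methods: what each stage
computes, which parameters matter and why they default to what they do, what
the synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The analysis problem

In families segregating candidate tumor-suppressor variants, three questions
recur for each sequenced tumor. Did the tumor lose the wildtype allele at the
candidate loci (the classic "second hit")? Does the tumor's mutation spectrum
carry the imprint of the repair defect the germline variant predicts — for
*BRCA1*, homologous recombination deficiency (HRD), visible as COSMIC
signatures SBS3 and ID6? And in the wider family, how do carriers, dual
carriers and phenotypes such as serrated polyposis co-distribute? The package
implements each step on standard inputs (VCF, BED, COSMIC-style signature
TSVs, a family CSV) with a seeded simulator supplying ground-truthed inputs
for every stage.

## Somatic consensus filtering

Somatic calls from two callers are intersected on the normalized
(chrom, pos, ref, alt) key after decomposing multi-allelic records, then
filtered to PASS calls with tumor VAF ≥ 0.1 and depth ≥ 50 reads. Both
thresholds are **inclusive**: "a minimum of 0.1" keeps a VAF of exactly 0.1.
VAF and depth are recomputed from the sample's allele depths (`AD`) rather
than taken from caller-specific fields, so the two callers' bookkeeping
differences cannot move a variant across the threshold. Indel representations
are assumed caller-normalized; no left-alignment is attempted, and matching
is strict — a deliberate simplification documented here rather than hidden.

Capture intervals use 0-based half-open (BED) coordinates internally; VCF
positions are converted on comparison. A variant whose 0-based coordinate
equals an interval's `end` is outside it. Chromosome-dialect mismatches
(`chr17` vs `17`) are refused with guidance instead of silently matching
nothing.

## LOH detection

Candidate sites are heterozygous **germline** variants — tumor-only calls are
never used — with germline VAF inside the inclusive window [0.4, 0.6] and
depth gates of 10 (germline) and 30 (tumor). At cellularity (tumor purity)
$p$, contaminating normal cells contribute an expected alternate fraction of
$\tfrac12$ at a heterozygous site, so the observed tumor fraction $f$ is
corrected to

$$ f_{\mathrm{adj}} = \mathrm{clamp}\!\left(\frac{f - (1-p)/2}{p},\ 0,\ 1\right). $$

A site supports LOH when $|f_{\mathrm{adj}} - f_{\mathrm{germline}}| \ge 0.3$
(inclusive), with the direction of the shift (toward homozygous reference or
alternative) recorded separately; the shift is absolute because loss of
either parental allele is equally informative. The default cellularity is
0.8. How purity should enter the 0.3 threshold is not uniquely determined by
the rule set the detector descends from; correcting the fraction before
thresholding is this package's declared convention, chosen because it makes
the threshold mean the same thing at every purity (at $p = 1$ it reduces to
the raw fraction, and under true copy-neutral LOH the adjusted fraction
concentrates at 0 or 1 as depth grows). `purity_correction = FALSE`
reproduces raw-fraction behavior.

Supporting sites are aggregated into regions: maximal runs of supporting
sites, treating uninformative sites as transparent and bridging at most
`region_max_gap_sites` (default 1) consecutive informative non-supporting
sites, emitted at `region_min_sites` (default 3) supporting sites. "At least
3 sites, bridge 1" is a configurable default chosen to suppress isolated
binomial-noise sites while keeping ~Mb-scale events intact at exome site
densities; the aggregation itself was open design space, so both knobs are
exposed. A gene is called LOH if it overlaps a region or contains a
supporting site, uninformative if it contains no informative site, otherwise
no-LOH. The allele-fraction plot draws one whole-chromosome panel plus one
zoom panel per focus interval with regions shaded.

## Mutation catalogues

SNVs are classified into the 96 trinucleotide-context channels on the
pyrimidine strand (purine reference bases reverse-complemented). Indels
follow the PCAWG/COSMIC ID-83 decision tree: 1-bp events split by C/T (A/G
counted on the complementary strand) and homopolymer length; longer events by
tandem repeat-unit count within ±100 bp; deletions of ≥ 2 bp not in a repeat
are checked for flanking microhomology (longest shared prefix with the 3'
flank or suffix with the 5' flank). Ties between repeat and microhomology
classification resolve repeat-first, per the published convention. Channel
orders follow COSMIC so shipped reference matrices drop in directly.

## Signature refitting and the HRD rule

With $S$ the selected reference-signature columns and $c$ the catalogue
normalized to proportions, exposures solve

$$ \min_e \|S e - c\|_2 \quad \text{s.t.}\quad e \ge 0,\ \textstyle\sum_i e_i = 1, $$

a strictly convex quadratic program solved deterministically (no random
initialization; a vanishing ridge is added only if the Gram matrix is
numerically singular). Proportion-normalized Euclidean loss is used rather
than count weighting — the refit is then scale-invariant in the catalogue,
which the tests assert. SBS and ID catalogues are refit independently on
their own alphabets. Exposures below $10^{-4}$ are suppressed in printed
output but retained in machine output.

The refit is restricted to signatures previously observed in CRC. The exact
membership of that subset is an analysis choice the upstream literature does
not pin down uniquely, so it is configuration: the shipped default
(SBS1, 2, 3, 5, 10a, 10b, 13, 15, 17a, 17b, 18, 28, 30, 40, 44 and
ID1, 2, 4, 5, 6) covers the commonly reported CRC processes and always
includes SBS3 and ID6, without which the HRD rule refuses to run. Tests use
synthetic signature matrices only, never a COSMIC download.

A tumor is HRD-positive when SBS3 exceeds 10% **or** ID6 exceeds 20% of the
profile; both comparisons are strict, so an exposure exactly at threshold is
negative. The rule is monotone in both exposures.

## Pedigree counts and WHO-2019 SPS criteria

Carrier counting treats obligate carriers as carriers; "cancer-affected"
means at least one malignancy diagnosis and "CRC-affected" at least one
diagnosis typed CRC (polyp records are never diagnoses). The WHO-2019
criteria are evaluated cumulatively over all ages: criterion 1 requires ≥ 5
serrated polyps (hyperplastic, SSL or TSA — adenomas never count) proximal to
the rectum, all ≥ 5 mm with ≥ 2 ≥ 10 mm; criterion 2 requires > 20 serrated
polyps with ≥ 5 proximal. Three conventions were open and are configurable:

* **Size ranges** ("6–8 mm") qualify by their lower bound by default — the
  conservative reading; `upper_bound` and `midpoint` are available.
  Unknown-size polyps never qualify under the default, which is why a record
  of "numerous small polyps" without sizes cannot satisfy criterion 1.
* **Proximal** means every colonic segment except the rectum (sigmoid
  included), the literal reading of "proximal to the rectum"; the segment
  set is configurable.
* **Carcinoma-background serrated lesions** (an SSL from which an
  adenocarcinoma arose) count by default and are flagged in the table, so
  the stricter exclusion is one switch away.

The packaged family table encodes the study family's published cancer and
polyp history in long CSV form; loading it and summarizing reproduces the
published counts (10 and 8 single-variant carriers, 7 dual carriers, 6
cancer-affected and 4 CRC-affected dual carriers, one member meeting SPS
criterion 1).

## The synthetic-data generator

`simulate_paired_sites()` places heterozygous sites uniformly on one
chromosome; germline alternate reads are Binomial(depth, 0.5) and tumor
reads Binomial(depth, $p a + (1-p)/2$) inside planted copy-neutral LOH
segments (lost-allele dosage $a \in \{0, 1\}$ drawn per segment) and
Binomial(depth, 0.5) outside. Defaults — 500 sites on an 80 Mb chromosome,
cellularity 0.8, germline/tumor depths 30/60 — mirror the study conditions
the detector is asserted under. `simulate_catalogue()` draws
Multinomial($n$, $S e$) counts. `random_signature_matrix()` draws flat
Dirichlet columns re-sampled until all pairwise cosines are below 0.8, so
recovery tests are well conditioned; 0.8 is lenient compared to the real
COSMIC catalogue's most similar pairs. `simulate_family()` emits family CSVs
with planted genotype structure. All generators are bit-reproducible given a
seed.

What the simulator does **not** emulate — and hence what green tests do not
show about real data: deletion-LOH and subclonal events (only clonal
copy-neutral LOH is planted), FFPE and mapping artifacts, non-uniform site
density, germline sites miscalled as heterozygous, signature flat-field
bleed-through between similar COSMIC signatures, and caller disagreement
beyond simple presence/absence.

## Numerical choices and degenerate inputs

Adjusted fractions are clamped to [0, 1]. The QP ridge escalates from 0 to
$10^{-6}$ only on solver failure; solutions are re-projected onto the simplex
(negative round-off zeroed, renormalized). Empty catalogues refuse to refit;
empty VCF bodies yield empty tables; unsorted site input to region
aggregation is an error, not a silent sort. Region aggregation counts only
bridged non-supporting sites inside the emitted span. Reports are JSON with a
stable key order and no timestamps, so identical configuration and seed give
byte-identical output.

Problem sizes used by the test suite and acceptance script — 100 planted and
100 neutral 500-site chromosomes, 50 refit replicates at 10,000 mutations,
grid-search cross-checks at 0.01 steps on 2–3 signature problems — are the
package's chosen verification scale: large enough for the 95%/5%
recovery/specificity and 0.02 exposure-error margins to be meaningful, small
enough to re-run routinely.

## Known limitations

The detector cannot distinguish copy-neutral LOH from hemizygous deletion
without read-depth modelling, which is out of scope. Purity is a single
global constant, not estimated per sample. The strict indel-matching policy
will miss consensus variants that two callers normalize differently. The
SPS evaluator is only as good as the polyp records: counts given as
"numerous" cannot be scored. And signature refitting inherits the usual
caveats of fixed-catalogue decomposition: similar signatures trade off
against each other, and exposures for signatures absent from the subset are
forced to zero.
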