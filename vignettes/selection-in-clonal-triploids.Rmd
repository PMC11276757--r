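---
title: "Measuring purifying selection in a clonal triploid: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring purifying selection in a clonal triploid: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpstools)
```

## The scientific question

Asexual lineages are expected to purge deleterious mutations less
efficiently than sexual ones: without recombination, selection cannot
separate a new deleterious allele from the genetic background it arose on.
A sensitive place to look for this inefficiency is the ratio of
nonsynonymous to synonymous polymorphism, **pN/pS** — the number of
amino-acid-changing SNPs per nonsynonymous site divided by the number of
silent SNPs per synonymous site. Under strong purifying selection pN/pS is
far below 1; as selection weakens it rises toward 1.

`pnpstools` implements this comparison for a study design built around a
triploid, apomictically parthenogenetic woodlouse population (genotypes
like `0/0/1`) and a diploid, sexually outcrossing relative (`0/1`),
genotyped from transcriptome (RNA-seq) SNP calls. The interesting contrast
is not species-wide pN/pS — in a hybrid-origin clone most heterozygous
sites predate asexuality and were already filtered by selection in the
sexual progenitors — but the pN/pS of *SNP classes*:

* **candidate novel SNPs**: sites where some clonal adults are `0/0/0` and
  others `0/0/1`, with no other genotype present. These are best explained
  by mutations arising after the clone's origin, and have experienced only
  asexual selection.
* **ancestral identical SNPs**: sites where every adult is exactly
  `0/0/1` — heterozygosity inherited from the founding hybridisation.
* **low-frequency SNPs** in the sexual species: a single `0/1` carrier
  among otherwise `0/0` diploids (alternate-allele frequency `1/2N`), the
  natural sexual comparison class for young, possibly mildly deleterious
  variants.

## Counting sites and classifying SNPs

SNP effects are classified against the reference codon: the alternate base
is substituted into the codon containing the site and the translations are
compared (stop gain or loss counts as nonsynonymous). No haplotype-aware
resolution of multi-variant codons is attempted; nothing in the underlying
study design calls for it, and at the SNP densities involved multi-hit
codons are rare.

Denominators use Nei–Gojobori (1986) site counting: each position of a
sense codon contributes `s/3` synonymous sites, where `s` of the three
possible single-base changes preserve the amino acid, and the remainder
nonsynonymous; every codon contributes exactly 3 sites in total. The
method is brute-force verifiable (the test suite enumerates all nine
mutants of all 61 sense codons with an independent translation table), and
it makes the synthetic-data calibration below exact.

A site only counts if it is *covered*: sequencing depth at least
`min_depth` (default 20, matching the genotype filter) in the focal sample
(per-individual summaries) or in every sample of the species (class
summaries). Coverage is judged per nucleotide, not per codon, so a codon
can contribute a fraction of its sites. Depth comes from a per-base depth
table covering every CDS position, including monomorphic ones — without
this, pN/pS denominators would be incomputable.

Two conventions worth noting:

* substitutions to or from stop codons are nonsynonymous, both in
  classification and in site counting;
* pN/pS is always computed from raw counts. Published tables sometimes
  divide already-rounded frequencies; for two of the bundled example rows
  this produces ratios of 0.0577/0.0866 where raw counts give
  0.0576/0.0865. The package reports the raw-count values.

## The likelihood-ratio test for unequal pN/pS

Let class \(i\) have \(n_{N,i}\) nonsynonymous and \(n_{S,i}\) synonymous
SNPs over \(S_{N,i}\) and \(S_{S,i}\) covered sites. Model the counts as
two Poisson processes with a shared synonymous rate \(\lambda_i\) and
ratio \(r_i\): \(n_{S,i} \sim \mathrm{Pois}(\lambda_i S_{S,i})\),
\(n_{N,i} \sim \mathrm{Pois}(r_i \lambda_i S_{N,i})\). Conditioning on the
class total \(n_i = n_{N,i} + n_{S,i}\) profiles out \(\lambda_i\) and
leaves

\[ n_{N,i} \mid n_i \sim \mathrm{Binomial}\!\left(n_i,\;
   \pi(r_i) = \frac{r_i S_{N,i}}{r_i S_{N,i} + S_{S,i}}\right). \]

The null model shares one ratio \(r\) across both classes; the alternative
gives each class its own. The per-class MLE has the closed form
\(\hat r_i = (n_{N,i}/S_{N,i}) / (n_{S,i}/S_{S,i})\) — exactly the pN/pS
point estimate — and the shared ratio is maximised numerically on the log
scale (golden-section search over a bracket spanning both per-class MLEs,
relative tolerance 1e-10). The statistic \(2(\ell_1 - \ell_0)\) is
compared to \(\chi^2_1\). When the two classes share the same
\(S_N/S_S\) ratio this test is algebraically the 2×2 G-test of
independence, which the test suite verifies numerically.

The ratio is unidentifiable when a class has no synonymous SNPs; the
function refuses such input rather than returning an arbitrary value.

## Ploidy from allele balance

At a heterozygous site, the fraction of reads carrying the reference
allele is centred on 1/2 in a diploid, but on 1/3 or 2/3 in a triploid
carrying one copy of one allele and two of the other (an AAB-style
genome). `infer_ploidy()` turns the visual two-peak histogram argument
into a likelihood comparison: reference-read counts \(r\) with \(n\)
informative reads score \(\mathrm{Binom}(r \mid n, 1/2)\) under the
diploid model against the symmetric mixture
\(\tfrac12\mathrm{Binom}(r \mid n, 1/3) +
\tfrac12\mathrm{Binom}(r \mid n, 2/3)\) under the triploid model, and the
higher total log-likelihood wins. Fewer than `min_sites` heterozygous
sites (default 100) returns `"undetermined"` rather than a call.

Two deliberate simplifications: there is no overdispersion term (raw
binomial likelihoods, adequate at depths of tens of reads), and the
mixture is symmetric even though real transcriptome assemblies often show
an asymmetry between the 1/3 and 2/3 peaks caused by reference-allele
bias. That bias is an artefact of upstream assembly and read mapping,
which this package does not model; a strongly biased dataset would shrink
the likelihood margin but not flip it, because a diploid model centred at
1/2 fits neither peak. Histograms (`balance_histogram()`, default bin
width 0.02, right-open bins except the last) are exported alongside the
calls so the peak structure can be inspected directly.

## Clonality and the exact tests

`identity_fraction()` measures the fraction of biallelic SNPs at which a
sample set shares identical genotypes, where "identical" means equal
sorted allele multisets — a diploid `0/1` and a triploid `0/0/1` are
never identical, by construction. Records with any missing call among the
compared samples leave both numerator and denominator. Multiallelic
records (more than one alternate allele, or any genotype referencing
allele 2 and above) are excluded up front, since genotyping errors and
paralog collapse concentrate there.

Sex ratios are tested with the standard two-sided exact binomial test
(minimum-likelihood rule, as in `binom.test`). Per-individual pN/pS values
are compared between species with an exact two-sample Mann–Whitney test
computed by full enumeration of all `choose(nA+nB, nA)` rank assignments;
tied values are an error (with group sizes of four per species, exactness
matters and ties do not arise from raw ratios). The enumeration is
cross-checked against `wilcox.test(exact = TRUE)` in the test suite.

## Pairwise dN/dS stand-in

`pairwise_dnds()` provides Nei–Gojobori counting with Jukes–Cantor
correction (`d = -3/4 ln(1 - 4p/3)`) for aligned coding sequence pairs:
sites are averaged over the two sequences, multi-difference codons average
the synonymous/nonsynonymous step counts over all substitution orderings
(2 or 6 paths; steps through stop codons are allowed and counted
nonsynonymous), and the ratio is reported missing when dS is zero or the
proportion saturates the correction (p ≥ 3/4). This is intentionally a
desk-scale stand-in for maximum-likelihood codon-model estimation: it
supports simulator-level property tests (symmetry, exact agreement with a
path-enumeration oracle, dN = 0 for purely 4-fold-degenerate differences)
but is not a substitute for ML divergence estimation on real orthologs.

## The synthetic-data generator

Every stage above is testable without any external download because
`simulate_dataset()` emits a complete, truth-labelled bundle — reference
FASTA, CDS table, sample sheet, per-species VCFs and per-base depth
tables — with the statistical structure the analysis assumes:

* a **triploid clone set**: haplotype B diverges from haplotype A at
  `Bernoulli(d)` CDS sites (default `d = 0.005`), giving ancestral
  `0/0/1` heterozygosity shared by all clones; each adult then gains novel
  mutations at per-site rate `mu` (default `2e-5`), each on a single
  haploid copy, giving private `0/0/1` genotypes. A pooled-offspring
  sample copies the first adult's genotypes exactly (apomixis as literal
  genotype copying: no recombination, no gene conversion).
* a **diploid outcrossing population**: segregating sites at density
  0.003 per CDS site, alternate-allele counts drawn from a `1/i`-shaped
  frequency spectrum (the neutral expectation), alleles assigned by
  sampling chromosome slots without replacement.
* **selection as a retention filter**: a proposed nonsynonymous change
  survives with class-specific probability `f` (novel class default 0.2;
  ancestral and sexual classes 0.1). Because mutation proposals are
  uniform over the three alternative bases — the same measure NG86 site
  counting integrates over — the expected pN/pS of a class equals its `f`
  exactly, which is what makes parameter recovery a sharp test: with
  `f = 1` the pipeline must estimate pN/pS near 1 and the class LRT must
  reject at the nominal rate only.
* **read backing**: per-site depths are negative binomial (mean 60, size
  40 — mild overdispersion around the mean); reference-allele depths are
  binomial in the true reference copy number over ploidy; GQ is a
  constant 99 and site QUAL a constant 60, because the package tests
  filter plumbing, not a variant caller's error model. The depth tables
  and the VCF DP fields are drawn from the same per-site depth matrix, so
  numerators and covered-site denominators are mutually consistent.

Default scale is 2,000 transcripts of 150 codons per species; at that
scale an end-to-end run produces on the order of 1,450 ancestral and 30
novel SNPs in the clone and 1,800 segregating sites in the sexual
population, and the full report completes in a few minutes on one CPU.
The test suite runs most properties on smaller configurations (tens to
hundreds of transcripts) chosen so that expected counts still make the
assertions sharp.

Two generator conventions: every CDS starts with `ATG`, contains only
sense codons and excludes its terminal stop codon from the counted
region; and the novel-mutation rate is interpreted per CDS site per
individual, with the mutation placed on one haploid copy — the reading
that reproduces the candidate-novel class sizes the analysis is designed
around (tens of SNPs against ~900 kb of CDS).

What the generator does **not** emulate — and therefore what passing
recovery tests do not establish about real data: transcript-level
expression variation (real RNA-seq depth varies by orders of magnitude
across transcripts, so real covered fractions are far lower and
non-uniform), reference-allele bias and the resulting histogram
asymmetry, genotyping error, alternative splicing and collapsed paralogs
(major sources of false SNPs in transcriptome genotyping), and linkage
between sites. Under the default conditions the expected all-adults
genotype identity is about 0.98 — novel mutations are rare but not
absent — which mirrors the magnitude seen in real clonal populations once
genotyping noise is set aside.

## Numerical and degenerate-input conventions

* pN/pS is `NA` (missing) when a class has no synonymous SNPs — never 0
  or infinity; frequencies of an empty class are 0.
* The LRT clamps tiny negative `2*(llAlt - llNull)` values (floating-point
  residue of the 1-D maximisation) to 0.
* `identity_fraction()` with an empty usable record set reports a missing
  fraction rather than `NaN`.
* Genotypes are canonicalised on input (`0/1/0` ≡ `0/0/1`); phase is
  discarded. Missing genotypes fail every filter rather than being
  imputed.
* Quality thresholds are inclusive (`>=`), with defaults DP ≥ 20,
  GQ ≥ 30, site QUAL ≥ 30.
* Report tables round the way the field prints them: pN/pS to 4 decimals,
  frequencies to 3 significant figures, percentages to 1 decimal,
  chi-square to 1 decimal; JSON output keeps full precision alongside.
* `run_report()` output is byte-deterministic for a fixed configuration
  (no timestamps; the single randomised choice — which adult pair to
  compare — is seeded).

## Known limitations

The effect classifier is reference-codon based and single-site; the
ploidy model considers only diploid vs triploid (AAB) karyotypes; the
clonality metric detects identity, not relatedness; the dN/dS module is a
counting method, not an ML estimator; and the generator's selection model
is a retention filter, not a population-genetic fixation process — ideal
for calibration, but not a simulator of segregating deleterious variation
under drift.
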