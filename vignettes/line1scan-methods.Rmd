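---
title: "Methods: detecting and testing a LINE-1 insertion at desk scale"
author: "line1scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and testing a LINE-1 insertion at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(line1scan)
```

# The problem

A full-length LINE-1 retrotransposon inserted into the first intron of
*MERTK* segregates with a recessive retinopathy in Swedish Vallhund dogs.
Finding such an insertion in short-read data, characterising its
structure, and quantifying its association with disease involves a chain
of small, well-defined computations that are usually spread across many
tools. `line1scan` implements that chain end to end, at desk scale, with
a read simulator that generates every input the chain needs, so the whole
pipeline can be exercised and validated on one workstation in seconds.

A LINE-1 integration leaves a characteristic scar. The endonuclease makes
a staggered cut, so a short stretch of the host sequence -- the target
site duplication (TSD), here 15 bp -- ends up flanking the element on
both sides. When reads from a carrier are aligned to the insertion-free
reference:

* reads entering the element from the left flank align up to the *end* of
  the TSD and carry a soft-clipped tail that is the start of the element;
* reads leaving the element into the right flank align from the *start*
  of the TSD and carry a left clip that is the element's end;
* both physical copies of the TSD map onto the single reference copy, so
  read depth over those 15 bp is elevated (approaching twice the flanking
  depth in a homozygote);
* read pairs fully inside the element have nowhere to align.

The detector looks for exactly this signature: two opposing soft-clip
clusters bracketing a short interval, scored with the depth ratio over
that interval.

# The simulator and what it emulates

The generator defaults encode the study conditions of the discovery data
set:

| parameter | default | meaning |
|---|---|---|
| `totalLen` | 6,401 bp | full element length (5'UTR, ORF1, spacer, ORF2, 3'UTR, poly-A) |
| `tsdLen` | 15 bp | target site duplication |
| `orf1Len` / `orf2Len` | 900 / 3,828 bp | the two open reading frames, ATG to stop |
| `spacerLen` | 49 bp | intergenic spacer between the ORFs |
| `polyaLen` | 30 bp | terminal A-run |
| `readLen` / `meanDepth` | 100 bp / 21x | paired-end sequencing configuration |
| `insertMean` / `insertSd` | 350 / 50 bp | fragment length distribution |
| `substErrorRate` | 0.001 | substitution-only error model |
| `penetranceHom` | 0.83 | P(case) for insertion homozygotes (57/69 in the pooled study sets) |
| `phenocopyRate` | 0.084 | P(case) for everyone else (16/190) |

The 5'UTR defaults to 1,300 bp -- a round value in the range typical of
mammalian full-length LINE-1 5'UTRs -- leaving a 294 bp 3'UTR as the
residual of the 6,401 bp total. ORFs are genuine: they begin with ATG,
end with a stop codon and are internally stop-free, and an in-frame stop
is placed immediately upstream of each so that an open-reading-frame scan
trimmed to the outermost ATG recovers the planted spans exactly. Draws
that happen to create a longer spurious ORF or an A-homopolymer of 10+ bp
outside the tail are rejected and redrawn.

Truth alignments are produced by construction rather than by running an
external aligner: each simulated fragment's donor coordinates are mapped
through the insertion onto reference coordinates, with three mapper-like
rules: (i) an aligned segment shorter than 20 bp is emitted unmapped
(real mappers will not place a 5 bp anchor); (ii) a mapped reverse-strand
mate is stored in reference-forward orientation, as SAM requires; (iii)
an unmapped read with a mapped mate inherits the mate's position, while a
fully unplaced pair carries none. One global seed drives everything, with
fixed offsets per subsystem, so a cohort and any individual's reads can
be regenerated independently and byte-identically.

What the generator does **not** emulate: indel sequencing errors, quality
score models, GC or coverage bias, chimeric fragments, multiple
chromosomes, aligner-specific clip placement heuristics, and other
repeats in the reference that could attract clipped tails. Passing tests
therefore demonstrate correctness of the pipeline's logic under a clean,
known-truth model -- not robustness against every artifact of real WGS.
For real data, externally aligned SAM text can be ingested directly.

# Detection

Terminal soft clips of at least 5 bp (`minClipLen`; shorter clips are
alignment noise) become events; events on one side within `posTol = 2` bp
are merged, clusters below `minSupport = 3` reads are dropped, and each
cluster's clipped tails are collapsed to a per-position majority
consensus (right clips aligned at their left edge, left clips at their
right edge, reflecting which end of the element they sample). Every
(right cluster at *e*, left cluster at *s*) pair with *s* &le; *e* and
*e* &minus; *s* &le; `maxTsd = 50` bp becomes a candidate call with TSD
`[s, e)`; candidates sharing a cluster are resolved by highest combined
support, then smallest TSD -- a deterministic tie-break. The 50 bp bound
covers retroelement TSDs generously while excluding tandem-duplication
artifacts. `posTol` absorbs the +/- 1--2 bp wobble real aligners show in
clip placement; detection accuracy is asserted to +/- 2 bp for the same
reason.

The depth ratio annotates each call with median depth over the TSD
divided by the median flanking depth (+/- 500 bp, TSD excluded). In a
homozygote the ratio approaches 2 but sits somewhat below it, because
junction reads whose aligned anchor would be shorter than a mapper's
minimum stay unmapped and contribute nothing to either side of the
junction.

# Assembly and annotation

Assembly mirrors a single-amplicon reconstruction task: unidirectional
greedy extension from the 5' junction consensus. At each step the read
with the longest exact suffix--prefix overlap of at least `minOverlap =
31` bp is merged (reads sorted lexicographically first, so the result is
a pure function of the input multiset). Harvested input is: clipped tails
at the two breakpoints, unmapped reads whose mates map within 1 kb of the
call, and -- decisively -- fully unplaced pairs, both orientations. With
350 bp fragments inside a 6.4 kb element, the interior is covered almost
exclusively by unplaced pairs, so without them no short-insert assembly
could cross the element. The restriction of the greedy merge to the
growing contig (rather than all read pairs) keeps the assembly linear in
read count without changing the greedy criterion.

Two numerical details matter. First, a substitution error in the most
recently merged tail blocks every subsequent exact overlap; the assembler
then backtracks by trimming terminal bases one at a time (budget 200
in total) until extension resumes, and if extension never resumes the
longest contig ever held is returned. Second, extension stops the moment
the growing 3' end is an A-run of 15+ bp: the element's poly-A tail is a
homopolymer that short reads cannot size, so the reported poly-A length
is a lower bound and the contig ends a few bases into the tail. The
assembled length is therefore expected to sit up to ~15 bp below the
true element length; the structure checks allow 25 bp.

Classification against a repeat library uses 11-mer seeds voting for a
diagonal per library entry and strand (k-mers occurring more than 5 times
in an entry are masked as low-complexity seeds), followed by a base-wise
identity count over the best diagonal's full overlap -- an ungapped
alignment, sufficient for substitution-mutated copies, with hits below
40% identity discarded as chance diagonals. ORF calling scans all six
frames for ATG-to-stop spans trimmed to the outermost ATG per
(stop, frame); ORF1 and ORF2 are the two longest non-overlapping forward
ORFs on the element strand, ties broken leftmost. The element is "full
length" when both ORFs reach 90% of the lengths found in the classifying
library entry. Orientation is the best hit's strand compared with the
host gene strand. The packaged library is synthetic (the generator's
element plus random decoys); a curated L1 consensus can be supplied for
real data, and percent identity to it is computed over the aligned span
only.

# Genotyping

The wet-lab assay this replaces is a three-primer competitive PCR read
out by fragment size; in silico, the two alleles are counted from reads.
A read supports the reference allele if it spans the TSD with 5 bp to
spare on both sides with no terminal clip, and the insertion allele if it
is clipped within `posTol` of either breakpoint. The two capture windows
differ in width (two clip windows of ~76 bp each versus one ~76 bp
spanning window), which biases the raw insertion-read fraction of a
heterozygote to ~0.64. The genotype decision therefore thresholds a
window-corrected balance -- each count divided by its capture width --
whose expectation is 0, 1/2 and 1 for the three genotypes; the raw
fraction is still reported. The het band is (0.2, 0.8) and calls need 8
informative reads (`minDepth`), below which the individual is excluded
(NOCALL), never imputed. Amplicon-size prediction locates a primer pair
on the wild-type template and adds element + TSD length for the
insertion allele, reproducing the diagnostic size gap (e.g. 180 bp
versus 6,596 bp products).

# The association battery

All estimators are implemented from first principles; `stats::fisher.test`
and `stats::glm` appear only as independent cross-checks in the test
suite.

* **Exact test.** The genotypic 2x3 table is tested with the
  Freeman--Halton generalisation of Fisher's exact test: enumerate all
  tables with the observed margins (a few thousand at these sample
  sizes), compute each table's multivariate hypergeometric probability
  via log-gamma, and sum the probabilities of tables no more probable
  than the observed one. A relative tolerance of 1e-12 on the
  probability comparison absorbs floating-point ties. Zero-margin rows
  or columns are collapsed first, with a warning. The genotypic (2 df)
  reading, rather than an allelic 2x2, matches the magnitudes of the
  published P-values reproduced by `reproducePublishedStats()`.
* **Logistic models.** Maximum likelihood by iteratively reweighted
  least squares on grouped (count-weighted) data; convergence when the
  score's maximum absolute entry falls below 1e-10, cap 50 iterations,
  step-halving if the likelihood would decrease, covariance from the
  inverse observed information. Complete or quasi-complete separation is
  flagged (coefficient beyond 15 on the logit scale) and reported as a
  non-converged fit rather than a number. The per-allele model is
  `logit P(case) = a + b*dose (+ study)`, with one indicator per
  additional study; the published pooled odds ratio and Wald interval
  correspond to `exp(b)` under exactly this coding, and the headline
  pooled P-value corresponds to the 1-df likelihood-ratio test of the
  per-allele term against the study-only null.
* **Model shape.** The general (genotypic) model frees separate
  heterozygote and homozygote effects; twice the log-likelihood gap to
  the per-allele model is chi-square on 1 df. A recessive locus -- no
  heterozygote risk -- rejects the linear shape, which is the statistical
  signature of the published "non-linear" conclusion; no test statistic
  for it was printed, so it is validated here by type-I and power
  simulation instead.
* **LD r-squared** is the squared Pearson correlation of per-individual
  genotype dosages (0/1/2), as in standard GWAS toolkits. The published
  r-squared values (0.94, 0.97) cannot be recomputed without the
  individual-level joint genotypes, which were never printed; the
  implementation is instead verified to return exactly 1.0 under perfect
  LD and to match the covariance formula on simulated pairs.
* **Concordance.** From pooled 2x3 counts: the percentage of cases that
  are not homozygotes, the percentage of controls that are, and the
  penetrance fraction among homozygotes. Rounding (half away from zero)
  happens only in the printed view; raw fractions are retained. Note the
  two distinct case-side quantities: 100 minus the discordant-case
  percentage (78%) and the penetrance among homozygotes (57/69 = 83%);
  both are reported.

```{r battery}
stats <- reproducePublishedStats()
signif(stats$exactP, 2)
stats$l1
```

# Problem sizes and reproducibility

The packaged checks run the whole chain at the study's stated sequencing
conditions (21x, 100 bp pairs) on a 20 kb reference window -- large
enough that flanks dwarf the fragment length, small enough that a
ten-seed recovery sweep (simulate, detect, assemble, annotate) completes
in well under a minute. The cohort-level pipeline default is 40
individuals at insertion-allele frequency 0.4, which yields all three
genotype classes with near certainty. `scripts/acceptance.R` re-runs the
ten-seed recovery from scratch and writes the recovered TSD length and
assembled contig length as JSON.

# Known limitations

* Exact-overlap assembly tolerates substitution errors only via
  backtracking; indel errors or very high error rates would require a
  consensus-aware assembler.
* The detector uses clip clusters and depth only; discordant-mate-pair
  evidence is not integrated, and only one locus is considered per
  window.
* Heterozygote detection at 21x rests on ~5--8 clipped reads per side;
  at half that depth, `minSupport = 3` starts to miss heterozygotes.
* The Freeman--Halton enumeration is exponential in table size; it is
  meant for the r x c tables of a candidate-locus study, not for
  genome-wide scans.
* The phenotype model is a pure recessive-with-phenocopies Bernoulli
  model; age of onset, relatedness and population structure are out of
  scope.
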