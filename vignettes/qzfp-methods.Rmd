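---
title: "Methods: Q-type C2H2 zinc-finger family analysis"
author: "qzfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Q-type C2H2 zinc-finger family analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qzfp)
```

This vignette documents the models, conventions and design choices
behind each analysis stage — what is computed, under which assumptions,
and what the synthetic-data tests do and do not demonstrate about real
data.

## Coordinate and sequence conventions

All coordinates in the package are **1-based inclusive**, the native
convention of GFF3, Biostrings and the wider R/Bioconductor ecosystem.
Interval arithmetic at the GFF3 boundary therefore needs no conversion;
the cost is that half-open interval formulas from other ecosystems must
be translated when comparing notes. Protein sequences are uppercase
20-letter strings; `X` (unknown residue) is tolerated and handled
per-descriptor (below). Gene models carry exon and CDS interval tables;
the "start codon" anchor used for promoters is the first CDS base in
transcription orientation, not the transcript start, because upstream
regions are conventionally measured from the translation start in
promoter-element surveys.

## Domain scanning and family grouping

The Q-type C2H2 finger is matched by the degenerate scaffold

```
C X(a) C X3 F X3 <hexapeptide> X(b) H,   a in 2..4, b in 3..5
```

with the hexapeptide either the invariant `QALGGH` (Q-type) or one of
the modified variants `KSLGGH`, `KALGGH`, `RSLGGH`, `RALGGH` (M-type).
Two choices deserve comment:

* **Cys–Cys spacer.** The family literature gives the spacer as
  `X(2-4)`; the stricter screens that produce compact family sets often
  use `X2` only. The default is the permissive 2–4 range (the family
  definition); `zf_pattern_config(cys_spacer = c(2, 2))` reproduces the
  strict screen. Both are documented because the choice changes which
  borderline proteins enter the family.
* **M-type definition.** "Modified QALGGH" is not a precisely defined
  set in the literature. The default list is the four variants that
  appear in clade naming (`KS/KA/RS/RA-LGGH`); `relaxed_m = TRUE`
  accepts any hexapeptide ending in `LGGH`. The scanner never reports
  other hexapeptides, so a protein whose finger deviates further is
  invisible to the scan — a deliberate conservative bias.
* **No trailing-residue requirement.** Some statements of the pattern
  end in "HX", suggesting a required residue after the final His. The
  scanner does not require one: a domain may end at the protein's last
  residue. Requiring a trailing residue would drop C-terminal fingers
  for no biological reason.

Matches are reported left-to-right and non-overlapping; at a given
start the shortest spacer expansion wins (smallest `a`, then smallest
`b`). This greedy rule is deterministic and is checked in the tests
against an exhaustive substring oracle. Group labels encode the domain
count (1 domain → `1i`, ... 4 → `4i`); membership requires at least one
Q-type finger, and proteins with more than four domains are flagged
`other` rather than dropped, so unusual architectures surface in
reports. Grouping uses the domain count alone; the His–His spacer is
retained as per-domain metadata but does not influence the group,
because the packaged 35-member reference set is fully explained by
count.

The scanner replaces a profile-HMM pre-screen with direct pattern
matching: a protein is family-eligible purely by scaffold match. This
is a methodological substitution — an HMM search scores diverged
fingers a regular pattern misses — so real-genome screens with this
package may be slightly more conservative than HMM-based ones.

## Auxiliary motifs

EAR repression motifs are matched as `L.L.L` (`LxLxL` variant) and
`DLN.{1,2}P` (`DLNx(1-2)P` variant); the L-box core as
`E.E..A.CL..L`. The wildcard positions accept **any** residue,
including L, D and P themselves, since no exclusion rule is documented
for these signatures. All occurrences are reported, overlapping ones
included; a protein with both EAR variants counts once toward "has an
EAR motif" but contributes to both per-variant tallies. Terminal
position classes use a configurable terminal fraction *f* (default
1/3): a hit is C-terminal when it starts in the last *f* of the
sequence, N-terminal when it ends within the first *f*, otherwise
internal. The default 1/3 is a convention, not a biological constant —
published statements like "predominantly C-terminal" come without a
cutoff.

## Physicochemical descriptors

All four descriptors follow the conventions of the standard ProtParam
tool, so values are comparable with published family tables:

* **Molecular weight**: sum of *average* (not monoisotopic) residue
  masses plus one water (18.0153 Da).
* **Theoretical pI**: root of the Henderson–Hasselbalch net-charge
  equation over the termini and D/E/C/Y/H/K/R side chains with the
  Bjellqvist pKa set, found by bisection on [0, 14] to 1e-4 pH units.
  Net charge is strictly decreasing in pH, so the root exists and is
  unique; the returned value satisfies |charge| < 1e-3. The pKa table
  is packaged data and swappable in principle — published pI values
  depend on the exact table the computing server used at access time.
* **Instability index**: `(10/L) * sum(DIWV(x_i, x_{i+1}))` over
  consecutive dipeptides with the published Guruprasad weights; values
  above 40 are conventionally "unstable". Note the exact formula keeps
  the `(L-1)/L` factor: a homopolymer's index approaches, but does not
  equal, `10 x DIWV` for finite lengths.
* **GRAVY**: mean Kyte–Doolittle hydropathy, bounded in [−4.5, 4.5].

`X` residues are excluded from mass/hydropathy sums and from dipeptide
pairs, while still counting toward sequence length; each result
carries an `n_x` attribute so silent degradation is visible. Group
summary means of Da-scale fields are **truncated** (floored) to
integers because that is how family-level average weights are reported
in the packaged reference table's source; min/max are left unrounded.

## Packaged reference table

`load_table1()` ships the 35-member sugar beet family table (gene
names, locus ids, protein/ORF lengths, molecular weight, pI,
instability, GRAVY, genomic coordinates, group). It is checksummed and
validated at load: 35 rows, ORF bp equal to exactly three times the
protein length on every row (the stop codon is excluded from the ORF
length under this convention — every row satisfies it exactly), groups
within 1i–4i. The table is both a usable reference dataset and the
regression surface for `validate_against_table1()`, which compares a
pipeline report per member with tolerances of 0.5 Da for molecular
weight and 0.05 for pI (descriptor implementations legitimately differ
at that scale) and exactness elsewhere.

## Phylogenetics

Distances are p-distances (mismatch proportion) with three gap-deletion
modes: `complete` (drop any gapped column), `pairwise` (per-pair), and
`partial` with a coverage threshold (default 0.95, the common default
in desktop phylogenetics tools). A Poisson correction `-ln(1 - p)` is
available; p-distance is the default because the alignment is an input
and no substitution model is assumed. Neighbor joining follows the
Saitou–Nei Q-criterion with a deterministic tie-break
(lexicographically lowest active pair), so results are reproducible to
the byte; negative branch-length estimates are clamped to zero with a
warning, per common practice. On additive matrices the implementation
recovers the generating tree exactly (tested against an exhaustive
least-squares topology oracle for 4–6 taxa and against the reference
implementation in ape).

Bootstrap supports resample alignment columns with replacement, rebuild
the tree per replicate, and report the percentage of replicates
containing each internal bipartition of the full-data tree. Supports
live on internal edges only; the basal trifurcation has none.

Clade assignment is by nearest anchor in tree path length. The
reference anchor panel is a **required input**: the 58-sequence
Arabidopsis anchor set used in published family trees is not
redistributable from here, so the package does not pretend to ship it;
tests use synthetic five-clade panels with two anchors per clade. The
clade vocabulary includes `C1-QM-C` for completeness although
demonstration sets exercise five clades; exact ties between anchors of
different clades leave a member `unassigned` with a warning rather than
silently picking one.

## Ka/Ks (NG86)

Site counting assigns each codon position a synonymous fraction equal
to the share of synonymous changes among its three single-nucleotide
changes, **excluding changes that create stop codons from both
numerator and denominator**. With this convention each position
contributes exactly one site and S + N equals the nucleotide length —
an invariant the tests enforce. Site counts are averaged over the two
sequences. Codons differing at k positions are resolved over all k!
minimal mutational pathways; pathways through stop codons are excluded
(with a fall-back to all pathways in the degenerate all-blocked case,
which cannot occur for single-position differences). Proportions are
Jukes–Cantor corrected; a proportion at or above 3/4 leaves the
correction undefined and the result is flagged rather than truncated.

Selection classes follow the standard reading with a neutrality band of
1e-9 around Ka/Ks = 1 (exact equality is measure-zero). A published
per-pair ratio from a different calculator is not expected to reproduce
to the digit — estimator choice (NG86 vs LWL85 vs YN00) shifts ratios —
which is why the tests validate this module against a brute-force
pathway oracle and a planted-truth simulation rather than against any
single published number.

`evolve_cds_pair()` plants **exactly** the requested synonymous and
nonsynonymous substitution counts, one per codon, never through stops.
One-change-per-codon keeps the pathway count unambiguous, so the
estimator's `Sd`/`Nd` must equal the planted counts exactly — a sharp
test. The cost is that multi-hit codons are only exercised by the
separately constructed oracle tests, not by the generator.

## Promoters and cis elements

Promoter windows are the configured length (default 2000 bp, the usual
window in plant promoter surveys) upstream of the start codon: for
minus-strand genes the genomic window right of the CDS end,
reverse-complemented so the returned sequence always reads 5'→3' toward
the start codon. Windows clip at chromosome boundaries and carry a
`clipped` flag; they never overlap the CDS. Scanning matches IUPAC
consensi via Biostrings on the forward strand and (by default) the
reverse complement, reporting promoter-relative offsets and match
strands; overlapping hits all count, because published element tallies
count raw occurrences. Both-strand scanning is the default since
element orientation is usually not annotated; it is configurable for
dictionaries whose elements are strand-specific.

The default element dictionary is a small **curated set of defaults**
(ABRE, TGACG-motif, TGA-element, TATC-box, TCA-element, LTR, MBS,
W-box, CAT-box, O2-site) with plausible consensi and category labels.
It is explicitly not a reproduction of any web service's proprietary
dictionary; analyses that depend on a specific dictionary must supply
their own table (`element_name`, `consensus`, `category`). Gene-level
summaries flag genes with at least 10 elements by default, mirroring
how element-rich promoters are typically highlighted.

## Expression

FPKM is computed as `counts x 1e9 / (library_size x gene_length)`;
library sizes default to column sums but can be supplied (the synthetic
generator fixes them at 1e6 so planted fold changes are exact in
expectation). Heatmap-ready values are `log2(FPKM + 1)`.

Two documented rules replace model-based differential testing, which is
out of scope here: a gene is "expressed" in a tissue when its mean
control FPKM exceeds 1 (a conventional detection threshold; published
tissue-specificity statements rarely state theirs), and a contrast is
called up/down when `log2((mean_t + 1)/(mean_c + 1))` crosses ±1. Both
thresholds and the pseudo-count are arguments, and outputs carry the
means so calls can be re-derived under other rules. These calls are
coarser than an edgeR-style analysis: they ignore dispersion and
replicate variance, and should be read as screening calls, not
significance statements.

## Synthetic data: what it does and does not show

The generators are seeded and byte-deterministic (`sim_config(seed)`;
identical configs give identical outputs, and the caller's RNG state is
restored). Default conditions mirror the study system they emulate: a
35-member family split 22/6/6/1 across groups 1i–4i, an EAR motif in
~90% of members (the published family has 32/35), 2000-bp promoters,
two tissues, a 0/12/24/48/72-h salt time course, a virus-vs-mock
contrast, three replicates, negative-binomial counts with dispersion
0.1 and planted fold change 4 on a baseline mean of 100 counts
(FPKM 100 at the fixed library size). Domain complements per group are
1i: Q; 2i: QQ; 3i: QQM; 4i: QQMM, matching the observation that
modified fingers appear in the higher groups; multi-finger members also
carry an L-box.

Three constructions make recovery tests exact rather than statistical:

* **Member linkers** avoid the letters C, F, H, L, D, E, so the planted
  domains/EAR/L-box are provably the only pattern matches in a member
  (each pattern needs at least one of those letters, which occur only
  inside planted features, and features are spaced further apart than
  any pattern length).
* **Background proteins** are uniform over all 20 residues and
  rejection-sampled against a regex (independent of the loop-based
  scanner under test) until they contain no scaffold, EAR or L-box
  match.
* **Promoter backgrounds** are drawn over {A, C} only; every default
  element contains at least one G or T, so elements can only match at
  planted positions on either strand. The generator verifies
  planted-only matching at build time and re-draws on the theoretical
  collision.

Consequently, perfect precision/recall on synthetic data demonstrates
the *coordinate bookkeeping* (strand handling, clipping, overlap rules,
spacer geometry) is correct — it does **not** demonstrate sensitivity
on real sequences, where fingers diverge beyond the recognised
hexapeptide set, promoters are full-alphabet, and motif-like strings
arise by chance. Statistical behaviour is exercised separately: the
expression caller is required to recover ≥95% of planted classes under
noise, and the Ka/Ks estimator's median ratio over 50 seeded replicates
at 300 codons must fall in [0.15, 0.25] under a true dN/dS of 0.2.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen
as the sizes at which the properties they check are already fully
expressed: 35-member proteomes (tens of kilobases of protein sequence),
9–12 gene synthetic genomes, 4–6-taxon trees against the exhaustive
topology oracle (the oracle's topology count grows super-exponentially;
at 6 taxa it already enumerates 105 trees), 100-replicate bootstraps,
300-codon alignments, and 40-gene count matrices. pI bisection
converges in ≤ 60 iterations; NJ tie-breaks, bootstrap seeds and all
generator randomness are fixed by explicit seeds; negative NJ branch
lengths clamp to zero with a warning; degenerate inputs (empty FASTA,
zero-exon models, all-gap alignment pairs, saturated codon pairs) error
with specific messages rather than propagating NA.

## Known limitations

* Pattern-based domain detection is blunter than profile HMMs for
  diverged fingers; the M-type set is a documented convention.
* Multiple sequence alignment is an input; the package does not align.
* The clade anchor panel and any specific cis-element dictionary must
  be supplied by the user.
* Expression calls are threshold rules, not hypothesis tests.
* Collinearity/synteny detection is out of scope; Ka/Ks gene pairs are
  an input.
* Real-genome family surveys additionally need the external genome
  resources themselves, which the package deliberately does not fetch.
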