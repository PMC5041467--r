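---
title: "Constructing RNA family models from a single sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing RNA family models from a single sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A newly discovered non-coding RNA is often the first known example of its
family.  To annotate relatives in other genomes one needs a *family model* —
a statistical profile of the family's sequence **and** secondary structure —
but building one traditionally requires a curated alignment of several known
members.  famforge automates the bootstrap: starting from one RNA sequence
(and optionally the taxon it came from), it collects putative homologs by
iterated similarity search, keeps only candidates whose *structure* is
conserved beyond what their sequence similarity alone would explain, and
returns members, a structural alignment with consensus structure, and a
calibrated family model.

The search is *taxonomy-guided*: close relatives are collected first, the
model is built and refined, then the search widens one taxonomic rank per
round.  This ordering matters — a model built from close homologs can judge
more divergent candidates that raw sequence search alone would score
ambiguously.

## The three phases

1. **Initial construction.**  The input sequence is searched against the
   sub-tree of its taxonomic *parent*.  Hits are pre-filtered (coverage
   strictly above 80% of the query; hits at ≥ 99% identity to the query or an
   existing member are redundant), expanded with flanking genomic sequence,
   and truncated back to the input scale by a semi-global alignment (input
   global, genomic excerpt local).  Each candidate is then gated on the
   normalized structure conservation index (below).  If a round accepts
   nothing, the search ascends one level and repeats, up to the root.  The
   accepted set plus the input is merged into a structural alignment, a
   consensus structure is folded, and the first family model is built and
   calibrated.

2. **Expansion.**  Each round ascends one taxonomy level and searches the new
   sub-tree *minus* the sub-tree already searched, so rounds partition the
   taxonomy and no organism is searched twice.  Up to five representative
   queries are used (the "first five" after collapsing members above 95%
   pairwise identity, or one representative per UPGMA cluster when clustering
   is enabled).  Pooled hits are filtered and truncated as in phase 1, then
   scored by the *current model*: E-values strictly below the strict cutoff
   (0.001) make a hit a member; E-values up to the relaxed cutoff (1.0) park
   it as a *potential* member for later re-evaluation.  After any round that
   added members, the members are re-aligned to the model, the consensus
   structure is recomputed, and the model is rebuilt and recalibrated.

3. **Finalization.**  One search round without taxonomic restriction, then the
   parked potential members are re-scored with the final model under the
   strict cutoff (passing ones join the family), and the model is rebuilt and
   calibrated once more.

## The gating statistics

Sequence identity is Levenshtein-based: with edit distance $D$ between the
*unaligned* input and candidate and $L$ the longer length,

$$SI = 1 - D/L.$$

Structure conservation is the SCI, the ratio of the consensus folding energy
of the pairwise alignment to the mean folding energy of its rows,
$SCI = E_{\mathrm{consensus}} / \overline{E_x}$.  An alignment of identical
sequences necessarily has $SCI = 1$, so conservation must be judged relative
to sequence identity:

$$nSCI = SCI / SI,$$

and a candidate is accepted when $nSCI > 1$ (strict).  Structured RNA
families conserve pairing through compensatory substitutions, which keep
$E_{\mathrm{consensus}}$ high while $SI$ drops — exactly the signal this
ratio isolates.  Two conventions make the ratio robust: energies are
stability magnitudes (non-negative, 0 when nothing folds), and $SI = 0$
yields $nSCI = 0$ (reject) rather than an error, so one junk hit cannot
abort a round.

## Backends

External heavyweight tools sit behind three contracts, each with an
in-package reference implementation, so the complete decision logic runs at
desk scale with no network access:

* **Similarity search** — best local alignment (Smith–Waterman, affine gaps,
  BLASTn-like +2/−3/−5/−2 scoring; a gap of length $k$ costs
  $\mathrm{open} + k\,\mathrm{extend}$) of every query against every
  in-scope contig on both strands, through Biostrings.  E-values follow
  Karlin–Altschul statistics, $E = K m n e^{-\lambda S}$, with $\lambda$
  solved from the scoring system under a uniform background.  At the
  contig sizes of the synthetic worlds an exhaustive scan is fast and
  deterministic, so no heuristic seeding layer is used.
* **Pairwise alignment for truncation** — sequence-based semi-global
  Needleman–Wunsch (match +2, mismatch −1, gap −2) with free end gaps on the
  genomic side.  Truncation needs coordinates, not structure; structure
  enters through the SCI gate.  The candidate is the *aligned span* of the
  expanded region, which may differ slightly from the input length.
* **Folding** — two backends.  The reference backend is a maximum
  base-pair-count folder (Nussinov-style, minimum hairpin loop 3, energy =
  number of pairs; the consensus variant scores a column pair only when
  *every* row can pair, and columns containing gaps never pair).  It is
  dependency-free and exactly checkable: identical rows give SCI = 1 with no
  floating-point slack.  The production backend shells out to ViennaRNA.
  There the two alignment-folding uses are deliberately parameterized
  differently: the **SCI** consensus energy uses default RNAalifold scoring
  (as in the RNA gene finder that introduced the index), whose strong
  penalty for inconsistent pairs makes the SCI collapse on alignments
  without conserved structure; the **consensus structure** used to annotate
  the family alignment is folded with RIBOSUM scoring and covariance weights
  (`--cfactor 0.6 --nfactor 0.5`), the parameterization recommended for
  consensus structure prediction.  Conflating the two (our first
  implementation did) lets dinucleotide-shuffled controls pass the nSCI gate
  more than half the time; with the split, shuffled controls essentially
  never pass while structure-conserved candidates always do.

## The family model

The reference family model is a *profile with pair bonuses*, standing behind
the covariance-model contract (build / calibrate / search / align) without
implementing stochastic context-free grammars:

* Per-column nucleotide scores are smoothed log-odds (pseudocount 0.5 per
  nucleotide) of column composition against a uniform background, in bits.
  Identical alignment rows are collapsed before counting — replicating a row
  must not sharpen the model (the analogue of effective-sequence-number
  weighting in covariance-model builders).
* Every consensus base pair carries a covariance bonus: the log-odds of
  observing complementary (Watson–Crick or G·U) residue pairs across rows
  against the independence expectation from the two smoothed column
  compositions.  A compensatory column pair therefore scores above a merely
  conserved one.
* Scoring places the model semi-globally (all columns consumed, free
  sequence flanks; gap open 4 bits, extend 1 bit) by dynamic programming,
  then adds the bonus of every consensus pair whose two aligned residues can
  pair.
* Calibration scores 200 sequences of consensus length drawn from a
  dinucleotide Markov null estimated on the member sequences and fits a
  Gumbel location/scale by the method of moments.  E-values are the
  database-size-scaled Gumbel tail,
  $E = (N/\mathrm{columns}) \cdot P(X \ge s)$, exactly linear in $N$.

**Database-size semantics.**  The pipeline sets the model-search database
size to the size of the similarity-search target collection (sum of contig
lengths), mirroring how a covariance-model search would be told the genome
size of the database just searched.  A fixed benchmark-style value
(e.g. $10^6$ or $10^9$ nt) can be supplied through the configuration; note
that inflating the database size by a factor $f$ inflates every E-value by
$f$ and will push genuinely homologous but divergent hits from the member
set into the potential set.

## Query selection

The default follows insertion order: collapse members above 95% pairwise
identity onto their first representative, take the first five.  The input is
member 0 and thus always a query while it remains a member.  Optional UPGMA
selection clusters members by average linkage on $d = 1 - SI$, raising the
cut height from zero until at most five clusters remain, and takes each
cluster's earliest member.  Starting the cut at height zero makes identical
members collapse even when fewer than five members exist — five identical
members yield one query, not five.  Ties in the dendrogram are resolved by
`hclust`'s deterministic merge order.

## The synthetic worlds

The simulator generates complete, deterministic test worlds: a 12-taxon,
depth-4 taxonomy (two "domains", four "genera", five "species", plus one
decoy species under every internal node), a 70-nt hairpin-with-bulge seed
RNA, family instances evolved along the tree, and 3-kb uniform-background
contigs with each instance embedded at a random position and strand,
together with a truth table of exact planted coordinates.

Evolution applies Poisson($rate \times length$) substitutions per branch.  A
substitution at a paired site is rescued with the compensatory probability
(partner set to the Watson–Crick complement), otherwise it breaks the pair.
Unpaired sites gain or lose single nucleotides at a small indel rate.  Each
branch draws from its own RNG substream, so overriding one branch's rate
(e.g. to create a strongly divergent clade) leaves every other branch's
sequence unchanged.

Default rates: 0.03 substitutions/site/branch, compensatory fraction 0.8,
loop indel rate 0.01.  With compensatory rescue, the *effective* divergence
per branch is roughly 1.5× the nominal rate, so the deepest leaf-to-leaf
identities land around 0.70–0.75 — inside the regime where a stringent
sequence search can still seed the iteration, which is the operating regime
of this construction strategy (its recall is bounded by what sequence search
can find; genuinely remote homologs require structure-aware search and are
out of scope).  A nominal 0.05 default was considered and rejected for
pushing deep splits to ~0.55 identity, below the detection floor of the
+2/−3 scoring regime.

What the simulator does *not* emulate: repeats and low-complexity sequence,
composition bias, rate heterogeneity along the molecule, indel length
distributions beyond single nucleotides, and sequencing artifacts.  Passing
the end-to-end tests therefore demonstrates the correctness of the decision
logic — scoping, filtering, gating, model refinement, bookkeeping — not
performance on real genomic data.

## Evaluation

Reconstructions are scored against the truth table: a reported member is
true when its provenance interval has ≥ 50% reciprocal overlap with a
planted interval (strand-agnostic; a hairpin locus refound on the opposite
strand is the same locus, and the pipeline deduplicates collected loci by
the same overlap rule).  Recall is planted instances recovered over planted;
specificity is true members over reported members.

Consensus structures are compared after projection onto the shared input
sequence: alignment columns where the input row has a gap are dropped, and a
pair losing one endpoint becomes unpaired.  The base-pair distance is the
symmetric difference of the projected pair sets, normalized by the ungapped
input length.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on the desk-scale
worlds above: 19 contigs of 3 kb, models of ~70 columns, 200 calibration
samples, 100 gate trials, oracle sweeps of ~$4^8$ string pairs and $10^4$
structure pairs.  A full pipeline run takes well under a minute on one CPU.

Numerical conventions worth knowing when reading the code: intervals are
0-based half-open on the plus strand everywhere (converted at format
boundaries); strict inequalities are used exactly where the decision rules
state them (coverage > 0.8, nSCI > 1, member E < 0.001, potential E ≤ 1);
DP traceback comparisons use an epsilon of 1e-7 with deterministic
preference order (match, then deletion, then insertion); derived RNG seeds
stay below $2^{31}$; and the root of the taxonomy is its own parent, so the
ascent terminates on the fixpoint `parent(node) == node`.

## Limitations

* The reference model is a profile with pair bonuses, not a full SCFG; it
  cannot model variable-length pair insertions the way a covariance model
  does, and its bit scores are not comparable with Infernal's.
* Truncation uses a sequence-only aligner; for families whose homologs are
  only alignable by structure, candidates may be truncated suboptimally
  before the gate sees them.
* Karlin–Altschul E-values assume ungapped statistics and a uniform
  background; they are calibrated for decision-making consistency, not for
  agreement with NCBI BLAST.
* The taxonomy traversal follows parent links only; ranks are annotations,
  not traversal rules.  The final phase performs a single unrestricted
  round (a per-kingdom split would be a configuration extension).
* Remote-service adapters (live BLAST, external structural aligner, external
  covariance-model toolkit) are intentionally absent; the backend contracts
  are the extension points.
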