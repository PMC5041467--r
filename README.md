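# famforge

Unsupervised construction of structural RNA family models from a single
sequence.

## The problem

Assigning a novel non-coding RNA to a family — or founding a new family for
it — normally needs a covariance model, and a covariance model needs a
curated alignment of several known members.  famforge automates that
bootstrap.  Given one RNA sequence (and optionally its NCBI-style taxon of
origin), it

1. searches the taxonomic neighborhood of the input for sequence-similar
   candidates, widening the searched sub-tree by one taxonomic rank per
   round while excluding everything already searched;
2. gates candidates on the **normalized structure conservation index**,
   `nSCI = SCI / SI`, where `SI = 1 − D/L` is Levenshtein-based sequence
   identity and `SCI = E_consensus / mean(E_x)` compares the consensus
   folding energy of the input–candidate alignment with the mean of the
   individually folded sequences.  Candidates with `nSCI > 1` conserve
   structure beyond what their sequence identity explains — the signature of
   a structured RNA homolog;
3. from the second round on, scores candidates with the current family model
   under dual E-value cutoffs (strict `E < 0.001` for membership, relaxed
   `E ≤ 1` for "potential" members re-examined at the end), re-aligning,
   re-folding the consensus, rebuilding and recalibrating the model after
   every round that grew the family;
4. finishes with one unrestricted round and a re-evaluation of all potential
   members under the final model.

The result is the member set, a structural alignment with consensus
structure (Stockholm `#=GC SS_cons`), a calibrated family model, a
machine-readable run log, and an evaluation report.

External heavyweight tools are abstracted behind backend contracts with
reference implementations in the package (Smith–Waterman search with
Karlin–Altschul E-values; semi-global truncation aligner; maximum-pairing
folding; a profile-with-pair-bonus family model with Gumbel calibration), so
the entire decision logic runs at desk scale with no network access.  When
ViennaRNA's `RNAfold`/`RNAalifold` are on the `PATH` they are used as the
production folding backend.

A synthetic-world simulator is part of the package, not an afterthought: it
evolves a structured RNA family along a small taxonomy with compensatory
base-pair mutations, embeds the instances in decoy contigs, and emits the
truth table that the end-to-end tests and the acceptance script score
against.

## Worked example

```r
library(famforge)

spec  <- family_sim_spec(seed = 42)     # 12-taxon world, 70-nt family
world <- simulate_world(spec)
world
#> <sim_world> 12 planted instances, 19 contigs of 3000 nt

bk <- default_backends()
bk$folding <- fold_backend_nussinov()   # exact reference folding
res <- benchmark_run(spec, pipeline_config(seed = 1), backends = bk)

res$report
#> <recovery_report> recall 1.000 (12/12 planted), specificity 1.000 (12/12 reported)
res$result
#> <family_result> 12 members, model of 75 columns, 25 log events
head(res$result$members[, c("id", "taxid", "origin", "evalue")], 5)
#> # A tibble: 5 × 4
#>   id                     taxid origin          evalue
#>   <chr>                  <int> <chr>            <dbl>
#> 1 input                      8 input     NA
#> 2 contig_t9/975-1045(+)      9 initial   NA
#> 3 contig_t4/718-785(-)       4 initial   NA
#> 4 contig_t2/319-389(+)       2 expansion  0.000000409
#> 5 contig_t5/1551-1623(+)     5 expansion  0.0000266
```

All 12 planted instances are recovered and nothing from the decoy contigs is
reported.  `origin` records how each member entered: `initial` members
passed the `nSCI > 1` gate against the input, `expansion` members passed the
strict model E-value cutoff in a later round (the E-value shown is from the
model that admitted them).  The alignment consensus, model and log are in
`res$result$alignment`, `res$result$model` and `res$result$log`;
`run_family_pipeline(..., outdir = "out")` writes `result.fa`, `result.stk`,
`model.json`, `log.jsonl` and `report.tsv`.

A command-line front end with the same outputs is installed as `exec/famforge`:

```sh
famforge run --input in.fa --taxid 8 --taxonomy tax.tsv \
             --targets genomes.fa --outdir out --seed 1
```

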