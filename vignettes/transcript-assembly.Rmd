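---
title: "Constraint-based transcript assembly with isocover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based transcript assembly with isocover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

RNA-seq reads aligned to a reference genome sample transcripts only in
short fragments. Reconstructing full-length isoforms from those fragments
is under-determined: within a gene, several combinations of exons can
explain the same read coverage, and most loci express more than one splice
variant. `isocover` addresses this with a three-stage, deliberately local
strategy:

1. **Exon inference per covered region.** Reads define maximal covered
   *regions*; splice-site boundaries (from gapped alignments) partition a
   region into *intervals*; candidate exons are interval runs delimited by
   an acceptor (or the region start) on the left and a donor (or the
   region end) on the right. Every feasible *combination* of candidate
   exons is scored by a small linear program over subexon coverages, and
   the best-scoring combination is kept.
2. **Splice graph and candidate transcripts.** Chosen exons become nodes;
   read-supported introns become directed edges; every maximal
   source-to-sink path is a candidate transcript.
3. **Transcript selection as set cover.** Each read or read pair
   contributes a contiguity *constraint* (the set of intervals it touches,
   its junction chain, and for pairs a fragment-length class). The final
   transcript set is the greedy (optionally annotation-weighted) set cover
   of all satisfiable constraints.

Decoupling exon inference from transcript selection keeps each linear
program tiny (a handful of variables per region) and makes no global
uniformity assumption about coverage — only that coverage is *locally*
roughly uniform within a region.

## The linear program

For a region partitioned into intervals $j = 1..k$ with observed mean
coverages $\bar C_j$ and lengths $L_j$, and a feasible exon combination
with subexon coverage variables $c_{i,j}$ (exon $i$ restricted to interval
$j$), the program is:

* **Additivity** (one slack per interval):
  $|\sum_i c_{i,j} - \bar C_j| \le \varepsilon_j$ — overlapping isoforms
  add up to the observed coverage.
* **Continuity** (one slack per adjacent subexon pair):
  $|c_{i,j} - c_{i,j+1}| \le \varepsilon_{i,j}$ — an exon's coverage does
  not jump across an internal boundary.
* **Conservation** (hard equality):
  $\sum_{i,j} c_{i,j} L_j = \sum_j \bar C_j L_j$ — total coverage mass is
  preserved.
* **Lower bound**: $c_{i,j} \ge 1$ read per base, so no phantom exons at
  zero expression.

The objective minimises total slack $\sum \varepsilon$. For paired-end
libraries a penalty is added per pair class $(i, j)$ whose achievable
fragment-length range, over chains of junction-linked member exons, misses
the window $f_\ell \pm 2 f_\sigma$ entirely: the penalty is the fraction
of pairs $n_{i,j}/N$ rendered unexplainable. The combination with the
minimal total score wins; ties go to fewer exons, then lexicographically
smallest boundaries (for reproducibility).

A combination enters scoring only if it is *feasible*: every splice site
must bound some member exon; every read must map onto a chain of member
exons whose boundaries match its junctions; and the two mates of every
pair must have compatible alignments — a member exon able to terminate the
left mate's chain must equal, or reach through junction-linked
non-overlapping members, one able to start the right mate's chain. The
mate-compatibility form of the third condition matters in practice:
with the weaker "inner endpoints lie in linked exons" reading, an
alternative donor and an alternative acceptor on the same exon admit a
chimeric subexon set that ties the LP at zero slack, and only
junction-spanning read pairs rule it out.

Numerical choices: the LP is solved with the dense two-phase simplex in
`boot::simplex` (systems here have at most a few dozen variables);
absolute values are linearised as paired inequalities; if conservation
plus the $c \ge 1$ bound is infeasible — possible at very low coverage —
the program is retried once with lower bound 0. Slack is allocated one
$\varepsilon$ per constraint (strictly more expressive than sharing one
slack across an exon's continuity constraints; it reduces to the shared
form when the optimum equalises them). Enumeration is capped at 16
candidate exons / 12 splice sites per region; beyond the cap, candidates
are restricted to exons with direct read evidence (uniquely required
exons, exact middle exons of spliced reads) plus a minimal completion per
splice site, and the downgrade is logged.

## Selection and weighting

Constraints deduplicate aggressively (all reads inside one interval
collapse to a single constraint), so the bipartite
constraint-by-transcript relation stays small. Constraints satisfied by no
candidate transcript — typically fragment-length outliers beyond
$2f_\sigma$ — are pruned as likely artifacts. Unweighted greedy cover adds
the transcript covering the most uncovered constraints; the weighted
variant minimises weight per newly covered constraint. A transcript's
weight is $1 + \lambda(1 - q)$ where $q$ is the fraction of its
consecutive intron pairs present in the evidence annotation
($\lambda = 1$ by default, so weights lie in $[1, 2]$); the additive 1
keeps fully supported transcripts at positive cost, which the ratio rule
requires. Transcripts with fewer than two introns have no intron pairs;
the measure is undefined for them and they get weight 1 rather than a
penalty that would bias against short genes. Tie-breaking is total:
largest gain (smallest ratio), then smaller weight, then more introns,
then smallest transcript id — selection is fully deterministic.

Multiplicity does not weight the cover objective: each *distinct*
constraint counts once, matching the set formulation; an abundant and a
rare isoform with private constraints are both kept.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_mapq` | 0 | phred | simulated alignments are unambiguous; raise for real data |
| `max_gap` | 0 | nt | zero-coverage gap bridged inside a region |
| `min_region_len` | 25 | nt | shorter covered islands are alignment noise |
| `min_junction_support` | 1 | reads | clean data; raise on noisy libraries |
| `min_anchor` | 8 | nt | junction flank needed to trust a gapped alignment |
| `frag_len`, `frag_sd` | estimated | nt | override when estimation is impossible (single-end) |
| `lambda` | 1 | — | weight scale for annotation evidence |
| `lp_lower_bound` | 1 | reads/base | minimum subexon coverage |
| `cap_candidates`, `cap_sites` | 16 / 12 | — | per-region enumeration cap |
| `max_paths` | 1000 | paths | per-component candidate cap, support-ranked |

Fragment statistics are estimated from pairs whose mates are both
unspliced and co-located in one region, with a 5% two-sided trim against
chimeras; the trimmed SD is rescaled by the truncated-normal consistency
factor, so the estimator is unbiased for Gaussian fragment lengths.
Because only pairs that fit inside a single exon are eligible, genes whose
exons are mostly shorter than the fragment length bias the estimate
downward (long fragments cannot be observed within an exon); downstream
use is robust to this because the window enters only as a pruning rule,
but libraries with short exons and precise external knowledge of the
insert distribution should pass `frag_len`/`frag_sd` explicitly.

## What the simulator emulates — and what it does not

`make_gene_models()` + `simulate_alignments()` generate multi-isoform
genes on a toy genome: 4–7 exons of 100–300 nt, introns of 100–500 nt,
1–3 isoforms per gene built from a base isoform by skipped exons,
alternative donors/acceptors, or alternative terminal exons; uniform
fragment sampling along each isoform proportional to its weight; Gaussian
fragment lengths truncated to the feasible range; exact spliced
alignments with gapped CIGARs and `XS` strand tags; no sequencing errors,
no multi-mapping, no intronic background.

Two design choices matter for interpreting results. First, all
alternative events of a gene act at a *single* variable site, so the set
of maximal splice-graph paths equals the true isoform set; with events at
multiple independent sites the graph also encodes mixed ("chimeric")
paths, and no assembler can distinguish them without fragments long
enough to span both sites — published accuracy on real data (~0.7
recall/precision) reflects that harder regime. Second, three-isoform
genes pair the exon skip with one alternative-splice-site event; the
(alternative donor + alternative acceptor)-on-one-exon combination is
excluded because it is provably not identifiable from coverage alone
(the LP ties exactly) and only stochastically identifiable from long
fragments. Passing end-to-end tests on this simulator therefore
demonstrates correctness of the machinery under locally concentrated,
identifiable alternative splicing with clean alignments — not performance
on error-prone, biased real libraries.

Problem sizes used by the test-suite and the reproduction script — 20
genes, depth 50, paired 75 nt reads, fragments 250 ± 25 nt — mirror a
small but fully determined study design; the suite also exercises
single-end mode, depth 30, and degenerate inputs (empty SAM, zero
fragments).

## Evaluation conventions

Transcript matching is by intron chain: in strict mode all of the
prediction's introns must appear consecutively in the reference (each
boundary within a margin `V`, default 0); compatible mode makes the
relation symmetric, which is the appropriate reading when the reference
itself may be partial (`V = 10` is customary there). Single-exon
transcripts match single-exon references by containment and can be
excluded wholesale (`multi_exon_only`), since single-exon assemblies are
predominantly artifacts. Effective coverage — the fraction of the assessed
transcript's exons inside the longest matched stretch — yields
recall/precision curves over cutoffs 0.1..1.0. Reported values are
rounded half-up to three decimals, the convention of published accuracy
tables; `F = 2RP/(R+P)`.

Exon-level accuracy distinguishes internal exons (both boundaries must
match), terminal exons (splice-site boundary must match, the exon must be
included in the reference exon), and unbounded exons (containment).
Distinct exons are counted once regardless of how many transcripts share
them.

## Known limitations

* Regions whose strand cannot be inferred (no spliced reads) yield
  unstranded single-exon models; overlapping genes on opposite strands
  with shared unspliced coverage are not deconvolved.
* The per-region LP sees only pairs with both mates in the region;
  cross-region pairs act later, as selection constraints.
* Path enumeration is capped; components encoding more than `max_paths`
  candidates return the highest-support paths and log truncation.
* No abundance estimation: selected transcripts can be quantified by any
  downstream tool.

## A worked run

```{r}
library(isocover)

sim <- simulate_rnaseq(file.path(tempdir(), "demo"), n_genes = 20,
                       seed = 1, depth = 50)
fit <- assemble_transcripts(sim$sam)
fit
tidy(fit)
write_gtf(fit, file.path(tempdir(), "assembled.gtf"))

rep <- accuracy_report(file.path(tempdir(), "assembled.gtf"), sim$gtf,
                       v = 0, multi_exon_only = TRUE)
rep
autoplot(rep)
```
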