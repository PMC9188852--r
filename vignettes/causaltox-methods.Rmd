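---
title: "Methods: causal drug–target profiling and network enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal drug–target profiling and network enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causaltox)
options(causaltox.quiet = TRUE)
```

`causaltox` contrasts the causal target profiles of a toxic and a non-toxic
compound group and places the resulting protein signature in its network and
pathway context. This vignette documents the model, the parameters that
matter, the design decisions taken where the design was genuinely open, and
what the synthetic fixtures do and do not demonstrate.

## The mode-of-action coding and its harmonization

All drug→protein (and later protein→protein) relations are coded on four
levels: **1** active–positive modulator, **2** active–negative modulator,
**3** active with no directional information, **4** inactive. The crucial
structural assumption is that 1 and 2 are *sub-groups* of 3: a source saying
"this compound is an agonist of X" and another saying "this compound is
active on X" are not in conflict.

Three kinds of evidence feed the profile:

* **Curated action terms** (mechanism records, receptor-pharmacology
  interaction tables, a DrugBank skim) are translated by exact,
  case-insensitive table lookup (`map_chembl_action()` and friends). An
  unmapped term is always an error carrying the term — silently assigning
  category 3 would launder vocabulary drift into fake "active" calls. The
  DrugBank table is a reconstruction under the same category semantics,
  since that vocabulary is not standardized; users can supply their own.
* **Assay records** go through `annotate_assays()`. Activity is decided by
  the pChEMBL cutoff (default 5, i.e. 10 µM; a single systemic-profile
  cutoff across protein families, adjustable per analysis). Direction comes
  from case-insensitive substring keywords in the assay description
  ("inhibitor" → 2, "channel opening activity" → 1, …). Substring matching
  is deliberate: it reproduces the semantics of leading-letter-dropped
  wildcard patterns used as a case-insensitivity workaround in graphical
  workflow tools, including their known false-positive surface ("activation"
  inside "inactivation"), which per-rule *exclusion phrases* guard against.
* **Exclusion rules.** A record is excluded — not guessed at — when (a) the
  activity comment contradicts the cutoff ("not active" at pChEMBL ≥ 5, or
  "active" below it; "inconclusive" always excludes), (b) pChEMBL is missing
  (activity cannot be established either way), or (c) keywords of both
  directions match and no exclusion phrase resolves the conflict. Choice (b)
  and the both-directions rule (c) follow the same philosophy as the
  consistency stage: contradictions are removed, never adjudicated.

## Consistency resolution

After deduplicating to unique (compound, target, category) connections,
`apply_consistency()` groups by drug–target pair and applies
`resolve_pair()`: {1,3} → 1, {2,3} → 2 (the more specific sub-group member is
retained — the alternative of keeping both rows would double-count compounds
in the significance stage), any set containing both 1 and 2 is removed, and
category 4 together with any active category is likewise treated as a
contradiction and removed. The report counts *connections*, not pairs: both
members of a removed {1,2} pair count as removed, all members of an agreeing
pair as retained. This bookkeeping is what makes percent-consistent
comparable with unique-connection totals; it is verified in the tests
against a brute-force enumeration of all 15 non-empty category subsets.

## Tissue filtering

`filter_tissue()` is presence/absence only: a target survives iff the
expression table lists it in the tissue of interest (case-insensitively). No
abundance threshold is applied, because the upstream evidence is a listing,
not a quantification. Targets absent from the table are dropped but counted
separately — expression catalogues have incomplete coverage, and a
well-known target disappearing at this stage is a coverage artifact the
analyst should see, not silent data loss.

## The significance quotient

For each protein and direction, distinct compounds per group are counted
(categories 1 and 2 only; category 3 never contributes to a directional
table) and scored as `n_tox / n_nontox`, or `n_tox` itself when the
non-toxic count is zero. Both rules use cutoff 5 by default: toxic-group
involvement at least five times the non-toxic group's, or at least five
toxic-only compounds. The score is a plain quotient with a cutoff, not a
test statistic — no p-value is attached, by design. Absolute counts are the
default; `normalize_by_group_size` divides counts by group sizes first
(useful for imbalanced groups) while the only-toxic rule deliberately keeps
using the raw count, since a normalized count has no natural "five
compounds" reading.

## Network and causal overlay

`build_network()` induces the STRING-style subgraph on a protein set,
rescaling combined scores to confidences in [0, 1]. The default
`min_score = 400` is the conventional medium-confidence threshold; the
upstream analysis this package generalizes did not fix one, so it is
exposed as configuration. `overlay_causal()` adds a *separate* directed
layer from SIGNOR-format records — protein–protein rows only, both
endpoints already in the network — with effects mapped to modes of
interaction by prefix ("up-regulates…" → 1, "down-regulates…" → 2,
non-directional terms → 3). The two layers are never merged: association
confidence and causal direction are different kinds of evidence. In GraphML
output the graph is directed (a single directedness per file), each
undirected confidence edge written once with `layer = "confidence"` and
causal edges with `layer = "causal"`.

## Topology-based enrichment

The enrichment stage replaces an external web service with a local,
documented reconstruction; numerical agreement with that service is *not*
claimed.

* **Random walk with restart** (`rwr()`): `s ← (1−r)·W·s + r·e` with `W` the
  column-normalized confidence-weighted adjacency and `e` uniform over the
  seeds. Dangling nodes keep their mass through a self-loop, so scores sum
  to 1 on every input and mass stays within the seeds' components. Default
  restart probability 0.5 (no published value to adopt; 0.5 balances local
  and global topology and is exposed in `enrichment_config()`).
  Convergence is declared at L1 change < 1e-10 (well below any score
  difference the downstream ranking could resolve), capped at 1000
  iterations with non-convergence an error, never a silent result. The
  iteration is tested against the dense closed form
  `s = r(I − (1−r)W)⁻¹e` on exhaustive small graphs.
* **XD-scores** (`xd_scores()`): node scores are rescaled so their mean over
  network nodes is 1; a pathway's raw score is the mean rescaled score over
  its in-network members; the XD-score is the deviation of that raw score
  from the mean over all scored pathways (hence XD-scores sum to zero).
  Pathways with no in-network member are skipped and reported. The
  XD > 1 significance convention is retained as the flagging threshold.
* **Overlap tests**: one-sided exact hypergeometric tails
  (`fisher_overlap()`, checked against direct enumeration) with
  Benjamini–Hochberg correction across all scored pathways of one run.

The pipeline builds the seed network (the toxicity signature's interactome)
on the significant proteins, but walks for enrichment over the network
induced on *all* tissue-filtered profiled targets: measuring a pathway's
proximity to the seeds only makes sense against a universe larger than the
seeds themselves.

## The synthetic-data generator

`generate_fixtures()` emits every input dialect with planted truth, fully
deterministic given its seed. Its defaults *are* the study conditions the
package was designed around: 180 toxic vs 272 non-toxic compounds, planted
separation 5 (the significance cutoff), contradiction rate 0.05 (so about
5% of unique connections are removed, the scale observed in practice for
multi-source MoA annotation), tissue fraction 0.8, and a planted
high-confidence clique + pathway on the negatively-modulated significant
proteins. pChEMBL values are drawn uniformly on [5, 9] for actives and
[3, 4.99] for inactives, keyword-bearing descriptions are category-consistent
by construction, and every planted significant protein is tissue-expressed.

What the fixtures *do not* emulate: real vocabulary noise (misspelled or
novel action terms), free-text assay descriptions beyond the keyword
templates, correlated protein panels, realistic network degree
distributions, or database version drift. Passing the planted-recovery
suites therefore demonstrates that the machinery is correct — precision and
recall 1.0 at the designed separation, the planted pathway at the top of
the XD ranking — not that real exports will be as clean; on real data the
exclusion counters and the unmapped-term errors are the instruments to
watch. Test and acceptance runs use a scaled-down shape (40/60 compounds,
50 targets, 10 pathways, 20 generator seeds), which keeps the planted
structure intact while the suite stays quick on one CPU.

## Degenerate inputs and tie-breaks

Empty compound lists, empty category sets, a tissue matching nothing, an
all-skipped pathway collection, and a seed set disjoint from the network are
all explicit errors or warnings, never silent empties (an empty *result*
after a legitimate filter is allowed and warned about). Reciprocal duplicate
STRING rows collapse to one undirected edge keeping the maximum score.
Significance ties are ordered by protein id for deterministic output; the
whole pipeline is bit-reproducible on identical inputs, with no unseeded
randomness anywhere.

## Known limitations

* Keyword mining is substring matching, not NLP; novel phrasings fall
  through to category 3 (active, direction unknown) rather than being
  guessed.
* The DrugBank action table and the assay keyword list are reconstructions;
  both are packaged as editable TSVs under `inst/extdata/mappings/`.
* The XD/RWR stage is a reconstruction of a network-propagation enrichment
  score; its absolute values are comparable within a run, not across tools.
* Tissue filtering inherits the coverage limits of the expression table;
  proteins missing from the table are reported but cannot be rescued.
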