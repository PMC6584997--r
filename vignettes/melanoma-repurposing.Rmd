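---
title: "Disease-based drug repurposing for cutaneous melanoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-based drug repurposing for cutaneous melanoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melanoseek)
```

## The problem and the approach

Cutaneous malignant melanoma has a large body of gene-level evidence scattered
across heterogeneous resources: genome-wide association studies (GWAS) link
risk alleles to the melanoma trait, phenome-wide association studies (PheWAS)
link variants to melanoma and skin-cancer phenotype codes, metabolomics
databases connect disease-associated metabolites to the enzymes and
transporters that process them, transcriptome studies nominate differentially
expressed genes, and curated disease--gene resources record causal loci for
the OMIM melanoma phenotype. Disease-based drug repurposing turns this
evidence directly into treatment hypotheses: pool every implicated gene and
protein into one harmonized set, find the approved drugs whose targets fall
in that set, remove drugs already used or trialled against melanoma, and keep
only the candidates whose mechanism plausibly counteracts the disease.

`melanoseek` implements that cascade as composable, data-frame-first
functions:

1. **Ingest** (`parse_gwas_evidence()`, `parse_phewas_evidence()`,
   `parse_metabolite_table()`, `parse_gene_list()`): five table dialects are
   harmonized into one evidence-record layout. Gene and protein symbols share
   a single namespace after uppercasing and whitespace stripping (with an
   optional user alias map); no live nomenclature service is queried, so runs
   are reproducible offline.
2. **Integrate** (`build_profiles()`, `venn_counts()`,
   `unified_gene_set()`): records collapse into per-gene provenance profiles
   carrying the set of supporting sources, per-source record counts, and the
   best association p-value where p-values exist (GWAS/PheWAS).
3. **Network** (`build_network()`, `network_stats()`, `export_network()`):
   the metabolite--protein associations become a bipartite graph (igraph
   underneath), exportable as SIF or GraphML for Cytoscape-style viewers.
4. **Drug cascade** (`map_drugs()`, `exclude_known()`,
   `pathogenesis_filter()`): the unified set is joined against drug--target
   records (approved drugs only, by default), known-indication drugs are
   removed by a name-level join, and the pathogenesis filter applies the
   concordance rule described below. Every drug's fate is logged in an audit
   trace.
5. **Connectivity** (`ks_enrichment()`, `connectivity_scores()`,
   `aggregate_drugs()`, `select_candidates()`): surviving candidates are
   scored against ranked drug-response expression signatures and oriented by
   anchor drugs with known melanoma relationships.

`run_pipeline()` chains all stages and returns a report with per-stage
drug/target counts; `generate_fixtures()` produces a complete synthetic input
tree with planted ground truth.

## The concordance model

Each annotated target carries a pathogenic direction: gain of function (GOF,
the gene's activity drives disease) or loss of function (LOF, the disease
reflects missing activity). Each drug--target link carries one or more action
modes. The verdict for a single (direction, action) pair is:

| action                          | GOF        | LOF        |
|---------------------------------|------------|------------|
| inhibitor, antagonist, blocker  | concordant | discordant |
| agonist, inducer, activator     | discordant | concordant |
| substrate, binder, unknown      | neutral    | neutral    |

A target's verdict over its action set is: concordant if any action is
concordant; otherwise discordant if any action is discordant; otherwise
neutral. The **strict** policy stops there. The **lenient** policy downgrades
a discordant target verdict to neutral when a neutral action co-occurs,
acknowledging that a drug recorded as both substrate and agonist of a GOF
target may act primarily through the direction-free mode. A drug is retained
when at least one *annotated* target is concordant or neutral; unannotated
targets are dropped from consideration rather than treated as evidence either
way, and a drug with no annotated target is rejected with reason
`NO_ANNOTATION`. Substrate is deliberately neutral rather than discordant:
published candidate panels retain substrate drugs under both GOF and LOF, so
substrate cannot be direction-breaking. The default policy is strict; the
switch exists because published panels contain at least one pairing (an
inhibitor kept on a LOF target) that no strict rule reproduces.

## The connectivity score

A ranked signature is a strict permutation of the gene universe, position 1 =
most up-regulated, as produced by rank-transforming a drug-treatment
expression profile (RNK files; ties must be resolved upstream). For a tag set
of size $t$ with ascending rank positions $V(j)$ in a list of $n$ genes,

$$a = \max_j\left[\tfrac{j}{t} - \tfrac{V(j)}{n}\right],\qquad
  b = \max_j\left[\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right],$$

and the enrichment score is $ES = a$ if $a > b$, else $-b$. Positive scores
mean the tags concentrate at the top of the ranking. Worked examples in a
universe of 10: tags at positions $\{1,2\}$ give $ES = 0.8$; tags at
$\{9,10\}$ give $ES = -0.9$.

Two discretization facts are worth stating because they are easy to assume
away:

* **The statistic is not exactly antisymmetric.** Reversing the ranking maps
  $a \to b - 1/n$ and $b \to a + 1/n$, so $ES(\mathrm{rev}) = -ES$ holds only
  up to the $1/n$ rank step in sign-definite cases ($|a-b| > 2/n$), and fails
  qualitatively for near-symmetric tag placements: tags at $\{1, n\}$ reverse
  onto themselves with an unchanged, non-zero score. The example pair above
  shows the $1/n$ offset ($0.8$ vs $-0.9$). The test suite asserts the exact
  property (agreement with a brute-force oracle on the reversed ranking) and
  the $1/n$-bounded negation where it genuinely holds.
* **Tagging the whole universe gives $ES = -1/n$**, not $0$: $a = 0$ while
  $b = 1/n$, and the tie-break prefers $-b$.

The per-instance connectivity combines the up- and down-tag scores: when both
sides are present and agree in sign the signature does not discriminate the
query and the raw score is 0; otherwise $raw = ES_{up} - ES_{down}$. An empty
side contributes 0 to that difference — this keeps a single formula for both
the two-sided and one-sided cases and preserves the sign convention that
down-tags at the top of a ranking indicate a reversed (negative) response.
Raw scores are then rescaled across the instance collection: positive raws
divided by the maximum positive raw, negative raws by the magnitude of the
minimum negative raw, so the extremes map to exactly $\pm 1$.

Per drug, `mean` is the arithmetic mean of its instances' scores and
`enrichment` is the same KS statistic applied to the drug's instance
positions within all instances ordered by decreasing score (ties broken by
instance id for determinism). With this formula top-concentration is already
positive, so no extra sign flip is applied; published connectivity outputs
vary in sign convention, and this package fixes top = positive throughout.

Final selection is anchor-oriented: a candidate is retained when its mean
agrees in sign with the mean of the positive anchors (drugs with known
activity against the disease — paclitaxel and vinblastine by default),
disagrees with the negative anchors (selegiline, which suppresses apoptosis
in melanoma cells), and exceeds `min_abs_mean` in magnitude. The default
threshold is 0: the published criterion is a correlation *sign*, not a
magnitude, so magnitude thresholding is exposed but off. Candidates absent
from the signature panel are reported as `NOT_IN_CMAP` rather than silently
dropped. Requesting tag genes outside the universe is an error by default
(`skip_missing = TRUE` downgrades it to a warning) so that harmonization bugs
surface instead of silently shrinking the query.

## The synthetic study and what it does (and does not) emulate

`synth_config()` defaults encode the study conditions end-to-end: per-source
unique-gene counts 55 (GWAS), 260 (PheWAS), 616 (metabolomics proteins), 27
(transcriptomics), 11 (biomedical); 50 genes planted in two or more sources;
23 metabolites with 800 total associations (every protein covered at least
once); GWAS p-values drawn log-uniformly on $[4\times10^{-37},
8\times10^{-6}]$ and PheWAS on $[1.106\times10^{-16}, 0.05]$; a mapping stage
of 731 approved drugs over 193 targets (plus non-approved and off-set decoys
the mapping must reject); a 215-drug trial list overlapping the panel in
exactly 75 drugs; annotations under which exactly 277 drugs spanning 74
targets survive the strict filter; and a final connectivity-active panel of
35 drugs spanning 20 targets, plus 60 planted-reversed drugs, with the
remaining survivors left out of the signature panel to exercise the
`NOT_IN_CMAP` path.

Note that the five source sizes sum to 969 memberships, so with 50
multi-source genes the unified set has roughly 910–919 members — a published
total of ~1178 unique members is not reachable from these per-source counts,
and the generator reports its own manifest union rather than forcing an
inconsistent figure. Similarly, removing 75 of 731 drugs leaves 656 (some
published text says 658), and the metabolomics protein count is taken as 616
(one passage says 617); the pipeline always reports computed counts.

Signature rank bias uses a truncated geometric distribution: an active drug's
up-tags get rank positions drawn without replacement with weights
$(1-r)^{k-1}$ from the top (down-tags mirrored from the bottom), where $r$ is
the `concentration` parameter (default 0.05, i.e. a mean unbiased draw depth
of ~20 in a 1000-gene universe). Geometric bias was chosen because it has one
interpretable parameter and a clean extreme: as $r \to 1$ the tags pack the
list ends and the connectivity score approaches $\pm 1$. Reversed drugs swap
the two biases; inactive drugs are uniform permutations whose mean
connectivity is near 0.

One master seed drives a separate named stream per generator (`evidence`,
`pharm`, `signatures`), so regeneration is byte-identical and adding a
generator never perturbs another's draws.

What the generator does **not** emulate: linkage structure among SNPs,
realistic minor-allele or effect-size distributions, correlated expression
(each signature instance is independent), batch or cell-line effects, and
drug-name messiness beyond case/punctuation variants. Passing the recovery
tests therefore demonstrates that the pipeline's *logic* is correct under the
planted study shape — not that the statistical behaviour on real catalog
extracts or real connectivity data would be identical.

## Numerical and design choices

* **p-value thresholds are inclusive** (≤): the retained PheWAS range
  includes 0.05 itself. The GWAS reader defaults to `p_max = 1` because the
  documented GWAS bound ($8\times10^{-6}$) reads as the observed maximum of a
  pre-filtered catalog extract, not a selection rule; it is a parameter when
  a rule is wanted.
* **Multi-gene cells** split on commas/semicolons, and intergenic
  `"GENE1 - GENE2"` labels contribute both flanking genes: nearest-gene
  annotation gives no principled way to pick one.
* **Unknown tokens are preserved, not dropped**: unmapped action strings
  become `UNKNOWN` (neutral in the concordance model) with a warning, and
  unknown metabolite-protein roles become `UNKNOWN`; silent dropping would
  change downstream counts.
* **Drug identity for exclusion is name-level**, case- and
  punctuation-insensitive, because trial registries carry no database
  accessions.
* **Ordering is deterministic everywhere**: gene sets are sorted with a
  locale-independent radix sort, selection output is ordered by decision,
  |mean|, then name, and reports are byte-identical across reruns.
* **Name collisions between a metabolite and a protein** are kept as two
  nodes (the graph is strictly bipartite) and disambiguated with `m:`/`p:`
  prefixes only in exports.
* **Degenerate inputs**: empty evidence yields an empty report with a
  warning; an empty trial list excludes nothing; conflicting GOF/LOF
  annotations for one target are an input error naming the target, as are
  two drug names sharing one accession.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the full default-sized synthetic
study (969 source memberships, 931 drug-target rows plus decoys, 196
signature instances over a 1000-gene universe) in a few seconds; unit tests
use a proportionally scaled configuration (about one fifth of each count)
where many runs are needed. The KS implementation is checked against a
brute-force oracle on 1000 random instances with $n \le 50$.

## Limitations

The pipeline inherits every bias of its inputs: catalog extracts decide which
genes can be found, the trial list decides what counts as "known", and the
annotation table decides which targets are judged. Anchor-oriented selection
keeps only candidates resembling the anchors' expression behaviour, so drugs
with novel mechanisms are invisible to it by construction. Permutation
p-values and specificity scores for the connectivity step are out of scope,
as is any live querying of the upstream services.
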