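---
title: "Methods: composite repurposing scores from structure, targets and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite repurposing scores from structure, targets and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugrepo)
```

## The model

Drug repurposing here is a similarity argument with three legs. A candidate
compound is a plausible treatment for a disease if it (1) looks like a drug
already approved for that disease, (2) hits the same protein targets as
that drug, and (3) has targets that sit close to the disease's associated
genes in the protein–protein interaction (PPI) network. Each leg is scored
on [0, 1] and the composite score is their unweighted mean; no leg is
privileged, so a candidate weak on one component can still rank well if the
other two are strong. This matters in practice because target profiles are
sparse — most compounds have only a handful of experimentally measured
targets — and the network component compensates when direct target overlap
is missing.

### Structural similarity (TC)

Structures are compared as ECFP4 fingerprints: extended-connectivity
circular fingerprints of radius 2, computed by the OpenBabel backend of
ChemmineOB and folded to its fixed 4,096-bit length. ECFP is invariant to
atom numbering, so equivalent SMILES writings of one molecule give
identical bit vectors; the Tanimoto coefficient
`N_AC / (N_A + N_C − N_AC)` is then a set similarity over substructure
bits. The fold length follows the toolkit; Tanimoto is length-agnostic, so
this choice does not bias scores, only bit-collision rates. Two empty
fingerprints formally give 0/0; the package defines that similarity as 0 so
that structureless records can never rank as perfect matches. Compounds
whose SMILES fail to parse are excluded from scoring with a logged count
rather than aborting a large run.

### Target overlap (OCTS)

A compound's profile is its set of *potent* targets: a (compound, target)
pair qualifies if any quantitative measurement (IC50/Kd/Ki-type, in nM) for
the pair is ≤ 1000 nM, or if a curated unary interaction exists — unary
databases report experimentally verified interactions without potency
values, and discarding them would empty the profiles of many approved
drugs. The 1000 nM cutoff separates potent from inactive bioactivities
(inactive profiles are typically reported above 10,000 nM). Aggregation
across repeated measurements is permissive by default (*any* qualifying
measurement keeps the pair); a median-based rule is available via
`filter_potent(aggregate = "median")` for users who prefer a consensus
across conflicting assays.

Profiles are compared with the overlap (Szymkiewicz–Simpson) coefficient:
the intersection divided by the *smaller* profile's size. With typical
profiles of fewer than ten measured targets against a druggable genome of
thousands, a union-normalized (Jaccard) index would be dominated by
coverage asymmetries; normalizing by the smaller set gives 1 whenever one
profile contains the other, which is the intended reading of "shares the
drug's known targets".

### Network proximity (CDS)

For compound targets `C_G` and disease genes `D_G`, every gene in either
set contributes the unweighted shortest-path distance to the nearest member
of the other set, and the finite contributions are averaged — the
bidirectional "closest" proximity, whose term count matches the
`|C_G| + |D_G|` denominator. Genes absent from the network, or with no path
to the other set, are excluded from the average rather than assigned a
penalty distance; inventing a penalty (graph diameter, say) would mix a
topological artifact into a biological score, and the excluded counts are
reported (`n_terms_used`) so data loss is auditable. A pair with no finite
term at all is flagged undefined.

Raw average distances are mapped to scores by min–max normalization over
the batch of all (candidate, disease) pairs scored in the run, inverted so
the closest pair gets CDS = 1 and the farthest CDS = 0. The inversion is
forced by the composite score's orientation: higher must mean better, and
well-matched compounds cluster at high CDS. Normalizing over the global
batch treats all diseases on one scale, mirroring a single score matrix; a
per-disease mode (`cds_normalization = "per_disease"`) rescales within each
disease instead, which changes the interpretation to "closest among this
disease's candidates". Degenerate batches (all raw distances equal) give
every defined pair CDS 1; undefined pairs get 0.

### Combination and filtering

Per (approved drug, candidate) pair, TC is computed first and pairs with
TC < 0.2 are discarded; with several approved drugs per disease, TC and
OCTS are averaged over the *surviving* pairs only. Averaging over all pairs
would let a disease's unrelated drugs dilute a strong match; the surviving
candidate still reflects every drug it genuinely resembles. (The
all-pairs average is available behind `average_all_pairs = TRUE`.) The
composite score is `(TC + OCTS + CDS) / 3`; records below 0.4 are dropped
from the report, a threshold at which predictions empirically begin to
enrich for clinically tested associations. Ties are broken
lexicographically by candidate identifier so runs are reproducible.
Approved drugs for the query disease are never their own candidates; drugs
approved for *other* diseases are — that is the repurposing case.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `potency_threshold_nm` | 1000 | nM | potency cutoff for target profiles |
| `tc_min` | 0.2 | — | per-pair structural similarity floor |
| `score_min` | 0.4 | — | composite score reporting floor |
| `cds_normalization` | global | — | min–max batch for CDS |
| `aggregate` (potency) | any | — | per-pair measurement aggregation |

All three thresholds are inclusive (≥ / ≤). Raising `tc_min` or
`score_min` can only shrink the output (tested as a monotonicity
property); the same holds for lowering `potency_threshold_nm`.

## The synthetic data generator

`fixture_spec()` / `generate_fixture()` emit the five input tables plus a
ground-truth manifest, fully reproducible from one seed. The generator
emulates the qualitative shape of the real inputs at desk scale: compounds
are built from ~20 drug-like scaffolds with combinatorial substituents
(every SMILES parses by construction); approved drugs carry 4–7 potent
targets and most diseases have 1–3 approved drugs, matching the sparsity
that motivates the three-component design; quantitative potencies straddle
the 1000 nM cutoff according to `potency_mix`; the PPI graph is a random
connected graph (spanning tree plus shortcuts) over the target namespace.
Defaults are 30 candidates, 6 drugs, 3 diseases, 40 targets and a
120-node network — small enough for test suites, large enough that the
planted structure competes against a background of filler compounds.

Planted repurposing pairs are constructed, not sampled: the planted drug is
built on one of five larger four-ring scaffolds reserved for planted pairs,
the planted candidate differs from it by a single substituent edit (so
their ECFP4 similarity stays high for every substituent draw — verified by
enumerating the generator's design space), shares a configured fraction of
its targets, and the disease's gene set equals the candidate's target set
(raw network distance 0). Each planted pair comes with a decoy candidate on
a different scaffold whose targets sit on a pendant chain attached to the
network periphery, far from any disease gene. Planted and decoy
bioactivities are additionally backed by unary records so the construction
survives any `potency_mix`, including 1.0 (all quantitative records
inactive). Identifiers are synthetic: shape-valid random InChIKeys,
P-number-style protein accessions and C-number-style disease CUIs, treated
as opaque strings throughout.

What passing tests on these fixtures do **not** show: real bioactivity
distributions are long-tailed and assay-heterogeneous, real PPI networks
are scale-free with dense hubs, and real disease–gene sets are noisy and
incomplete. The fixtures validate the algorithmic contract — score
definitions, filters, ranking, normalization — not biological performance
at database scale.

## Numerical choices and degenerate inputs

- Expected overlap in the significance statistic uses exact division, no
  rounding; `Sig_d = N_overlap − N_expected` is a raw excess count with no
  variance attached (a Monte-Carlo property test confirms the closed form
  against random draws).
- Hit ratios with an empty denominator (no prediction reaches the
  threshold) are omitted rather than reported as 0 or NaN.
- Both-empty fingerprint pairs score 0; empty target or gene sets are typed
  errors (`drugrepo_empty_set_error`) — the caller must exclude
  profile-less compounds, and the pipeline does so with logged counts.
- Identifier validation is shape-only (no InChIKey checksum); invalid rows
  are skipped with row-numbered warnings so large noisy dumps still load.
- Gene, protein and target identifiers must share one namespace across the
  bioactivity, PPI and disease–gene tables; the package treats them as
  opaque strings and leaves harmonization to the caller.
- All tabular output is written with 4 decimal places so repeated runs are
  byte-comparable.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
default fixture (30 candidates × 3 diseases over a 120-node network, ~60
proximity pairs), where an end-to-end run takes a few seconds; the
published-scale worked example enters only through the closed-form
significance statistic, which is O(set size). Property tests use 100
seeded random graphs of ≤ 30 nodes against a brute-force BFS oracle and
1000 random bit-vector pairs against a positionwise loop oracle.

## Known limitations

- ECFP4 is the only fingerprint family; no 3D or pharmacophore descriptors.
- Shortest paths are unweighted; no degree-preserving permutation z-scores
  (the normalization is min–max by design, which makes CDS batch-relative:
  adding pairs to a run can change other pairs' CDS values).
- Activity types (IC50 vs Kd vs Ki) are treated identically.
- The significance statistic is an excess count, not a calibrated test; use
  it comparatively across diseases, not as a p-value.
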