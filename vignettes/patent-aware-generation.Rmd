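---
title: "Patent-aware molecular generation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patent-aware molecular generation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Generative models for de novo drug design rarely know anything about
patents, yet a generated molecule that is already claimed in a substance
patent is usually worthless to a discovery program, and conversely a
molecule close to — but not inside — patented chemical space can be very
valuable. `patgen` implements a complete system for steering a SMILES
language model toward or away from patented chemical space:

1. an indexed **drug-patent database** of standardized structures from
   patent-compound tables,
2. three interchangeable **exact-structure match engines** over that
   database,
3. a **curation pipeline** that turns patented compounds into a language
   model training corpus,
4. a **GRU language model** over SMILES tokens,
5. a **Monte Carlo tree search** (MCTS) generator whose reward is patent
   membership, and
6. an **evaluation suite** (validity, uniqueness, match counts,
   similarity and QED distributions, UMAP chemical-space projections,
   analog reports).

## Structure identity

Every component agrees on one identity: the 27-character InChIKey of the
standardized structure with all stereochemistry removed. Stereoisomers
therefore collide by design — a patent claiming one enantiomer covers the
matched identity here. Standardization follows ChEMBL-structure-pipeline
semantics (functional-group normalization, largest organic fragment,
neutralization) computed by RDKit in a persistent worker process.
Records whose largest fragment contains no carbon fail standardization:
an all-inorganic salt cannot be a training or reward input.

Keys are compared as **full 27-character strings**, not first blocks.
The first block already encodes the stereo-free skeleton, but the
protonation/charge block disambiguates tautomer-style collisions cheaply,
and the full string is what the database stores, so nothing is gained by
truncation. This is a deliberate design choice; see `inchikey_nostereo()`.

## The drug-patent database

A patent is *drug-related* when any IPC or CPC code starts with `A61K`
(medicinal preparations) or `A61P` (therapeutic activity) after
whitespace removal and uppercasing — a prefix match on the
section/class/subclass, deliberately insensitive to the formatting
variance of classification exports. Compounds are retained when linked
to at least one drug-related patent; structures flagged as OCR-derived
(automatic image recognition, a known error source in patent mining) are
excluded by default. Survivors are standardized and stored as
`(inchikey, external_id)` rows in a single-file SQLite database with an
index on the key column. Patent numbers live in a JSON build-report
sidecar, not in the hot table. Standardization failures are counted in
the report, never silently dropped. Duplicate keys across external ids
are kept; `db_stats()` reports entries and distinct keys separately.

## Exact matching

Three engines answer "is this structure in the database?":

* `match_inchikey()` — an indexed SQL `SELECT` per query key.
* `match_mhfp_lsh()` — MHFP6 MinHash fingerprints (2048 permutations)
  in a banded locality-sensitive hash (default 128 bands x 16 rows).
  A band is the FNV-1a hash of 16 consecutive minhash values, so two
  identical fingerprints collide in every band and exact-match recall is
  structural: candidates are ranked by estimated Jaccard and the top
  `k = 10` verified.
* `match_morgan_bruteforce()` — radius-3 2048-bit Morgan fingerprints,
  maximum Tanimoto over all references by packed-word popcount.

Both fingerprint engines carry an InChIKey **verification step**: a
fingerprint collision alone never counts as a match, so "exact match"
always means structure identity and the three engines must agree —
which the tests assert on a universe with known membership.
`benchmark_matchers()` times only the query phase; reference-side
preparation (index construction, fingerprinting, database build) is
reported separately, since in production the references are prepared
once. Query-side conversion (fingerprinting the queries) is part of the
query phase.

## Corpus curation

`curate_training_set()` applies ordered stages: seeded sampling; removal
of unparseable or ringless molecules; removal of disallowed elements
(default allowed set H, B, C, N, O, F, Si, P, S, Cl, Br, I), isotope
labels, and blacklist substructures; desalting; property-tail trimming;
seeded subsampling; standardization. The trim quantiles per descriptor
(atom count, heavy atoms, molecular weight, SlogP, aromatic rings,
fraction sp3 carbon) default to `(0.005, 0.995)` — the removal of
"atypical compounds at both ends of the distribution" does not pin down
thresholds, so they are explicit configuration and a documented
reproduction caveat. The substructure blacklist ships as a small default
list of reactive groups (acyl halides, isocyanates, peroxides,
N-nitroso, azides, non-benzylic alkyl halides) and is replaceable
configuration: it stands in for a curated exclusion list whose exact
content is environment-specific.

## The language model

The sequence model is an embedding, two stacked gated-recurrent-unit
layers, and a softmax head, written in RcppArmadillo (no deep-learning
runtime is required). Training minimizes next-token cross-entropy over
start-prefixed, end-terminated, pad-filled token sequences with Adam,
inter-layer dropout, gradient-norm clipping at 5, and a seeded shuffle
split for validation. The SMILES tokenizer treats bracket atoms, `Cl`,
`Br` and `%nn` ring closures as single tokens and is lossless by
construction. Full-scale defaults in `lm_hyperparams()` are dropout
0.1077, learning rate 0.000434, batch size 384, 896 hidden units and 500
epochs with 10% validation; desk-scale work uses smaller models
explicitly. Two recurrent layers and the Adam optimizer are fixed
package choices (recorded configuration, since only the four searched
hyperparameters above are externally determined). After the end symbol
the next-token distribution is defined as a point mass on the pad
symbol. Checkpoints restore bit-identical next-token distributions.

All randomness in the C++ layer draws from R's RNG, so `set.seed()` (or
the `seed` fields of the config objects) controls initialization,
shuffling, dropout and sampling end to end.

## Tree search and rewards

`mcts_generate()` grows a tree over token prefixes. Selection uses UCT:

    W_i / N_i + C * sqrt(2 * ln N / N_i)

with unvisited children prioritized and ties broken toward the lowest
index. The formula is the ChemTS-lineage form, adopted here as an
explicit design choice and unit-tested against a brute-force score
oracle. Expansion considers only tokens whose language-model prior
exceeds `prune_threshold` (default `1e-4`, configurable), highest prior
first. Rollouts sample completions at the configured temperature;
proposals are parsed, standardized and filtered, and the reward of
surviving molecules is backpropagated along the selection path.
Filtered or invalid proposals backpropagate reward 0 by default
(`filtered_reward_mode = "zero"`); `"skip"` leaves visit counts
untouched — whether a search should be discouraged from regions of
invalid strings is genuinely open, so both modes exist.

Two search details matter numerically:

* **Exhaustion pruning.** A terminal node (end token or maximum length)
  is evaluated once and then marked exhausted; an internal node with
  nothing left to expand and only exhausted children becomes exhausted,
  and exhausted subtrees are excluded from selection. Without this, a
  binary reward makes the search hammer its first reward-1 terminal
  (its mean stays 1 forever), which stalls uniqueness on small
  enumerable languages. With it, the search enumerates; duplicate
  proposals still arise from stochastic rollouts, so uniqueness remains
  a meaningful metric.
* **Budgets.** The budget can be a target count of valid unique
  molecules (the evaluation protocol used throughout), a wall-clock
  limit, or an iteration cap; generation stops early if the entire
  token language is exhausted.

The rewards are `r_patent()` (1 exactly when the stereo-free key is in
the database), its complement `r_not_patent()`, and the baseline
`r_rand()`, which ignores the molecule and draws from a private seeded
linear-congruential stream so reward draws never perturb the sampler's
RNG stream. The exploration constant `C` controls the depth/breadth
trade-off; the package exposes the conventional grid 0.1-1.0 without
restricting other positive values.

The five generation filters are: a configurable rare-substructure
pattern list (standing in for a corpus-frequency-derived filter whose
frequency table is environment-specific); Lipinski's rule of five
(fail iff MW > 500, SlogP > 5, H-bond donors > 5 or acceptors > 10);
radical species; synthetic accessibility score >= 3.5; and largest ring
size > 6. Filtered molecules never receive rewards.

## Metrics

Validity is the fraction of all proposed strings that parse **and** pass
every enabled filter; uniqueness is the fraction of valid strings that
are distinct by canonical SMILES (the denominator is valid strings, not
all strings). Database match counts deduplicate by canonical SMILES
before lookup, i.e. they are counts over the valid-unique set.
Similarity histograms use 0.05-wide left-closed bins with a closed top
bin, so an exact match (similarity 1.0) lands in the last bin; bin
assignment rounds `s * 20` to 9 decimals first because 0.35 * 20 < 7 in
double arithmetic. Chemical-space projections embed radius-2 Morgan
fingerprints under the exact Jaccard metric: nearest neighbours are
computed exactly over the fingerprint bit sets in C++ and passed to
uwot's UMAP, which keeps the embedding deterministic for a fixed seed.

## The synthetic universe

`make_universe()` enumerates scaffold x substituent combinations from
ring-bearing templates, standardizes, deduplicates by stereo-free key
and truncates — enumeration rather than random SMILES mutation, so the
patented/novel partition from `split_universe()` is exact ground truth
on every platform. The default universe holds 5,000 molecules with a
60/40 patented/novel split, large enough to exercise the LSH banding and
the matcher benchmark while keeping test runs in minutes. The synthetic
patents attach A61K/A61P codes (50 compounds per patent), with optional
fractions of OCR-flagged records and non-drug classifications to
exercise the database filters.

What the fixtures do **not** emulate: the property distributions,
scaffold diversity and sheer scale of real patent compound collections;
multi-component salts and exotic elements (the enumeration is clean by
construction, so standardization-failure paths are tested with
hand-built inputs instead); and OCR structure *errors* (only the flag is
modelled). Passing tests therefore demonstrate correctness of the
machinery — exact matching, reward wiring, steering direction, metric
formulas — not performance claims about real patent data.

## Problem sizes used by the checks

The test suite trains a 2-layer, 64-unit model for 30 epochs on a
2,000-molecule fixture corpus (validity of unconditional samples is
asserted at a loose >= 50% floor; the fixture grammar is far more regular
than real corpora and reaches ~90%). Steering runs use C = 0.4 with a
budget of 3,000 valid-unique molecules, in triplicate per reward, and
assert the ordering patent > random > not-patent of mean database match
counts. The matcher benchmark uses 100,000 references and 1,000 queries
and asserts only the ordinal latency ordering inchikey < MHFP6-LSH <
Morgan brute force; absolute times are hardware-dependent. The
acceptance script runs a 2,000-molecule universe, a 1,000-molecule
corpus, 25 epochs and 1,000-molecule generation budgets, chosen as the
smallest sizes at which the steering and agreement behaviours are
stable across seeds.

## Known limitations

* Patent membership is exact-structure membership; the system does not
  assess claim scope, Markush structures, or legal patentability.
* Exact matching deliberately ignores stereochemistry; uses requiring
  stereo-aware identity need a different key.
* Tautomers are not canonicalized; two tautomers can carry different
  keys.
* The MHFP6/LSH engine holds its 2048-permutation minhash matrix in
  memory (~800 MB at 100,000 references), which is the known cost of
  that method.
* At full scale (10^7 references, 500-epoch training, day-long
  generation runs) the package's algorithms apply unchanged, but the
  tests and the acceptance script exercise desk-scale configurations
  only.
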