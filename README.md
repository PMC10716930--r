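# patgen — patent-aware de novo molecular generation

`patgen` generates small molecules with a language model + Monte Carlo
tree search while steering the search **toward or away from patented
chemical space**. It is aimed at computational chemists who want to know,
*during* generation, whether a proposed structure is already claimed in a
drug-related patent — and to use that answer as the optimization signal
itself.

The package provides the full system:

* **Drug-patent database** — builds an indexed SQLite store of
  drug-related patented compounds from patent-compound tables. Patents
  are drug-related when an IPC/CPC code starts with `A61K` or `A61P`;
  OCR-derived structures are excluded; structures are standardized
  (ChEMBL-pipeline-style desalting/neutralization via RDKit) and keyed by
  their stereochemistry-free 27-character InChIKey, so stereoisomers
  collide by design.
* **Exact-structure matchers** — three interchangeable engines over the
  same question (InChIKey text lookup; MHFP6 MinHash + banded LSH;
  Morgan radius-3 brute force), each with a structure-identity
  verification step, plus a query-phase latency benchmark.
* **Corpus curation** — staged filters (parseability, rings, element
  whitelist, isotopes, substructure blacklist, desalting, property-tail
  trimming, seeded sampling) turning database compounds into a training
  corpus.
* **SMILES language model** — a 2-layer GRU next-token model
  (RcppArmadillo; no deep-learning runtime needed) with a lossless
  SMILES tokenizer, seeded training and bit-reproducible checkpoints.
* **MCTS generator** — UCT tree search over token prefixes guided by the
  model, with plug-in rewards and the five generation filters
  (rare substructures, Lipinski, radicals, SA score >= 3.5, ring > 6).
* **Analysis** — validity/uniqueness, patent-match counts,
  maximum-similarity and QED distributions, UMAP chemical-space
  embedding, analog reports; `tidy()`/`glance()`/`autoplot()` methods
  throughout.

## The model in brief

For a generated molecule *x* with stereo-free key *k(x)* and database
*D*:

    R_patent(x)     = 1 if k(x) ∈ D, else 0
    R_not-patent(x) = 1 − R_patent(x)
    R_rand(x)       ~ Uniform[0, 1)   (baseline, molecule-independent)

MCTS selects children by UCT,

    argmax_i  W_i / N_i + C · sqrt(2 ln N / N_i),

where the exploration constant *C* trades depth against breadth;
rollouts sample SMILES completions from the GRU; rewards of
filter-passing molecules are backpropagated. Validity is the fraction of
proposals that parse **and** pass all filters; uniqueness is the
fraction of valid proposals that are distinct canonical SMILES.

## Requirements and installation

R (>= 4.3) with the declared package dependencies, plus a `python` on
the PATH with RDKit (standard chemistry — parsing, standardization,
InChIKeys, descriptors, fingerprints — runs in a persistent RDKit worker
subprocess).

```sh
R CMD INSTALL .
# run the tests
Rscript -e 'testthat::test_dir("tests/testthat", package = "patgen", load_package = "installed")'
```

## Worked example

Everything below runs on a synthetic patent universe — enumerated
scaffold × substituent molecules with a known patented/novel split — so
the whole pipeline works offline with exact ground truth.

```r
library(patgen)

# 1. a 1,000-molecule universe, 60% of it "patented"
spec     <- fixture_spec(n_target = 1000, seed = 42)
universe <- make_universe(spec)
split    <- split_universe(universe, frac_patented = 0.6, seed = 42)
tabs     <- write_fixture_tables(split, "fixtures")
db <- build_db(read_compound_table(tabs["compounds"]),
               read_compound_table(tabs["patents"]),
               path = "fixtures/db.sqlite")
db
#> <drug_patent_db> 600 entries at fixtures/db.sqlite

# 2. train a small SMILES language model on patented compounds
corpus <- make_corpus(split$patented, 500, seed = 1)
lm <- train_lm(corpus, lm_hyperparams(
  epochs = 30, hidden_units = 64, batch_size = 32,
  learning_rate = 0.003, dropout = 0.1, embedding_dim = 32, seed = 7
))
lm
#> <patent_lm> vocab 20 tokens, 2x64 GRU, 30 epochs (final train loss 0.3741)

# 3. generate, steering toward patented space
log <- mcts_generate(lm, r_patent(db), generation_config(
  c_explore = 0.4, target_valid_unique = 200,
  max_iterations = 20000, seed = 7
))
log
#> <generation_log> reward patent, C 0.4: 1494 proposals, 208 valid, 200 valid-unique
compute_metrics(log, db)
#> # A tibble: 1 × 8
#>   reward c_explore n_all n_valid n_valid_unique validity uniqueness n_db_matches
#>   <chr>      <dbl> <int>   <int>          <int>    <dbl>      <dbl>        <int>
#> 1 patent       0.4  1494     208            200    0.139      0.962           53
```

Of the 1,494 SMILES the search proposed, 208 parsed and passed every
filter (validity 0.139), 200 of those were distinct (uniqueness 0.962),
and 53 of the 200 distinct molecules are compounds of the patent
database — the patent reward pulled roughly a quarter of the output into
patented space on this small fixture. The metrics row reports `n_all`
(every SMILES the search proposed),
`validity` (parse + filter pass rate), `uniqueness` (distinct fraction
of the valid), and `n_db_matches` — how many of the distinct valid
molecules are patented compounds, i.e. how strongly the reward steered
the search into the database. Swapping `r_patent(db)` for
`r_not_patent(db)` drives that count toward zero; `r_rand()` sits in
between (the tests assert exactly this ordering over triplicate runs).

## Scope notes

Patent membership here is exact-structure membership: the package does
not interpret claim scope, Markush generics, or legal status. See the
methods vignette (`vignettes/patent-aware-generation.Rmd`) for the
model's assumptions, numerical choices and limitations.
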