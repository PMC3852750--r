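# simmapr

**Similarity maps for molecular fingerprints and activity models in R.**

Fingerprint similarity scores and classifier probabilities are single
numbers with no anatomy: a medicinal chemist asking *why* two molecules
count as similar, or *which part* of a molecule drives a predicted
activity, gets no answer from the score alone. simmapr answers by direct
attribution. For every heavy atom *i* of a test molecule it removes the
fingerprint bits that atom participates in and recomputes the score:

```
w_i = s_orig − s_mod(i)
```

where `s` is the Dice (or Tanimoto) similarity to a reference compound,
or a model's P(active) (ln P(active) for naive Bayes). Atoms whose
removal *lowers* the score carry positive weight (they support the
similarity/activity), atoms whose removal *raises* it carry negative
weight. Normalized weights are drawn as a sum of atom-centered Gaussians
over the 2D structure — green positive, pink negative, gray neutral —
giving a topography-like "similarity map".

Supported fingerprints: atom pairs (count vector, 2^32 bit-space),
element-typed circular/ECFP-style fingerprints of radius 2 (2^32 count
vector or 1024-bit folded vector) and feature-typed (FCFP-style)
circular fingerprints. Supported models: balanced random forest (per-tree
majority down-sampling, recorded subsets) and Bernoulli naive Bayes with
Laplace smoothing. Molecule parsing, 2D layout and fingerprint hashing
are delegated to RDKit via a bundled Python helper; the attribution
machinery, metrics, classifiers and renderer are implemented in R.

## Worked example

The package bundles two dopamine D3 receptor ligands
(`inst/extdata/d3_ligands.smi`): a reference compound (`mol1`, an
arylpiperazine with a butyl linker and naphthalene head) and a test
molecule (`mol2`, a methoxybenzofuran carboxamide bearing a
quinoxalinyl-piperazine).

```r
library(simmapr)
lig  <- read_smiles_file(system.file("extdata", "d3_ligands.smi", package = "simmapr"))
ref  <- lig[[1]]; probe <- lig[[2]]

rf <- atom_pair_fingerprint(ref)
pf <- atom_pair_fingerprint(probe)
dice(rf$fp, pf$fp)
#> [1] 0.6042241

w <- similarity_weights(rf$fp, pf$fp, pf$ownership)
w
#> <atom_weights (similarity): 34 atoms, original score 0.6042, max |raw| 0.02847>

render_map(probe, w, map_style(), "mol2_ap_map.png")
```

The strongest and weakest atoms of the weight vector:

```
 atom element    raw normalized
   17       N 0.0285      1.000     # piperazine nitrogen
    8       C 0.0266      0.933     # benzofuran ring carbon
   23       C 0.0266      0.933     # quinoxaline ring carbon
   14       C 0.0247      0.867     # butyl linker carbon
   18       C 0.0247      0.867     # piperazine carbon
   ...
   26       N -0.0189     -0.663    # quinoxaline nitrogen
   29       N -0.0189     -0.663    # quinoxaline nitrogen
   33       O -0.0189     -0.663    # benzofuran oxygen
```

The piperazine, the alkyl linker and the aryl carbons the two ligands
share are what make the pair similar; the heteroatoms the reference
lacks pull the similarity down. For probability maps, train a model on a
labeled set and swap `similarity_weights` for `probability_weights`:

```r
screen <- make_synthetic_screen(n_active = 6, n_inactive = 30, seed = 7)
model  <- train_activity_model(screen, "balanced_rf")
fp     <- fingerprint(parse_molecule(screen$smiles[1]), fingerprint_spec("morgan"))
probability_weights(model, fp$fp, fp$ownership)
```

## Command line

A launcher is installed at `exec/simmap` inside the package tree:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","simmap",package="simmapr"))')" \
  simmap --ref ref.smi --probe "COc1ccccc1N1CCNCC1" --fp ap --out run
# -> run.png, run_weights.tsv, run_config.json; re-run with --config run_config.json
```

Subcommands: `simmap`, `probmap`, `train`, `fixtures`. Every run writes
its resolved configuration next to its outputs; the TSV weight table is
the machine-readable artifact.

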