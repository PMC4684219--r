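# hotspotRF

Prediction and characterization of **protein–protein binding hot spots** —
interfacial residues whose mutation to alanine raises the binding free
energy change (ΔΔG) by ≥ 2 kcal/mol — from crystal structures.

The package is aimed at structural bioinformaticians who have a complex in
PDB format, a table of alanine mutations (optionally with experimental ΔΔG
in kcal/mol or Strong/Intermediate/Weak/Insignificant labels), and want
per-mutation ΔΔG predictions with interpretable, contact-level features.

## The model

For a complex split into two sides, atomic **β contacts** are pairs with
`dist(i,j) ≤ 1.25·(vdw_i + vdw_j)` and no third atom k seeing the pair
under an angle ∠(i,k,j) ≥ 85° (the β-skeleton "forbidden region" test).
Aromatic rings contribute π pseudo-atoms 0.5 Å above and below the ring
centroid; buried waters with ≥ 3 donor/acceptor contacts join the graph.
Each mutation is described by **143 features**:

    2 ΔASA  +  8 B-factor  +  14 mutated contacts
    + 14 neighborhood cross-interface contacts
    + 105 co-occurring contact-type pairs ( = 14·15/2 )

Every contact is weighted by `(B̈_i + B̈_j)/2`, where B̈ is the per-complex
normalized, clamped B factor `clamp(B_norm − 1, [−2, 0])` with
`B_norm = (B − B̄)/(1.645·δ_B)` over the trimmed (1% low / 9% high) atomic
B factors. Two contacts *co-occur* when their endpoints are within 3
covalent-bond steps (a shared atom counts). ΔΔG is regressed by a random
forest (500 trees, terminal nodes ≥ 3 mutations, features with ≤ 3
non-zero values dropped per training fold) and evaluated by
**leave-complex-out cross-validation**; hot spots are called at predicted
ΔΔG ≥ 1.5 kcal/mol against the observed ≥ 2 kcal/mol ground truth.

See `vignette("contact-hotspots")` for the full model description,
assumptions and limitations.

## Worked example

```r
library(hotspotRF)

# a synthetic two-chain complex with a planted interface
toy <- make_toy_complex(fixture_spec(n_residues = 6, seed = 42))
s   <- read_fixture(toy$pdb)          # or read_complex("file.pdb", "A", "B")
ctx <- prepare_complex(s)
ctx$graph
#> contact_graph 'fixture': 10 contacts (5 cross-interface), 8 interfacial /
#>   0 supporting / 51 neighborhood atoms, 0 qualified waters

# 143-element descriptor of mutating the tryptophan at A2
f <- extract_features(s, data.frame(chain = "A", resno = 2, wt = "TRP"),
                      ctx = ctx)
round(f$X[1, f$X[1, ] != 0], 3)
#>     dASA_log     dASA_rel      Bavg_g4      Bdif_g4      mut_t02      mut_t03
#>        3.706        0.204       -0.988       -0.485       -0.924       -0.810
#>      mut_t04      mut_t06      mut_t09      nbr_t02      nbr_t09 cooc_t02_t02
#>       -0.938       -0.915       -3.156       -1.164       -3.156       -2.088
#> cooc_t02_t03 cooc_t02_t04 cooc_t02_t06 cooc_t02_t09 cooc_t03_t04 cooc_t03_t06
#>       -3.708       -1.861       -1.838       -5.928       -1.748       -1.725
#> cooc_t03_t09 cooc_t04_t06 cooc_t04_t09 cooc_t06_t09 cooc_t09_t09
#>       -5.587       -1.852       -5.969       -5.900       -6.312
```

The negative contact features read as "how much rigid contact surface the
mutation removes": here the tryptophan loses hydrophobic (`t03`) and
π-involving (`t09`) contacts and their co-occurrences — the two contact
classes most diagnostic of hot spots.

On the bundled 20-complex planted-signal benchmark (~300 mutations,
signal-to-noise 2:1):

```r
bench <- make_benchmark_set(seed = 1)
cv <- loco_cv(bench$X, bench$ddg, bench$complex_id)
pearson_cc(cv$predicted, cv$observed)
#> [1] 0.8630395
hotspot_metrics(cv$predicted, cv$observed)
#> TP 35  FP 17  TN 242  FN 6
#>   precision          0.673
#>   recall             0.854
#>   F1                 0.753
#>   accuracy           0.923
#>   specificity        0.934
#>   negative_precision 0.976
#>   pcc                0.863
```

A thin command-line interface wraps the same pipeline
(`inst/cli/hotspotrf`): `extract`, `train`, `predict`, `cv`, `evaluate`,
`make-fixtures`; see `?run_hotspot_cli`.

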