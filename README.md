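# spminer

Profile-HMM mining and biochemical characterization of substrate-specific
sugar transporters.

## What this is for

Fungal proteomes contain dozens of major-facilitator-superfamily (MFS)
sugar porters, and annotation alone cannot tell which of them transport
D-xylose — the key pentose in lignocellulosic feedstocks — rather than
glucose. `spminer` is an R toolkit for the computational side of finding
out, aimed at people mining proteomes of industrial fungi (e.g.
*Aspergillus niger*, *Trichoderma reesei*) for transporter candidates and
characterizing them:

* **Profile HMM** — build a function-specific profile hidden Markov model
  from a curated alignment of validated transporters (match/insert/delete
  states per column, Henikoff position-based sequence weights, Laplace-
  style pseudocounts), and score whole proteomes by Forward log-odds in
  bits against an i.i.d. background null,
  `score = log2 P(seq | model) / P(seq | null)`,
  in local (uniform entry/exit over match states) or glocal mode.
  Candidates are the top-N ranked proteins (N = 15 by default).
* **Phylogenetics** — p-distances with pairwise deletion, Saitou–Nei
  neighbor joining (exact on additive matrices), column-bootstrap
  supports, and collapsing of internal edges with support strictly below
  75%.
* **Motifs** — locate and classify the substrate-discriminating variants
  of the first-transmembrane-span motif (xylose `GGLXXGYD/N`, arabinose
  `XGXXFGFD`, glucose `GGFXFGWG`, generic `GG/FXXXG`), map reference
  residues and windows (e.g. TM7 `YFFYY`) across an alignment, and scan
  1-kb upstream regions on both strands for an IUPAC regulator-binding
  motif (default: the XlnR consensus `GGCTAAA`).
* **Kinetics** — initial uptake rates from radiolabel counts, nonlinear
  least-squares Michaelis–Menten fits (`V = Vmax·[S]/(Km+[S])`) with
  standard errors, and specific growth rates µ from ln(OD) regression up
  to stationary-phase onset.
* **Synthetic data** — seeded generators for protein families,
  planted-homolog proteomes, uptake assays and growth curves, so every
  stage is testable end to end with known ground truth.

## Worked example

Simulate a 24-member transporter family with a planted xylose-class motif,
mine a 100-decoy proteome, and characterize the kinetics:

```r
library(spminer)

fam <- simulate_family(family_spec(length = 200, n_members = 24,
                                   sub_prob = 0.15, del_prob = 0.02,
                                   seed = 11,
                                   motifs = list(list(pattern = "GGLMFGYD",
                                                      position = 31))))
model <- build_profile(fam$alignment)
proteome <- plant_homolog_proteome(fam$alignment, decoys = 100, seed = 12)
scan_proteome(model, proteome, top_n = 5)
#>   rank       id       bits
#> 1    1    fam24 537.039667
#> 2    2 decoy058  10.599847
#> 3    3 decoy068   9.052069
#> 4    4 decoy093   6.627876
#> 5    5 decoy079   6.571089
```

The held-out family member (`fam24`) scores ~537 bits, more than 50× the
best decoy — the log-odds margin that makes score-rank selection work.
The conservation report classifies the planted window in every member:

```r
anchors <- data.frame(name = "tm1", ref_id = "fam01", start = 31, end = 38)
head(conservation_report(fam$alignment, anchors), 2)
#>   anchor    id     text                           classes conserved class_call
#> 1    tm1 fam01 GGLMFGYD aliphatic,...,aromatic,polar      TRUE     xylose
#> 2    tm1 fam02 GGLMFGYD aliphatic,...,aromatic,polar      TRUE     xylose
```

Kinetics: generate a noisy uptake assay from high-affinity xylose-uptake
parameters (Vmax = 1.08 nmol min⁻¹ mgDW⁻¹, Km = 0.09 mM) over a
log-spaced 1 µM – 100 mM grid and refit:

```r
obs <- simulate_uptake_data(Vmax = 1.08, Km = 0.09,
                            concentrations = exp(seq(log(0.001), log(100),
                                                     length.out = 25)),
                            noise_sd_fraction = 0.05, replicates = 3,
                            seed = 14)
fit_michaelis_menten(obs)
#> Michaelis-Menten fit (n = 75):
#>   Vmax = 1.073 +/- 0.0063 nmol min^-1 mgDW^-1
#>   Km   = 0.08895 +/- 0.0032 mM
#>   RSS  = 0.08546

fit_growth_rate(simulate_od_curve(od0 = 0.1, mu = 6e-3,
                                  t_end = 400, step = 10))
#> growth fit: mu = 0.006 h^-1 (41 points to onset t = 400 h)
```

Both generating parameters are recovered within their standard errors.
The full pipeline (build → scan → tree → conservation → promoter scan,
with a run manifest and byte-deterministic outputs) is one call,
`run_mining_pipeline(pipeline_config(...))`, or the bundled CLI:

```sh
$(Rscript -e 'cat(system.file("cli","spminer",package="spminer"))') \
    run --config pipeline.yaml --out results/
```

See the vignette (`vignettes/transporter-mining.Rmd`) for the model
details, parameter conventions and limitations.

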