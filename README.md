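# gestnet

Tools for asking whether the *way* primates gesture — one-off gestures,
rapid bursts, or persistent series with response-waiting pauses — tracks
how social each pair of animals is.

`gestnet` implements the full analysis chain used in observational studies
of wild chimpanzee gestural communication:

1. **Sequence coding.** A time-stamped gesture event log is segmented into
   sequences (same signaller, same recipient, same context, consecutive
   gestures ≤ 30 s apart) and each sequence is classified by its
   inter-gesture gaps: a lone gesture is a *single*; ≥ 2 gestures with every
   gap < 1 s form a *rapid sequence* (no time for response waiting); ≥ 2
   gestures with at least one gap ≥ 1 s form a *persistence sequence*
   (the signaller paused 1–5 s to monitor the recipient before gesturing
   again). Recipient responses are annotated as activity change,
   vocalisation, or visual/tactile gesture.
2. **Dyadic matrices.** From scan-sampled focal follows (nine 2-min scans
   per 18-min follow) the package tallies, for every ordered pair (A, B),
   party co-membership and within-10 m counts, and converts communication
   counts to rates per hour of co-proximity:

   CA_AB = (C_AB × 60) / (P10_AB × 2)

   where C_AB counts sequences A directed at B while B was within 10 m and
   P10_AB counts 2-min scans with B within 10 m of A. Proximity is measured
   as minutes within 10 m per hour in the same party,
   PROX_AB = 60 · P10_AB / party_AB ∈ [0, 60]. Binary similarity matrices
   code shared sex, age class (≤ 5 years difference), reproductive pairing
   (male × cycling female) and maternal kinship.
3. **Permutation inference.** Because dyadic observations are not
   independent, associations between matrices are tested with
   quadratic-assignment permutations (simultaneous row-and-column
   relabelings): QAP correlation, multiple-regression QAP with
   Double-Dekker semi-partialling (each predictor's null is built by
   relabeling its residual matrix after removing the other predictors —
   robust to network autocorrelation), and node-level regression of degree
   centralities with outcome-vector permutation. For small networks
   (n! ≤ 5040) the tests switch to exhaustive enumeration and are exact.
4. **Synthetic fission–fusion generator.** A latent log-normal sociality
   per dyad drives both party/proximity probabilities and the
   persistence-sequence initiation rate, so the entire pipeline can be
   validated against planted effects without field data.

## Worked example

```r
library(gestnet)

cfg <- synthetic_config(seed = 42)      # 12 adults, 25 follows each
study <- simulate_gesture_study(cfg)
seqs <- segment_sequences(study$events)
table(seqs$cls)
#> persistence       rapid      single
#>          63         107         291

nets <- build_networks(study$attrs, study$scans, seqs)
round(mean(dyad_vectorize(nets$proximity)), 1)   # min per party-hour
#> [1] 24.2

h1 <- mrqap_dsp(nets$proximity,
                nets[c("age", "sex", "kin", "oestrous",
                       "rapid", "single", "persistence")],
                n_perm = 999, seed = 7)
h1
#> MRQAP (Double-Dekker semi-partialling): proximity ~ age + sex + kin + ...
#> 132 dyads, R-squared 0.2831, sampled 999 permutations, seed 7
#>                coef std_coef se_ols     p
#> age          0.2487   0.0096 2.0257 0.919
#> sex          2.0623   0.0811 2.3728 0.536
#> kin         11.3864   0.1872 5.0956 0.100
#> oestrous    -1.3656  -0.0480 2.8371 0.743
#> rapid        1.6997   0.0817 1.6195 0.321
#> single      -0.3215  -0.0363 0.6856 0.584
#> persistence 20.2579   0.4859 3.2770 0.001
```

The generator plants a positive sociality effect on persistence-sequence
rates only; the model recovers it (std. coefficient 0.49, p = 0.001 here)
while the rapid and single rates, which carry no planted effect, stay
non-significant. `run_pipeline()` chains the whole analysis (six dyadic
models plus the node-level centrality model) and writes every matrix,
result table and a run log to an output directory;
`run_centrality_model()` fits the centrality model alone; `cohens_kappa()` and
`kappa_report()` cover inter-coder reliability.

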