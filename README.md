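# bcrflow

Longitudinal B-cell receptor (BCR) repertoire analysis for paired blood
and intestinal-mucosa samples, aimed at studies that track how a mucosal
B-cell compartment is established and maintained over time — for example
serial surveillance biopsies after intestinal transplantation, where
recipient B cells progressively repopulate the allograft and their clones
can be followed across tissues and post-operative time.

The package takes annotated heavy-chain rearrangement tables (AIRR-C
rearrangement TSV, or an ImmuneDB-style dialect) plus per-sample metadata
and implements the downstream analysis layer:

* **Clonal inference** — sequences sharing the same V gene, J gene and
  CDR3 length are combined into a clone when their CDR3 amino-acid
  identity is at least 85% (single linkage within each V/J/length
  bucket). Clone size is the number of *unique instances* (one unique
  sequence observed in one sample) summed over a time bracket.
* **Mutation profiling** — per-sequence mutation frequency
  `v_mutation_count / v_sequenced_length`; a clone is *mutated* when its
  instance-averaged frequency strictly exceeds 2%; *trunk clones* carry
  ≥ 5 distinct mutations each shared by ≥ 85% of their unique sequences.
* **Lineage trees** — a germline-rooted mutation-containment tree per
  clone: each unique sequence is a populated node at its V-mutation set,
  unpopulated ancestors are inferred at sibling-set intersections, and
  nodes carry tissue-label multisets.
* **Clumpiness** — a 0–1 metric of how interleaved two tissue labels are
  within a lineage. Each label instance scores `2^-d` for the edge
  distance `d` to the nearest populated node carrying the other label;
  paths through the germline root earn nothing. 0 means the tissues sit
  on separate founder branches, 1 means every node carries both.
* **Diversity** — Hill numbers `D_q = (Σ p_i^q)^{1/(1-q)}` on clone-size
  proportions (`D_0` = richness, `D_1 = exp(H)` the entropy limit) and
  evenness `D_1 / D_0`.
* **Repertoire overlap** — cosine similarity of clone-size vectors over
  the union of clone ids between two (patient, tissue, bracket) slices.
* **Longitudinal statistics** — POD brackets (pre = 0, early = 1–90,
  mid = 91–365, late > 365), an exact two-sided sign test on clone-size
  changes between brackets, two-sided Mann–Whitney U comparisons,
  trapezoidal chimerism AUC normalized by days of measurement
  (POD_last − POD_first) behind a ≥ 40-event parent-gate filter, and
  DSA-positivity calls at +2,000 MFI (serum) / +500 MFI (supernatant).
* **Synthetic data** — a fully seeded generator
  (`sim_config()` / `simulate_repertoire()`) that emulates
  post-alignment annotated input: branching-process lineages with nested
  mutation sets, a tissue-mixing dial `π`, power-law clone sizes, a
  growth-bias dial for clone dynamics and logistic chimerism curves — so
  the whole pipeline is testable without any sequencing data.

## Worked example

```r
library(bcrflow)

cfg    <- sim_config(seed = 7, n_patients = 1, n_clones = 30, tissue_mix = 0.6)
sim    <- simulate_repertoire(cfg)
clones <- group_clones(sim$rearrangements)           # 85% CDR3 identity rule
a      <- annotate_samples(clones, sim$metadata)

sizes <- clone_bracket_sizes(a, sim$metadata)
sl    <- repertoire_slices(sizes)
evenness(sl[["P01|blood|early"]])                    # 0.89359
evenness(sl[["P01|blood|late"]])                     # 0.8356062

st <- sign_test_clone_sizes(sl[["P01|ileum|mid"]], sl[["P01|ileum|late"]])
st$p_value                                           # 0.701108 (+15 / -12)

el   <- min_unique_sequences_filter(a)               # >=3 unique seqs, both tissues
vals <- sapply(split(seq_len(nrow(el)), el$clone_id), function(i)
  clumpiness(build_lineage(el[i, , drop = FALSE]), "blood", "ileum"))
median(vals, na.rm = TRUE)                           # 0.8552632 over 23 clones

cosine_similarity(sl[["P01|blood|early"]], sl[["P01|ileum|early"]])  # 0.8512938

m <- subset(sim$metadata, tissue == "ileum")
chimerism_auc_normalized(data.frame(pod = m$pod, percent = m$chimerism_pct),
                         "mid")                      # 93.1609
```

Reading those numbers: at a mixing dial of 0.6 most clones interleave
their blood and ileum sequences within shared branches (median
clumpiness 0.86), the blood repertoire is slightly less even late than
early (0.84 vs 0.89), clone sizes show no directional drift between mid
and late brackets (sign test p = 0.70), and the simulated graft is
~93% recipient during the mid period.

A full report (one TSV per analysis plus a `manifest.json` recording
every threshold and input digest) is produced with:

```r
paths <- write_simulation(cfg, "simdata")
run_report(paths[["rearrangements"]], paths[["metadata"]], "report")
```

or from the shell via the bundled CLI
(`inst/cli/bcrflow <simulate|clones|lineages|clumpiness|metrics|stats|report> --options`).

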