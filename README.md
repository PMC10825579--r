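# vhhtrack

Tracking VHH antibody repertoire evolution across an immunization time
course, and predicting — purely in silico — which clonal clusters
contain antigen-responsive antibodies.

## The problem

Camelids make heavy-chain-only antibodies whose variable domains (VHH,
"nanobodies") can be amplicon-sequenced deeply from blood at successive
weeks of an immunization. Lineages that respond to the antigen leave a
characteristic signature in such data: they appear shortly after
immunization looking nearly germline, then accumulate somatic
hypermutations week after week while newly arisen clones keep replacing
the previously dominant ones. Pre-existing ("pre-matured") lineages
show none of this. `vhhtrack` implements the full analysis that turns
raw per-week, per-isotype (IgG2 short hinge / IgG3 long hinge) amplicon
reads into that prediction:

1. **reads** — paired-mate overlap merging (match +1, mismatch −2, gap
   −3, minimum score 8), modified-Mott quality trimming (limit 0.01),
   3′ constant-region trimming (21 nt IgG2 / 24 nt IgG3), and a VHH
   validity filter (ACGT only, length ≡ 0 mod 3, stop-free frame-1
   translation), tabulated into per-sample sequence–frequency tables.
2. **denoise** — iterative frequency-driven error cleanup: the most
   frequent sequence (the reference sequence, RS) absorbs rarer
   same-length sequences within a Hamming radius *n* that widens with
   RS frequency (*n* = 3 for 2–400, 4 for 401–1,000, 5 above 1,000),
   unless a member's frequency ratio to the RS exceeds the independence
   threshold *r* for its number of base changes (8%, 3%, 1%, 0.2% for
   1, 2, 3, ≥4 changes) — such members are independent true variants
   (their pattern-superset derivatives likewise) and survive.
3. **chronology** — full join of weekly tables per isotype, a maximum
   frequency column, and S#/L# sequence IDs in descending maximum
   frequency.
4. **germline** — Smith–Waterman local alignment (affine gaps) against
   a germline V/J FASTA; the best bit score
   *(λ·raw − ln K)/ln 2* names the originating gene, and the V-region
   bit score doubles as the somatic-hypermutation distance.
5. **clustering** — U40 "loneliness" filter (drop sequences with fewer
   than 10 equal-length neighbors under 40 differences, and singleton
   sequences), grouping by (length, V, J), Jukes–Cantor distances
   *d = −¾ ln(1 − 4p/3)* cut at 0.04, connected components with more
   than seven members as clusters, and discard of any cluster already
   present before immunization.
6. **predict** — per cluster, an OLS line of member bit score against
   week of first appearance. A **hit** is called when (1) the slope is
   negative, (2) the intercept (the "initial bit score" — how close
   the founding sequence is to germline) exceeds 380 bits, and (3)
   weekly dominant clones keep turning over (positive Spearman rank
   correlation of week with the dominant's first week, ≥3 distinct
   dominants).

A **simulate** module generates complete immunization studies with
known ground truth (responding / static / pre-immune lineages, clonal
turnover, multinomial read sampling, per-copy sequencing errors), so
every stage of the pipeline is testable without any sequencing run.

## Worked example

Simulate an 11-week study (5 responding, 5 static, 2 pre-immune
lineages; 4,000 reads per week and isotype) and run the whole pipeline:

```r
library(vhhtrack)
sim <- simulate_study(sim_config(seed = 42, weeks = 0:10,
                                 n_responding = 5, n_static = 5,
                                 n_preimmune = 2, depth = 4000))
res <- analyze_tables(sim$tables, sim$db$v, sim$db$j)
res$predictions
```

```
  cluster_id n_members   slope intercept turnover_idx n_dominants max_pct_appearance predicted_hit
1        C-1        14   0.719       195           NA           1              49.47         FALSE
2        C-2        15  -2.664       234           NA           1              40.08         FALSE
3        C-3        12   2.940       214           NA           1              32.55         FALSE
4        C-4        16 -15.390       561        0.979           6              19.80          TRUE
5        C-5        18 -13.951       515        0.994           8              17.15          TRUE
6        C-6        14   0.249       212           NA           1              16.88         FALSE
7        C-7        15  -9.764       538        0.979           6              10.45          TRUE
8        C-8        12   3.705       220           NA           1               8.85         FALSE
9        C-9        16 -12.725       554        0.953           5               7.70          TRUE
```

Both pre-immune lineages were discarded before prediction
(`res$attrition["clusters_preimmune_discarded"]` is 2). The four
predicted hits are exactly the responding lineages that survived
filtering: steeply negative bit-score slopes (ongoing mutation), high
intercepts (germline-like start, well above the 380-bit threshold),
and many distinct weekly dominants (turnover). The static lineages
show flat-or-positive slopes, low intercepts (~200–230 bits: they
started pre-matured), and a single dominant throughout. Checked
against the simulator's ground truth
(`score_simulation(res$predictions, res$clusters, sim$truth)`), this
run classifies 9 of 10 scoreable lineages correctly — one responding
lineage produced too few surviving members to form a cluster at this
depth.

Per-cluster phylogenies are available as newick via
`build_nj_tree(res$clusters[["C-4"]])`, and a file-based run (TSV
tables + manifest JSON in, TSVs + `summary.json` out) via
`run_pipeline()` or the `inst/scripts/vhhtrack.R` command-line
wrapper.

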