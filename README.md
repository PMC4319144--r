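# mhealthscape

Landscape analysis of mobile health (mHealth) app stores with a focus on
information-security and privacy risk. App stores list tens of thousands of
health-related apps whose risk profiles differ radically — from static
first-aid guides that store nothing to full health-record vaults. This
package implements, as tested and reusable R functions, the pipeline such an
analysis needs:

1. **Tagging** — app descriptions are matched against a manually seeded tag
   corpus (many surface strings → one tag label; case-insensitive,
   word-boundary, exact). Apps with fewer than four distinct tags are
   excluded, which doubles as a language/topicality filter.
2. **Graph construction** — apps are vertices; edge weights count shared
   tags.
3. **Clustering** — Louvain modularity optimisation, implemented in package
   code with controlled seeding and tie-breaking, validated against an
   exhaustive set-partition oracle on small graphs. Partition quality is
   weighted Newman–Girvan modularity
   *Q* = (1/2m) Σ<sub>ij</sub> [A<sub>ij</sub> − k<sub>i</sub>k<sub>j</sub>/2m] δ(c<sub>i</sub>, c<sub>j</sub>).
4. **Assessment** — human raters score each informative cluster on five
   nominal characteristics (health specificity of accessible information;
   potential damage through leaks, manipulation, loss; value to third
   parties). Inter-rater agreement is the Janson–Olsson ι, a multivariate
   extension of Cohen's κ: ι = 1 − D<sub>obs</sub>/D<sub>exp</sub> under the
   variable-wise mismatch distance.
5. **Archetypes** — clusters with identical resolved assessments consolidate
   into archetypes, ordered by signature severity; per-characteristic level
   aggregates reproduce the published summary tables bundled under
   `inst/extdata/`.

Because the 2013 store snapshot this design targeted is unrecoverable, the
package ships a seeded **synthetic corpus generator** with planted archetype
structure and realistic rating metadata (store imbalance, zero-inflated
heavy-tailed rating counts, truncated-normal star ratings, download bands
coupled to rating counts), so every stage is testable without store access.
See the methods vignette (`vignettes/mhealth-app-landscape.Rmd`) for the
model details and design decisions.

## Worked example

```r
library(mhealthscape)

cfg <- generator_config(seed = 42)           # defaults: 2000 apps, 8 planted archetypes
cc  <- generate_corpus(cfg)
asg <- auto_tag_corpus(cc$apps, cc$corpus, k_min = 4)
fl  <- filter_min_tags(asg, 4)
build_flow(discovered = nrow(cc$apps), excluded_by_tagging = fl$n_excluded)
#> App selection flow
#>   discovered:           2000
#>   excluded by tagging:  667  (33.35%)
#>   clustered:            1333

g <- build_graph(fl$included)                # 1333 vertices, 230681 edges
r <- louvain_cluster(g, seed = 7)
sprintf("louvain: %d clusters, Q = %.3f", r$n_clusters, r$modularity)
#> [1] "louvain: 8 clusters, Q = 0.461"

truth <- cc$truth[cc$truth$app_id %in% fl$included$app_id,
                  c("app_id", "planted_archetype")]
recovery_score(r$partition, truth)
#> [1] 1
```

The flow report shows a third of the generated apps failing the four-tag
filter (the planted noise fraction); Louvain then recovers all eight planted
archetypes exactly (adjusted Rand index 1) at a modularity of 0.46 —
clusterings around 0.5 indicate strong community structure. Aggregating the
bundled reference archetype table reproduces the published
per-characteristic summaries, e.g. for potential damage through
manipulation:

```r
characteristic_table(read_archetype_table())[7:9, ]
#>   characteristic level clusters cluster_pct  apps app_pct
#> 1 change         none         9         5.1   786    4.37
#> 2 change         low         97        55.4 11641   64.75
#> 3 change         high        69        39.4  5552   30.88
```

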