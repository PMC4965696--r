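# modulecover

De novo pathway enrichment by module-cover subnetwork extraction, with
network-perturbation robustness and gold-standard validation analyses.

## The problem

Given a large biological interaction network *G(V, E)* (protein–protein
interactions, for instance) and one or more molecular profiles encoded as
binary **indicator matrices** — genes as rows, cases/samples as columns,
a `1` marking an "active" case for that gene (differential expression, a
variant call, a methylation signal) — de novo pathway enrichment asks for
**connected subnetworks enriched for active genes**, without restricting
the search to pathways already annotated in curated databases.

`modulecover` follows the module-cover formulation with two
easy-to-interpret parameters:

* **L** — the number (or percentage) of *case exceptions*: a gene counts
  as active when it is active in all but at most *L* cases.
* **K** — the number of *exception nodes*: inactive genes that may be
  included anyway to bridge active regions.

Two enrichment strategies are provided:

* **INES** (individual node exceptions): maximal connected subnetworks
  with at most *K* inactive nodes, each remaining gene active under the
  per-gene *L* rule.
* **GLONE** (global node exceptions): a single budget *L* on the total
  number of case exceptions summed over all genes of the solution, which
  tempers INES's preference for hub nodes.

Solutions are scored and compared with the Jaccard index
*J(A, B) = |A ∩ B| / |A ∪ B|*. Because interaction networks evolve
continuously, the package can perturb the input network — node-label
permutation, degree-preserving (Maslov–Sneppen) rewiring, node removal,
edge removal — over a range of perturbation levels, re-run the identical
extraction on each perturbed replicate, and report
*J(S_perturbed, S_unperturbed)* (robustness) or *J(S, S_gold)* against a
curated gold-standard gene set (validation).

Also included: an optional **border-exception-node (BEN) filter** that
prunes exception nodes hanging off the periphery of a solution (removing
a BEN never disconnects a region containing active genes), batch grids
over K/L ranges, and a planted-module synthetic benchmark generator so
the entire pipeline runs offline.

## Worked example

The package ships a small demo: a 40-gene synthetic interaction network
with up- and down-regulation indicator matrices (10 cases each) combined
with an `OR` formula, and a curated gold list.

```r
library(modulecover)

demo <- system.file("extdata", "demo", package = "modulecover")
net  <- read_network(file.path(demo, "network.tsv"))
up   <- read_indicator_matrix(file.path(demo, "matrix-up.tsv"), "UP")
down <- read_indicator_matrix(file.path(demo, "matrix-down.tsv"), "DOWN")
sets <- dataset_collection(list(up, down), "UP OR DOWN")

cfg  <- extraction_config("INES", "greedy", k = 2, l = "20%")
top  <- largest_solution(extract_pathways(net, sets, cfg))
top
#> <pathway: 11 node(s), 2 exception node(s), 21 total case exception(s)>
#>   g01 g02 g03 g04 g05 g07 g13 g20 g23 g36 g37

gold <- read_gene_list(file.path(demo, "gold.txt"))
jaccard(top$nodes, gold)
#> [1] 0.8181818
```

The largest solution contains 11 genes, two of which are exception nodes
(inactive bridges admitted by `K = 2`); it overlaps the curated gold set
at Jaccard 0.82. How robust is it to an incomplete network?

```r
rr <- robustness_analysis(net, sets, cfg, "edge_removal",
                          levels = seq(10, 50, 10), n_per_level = 10,
                          master_seed = 42)
summarize_levels(rr)
#>   level  n  mean     sd median   min max
#> 1    10 10 0.936 0.1101  1.000 0.692   1
#> 2    20 10 0.900 0.0861  0.833 0.833   1
#> 3    30 10 0.827 0.0987  0.833 0.615   1
#> 4    40 10 0.819 0.1193  0.826 0.583   1
#> 5    50 10 0.654 0.1965  0.625 0.385   1
```

Each row summarises 10 independently perturbed networks: even with half
of the interactions deleted, the re-extracted solution still shares about
two thirds of its genes with the unperturbed one — and the decay with the
perturbation level is the robustness profile of the result.

The same analyses are available from the shell via the thin wrapper in
`exec/`:

```sh
Rscript exec/modulecover synth --nodes 100 --module 10 --cases 40 --seed 1 --out synth/
Rscript exec/modulecover extract --network synth/network.tsv \
    --matrix D1=synth/matrix.tsv -K 0:3:1 -L 20% --out runs/
Rscript exec/modulecover robustness --network synth/network.tsv \
    --matrix D1=synth/matrix.tsv -K 2 -L 20% \
    --perturb edgeremove --levels 10:50:10 --replicates 10 --out rob/
```

Every run writes a `manifest.json` (parameters, input checksums, derived
per-replicate seeds); `replay_manifest()` reproduces a run bit-for-bit.

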