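# lineagedist

Distance-based reconstruction of cell lineage trees from
whole-genome-amplified single-cell DNA sequencing data of healthy,
diploid tissue, with a bulk sample as the non-mutated reference.

Somatic mutations in healthy tissue are scarce, and single-cell DNA
sequencing — the only data type that reveals enough of them — is
distorted by the amplification step: allelic dropout (ADO) silently
removes one or both alleles of a locus, and amplification errors (AE)
are substitutions that propagate to every descendant copy of the
erroneous molecule, mimicking true mutations. `lineagedist` models both,
together with Phred-scored sequencing error, in a per-site probabilistic
model:

* the amplification of each allele is a generalized Pólya urn whose
  fragment genealogy (the *amplification tree*, `C(n) = (n-1)!`
  order-labelled topologies for `n` fragments) is marginalized
  analytically;
* the number of AEs is Binomial over the `E ∈ {2L-2, 2L-1}`
  amplification-tree edges, truncated to at most one;
* reads are assigned to fragments by an `O(L³)` dynamic program, with
  per-position error probabilities `q = 10^(-ρ/10)` from the Phred
  scores;
* mutation statuses of all cells are marginalized under the infinite
  sites assumption with a Dirichlet-Categorical prior on the shared
  mutation type and an integrated Beta prior on the mutation rate.

For every candidate site and cell pair `(c, c')` this yields the
posterior `P(G_c, G_c' | reads)`; the site distance is
`P(0,1) + P(1,0)`, distances are averaged over co-covered sites
(Eq. `M_{c,c'} = Σ_π M^π_{c,c'} 1[L_c^π>0, L_c'^π>0] / Σ_π 1[...]`),
and the tree is built by neighbor joining with the bulk as outgroup.
Candidate sites are found by threshold heuristics and, where a nearby
germline SNV is co-covered by the same reads, analyzed as *paired sites*
with read-phasing (3 mutation types at a singleton site, 6 at a paired
site). Site-bootstrap trees give transfer bootstrap expectation (TBE)
edge supports, and `p_ado`/`p_ae` can be estimated by random-walk
Metropolis-Hastings. A full forward simulator with known ground truth
(tree, mutation map, gSNVs, ADO masks, urn amplification, Phred-scored
reads, replicated bulk) is part of the package.

## Worked example

```r
library(lineagedist)

cfg <- sim_config(n_cells = 6, genome_length = 4000, mu = 3, rho = 1,
                  p_ado = 0.1, p_ae = 1e-3, lambda = 10, seed = 42)
ds <- simulate_dataset(cfg)
#> synthetic dataset: 6 cells, 4,000 bp genome, 30 mutations, 2000 gSNVs, 119414 reads

sites <- select_sites(ds$reads, ds$bulk_reads, cfg$n_cells, mode = "hybrid")
#> 13 selected site(s) (paired+singleton) over 6 cells

d <- compute_distances(sites, model_params(p_ado = 0.1, p_ae = 1e-3))
round(d$matrix[1:3, 1:3], 4)
#>        cell1  cell2  cell3
#> cell1 0.0000 0.3358 0.6147
#> cell2 0.3358 0.0000 0.3846
#> cell3 0.6147 0.3846 0.0000

tree <- nj_tree(d)                      # NJ + rerooting at the bulk
rf_similarity(ds$tree, tree)
#> [1] 1

boots <- bootstrap_trees(d, n_boot = 100, seed = 1)
tbe_supports(ds$tree, boots)
#> # A tibble: 3 × 4
#>    edge clade                 p support
#> 1     1 cell1,cell2           2   0.99
#> 2     2 cell4,cell5,cell6     3   0.985
#> 3     3 cell5,cell6           2   0.82
```

The distance matrix entries are posterior probabilities that two cells
differ in genotype, averaged over their co-covered sites: `cell5` and
`cell6` (sister cells in the true tree, distance 0.067) share almost all
of their mutations, while `cell6` and the bulk (distance 1.00) disagree
at essentially every informative site. `rf_similarity` is 1 minus the
normalized Robinson-Foulds distance — 1 here means the true topology was
recovered exactly — and every internal edge of the true tree keeps a TBE
support above 0.8 across 100 site-bootstrap trees.

Parameter estimation and the one-shot pipeline:

```r
fit <- estimate_parameters(sites, n_sites = 20, n_iter = 5000,
                           n_chains = 3, seed = 1)
glance(fit)      # pooled post-burn-in means, acceptance rate
autoplot(fit)    # trace plot

run_pipeline("out/", config = cfg, n_boot = 100, jobs = 4)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/lineagedist.R` (subcommands `simulate`, `select-sites`,
`estimate-params`, `distance`, `tree`, `evaluate`, `run`).

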