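---
title: "The probabilistic model behind lineagedist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The probabilistic model behind lineagedist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Somatic mutations in healthy tissue are rare (on the order of 10^-9 per
locus per division), so reconstructing the lineage tree of a handful of
cells requires single-cell DNA sequencing — and single-cell DNA sequencing
requires whole-genome amplification (MDA, MALBAC), which introduces
allelic dropout (ADO: one or both alleles of a locus are lost) and
amplification errors (AE: a substitution introduced in one copy and
propagated to all of its descendants). Sequencing adds Phred-scored
base-calling errors on top. `lineagedist` models all three noise sources
at each candidate site, computes for every pair of cells the posterior
probability that their genotypes differ at that site, averages these
probabilities into a distance matrix, and reconstructs the tree by
neighbor joining with the unamplified bulk sample as outgroup.

## The per-site generative model

At a candidate site $\pi$ the bulk genotype $B$ is observed and the
common mutation type $Z$ differs from $B$ by a single nucleotide at the
candidate position (infinite sites assumption: one mutation per site, all
mutated cells share it). $Z$ has a Dirichlet-Categorical prior with
concentration $\alpha$ (all ones by default, i.e. uniform over the $K$
types: $K = 3$ at a singleton site, $K = 6$ at a paired site). Each
cell's mutation status $G_c$ is Bernoulli with rate $p_m$, and $p_m$
carries a Beta$(a, b)$ prior that is integrated out analytically: a
status vector with $m$ mutated cells out of $C$ has probability
$\mathrm{B}(m + a,\; C - m + b)/\mathrm{B}(a, b)$. The genotype is
$X_c = B$ if $G_c = 0$ and $Z$ otherwise.

**Amplification.** The two alleles drop out independently with
probability `p_ado`. The surviving molecules seed a generalized Pólya
urn: repeatedly, a fragment is drawn, copied (the copy acquiring an error
with a small probability), and both are returned, until the urn holds
$L_c$ fragments — the observed coverage; the original molecules stay
sequencing-eligible. The genealogy of the fragments of one allele is an
*amplification tree* whose internal nodes are ordered by draw time; an
extra incoming root edge accounts for subsampling. With no ADO the
allele split of $L$ fragments is Beta-Binomial, i.e. uniform over the
$L - 1$ splits $(1, L-1), \dots, (L-1, 1)$; with one ADO there is a
single split. The number of AEs is Binomial over the
$E \in \{2L-2,\, 2L-1,\, 0\}$ edges and truncated to $\{0, 1\}$ without
renormalisation — the neglected mass is $P(A \ge 2)$, which is
negligible at realistic rates (the per-cell likelihood is therefore a
very slight underestimate).

Conditioned on one error, the error edge is uniform over the $E$ edges
and the tree topology is uniform over the $C(n) = (n-1)!$ order-labelled
topologies, so a configuration with $n_3$ erroneous fragments in an
$n$-fragment tree has topology factor $C(n, n_3) / (C(n) \cdot E)$,
where $C(n, k)$ counts the $k$-edges over all topologies. We compute the
ratio $w(n,k) = C(n,k)/C(n)$ by the recurrence
$w(n, k) = \big[(n-1-k)\, w(n-1, k) + (k-1)\, w(n-1, k-1)\big]/(n-1)$
with $w(n, 1) = n$, validated in the tests against exhaustive history
enumeration. Because the root edge is included, $k = n$ is admissible:
an error on the root edge makes the entire tree erroneous, so
configurations with zero surviving-allele fragments and no ADO carry
positive probability — they are required for the configuration
distribution to normalise ($\sum_k C(n,k) = C(n)(2n-1)$, one term per
edge). The erroneous fragment type is uniform over the Hamming-1
neighbours of its source allele: factor $1/3$ at singleton sites, $1/6$
at paired sites.

**Sequencing.** Each read descends from a uniformly chosen fragment and
miscalls each covered position with its Phred-derived probability
$q = 10^{-\rho/10}$ (specific wrong nucleotide: $q/3$). The likelihood
of a cell's read multiset given fragment types and counts is the
assignment sum divided by the multinomial coefficient, computed by a
dynamic program over (reads introduced, fragment-1 uses, fragment-3
uses) in $O(L^3)$. The division makes the read likelihood a proper
distribution over outcomes — the model description leaves the
normalisation implicit, and the outcome-space normalisation test pins
this choice down.

**Distances.** For a cell pair the statuses of the other $C - 2$ cells
are marginalized with a subset-sum dynamic program (polynomial in the
per-cell likelihood ratios), giving the normalized 2x2 posterior over
$(G_c, G_{c'})$; the site distance is
$P(0,1) + P(1,0)$. The distance of a cell to the bulk is the marginal
$P(G_c = 1)$: the bulk-distance formula sums the pair posterior over the
partner's status, which is exactly the marginal, and implementing it as
such avoids an arbitrary choice of partner. Site distances are averaged
over the sites where both cells have coverage (for the bulk column,
where the cell has coverage).

## Site selection

Candidate sites must show an alternative nucleotide in at least 2 and at
most $C - 1$ cells (a lone signal or a universal one is uninformative
for topology), each such cell showing the *same* alternative in at least
20% of its reads; the bulk reference call needs depth at least 10 with at
least 80% agreement. Paired sites additionally need a heterozygous
germline SNV (bulk depth at least 10, minor frequency at least 0.2)
displayed by at least two cells (both alleles at 20% or more of the
cell's reads), co-covered with the candidate by at least one read; the
nearest qualifying gSNV is used and the display criterion is re-checked
on the co-covering reads only. Hybrid mode falls back to a singleton
site when no gSNV qualifies. Two knobs are deliberate package choices
where the procedure is silent: a cell is only evaluated as "alternative"
at depth 2 or more (configurable `min_cell_depth`), and all thresholds
are non-strict (`>=`).

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `p_ado` | per-allele dropout probability | 0.1 | estimable by MH |
| `p_ae`  | per-edge/per-copy amplification error rate | 1e-3 | estimable by MH |
| `alpha` | mutation-type concentration | 1 (all types equal) | |
| `a`, `b` | Beta prior on the mutation rate | 1, 1 (uniform) | |
| `lambda` | simulator mean coverage per site pair | 10 | Poisson |
| `phred_range` | simulator Phred scores | [30, 42] | discrete uniform |
| `bulk_copies` | error-free bulk replicates per haplotype | 15 | |

The default `p_ado = 0.1`, `p_ae = 1e-3` used when estimation is skipped
sit in the middle of the simulated regimes and are package defaults, not
prescriptions. Metropolis-Hastings estimation runs 3 chains of 5000
iterations (20% burn-in) on 20 randomly chosen sites, with independent
Gaussian random-walk proposals of standard deviation 0.01 and uniform
priors, so the acceptance ratio is exactly the likelihood ratio;
proposals outside $[0,1]$ are rejected (prior support), not reflected.
Estimates are the post-burn-in means pooled across chains (per-chain
versus pooled is not specified anywhere; pooling uses all samples).

## The synthetic-data generator

The simulator *is* the study design, not a test fixture: a random binary
lineage tree over `n_cells` cells; exactly `2 (C-1) mu` mutations at
distinct odd (0-based) positions, at least one per edge, inherited by
all leaves below the edge on a random haplotype; a diploid genome
(default 1 Mbp) homozygous except at `round(rho * genome_length / 2)`
gSNV positions placed at even indices; per cell, per (even, odd) site
pair, independent Bernoulli(`p_ado`) dropout of each allele; forward urn
amplification to a Poisson(`lambda`) coverage, each copy corrupted with
probability `p_ae` (several errors may accumulate along a lineage, even
though inference truncates to one — a deliberate asymmetry); Phred
scores uniform on [30, 42] and base miscalls at rate $10^{-\rho/10}$;
and 15 error-free copies of each bulk haplotype as bulk reads (whether
real bulk reads carry sequencing errors is left open by the protocol;
error-free is the simplest reading and only strengthens the bulk calls).
Two conventions the protocol leaves open: the original allele molecules
are counted *inside* the requested coverage (the urn grows until it
holds $L$ balls; if $L$ is below the number of surviving originals they
are subsampled), and a Poisson draw of 0 simply leaves the cell
uncovered at that pair. Reads are 2 bases long by default — exactly one
site pair — which exercises paired-site co-coverage; longer reads pad
from the originating haplotype.

What the generator does *not* emulate: realistic read-length or insert
distributions, chimeric MDA artifacts, copy-number events, mapping
ambiguity, or base-quality miscalibration. Passing tests on simulated
data therefore demonstrate correctness of the inference given the model,
not robustness to every real-data pathology.

## Numerical choices and degenerate inputs

* All posterior and likelihood accumulation is done with per-cell
  scaling and log-sum-exp; the per-cell branch sums that do not depend
  on `(p_ado, p_ae)` are cached, which makes MH iterations cheap.
* With `p_ado = 0` exactly and a single read ($L_c = 1$), the no-ADO
  branch has no valid urn partition and the cell's likelihood is 0 under
  every genotype; such cells are dropped from the site via the coverage
  masks instead of producing 0/0 posteriors.
* Cell pairs with no co-covered site are imputed with the mean of the
  two cells' defined distances (with a warning) because neighbor joining
  needs a complete matrix; the bootstrap falls back to the full-data
  entry if a pathological resample leaves a pair undefined.
* Negative neighbor-joining branch lengths are clamped to zero at
  serialization only; topology is never altered.
* Site selection ties between alternative nucleotides are broken by
  agreeing-cell count, then pooled read count, then alphabetically, so
  selection is independent of read input order.
* Bipartitions are always computed on the cell leaf set after removing
  the bulk tip, so trees with and without the bulk compare consistently.

## Problem sizes used in the tests

The oracle-equivalence tests enumerate urn histories up to coverage 5,
read assignments up to 6 reads, and mutation-status vectors up to
$2^8$ cells. The tree-recovery check runs 5 seeds of a 10-cell, fully
phased, near-noiseless simulation (`mu = 10`, `lambda = 20`,
`p_ae = 1e-5`, `p_ado = 0`) on a 30 kb genome — the genome length only
scales the number of background positions, not the per-site model, and
180 mutations fit comfortably; the parameter-recovery check uses an
8 kb genome with `p_ado = 0.1`, `p_ae = 1e-3` and 20 sites, 3 chains of
5000 iterations. These sizes were chosen so the whole suite runs on one
CPU in minutes while every scientific claim stays at full strength.

One property from the study conditions is tested in a sharpened form:
with no dropout and no amplification errors, "selected sites = true
mutation loci carried by 2..C-1 covered cells" cannot hold verbatim,
because the urn's allele split is uniform — a true carrier shows the
alternative allele in fewer than 20% of its reads with probability about
3/19 at coverage 20, and such loci are (correctly) rejected by the
thresholds. The tests therefore assert no false positives, and equality
with the threshold-eligible ground-truth set recomputed from the reads.

## Known limitations

* Branch lengths of the NJ tree are carried but not validated; only the
  topology is interpreted.
* Inference truncates to at most one amplification error per site and
  cell; simulation does not, so the likelihood is mildly misspecified at
  high `p_ae` — by design.
* The hyperparameters `alpha`, `a`, `b` are fixed, not estimated.
* BAM/CRAM, indels, and mapping-quality filtering are out of scope; the
  SAM reader accepts ungapped (`M`/`S`) text alignments only and fails
  loudly otherwise.
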