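#' Configuration of a synthetic dataset
#'
#' Collects the parameters of the forward simulation: a random binary
#' lineage tree over `n_cells` cells, a diploid genome with germline SNVs at
#' even (0-based) positions and somatic mutations at odd positions, allelic
#' dropout per site pair and allele, Polya-urn amplification with per-copy
#' errors, and Phred-scored sequencing.
#'
#' @param n_cells number of single cells (>= 3).
#' @param genome_length diploid genome length in base pairs (even).
#' @param mu mutations per tree edge; the tree carries exactly
#'   `2 * (n_cells - 1) * mu` mutations.
#' @param rho phasing frequency: the fraction of the `genome_length / 2`
#'   even positions that carry a germline SNV.
#' @param p_ado allelic dropout probability (per site pair and allele).
#' @param p_ae amplification error probability (per urn copy event; the
#'   simulation allows several errors to accumulate along a fragment
#'   lineage even though inference truncates to one).
#' @param lambda mean read coverage per site pair (Poisson rate).
#' @param phred_range inclusive integer range of simulated Phred scores.
#' @param bulk_copies number of error-free replicates of each bulk
#'   haplotype emitted as bulk reads.
#' @param read_length read length in bases (>= 2; reads start at the even
#'   position of their site pair).
#' @param seed integer seed governing all randomness of the simulation.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 10, genome_length = 1e6, mu = 10, rho = 1,
                       p_ado = 0.1, p_ae = 1e-3, lambda = 10,
                       phred_range = c(30, 42), bulk_copies = 15,
                       read_length = 2, seed = 1) {
  if (n_cells < 3) stop("n_cells must be >= 3")
  if (genome_length %% 2 != 0) stop("genome_length must be even")
  stopifnot_prob(rho, "rho")
  stopifnot_prob(p_ado, "p_ado")
  stopifnot_prob(p_ae, "p_ae")
  if (mu < 1) stop("mu must be a positive integer")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (read_length < 2) stop("read_length must be >= 2")
  stopifnot(length(phred_range) == 2, phred_range[1] <= phred_range[2])
  structure(list(n_cells = as.integer(n_cells),
                 genome_length = as.integer(genome_length),
                 mu = as.integer(mu), rho = rho, p_ado = p_ado, p_ae = p_ae,
                 lambda = lambda, phred_range = as.integer(phred_range),
                 bulk_copies = as.integer(bulk_copies),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random binary lineage tree
#'
#' @param n_cells number of leaves (>= 3); leaves are labelled
#'   `cell1 ... cellC`.
#' @param seed optional seed (set before drawing).
#' @return a rooted binary `phylo` tree with `2 * (n_cells - 1)` edges and
#'   unit branch lengths.
#' @export
generate_lineage_tree <- function(n_cells, seed = NULL) {
  if (n_cells < 3) stop("n_cells must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n_cells, rooted = TRUE)
  # label by tip index so cell c is always tip c
  tree$tip.label <- paste0("cell", seq_len(n_cells))
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

# leaf index sets below each edge (edge i = row i of tree$edge)
edge_leaf_sets <- function(tree) {
  C <- length(tree$tip.label)
  desc <- vector("list", C + tree$Nnode)
  for (i in seq_len(C)) desc[[i]] <- i
  # postorder guarantees children are accumulated before their parent
  for (i in ape::postorder(tree)) {
    child <- tree$edge[i, 2]
    parent <- tree$edge[i, 1]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  lapply(seq_len(nrow(tree$edge)), function(i) sort(desc[[tree$edge[i, 2]]]))
}

#' Assign mutations to lineage tree edges
#'
#' Picks `2 * (C - 1) * mu` distinct odd (0-based) genome positions and maps
#' each to one tree edge, guaranteeing at least one mutation per edge; every
#' leaf below an edge inherits its mutations. The carrying haplotype of each
#' mutation is drawn uniformly.
#'
#' @param tree a rooted binary `phylo` lineage tree.
#' @param mu mutations per edge.
#' @param genome_length genome length in bases.
#' @param seed optional seed.
#' @return a tibble with columns `locus` (0-based odd position), `edge`
#'   (row of `tree$edge`) and `hap` (1 or 2).
#' @export
assign_mutations <- function(tree, mu, genome_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- length(tree$tip.label)
  n_edges <- nrow(tree$edge)
  n_mut <- n_edges * mu
  odd <- seq(1L, genome_length - 1L, by = 2L)
  if (length(odd) < n_mut) {
    stop(sprintf("genome too short: %d odd positions for %d mutations",
                 length(odd), n_mut))
  }
  loci <- sample(odd, n_mut)
  edges <- c(sample(n_edges), sample(n_edges, n_mut - n_edges, replace = TRUE))
  tibble::tibble(locus = as.integer(loci), edge = as.integer(edges),
                 hap = sample(1:2, n_mut, replace = TRUE))
}

#' Generate the bulk genome, germline SNVs and per-cell substitutions
#'
#' The bulk diploid genome is homozygous everywhere except at
#' `round(rho * genome_length / 2)` germline SNV positions, placed at even
#' (0-based) indices, where the two haplotypes differ. Each mutation locus
#' gets a random alternative base on its carrying haplotype; cells below
#' the mutation's edge inherit it.
#'
#' @param config a [sim_config()].
#' @param tree the lineage tree.
#' @param mutation_map a tibble from [assign_mutations()].
#' @param seed optional seed.
#' @return a list: `h1`, `h2` (bulk haplotypes as 0..3 base codes),
#'   `gsnv_loci` (0-based even positions), `mutations` (the mutation map
#'   extended with `ref`, `alt` and the inheriting cells) and `mut_cells`
#'   (mutations x cells logical matrix).
#' @export
generate_genomes <- function(config, tree, mutation_map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- config$genome_length
  h1 <- sample(0:3, G, replace = TRUE)
  h2 <- h1
  n_gsnv <- round(config$rho * G / 2)
  even <- seq(0L, G - 2L, by = 2L)
  gsnv <- sort(sample(even, n_gsnv))
  shift <- sample(1:3, n_gsnv, replace = TRUE)
  h2[gsnv + 1L] <- (h1[gsnv + 1L] + shift) %% 4L
  ref <- ifelse(mutation_map$hap == 1, h1[mutation_map$locus + 1L],
                h2[mutation_map$locus + 1L])
  alt <- (ref + sample(1:3, nrow(mutation_map), replace = TRUE)) %% 4L
  leaf_sets <- edge_leaf_sets(tree)
  C <- length(tree$tip.label)
  mut_cells <- matrix(FALSE, nrow(mutation_map), C)
  for (i in seq_len(nrow(mutation_map))) {
    mut_cells[i, leaf_sets[[mutation_map$edge[i]]]] <- TRUE
  }
  mutations <- dplyr::mutate(mutation_map, ref = as.integer(ref),
                             alt = as.integer(alt))
  list(h1 = h1, h2 = h2, gsnv_loci = gsnv, mutations = mutations,
       mut_cells = mut_cells)
}

#' Draw the allelic-dropout mask
#'
#' Per cell, per site pair and per allele an independent Bernoulli(p_ado)
#' dropout flag; both alleles of a pair may drop.
#'
#' @param n_cells,n_pairs dimensions of the mask.
#' @param p_ado dropout probability.
#' @param seed optional seed.
#' @return a list of two `n_cells x n_pairs` logical matrices `d1`, `d2`.
#' @export
apply_ado_mask <- function(n_cells, n_pairs, p_ado, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot_prob(p_ado, "p_ado")
  d1 <- matrix(rbinom(n_cells * n_pairs, 1, p_ado) == 1, n_cells, n_pairs)
  d2 <- matrix(rbinom(n_cells * n_pairs, 1, p_ado) == 1, n_cells, n_pairs)
  list(d1 = d1, d2 = d2)
}

#' Amplify one site with the generalized Polya urn
#'
#' The urn is initialized with the surviving allele fragments (0, 1 or 2)
#' and draw-copy-return steps are repeated until it holds `L` fragments
#' (the originals are sequencing-eligible and counted inside `L`). Each
#' copy is corrupted at one uniformly chosen position with probability
#' `p_ae`; errors propagate to the copies of an erroneous fragment. With
#' both alleles dropped no fragments are produced regardless of `L`.
#'
#' @param genotype character vector of surviving allele fragment strings
#'   (length 0, 1 or 2; equal widths).
#' @param L requested coverage.
#' @param p_ae per-copy amplification error probability.
#' @param seed optional seed.
#' @return a character vector of `min(L, ...)` fragment strings (empty when
#'   no allele survived or `L == 0`), with the originating allele index as
#'   attribute `origin`.
#' @export
amplify_site <- function(genotype, L, p_ae, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot_prob(p_ae, "p_ae")
  if (length(genotype) == 0 || L == 0) {
    out <- character(0)
    attr(out, "origin") <- integer(0)
    return(out)
  }
  width <- nchar(genotype[1])
  init <- do.call(rbind, lapply(genotype, function(s) {
    match(strsplit(s, "")[[1]], NUC) - 1L
  }))
  res <- cpp_amplify_site(init, as.integer(L), p_ae)
  frags <- apply(res$fragments, 1, function(r) paste(NUC[r + 1], collapse = ""))
  if (length(frags) == 0) frags <- character(0)
  attr(frags, "origin") <- res$origin
  frags
}

#' Sequence fragments into Phred-scored reads
#'
#' One read per fragment; each covered position draws an integer Phred
#' score uniformly from `phred_range` and is miscalled (uniform different
#' nucleotide) with probability `10^(-0.1 * rho)`.
#'
#' @param fragments character vector of fragment strings.
#' @param phred_range inclusive integer Phred range.
#' @param seed optional seed.
#' @return a tibble with columns `bases` and `quals` (Phred+33 strings).
#' @export
sequence_reads <- function(fragments, phred_range = c(30, 42), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(fragments) == 0) {
    return(tibble::tibble(bases = character(0), quals = character(0)))
  }
  mat <- do.call(rbind, lapply(fragments, function(s) {
    match(strsplit(s, "")[[1]], NUC) - 1L
  }))
  res <- cpp_sequence_fragments(mat, phred_range[1], phred_range[2])
  bases <- apply(res$bases, 1, function(r) paste(NUC[r + 1], collapse = ""))
  quals <- apply(res$phred, 1, function(p) intToUtf8(p + 33L))
  tibble::tibble(bases = bases, quals = quals)
}

#' Emit the bulk reads
#'
#' The bulk sample is represented by `bulk_copies` error-free copies of
#' each haplotype per site pair (no amplification step), so every position
#' is covered by `2 * bulk_copies` reads and a heterozygous gSNV shows both
#' nucleotides at 50%.
#'
#' @param h1,h2 bulk haplotypes as 0..3 base codes.
#' @param bulk_copies copies per haplotype.
#' @param read_length read length (reads start at even positions).
#' @return a tibble with columns `start` (0-based), `bases`, `quals`.
#' @export
make_bulk_reads <- function(h1, h2, bulk_copies = 15, read_length = 2) {
  G <- length(h1)
  starts <- seq(0L, G - 2L, by = 2L)
  seq_of <- function(h, s) {
    idx <- pmin(s + seq_len(read_length) - 1L, G - 1L)
    paste(NUC[h[idx + 1L] + 1L], collapse = "")
  }
  b1 <- vapply(starts, function(s) seq_of(h1, s), character(1))
  b2 <- vapply(starts, function(s) seq_of(h2, s), character(1))
  qual <- strrep("K", read_length) # Phred 42: error-free replicates
  tibble::tibble(
    start = rep(starts, each = 2L * bulk_copies),
    bases = as.vector(vapply(seq_along(starts), function(i) {
      c(rep(b1[i], bulk_copies), rep(b2[i], bulk_copies))
    }, character(2L * bulk_copies))),
    quals = qual)
}

#' Simulate a complete synthetic dataset with known ground truth
#'
#' Runs the whole forward protocol: random binary lineage tree, mutation
#' assignment (at least one per edge), diploid bulk genome with germline
#' SNVs, per-cell inherited mutations, allelic dropout, Polya-urn
#' amplification with per-copy errors, Phred-scored sequencing, and
#' error-free replicated bulk reads. All randomness flows from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `sc_dataset`: `config`, `tree`,
#'   `mutations`, `mut_cells`, `gsnv_loci`, `h1`, `h2`, `ado`, `reads`
#'   (tibble: `cell`, `start`, `bases`, `quals`) and `bulk_reads`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  C <- config$n_cells
  tree <- generate_lineage_tree(C)
  mutation_map <- assign_mutations(tree, config$mu, config$genome_length)
  gen <- generate_genomes(config, tree, mutation_map)
  n_pairs <- config$genome_length %/% 2L
  ado <- apply_ado_mask(C, n_pairs, config$p_ado)
  raw <- cpp_simulate_cell_reads(
    gen$h1, gen$h2, gen$mutations$locus, gen$mutations$hap,
    gen$mutations$alt, gen$mut_cells, ado$d1, ado$d2,
    config$lambda, config$p_ae, config$phred_range[1],
    config$phred_range[2], config$read_length)
  reads <- tibble::tibble(
    cell = raw$cell,
    start = 2L * (raw$pair - 1L),
    bases = encode_base_rows(raw$bases),
    quals = encode_qual_rows(raw$phred))
  bulk_reads <- make_bulk_reads(gen$h1, gen$h2, config$bulk_copies,
                                config$read_length)
  structure(list(config = config, tree = tree, mutations = gen$mutations,
                 mut_cells = gen$mut_cells, gsnv_loci = gen$gsnv_loci,
                 h1 = gen$h1, h2 = gen$h2, ado = ado, reads = reads,
                 bulk_reads = bulk_reads),
            class = "sc_dataset")
}

# vectorized int-matrix -> string encoders for read tables
encode_base_rows <- function(m) {
  if (nrow(m) == 0) return(character(0))
  cols <- lapply(seq_len(ncol(m)), function(j) NUC[m[, j] + 1L])
  do.call(paste0, cols)
}

encode_qual_rows <- function(m) {
  if (nrow(m) == 0) return(character(0))
  k <- ncol(m)
  flat <- as.vector(t(m)) + 33L
  s <- rawToChar(as.raw(flat))
  substring(s, seq(1, nchar(s), k), seq(k, nchar(s), k))
}

#' Reconstruct the true diploid genome of one cell
#'
#' @param ds an `sc_dataset`.
#' @param cell cell index.
#' @return list of two 0..3 integer haplotype vectors.
#' @export
cell_genome <- function(ds, cell) {
  h1 <- ds$h1
  h2 <- ds$h2
  mine <- which(ds$mut_cells[, cell])
  for (i in mine) {
    loc <- ds$mutations$locus[i] + 1L
    if (ds$mutations$hap[i] == 1) h1[loc] <- ds$mutations$alt[i]
    else h2[loc] <- ds$mutations$alt[i]
  }
  list(h1 = h1, h2 = h2)
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic dataset: %d cells, %s bp genome, %d mutations, %d gSNVs, %d reads\n",
    x$config$n_cells, format(x$config$genome_length, big.mark = ","),
    nrow(x$mutations), length(x$gsnv_loci), nrow(x$reads)))
  invisible(x)
}
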