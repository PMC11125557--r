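#' Read a SAM text file into a read tibble
#'
#' Supports ungapped alignments: CIGAR strings composed of `M` (match) and
#' `S` (soft clip) operations only; soft-clipped bases are removed from the
#' sequence and qualities. Any other CIGAR operation raises an error naming
#' the unsupported operation.
#'
#' @param path path to a SAM text file.
#' @param cell optional cell id stored in the `cell` column.
#' @return a tibble with columns `cell`, `qname`, `start` (0-based
#'   reference position), `bases` and `quals` (Phred+33).
#' @export
read_sam <- function(path, cell = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble::tibble(cell = integer(0), qname = character(0),
                          start = integer(0), bases = character(0),
                          quals = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(fields, `[[`, character(1), 1)
  pos1 <- as.integer(vapply(fields, `[[`, character(1), 4))
  cigar <- vapply(fields, `[[`, character(1), 6)
  seqs <- vapply(fields, `[[`, character(1), 10)
  quals <- vapply(fields, `[[`, character(1), 11)
  ops_list <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))
  out_b <- character(length(lines))
  out_q <- character(length(lines))
  for (i in seq_along(lines)) {
    ops <- ops_list[[i]]
    lens <- as.integer(sub("[A-Z=]$", "", ops))
    kinds <- sub("^[0-9]+", "", ops)
    bad <- setdiff(kinds, c("M", "S"))
    if (length(bad) > 0) {
      stop(sprintf("unsupported CIGAR operation '%s' in record %s",
                   bad[1], qname[i]), call. = FALSE)
    }
    keep <- kinds == "M"
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    b <- q <- character(0)
    for (k in which(keep)) {
      b <- c(b, substr(seqs[i], starts[k], ends[k]))
      q <- c(q, substr(quals[i], starts[k], ends[k]))
    }
    # leading soft clip does not consume reference
    out_b[i] <- paste(b, collapse = "")
    out_q[i] <- paste(q, collapse = "")
  }
  tibble::tibble(cell = cell, qname = qname, start = pos1 - 1L,
                 bases = out_b, quals = out_q)
}

write_sam <- function(reads, path, ref_name = "ref", ref_len = NULL,
                      qname_prefix = "r") {
  if (is.null(ref_len)) ref_len <- max(reads$start) + max(nchar(reads$bases))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_len)))
  n <- nrow(reads)
  body <- sprintf("%s%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  qname_prefix, seq_len(n), ref_name, reads$start + 1L,
                  nchar(reads$bases), reads$bases, reads$quals)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits the reference haplotypes as FASTA, one SAM text file per cell plus
#' one for the bulk reads, the ground-truth tree as Newick, the mutation
#' map as TSV and the configuration as JSON. The files round-trip through
#' [read_dataset()].
#'
#' @param ds an `sc_dataset` from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir))
  G <- length(ds$h1)
  seqs <- list(hap1 = tolower(NUC[ds$h1 + 1L]), hap2 = tolower(NUC[ds$h2 + 1L]))
  ape::write.FASTA(ape::as.DNAbin(seqs), file.path(dir, "reference.fasta"))
  for (c in seq_len(ds$config$n_cells)) {
    r <- ds$reads[ds$reads$cell == c, ]
    write_sam(r, file.path(dir, sprintf("cell_%02d.sam", c)), ref_len = G,
              qname_prefix = sprintf("c%d_", c))
  }
  write_sam(ds$bulk_reads, file.path(dir, "bulk.sam"), ref_len = G,
            qname_prefix = "b")
  write_newick(ds$tree, file.path(dir, "true_tree.nwk"))
  write.table(ds$mutations, file.path(dir, "mutation_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(as.character(jsonlite::toJSON(unclass(ds$config),
                                           auto_unbox = TRUE)),
             file.path(dir, "config.json"))
  writeLines(as.character(ds$gsnv_loci), file.path(dir, "gsnv_loci.txt"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a list with `config`, `reads`, `bulk_reads`, `tree`, `mutations`,
#'   `gsnv_loci`, `h1`, `h2`.
#' @export
read_dataset <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  fasta <- ape::read.FASTA(file.path(dir, "reference.fasta"))
  haps <- lapply(as.character(fasta), function(x) match(toupper(x), NUC) - 1L)
  sams <- sort(list.files(dir, pattern = "^cell_.*\\.sam$", full.names = TRUE))
  reads <- dplyr::bind_rows(lapply(seq_along(sams), function(i) {
    read_sam(sams[i], cell = i)
  }))
  bulk_reads <- read_sam(file.path(dir, "bulk.sam"))
  tree <- ape::read.tree(file.path(dir, "true_tree.nwk"))
  mutations <- tibble::as_tibble(
    read.delim(file.path(dir, "mutation_map.tsv")))
  gsnv <- as.integer(readLines(file.path(dir, "gsnv_loci.txt")))
  list(config = cfg, reads = reads, bulk_reads = bulk_reads, tree = tree,
       mutations = mutations, gsnv_loci = gsnv,
       h1 = haps[[1]], h2 = haps[[2]])
}

#' Write a tree as Newick
#'
#' Negative neighbor-joining branch lengths are clamped to zero for
#' serialization only; the topology is untouched.
#'
#' @param tree a `phylo`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
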