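# Expand a read tibble (cell, start, bases, quals) into one row per covered
# position. `id` identifies the originating read so multi-position reads can
# be regrouped.
reads_long <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble::tibble(id = integer(0), cell = integer(0),
                          pos = integer(0), base = character(0),
                          q = numeric(0)))
  }
  w <- nchar(reads$bases)
  idx <- rep.int(seq_len(nrow(reads)), w)
  off <- sequence(w) - 1L
  base <- strsplit(paste(reads$bases, collapse = ""), "")[[1]]
  phred <- utf8ToInt(paste(reads$quals, collapse = "")) - 33L
  tibble::tibble(id = idx,
                 cell = if ("cell" %in% names(reads)) reads$cell[idx] else NA_integer_,
                 pos = reads$start[idx] + off,
                 base = base,
                 q = phred_to_error(phred))
}

# per-position nucleotide counts, ordered deterministically
pos_base_counts <- function(long) {
  dplyr::count(long, .data$pos, .data$base, name = "n")
}

# top-two summary per position: depth, first/second base and counts
pos_top2 <- function(counts) {
  counts <- dplyr::arrange(counts, .data$pos, dplyr::desc(.data$n), .data$base)
  dplyr::summarise(
    dplyr::group_by(counts, .data$pos),
    depth = sum(.data$n),
    b1 = .data$base[1], n1 = .data$n[1],
    b2 = dplyr::nth(.data$base, 2, default = NA_character_),
    n2 = dplyr::nth(.data$n, 2, default = 0L),
    .groups = "drop")
}

# reference calls for every acceptable bulk position: tibble(pos, ref)
bulk_reference_calls <- function(bulk_top2, min_depth = 10, ref_frac = 0.8) {
  s <- bulk_top2[bulk_top2$depth >= min_depth &
                   bulk_top2$n1 / bulk_top2$depth >= ref_frac, ]
  tibble::tibble(pos = s$pos, ref = s$b1)
}

#' Call the bulk reference nucleotide at a position
#'
#' The reference is the majority nucleotide, accepted only when the bulk
#' depth is at least `min_depth` and the majority frequency is at least
#' `ref_frac`; otherwise the position is rejected (`NA`).
#'
#' @param bulk_reads bulk read tibble (`start`, `bases`, `quals`).
#' @param pos 0-based position.
#' @param min_depth,ref_frac acceptance thresholds.
#' @return the reference nucleotide or `NA`.
#' @export
call_bulk_reference <- function(bulk_reads, pos, min_depth = 10,
                                ref_frac = 0.8) {
  long <- reads_long(bulk_reads)
  s <- pos_top2(pos_base_counts(long[long$pos == pos, ]))
  refs <- bulk_reference_calls(s, min_depth, ref_frac)
  if (nrow(refs) == 0) NA_character_ else refs$ref[1]
}

#' Call heterozygous germline SNVs from bulk reads
#'
#' A position is reported as a gSNV when the bulk depth is at least
#' `min_depth` and the second most frequent nucleotide reaches frequency
#' `alt_frac`; the genotype is the top two nucleotides.
#'
#' @param bulk_reads bulk read tibble.
#' @param min_depth,alt_frac thresholds.
#' @return a tibble with columns `pos`, `a1`, `a2`.
#' @export
call_gsnvs <- function(bulk_reads, min_depth = 10, alt_frac = 0.2) {
  long <- reads_long(bulk_reads)
  s <- pos_top2(pos_base_counts(long))
  gsnv_calls(s, min_depth, alt_frac)
}

gsnv_calls <- function(bulk_top2, min_depth = 10, alt_frac = 0.2) {
  s <- bulk_top2[bulk_top2$depth >= min_depth & !is.na(bulk_top2$b2) &
                   bulk_top2$n2 / bulk_top2$depth >= alt_frac, ]
  tibble::tibble(pos = s$pos, a1 = s$b1, a2 = s$b2)
}

# number of cells whose reads (already restricted to the gSNV position)
# show both alleles at >= frac of the cell's covering reads
gsnv_cells_displaying <- function(long, alleles, frac = 0.2) {
  if (nrow(long) == 0) return(0L)
  ok <- 0L
  for (cl in unique(long$cell)) {
    b <- long$base[long$cell == cl]
    f1 <- mean(b == alleles[1])
    f2 <- mean(b == alleles[2])
    if (f1 >= frac && f2 >= frac) ok <- ok + 1L
  }
  ok
}

#' Check that a gSNV is displayed by at least two single cells
#'
#' @param cell_reads single-cell read tibble (`cell`, `start`, `bases`,
#'   `quals`).
#' @param gsnv_pos 0-based gSNV position.
#' @param alleles the two heterozygous nucleotides.
#' @param frac minimum per-cell frequency of each allele.
#' @param min_cells number of cells that must display both alleles.
#' @return `TRUE` when at least `min_cells` cells each show both alleles at
#'   frequency `frac` among their reads covering the position.
#' @export
validate_gsnv_in_cells <- function(cell_reads, gsnv_pos, alleles,
                                   frac = 0.2, min_cells = 2) {
  long <- reads_long(cell_reads)
  long <- long[long$pos == gsnv_pos, ]
  gsnv_cells_displaying(long, alleles, frac) >= min_cells
}

# Core of the candidate filter, on a prebuilt long table and reference
# calls. Returns tibble(pos, ref, alt, n_alt_cells).
select_candidates_long <- function(long, refs, n_cells, alt_frac = 0.2,
                                   min_cells = 2, min_cell_depth = 2) {
  empty <- tibble::tibble(pos = integer(0), ref = character(0),
                          alt = character(0), n_alt_cells = integer(0))
  long <- dplyr::inner_join(long, refs, by = "pos")
  cand0 <- unique(long$pos[long$base != long$ref])
  if (length(cand0) == 0) return(empty)
  sub <- long[long$pos %in% cand0, ]
  cnt <- dplyr::count(sub, .data$pos, .data$cell, .data$base, name = "n")
  dp <- dplyr::summarise(dplyr::group_by(cnt, .data$pos, .data$cell),
                         depth = sum(.data$n), .groups = "drop")
  cnt <- dplyr::left_join(cnt, dp, by = c("pos", "cell"))
  cnt <- dplyr::left_join(cnt, dplyr::distinct(sub[, c("pos", "ref")]),
                          by = "pos")
  alt <- cnt[cnt$base != cnt$ref & cnt$depth >= min_cell_depth &
               cnt$n / cnt$depth >= alt_frac, ]
  if (nrow(alt) == 0) return(empty)
  per_alt <- dplyr::summarise(
    dplyr::group_by(alt, .data$pos, .data$ref, .data$base),
    n_alt_cells = dplyr::n_distinct(.data$cell),
    pooled = sum(.data$n), .groups = "drop")
  per_alt <- dplyr::arrange(per_alt, .data$pos,
                            dplyr::desc(.data$n_alt_cells),
                            dplyr::desc(.data$pooled), .data$base)
  best <- dplyr::ungroup(dplyr::slice_head(dplyr::group_by(per_alt,
                                                           .data$pos), n = 1))
  best <- best[best$n_alt_cells >= min_cells &
                 best$n_alt_cells <= n_cells - 1, ]
  tibble::tibble(pos = best$pos, ref = best$ref, alt = best$base,
                 n_alt_cells = as.integer(best$n_alt_cells))
}

#' Select candidate mutation positions from single-cell reads
#'
#' A position is kept when between `min_cells` and `n_cells - 1` cells
#' agree on the same alternative nucleotide, each showing it in at least
#' `alt_frac` of its reads (cells are only evaluated at depth
#' `min_cell_depth` or more). A lone alternative cell or an alternative
#' shared by all cells carries no lineage information. Ties between
#' alternative nucleotides are broken by the number of agreeing cells,
#' then the pooled read count, then alphabetically.
#'
#' @param cell_reads single-cell read tibble.
#' @param bulk_reads bulk read tibble (for the reference call).
#' @param n_cells number of cells.
#' @param alt_frac per-cell alternative frequency threshold.
#' @param min_cells minimum number of agreeing cells.
#' @param min_cell_depth minimum per-cell depth to evaluate a cell.
#' @param min_bulk_depth,ref_frac bulk reference thresholds.
#' @return a tibble with columns `pos`, `ref`, `alt`, `n_alt_cells`.
#' @export
select_candidates <- function(cell_reads, bulk_reads, n_cells,
                              alt_frac = 0.2, min_cells = 2,
                              min_cell_depth = 2, min_bulk_depth = 10,
                              ref_frac = 0.8) {
  bsum <- pos_top2(pos_base_counts(reads_long(bulk_reads)))
  refs <- bulk_reference_calls(bsum, min_bulk_depth, ref_frac)
  select_candidates_long(reads_long(cell_reads), refs, n_cells,
                         alt_frac, min_cells, min_cell_depth)
}

#' Pair a candidate position with the closest usable gSNV
#'
#' Among the validated gSNVs, the closest one that is co-covered with the
#' candidate by at least one read is chosen; the gSNV display criterion is
#' then re-checked using only the co-covering reads. When no gSNV
#' qualifies the candidate is emitted as a singleton (hybrid mode) or
#' dropped (paired mode).
#'
#' @param cand_pos candidate 0-based position.
#' @param gsnvs tibble of validated gSNVs (`pos`, `a1`, `a2`).
#' @param cell_reads single-cell read tibble.
#' @param frac,min_cells gSNV display thresholds for the final re-check.
#' @return a list `(gsnv_pos, a1, a2)` or `NULL` when no gSNV qualifies.
#' @export
pair_with_gsnv <- function(cand_pos, gsnvs, cell_reads, frac = 0.2,
                           min_cells = 2) {
  pair_with_gsnv_long(cand_pos, gsnvs, reads_long(cell_reads), frac,
                      min_cells)
}

pair_with_gsnv_long <- function(cand_pos, gsnvs, long, frac = 0.2,
                                min_cells = 2) {
  if (is.null(gsnvs) || nrow(gsnvs) == 0) return(NULL)
  cov_ids <- unique(long$id[long$pos == cand_pos])
  if (length(cov_ids) == 0) return(NULL)
  covering <- long[long$id %in% cov_ids, ]
  co_pos <- setdiff(unique(covering$pos), cand_pos)
  cands <- gsnvs[gsnvs$pos %in% co_pos, ]
  if (nrow(cands) == 0) return(NULL)
  cands <- cands[order(abs(cands$pos - cand_pos), cands$pos), ]
  for (i in seq_len(nrow(cands))) {
    g <- cands[i, ]
    co <- covering[covering$pos == g$pos, ]
    # one last gSNV check on the co-covering reads only
    if (gsnv_cells_displaying(co, c(g$a1, g$a2), frac) >= min_cells) {
      return(list(gsnv_pos = g$pos, a1 = g$a1, a2 = g$a2))
    }
  }
  NULL
}

#' Select candidate sites and build per-cell observations
#'
#' Applies the full site-selection heuristics: bulk reference and gSNV
#' calling, the alternative-cell-count filter, gSNV validation in the
#' single cells, pairing each candidate with the nearest co-covered gSNV
#' (paired and hybrid modes) and the final co-covering gSNV re-check. The
#' result carries, per site, the per-cell reads restricted to the site's
#' position(s). Selection is deterministic and independent of the read
#' input order.
#'
#' @param cell_reads single-cell read tibble (`cell`, `start`, `bases`,
#'   `quals`).
#' @param bulk_reads bulk read tibble.
#' @param n_cells number of single cells.
#' @param mode `"hybrid"` (default), `"paired"` or `"singleton"`.
#' @param min_bulk_depth,ref_frac bulk reference thresholds.
#' @param alt_frac alternative / gSNV frequency threshold.
#' @param min_cells minimum agreeing (or displaying) cells.
#' @param min_cell_depth minimum per-cell depth for the alternative call.
#' @return a tibble of class `ld_sites`, sorted by position, with columns
#'   `kind`, `pos`, `gsnv_pos`, `n_alt_cells` and a `site` list column of
#'   site observations; the number of cells is stored in the `n_cells`
#'   attribute.
#' @export
select_sites <- function(cell_reads, bulk_reads, n_cells,
                         mode = c("hybrid", "paired", "singleton"),
                         min_bulk_depth = 10, ref_frac = 0.8,
                         alt_frac = 0.2, min_cells = 2, min_cell_depth = 2) {
  mode <- match.arg(mode)
  empty <- tibble::tibble(kind = character(0), pos = integer(0),
                          gsnv_pos = integer(0), n_alt_cells = integer(0),
                          site = list())
  attr(empty, "n_cells") <- as.integer(n_cells)
  class(empty) <- c("ld_sites", class(empty))
  bsum <- pos_top2(pos_base_counts(reads_long(bulk_reads)))
  refs <- bulk_reference_calls(bsum, min_bulk_depth, ref_frac)
  long <- reads_long(cell_reads)
  cands <- select_candidates_long(long, refs, n_cells, alt_frac,
                                  min_cells, min_cell_depth)
  if (nrow(cands) == 0) return(empty)
  # restrict the long table to reads that touch a candidate position
  touch <- long$id[long$pos %in% cands$pos]
  near <- long[long$id %in% unique(touch), ]
  gsnvs <- NULL
  if (mode != "singleton") {
    gsnvs <- gsnv_calls(bsum, min_bulk_depth, alt_frac)
    # validate (over all reads) only the gSNVs that could ever be paired
    reachable <- intersect(gsnvs$pos, unique(near$pos))
    gsnvs <- gsnvs[gsnvs$pos %in% reachable, ]
    if (nrow(gsnvs) > 0) {
      at_g <- long[long$pos %in% gsnvs$pos, ]
      keep <- vapply(seq_len(nrow(gsnvs)), function(i) {
        g <- gsnvs[i, ]
        gsnv_cells_displaying(at_g[at_g$pos == g$pos, ],
                              c(g$a1, g$a2)) >= min_cells
      }, logical(1))
      gsnvs <- gsnvs[keep, ]
    }
  }
  rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    pairing <- NULL
    if (mode != "singleton") {
      pairing <- pair_with_gsnv_long(cand$pos, gsnvs, near)
    }
    if (is.null(pairing) && mode == "paired") next
    if (is.null(pairing)) {
      positions <- cand$pos
      bulk <- c(cand$ref, cand$ref)
      kind <- "singleton"
      gsnv_pos <- NA_integer_
    } else {
      positions <- c(cand$pos, pairing$gsnv_pos) # candidate site first
      bulk <- c(paste0(cand$ref, pairing$a1), paste0(cand$ref, pairing$a2))
      kind <- "paired"
      gsnv_pos <- pairing$gsnv_pos
    }
    site <- build_site_observation(near, positions, bulk, n_cells)
    rows[[i]] <- tibble::tibble(
      kind = kind, pos = cand$pos, gsnv_pos = as.integer(gsnv_pos),
      n_alt_cells = cand$n_alt_cells, site = list(site))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$pos)
  attr(out, "n_cells") <- as.integer(n_cells)
  class(out) <- c("ld_sites", class(out))
  out
}

# Assemble the per-cell observation matrices of one site from the long read
# table. positions[1] is the candidate site.
build_site_observation <- function(long, positions, bulk, n_cells) {
  P <- length(positions)
  sub <- long[long$pos %in% positions, ]
  cells <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    sc <- sub[sub$cell == c, ]
    if (nrow(sc) == 0) next
    ids <- sort(unique(sc$id))
    L <- length(ids)
    bmat <- matrix(NA_character_, L, P)
    qmat <- matrix(NA_real_, L, P)
    row_of <- match(sc$id, ids)
    col_of <- match(sc$pos, positions)
    bmat[cbind(row_of, col_of)] <- sc$base
    qmat[cbind(row_of, col_of)] <- sc$q
    cells[[c]] <- list(bases = bmat, error_probs = qmat)
  }
  list(kind = if (P == 1) "singleton" else "paired",
       positions = as.integer(positions), bulk = bulk, cells = cells)
}

#' @export
print.ld_sites <- function(x, ...) {
  cat(sprintf("%d selected site(s) (%s) over %d cells\n", nrow(x),
              paste(unique(x$kind), collapse = "+"),
              attr(x, "n_cells") %||% NA_integer_))
  NextMethod()
}

#' Write selected sites to JSON
#'
#' The schema is versioned: per site its kind, 0-based positions
#' (candidate first), the bulk genotype and, per cell, the read bases and
#' base-calling error probabilities at the site positions (`null` marks an
#' uncovered position).
#'
#' @param sites an `ld_sites` tibble from [select_sites()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sites <- function(sites, path) {
  n_cells <- attr(sites, "n_cells")
  out <- list(version = 1L, n_cells = n_cells,
              sites = lapply(seq_len(nrow(sites)), function(i) {
                s <- sites$site[[i]]
                list(kind = s$kind, positions = s$positions, bulk = s$bulk,
                     cells = lapply(s$cells, function(obs) {
                       if (is.null(obs)) {
                         return(list(bases = list(), error_probs = list()))
                       }
                       list(bases = lapply(seq_len(nrow(obs$bases)),
                                           function(r) as.list(obs$bases[r, ])),
                            error_probs = lapply(seq_len(nrow(obs$bases)),
                                                 function(r) as.list(obs$error_probs[r, ])))
                     }))
              }))
  writeLines(as.character(jsonlite::toJSON(out, auto_unbox = TRUE,
                                           digits = NA, null = "null",
                                           na = "null")),
             path)
  invisible(path)
}

#' Read a sites JSON file written by [write_sites()]
#'
#' @param path path to the JSON file.
#' @return an `ld_sites` tibble.
#' @export
read_sites <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  n_cells <- raw$n_cells
  rows <- lapply(raw$sites, function(s) {
    positions <- as.integer(unlist(s$positions))
    P <- length(positions)
    cells <- lapply(s$cells, function(obs) {
      nb <- length(obs$bases)
      if (nb == 0) return(NULL)
      bmat <- matrix(NA_character_, nb, P)
      qmat <- matrix(NA_real_, nb, P)
      for (r in seq_len(nb)) {
        for (j in seq_len(P)) {
          b <- obs$bases[[r]][[j]]
          q <- obs$error_probs[[r]][[j]]
          if (!is.null(b)) bmat[r, j] <- b
          if (!is.null(q)) qmat[r, j] <- q
        }
      }
      list(bases = bmat, error_probs = qmat)
    })
    site <- list(kind = s$kind, positions = positions,
                 bulk = unlist(s$bulk), cells = cells)
    tibble::tibble(kind = s$kind, pos = positions[1],
                   gsnv_pos = if (P > 1) positions[2] else NA_integer_,
                   n_alt_cells = NA_integer_, site = list(site))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_cells") <- as.integer(n_cells)
  class(out) <- c("ld_sites", class(out))
  out
}
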