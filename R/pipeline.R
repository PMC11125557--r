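#' Run the full lineage reconstruction workflow
#'
#' Orchestrates simulate (or load) -> select sites -> (optionally)
#' estimate parameters -> distances -> tree -> bootstrap -> evaluate,
#' writing every artifact under `out_dir`. Stages whose outputs already
#' exist are skipped unless `overwrite = TRUE`. The per-site distance
#' computations are dispatched over `jobs` workers; the reduction is
#' order-invariant, so the outputs are identical for any `jobs`.
#'
#' @param out_dir output directory.
#' @param config a [sim_config()] used when `data_dir` is `NULL`.
#' @param data_dir optional existing dataset directory
#'   (see [write_dataset()]); when given, `config` is ignored.
#' @param mode site-selection mode (`"hybrid"`, `"paired"`,
#'   `"singleton"`).
#' @param params optional [model_params()]; defaults to
#'   `model_params(p_ado = 0.1, p_ae = 1e-3)` when estimation is off.
#' @param estimate estimate `p_ado`/`p_ae` by Metropolis-Hastings before
#'   computing distances.
#' @param n_boot number of bootstrap trees (0 disables bootstrapping).
#' @param jobs number of parallel workers for the distance stage.
#' @param seed seed for the stochastic stages (defaults to
#'   `config$seed`).
#' @param overwrite recompute stages whose outputs already exist.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the artifact paths and, when the true
#'   tree is known, the similarity of the inferred tree to it.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), data_dir = NULL,
                         mode = c("hybrid", "paired", "singleton"),
                         params = NULL, estimate = FALSE, n_boot = 0,
                         jobs = 1, seed = NULL, overwrite = FALSE,
                         quiet = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-16s %6.1fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  paths <- list(
    dataset = file.path(out_dir, "dataset"),
    sites = file.path(out_dir, "sites.json"),
    params = file.path(out_dir, "params.json"),
    distances = file.path(out_dir, "distances.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    bootstrap = file.path(out_dir, "bootstrap.nwk"),
    supports = file.path(out_dir, "tbe_supports.tsv"),
    metrics = file.path(out_dir, "metrics.json"))

  # --- data ---------------------------------------------------------------
  truth_tree <- NULL
  if (is.null(data_dir)) {
    data_dir <- paths$dataset
    if (overwrite || !file.exists(file.path(data_dir, "config.json"))) {
      ds <- stage("simulate", {
        d <- simulate_dataset(config)
        write_dataset(d, data_dir)
        d
      })
      reads <- ds$reads
      bulk_reads <- ds$bulk_reads
      truth_tree <- ds$tree
      n_cells <- ds$config$n_cells
    } else {
      say("stage %-16s cached", "simulate")
      d <- stage("load", read_dataset(data_dir))
      reads <- d$reads
      bulk_reads <- d$bulk_reads
      truth_tree <- d$tree
      n_cells <- d$config$n_cells
    }
  } else {
    d <- stage("load", read_dataset(data_dir))
    reads <- d$reads
    bulk_reads <- d$bulk_reads
    truth_tree <- d$tree
    n_cells <- d$config$n_cells
  }
  seed <- seed %||% config$seed

  # --- site selection -----------------------------------------------------
  if (overwrite || !file.exists(paths$sites)) {
    sites <- stage("select-sites", {
      s <- select_sites(reads, bulk_reads, n_cells, mode = mode)
      write_sites(s, paths$sites)
      s
    })
  } else {
    say("stage %-16s cached", "select-sites")
    sites <- read_sites(paths$sites)
  }
  if (nrow(sites) == 0) {
    stop("stage 'select-sites' failed: no candidate sites found",
         call. = FALSE)
  }

  # --- parameters ---------------------------------------------------------
  if (is.null(params)) {
    if (estimate) {
      fit <- stage("estimate-params",
                   estimate_parameters(sites, seed = seed + 1L))
      params <- model_params(p_ado = unname(fit$estimates["p_ado"]),
                             p_ae = unname(fit$estimates["p_ae"]))
    } else {
      params <- model_params(p_ado = 0.1, p_ae = 1e-3)
    }
  }
  writeLines(as.character(jsonlite::toJSON(
    list(p_ado = params$p_ado, p_ae = params$p_ae, a = params$a,
         b = params$b), auto_unbox = TRUE, digits = NA)), paths$params)

  # --- distances ----------------------------------------------------------
  dist <- stage("distance", compute_distances(sites, params, jobs = jobs))
  write.table(format(dist$matrix, digits = 17), paths$distances, sep = "\t",
              quote = FALSE, col.names = NA)

  # --- tree ---------------------------------------------------------------
  tree <- stage("tree", nj_tree(dist))
  write_newick(tree, paths$tree)

  results <- list(paths = paths, params = params, n_sites = nrow(sites),
                  tree = tree)

  # --- bootstrap + supports ----------------------------------------------
  if (n_boot > 0) {
    boots <- stage("bootstrap",
                   bootstrap_trees(dist, n_boot = n_boot, seed = seed + 2L))
    txt <- vapply(boots, function(t) {
      t$edge.length <- pmax(t$edge.length, 0)
      ape::write.tree(t)
    }, character(1))
    writeLines(txt, paths$bootstrap)
    ref <- truth_tree %||% tree
    sup <- stage("tbe", tbe_supports(ref, boots))
    write.table(sup, paths$supports, sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$supports <- sup
  }

  # --- evaluation ---------------------------------------------------------
  if (!is.null(truth_tree)) {
    results$similarity <- stage("evaluate", rf_similarity(truth_tree, tree))
    writeLines(as.character(jsonlite::toJSON(
      list(similarity = results$similarity, n_sites = nrow(sites)),
      auto_unbox = TRUE, digits = NA)), paths$metrics)
    say("similarity to true tree: %.3f", results$similarity)
  }
  invisible(results)
}
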