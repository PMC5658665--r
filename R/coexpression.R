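# Thresholded Pearson co-expression networks per (brain region x
# developmental stage) cell, the within-gene-set edge-count statistic, and
# its permutation null with Bonferroni correction across the 12 networks.

#' Enrichment analysis configuration
#'
#' @param r_threshold absolute Pearson correlation above which two genes
#'   are connected (default 0.8).
#' @param n_replicates permutation replicates for the empirical p-value
#'   (default 10000).
#' @param alpha family-wise significance level (default 0.05); the
#'   per-network threshold is `alpha / n_networks` (Bonferroni).
#' @param universe_mode `"all_genes"` samples replicate gene sets from the
#'   whole matrix; `"connected_in_temporal"` restricts the universe (and
#'   the observed set) to genes with at least one connection in a
#'   temporal-parietal region network (conservative variant).
#' @param exclude_observed_set drop the observed gene set from the sampling
#'   universe (off by default: replicates are simple random draws).
#' @param seed integer seed for the permutation draws.
#' @return a list of class `"enrichment_config"`.
#' @export
enrichment_config <- function(r_threshold = 0.8, n_replicates = 10000,
                              alpha = 0.05,
                              universe_mode = c("all_genes",
                                                "connected_in_temporal"),
                              exclude_observed_set = FALSE,
                              seed = 1) {
  stopifnot(r_threshold > 0, r_threshold < 1, n_replicates >= 1, alpha > 0)
  universe_mode <- match.arg(universe_mode)
  structure(as.list(environment()), class = "enrichment_config")
}

#' Build a thresholded co-expression network for one cell
#'
#' Pearson correlation is computed for every gene pair across the samples
#' of the (region, stage) cell; genes are connected iff the absolute
#' correlation exceeds `cfg$r_threshold`. Zero-variance genes yield
#' undefined correlations and carry no edges.
#'
#' @param expr an `expression_matrix`.
#' @param region,stage cell labels (see `REGION_GROUPS`, `STAGE_GROUPS`).
#' @param cfg an [enrichment_config()].
#' @param sample_ids optional explicit sample subset overriding
#'   (region, stage) selection.
#' @return list of class `"coexpression_network"`: `network_id`, `genes`,
#'   `adjacency` (logical genes x genes, no self-edges), `n_samples`.
#' @export
build_network <- function(expr, region, stage, cfg = enrichment_config(),
                          sample_ids = NULL) {
  meta <- expr$sample_meta
  ids <- if (!is.null(sample_ids)) sample_ids else
    meta$sample_id[meta$region_group == region & meta$stage_group == stage]
  if (length(ids) < 3) {
    stop(sprintf("cell (%s, %s) has %d sample(s); >= 3 required",
                 region, stage, length(ids)), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(t(expr$values[, ids, drop = FALSE])))
  adj <- !is.na(r) & abs(r) > cfg$r_threshold
  diag(adj) <- FALSE
  structure(list(network_id = c(region = region, stage = stage),
                 genes = rownames(expr$values), adjacency = adj,
                 n_samples = length(ids)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network (%s, %s): %d genes, %d edges, %d samples\n",
              x$network_id[["region"]], x$network_id[["stage"]],
              length(x$genes), sum(x$adjacency) / 2, x$n_samples))
  invisible(x)
}

#' Count network edges with both endpoints in a gene set
#'
#' @param net a `coexpression_network`.
#' @param gene_set character vector of gene symbols; symbols absent from
#'   the network are recorded in the `missing` attribute, not an error.
#' @return integer edge count, with attribute `missing`.
#' @export
count_within_set_edges <- function(net, gene_set) {
  idx <- match(gene_set, net$genes)
  missing <- gene_set[is.na(idx)]
  idx <- idx[!is.na(idx)]
  n <- if (length(idx) >= 2) sum(net$adjacency[idx, idx]) / 2 else 0
  structure(as.integer(n), missing = missing)
}

# fast edge count on pre-extracted adjacency, used in the permutation loop
.edges_at <- function(adj, idx) sum(adj[idx, idx]) %/% 2L

# empirical p with the add-one correction: never 0, floor 1/(n+1);
# replicates tied with the observed count fall in the tail (conservative)
empirical_p <- function(obs, null_counts) {
  (1 + sum(null_counts >= obs)) / (1 + length(null_counts))
}

# genes with >= 1 edge in any temporal-parietal network
connected_in_temporal <- function(expr, cfg) {
  connected <- rep(FALSE, nrow(expr$values))
  for (stage in STAGE_GROUPS) {
    net <- build_network(expr, "temporal_parietal", stage, cfg)
    connected <- connected | rowSums(net$adjacency) > 0
  }
  rownames(expr$values)[connected]
}

#' Permutation enrichment of a gene set in one prebuilt network
#'
#' The single-network statistic behind [permutation_enrichment()]: counts
#' edges within `gene_set`, draws `cfg$n_replicates` equal-sized random
#' gene sets without replacement from `universe`, and returns the add-one
#' empirical p-value with a Bonferroni flag at `cfg$alpha / bonferroni_m`.
#' Useful when the same network is interrogated repeatedly (e.g. null
#' calibration) without rebuilding the other 11 cells.
#'
#' @param net a `coexpression_network` from [build_network()].
#' @param gene_set candidate gene symbols.
#' @param universe gene symbols to sample replicate sets from.
#' @param cfg an [enrichment_config()].
#' @param bonferroni_m number of tests the Bonferroni correction divides
#'   by (12 for the full region-by-stage grid).
#' @return an `enrichment_result` (see [permutation_enrichment()]).
#' @export
network_enrichment <- function(net, gene_set, universe,
                               cfg = enrichment_config(),
                               bonferroni_m = 12) {
  enrich_one_network(net, gene_set, universe, cfg, bonferroni_m)
}

# permutation test for one prebuilt network against a fixed universe
enrich_one_network <- function(net, gene_set, universe, cfg,
                               bonferroni_m) {
  obs <- count_within_set_edges(net, gene_set)
  k <- length(intersect(gene_set, universe))
  if (length(universe) < k) {
    stop("sampling universe smaller than the gene set", call. = FALSE)
  }
  uni_idx <- match(universe, net$genes)
  null_counts <- integer(cfg$n_replicates)
  for (b in seq_len(cfg$n_replicates)) {
    idx <- uni_idx[sample.int(length(uni_idx), k)]
    null_counts[b] <- .edges_at(net$adjacency, idx)
  }
  p <- empirical_p(as.integer(obs), null_counts)
  thr <- bonferroni_threshold(cfg$alpha, bonferroni_m)
  structure(list(network_id = net$network_id,
                 observed_edges = as.integer(obs),
                 set_size_used = k,
                 null_edge_counts = null_counts,
                 empirical_p = p,
                 bonferroni_threshold = thr,
                 significant_after_bonferroni = p <= thr,
                 missing_genes = attr(obs, "missing")),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("(%s, %s): E_obs = %d, empirical p = %.4g%s\n",
              x$network_id[[1]], x$network_id[[2]], x$observed_edges,
              x$empirical_p,
              if (x$significant_after_bonferroni) " *" else ""))
  invisible(x)
}

#' Permutation enrichment of a gene set across the 12 networks
#'
#' For each of the 12 (region, stage) networks: counts the edges within
#' `gene_set`, draws `cfg$n_replicates` random gene sets of equal size
#' without replacement from the universe, and reports the empirical
#' p-value `(1 + #\{null >= observed\}) / (1 + n_replicates)` together
#' with the Bonferroni flag at `alpha / 12`.
#'
#' @param expr an `expression_matrix`.
#' @param gene_set candidate gene symbols (>= 2).
#' @param cfg an [enrichment_config()].
#' @return named list of `enrichment_result`, one per network
#'   (`region.stage` names).
#' @export
permutation_enrichment <- function(expr, gene_set,
                                   cfg = enrichment_config()) {
  stopifnot(length(gene_set) >= 2)
  with_seed(cfg$seed, {
    universe <- rownames(expr$values)
    if (cfg$universe_mode == "connected_in_temporal") {
      universe <- connected_in_temporal(expr, cfg)
      gene_set <- intersect(gene_set, universe)
    }
    if (cfg$exclude_observed_set) {
      universe_draw <- setdiff(universe, gene_set)
    } else {
      universe_draw <- universe
    }
    cells <- expand.grid(region = REGION_GROUPS, stage = STAGE_GROUPS,
                         stringsAsFactors = FALSE)
    out <- vector("list", nrow(cells))
    names(out) <- paste(cells$region, cells$stage, sep = ".")
    for (i in seq_len(nrow(cells))) {
      net <- build_network(expr, cells$region[i], cells$stage[i], cfg)
      out[[i]] <- enrich_one_network(net, gene_set, universe_draw, cfg,
                                     bonferroni_m = nrow(cells))
    }
    out
  })
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha family-wise level.
#' @param n_networks number of networks (tests).
#' @return `alpha / n_networks` (0.05 over 12 networks gives 0.0042 at two
#'   significant figures).
#' @export
bonferroni_threshold <- function(alpha, n_networks) {
  stopifnot(n_networks >= 1)
  alpha / n_networks
}

#' Windowed embryonic enrichment by post-conception week
#'
#' Rebuilds the networks per (region, p.c.w. window) from fetal samples
#' whose `pcw` lies in the window, and applies the same edge-count
#' permutation statistic. Cells with fewer than 3 samples are skipped and
#' listed in the `skipped` attribute. The Bonferroni denominator is the
#' number of (region, window) tests actually performed.
#'
#' @param expr an `expression_matrix` whose fetal samples carry `pcw`.
#' @param gene_set candidate gene symbols (>= 2).
#' @param windows list of length-2 integer vectors `c(lo, hi)` (inclusive).
#' @param cfg an [enrichment_config()].
#' @return named list of `enrichment_result` (names `region.lo_hi`), with
#'   attribute `skipped` naming cells with too few samples.
#' @export
embryonic_window_enrichment <- function(expr, gene_set, windows,
                                        cfg = enrichment_config()) {
  stopifnot(length(gene_set) >= 2, length(windows) >= 1)
  meta <- expr$sample_meta
  cells <- list(); skipped <- character(0)
  for (region in REGION_GROUPS) {
    for (w in windows) {
      lab <- sprintf("%s.%d_%d", region, w[1], w[2])
      ids <- meta$sample_id[meta$stage_group == "fetal" &
                              !is.na(meta$pcw) &
                              meta$pcw >= w[1] & meta$pcw <= w[2] &
                              meta$region_group == region]
      if (length(ids) < 3) skipped <- c(skipped, lab)
      else cells[[lab]] <- ids
    }
  }
  with_seed(cfg$seed, {
    universe <- rownames(expr$values)
    if (cfg$universe_mode == "connected_in_temporal") {
      universe <- connected_in_temporal(expr, cfg)
      gene_set <- intersect(gene_set, universe)
    }
    out <- vector("list", length(cells))
    names(out) <- names(cells)
    for (lab in names(cells)) {
      region <- sub("\\..*$", "", lab)
      net <- build_network(expr, region, "fetal", cfg,
                           sample_ids = cells[[lab]])
      net$network_id <- c(region = region, window = sub("^.*\\.", "", lab))
      out[[lab]] <- enrich_one_network(net, gene_set, universe, cfg,
                                       bonferroni_m = length(cells))
    }
    structure(out, skipped = skipped)
  })
}
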