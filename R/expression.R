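# Synthetic brain expression matrices: 4 region groups x 3 stage groups,
# log-scale continuous values (latent factor + Gaussian noise). A planted
# module of genes shares a latent factor in designated (region, stage) cells,
# giving expected pairwise Pearson correlation rho = v / (v + noise_sd^2)
# where v is the latent-factor variance.

REGION_GROUPS <- c("frontal_cortex", "temporal_parietal", "sensory_motor",
                   "sub_cortical")
STAGE_GROUPS  <- c("fetal", "infancy_to_late_childhood",
                   "adolescence_to_adulthood")

#' Configuration for a synthetic expression matrix
#'
#' @param n_genes number of genes (rows).
#' @param samples_per_cell samples per (region, stage) cell; must be >= 3
#'   for correlations to be defined.
#' @param planted_module_genes gene symbols of the planted co-expression
#'   module (must be a subset of the generated gene universe; `character(0)`
#'   plants nothing).
#' @param module_correlation target pairwise Pearson correlation of the
#'   module genes inside the planted cells, in (0, 1).
#' @param planted_cells data.frame with columns `region_group`,
#'   `stage_group` naming the cells that carry the module signal; default is
#'   the single cell (frontal_cortex, fetal).
#' @param noise_sd residual standard deviation of the log-scale expression
#'   model.
#' @param pcw_range integer interval (length 2) from which fetal samples'
#'   post-conception weeks are drawn uniformly.
#' @param seed integer seed.
#' @return a list of class `"synthetic_expression_config"`.
#' @export
synthetic_expression_config <- function(n_genes = 300,
                                        samples_per_cell = 20,
                                        planted_module_genes = character(0),
                                        module_correlation = 0.95,
                                        planted_cells = data.frame(
                                          region_group = "frontal_cortex",
                                          stage_group = "fetal"),
                                        noise_sd = 1,
                                        pcw_range = c(8L, 37L),
                                        seed = 1) {
  stopifnot(module_correlation > 0, module_correlation < 1, noise_sd > 0,
            length(pcw_range) == 2, pcw_range[1] <= pcw_range[2])
  if (samples_per_cell < 3) {
    stop("samples_per_cell must be >= 3 (pairwise correlation is ",
         "degenerate below that)", call. = FALSE)
  }
  stopifnot(all(planted_cells$region_group %in% REGION_GROUPS),
            all(planted_cells$stage_group %in% STAGE_GROUPS))
  structure(as.list(environment()),
            class = "synthetic_expression_config")
}

#' Simulate a genes-x-samples expression matrix with a planted module
#'
#' Samples are laid out as 4 region groups x 3 stage groups (12 cells) with
#' `samples_per_cell` samples each. In the designated planted cells, module
#' genes load on a shared per-sample latent factor with variance
#' `v = rho * noise_sd^2 / (1 - rho)`, so their expected pairwise Pearson
#' correlation is `rho = module_correlation`; everywhere else (and for all
#' non-module genes) values are independent Gaussian noise with the same
#' marginal variance `v + noise_sd^2`. Fetal samples carry a post-conception
#' week drawn uniformly from `pcw_range`; other samples have `pcw = NA`.
#'
#' @param cfg a [synthetic_expression_config()].
#' @return an object of class `"expression_matrix"`: list with `values`
#'   (genes x samples numeric matrix) and `sample_meta` (data.frame with
#'   `sample_id`, `region_group`, `stage_group`, `pcw`).
#' @export
simulate_expression <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (length(cfg$planted_module_genes)) {
    # planted symbols take the leading slots of the gene universe
    genes[seq_along(cfg$planted_module_genes)] <- cfg$planted_module_genes
  }
  if (!all(cfg$planted_module_genes %in% genes)) {
    stop("planted_module_genes must lie in the gene universe", call. = FALSE)
  }
  cells <- expand.grid(region_group = REGION_GROUPS,
                       stage_group = STAGE_GROUPS,
                       stringsAsFactors = FALSE)
  n_samp <- nrow(cells) * cfg$samples_per_cell
  meta <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samp)),
    region_group = rep(cells$region_group, each = cfg$samples_per_cell),
    stage_group = rep(cells$stage_group, each = cfg$samples_per_cell),
    pcw = NA_integer_, stringsAsFactors = FALSE)

  rho <- cfg$module_correlation
  v <- rho * cfg$noise_sd^2 / (1 - rho)   # latent factor variance
  sd_tot <- sqrt(v + cfg$noise_sd^2)      # marginal sd, homogeneous

  with_seed(cfg$seed, {
    fetal <- meta$stage_group == "fetal"
    meta$pcw[fetal] <- sample(seq(cfg$pcw_range[1], cfg$pcw_range[2]),
                              sum(fetal), replace = TRUE)
    vals <- matrix(stats::rnorm(cfg$n_genes * n_samp, sd = sd_tot),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, meta$sample_id))
    if (length(cfg$planted_module_genes) >= 2) {
      planted_samp <- rep(FALSE, n_samp)
      for (i in seq_len(nrow(cfg$planted_cells))) {
        planted_samp <- planted_samp |
          (meta$region_group == cfg$planted_cells$region_group[i] &
             meta$stage_group == cfg$planted_cells$stage_group[i])
      }
      k <- sum(planted_samp)
      f <- stats::rnorm(k, sd = sqrt(v))
      eps <- matrix(stats::rnorm(length(cfg$planted_module_genes) * k,
                                 sd = cfg$noise_sd),
                    nrow = length(cfg$planted_module_genes))
      vals[cfg$planted_module_genes, planted_samp] <-
        sweep(eps, 2, f, "+")
    }
    structure(list(values = vals, sample_meta = meta),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d cells)\n",
              nrow(x$values), ncol(x$values),
              nrow(unique(x$sample_meta[, c("region_group",
                                            "stage_group")]))))
  invisible(x)
}

#' Write an expression matrix and its sample metadata as TSV
#'
#' @param expr an `expression_matrix`.
#' @param values_path path for the genes-in-rows expression TSV.
#' @param meta_path path for the sample-metadata TSV
#'   (`sample_id`, `region_group`, `stage_group`, `pcw`).
#' @return `values_path`, invisibly.
#' @export
write_expression_tsv <- function(expr, values_path, meta_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#' @param values_path expression TSV (genes in rows, first column `gene`).
#' @param meta_path sample metadata TSV.
#' @return an `expression_matrix`.
#' @export
read_expression_tsv <- function(values_path, meta_path) {
  df <- utils::read.delim(values_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta$pcw <- as.integer(meta$pcw)
  if (!identical(colnames(vals), meta$sample_id)) {
    stop("expression columns and sample metadata disagree", call. = FALSE)
  }
  structure(list(values = vals, sample_meta = meta),
            class = "expression_matrix")
}
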