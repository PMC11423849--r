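# In-code fixtures used across the suite.

toy_series <- function() list(OC = c("S1", "S2"), GC = c("S1", "S2"))

# 3 genes x 4 samples: OC at two stages, 2 replicates each
toy_expr <- function(values = NULL) {
  meta <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                     cell_type = "OC",
                     stage = rep(c("S1", "S2"), each = 2),
                     replicate = c(1, 2, 1, 2))
  if (is.null(values))
    values <- matrix(c(1, 2, 3, 4,
                       10, 10, 0, 0,
                       0.2, 0.9, 0.5, 0.4), nrow = 3, byrow = TRUE,
                     dimnames = list(c("g1", "g2", "g3"), meta$sample_id))
  expression_matrix(values, meta, toy_series())
}

# expression matrix with explicit per-group replicate values for one cell type
group_expr <- function(groups, reps_per_stage, series_name = "OC") {
  # groups: named list stage -> genes x reps matrix
  stages <- names(groups)
  n_genes <- nrow(groups[[1]])
  genes <- rownames(groups[[1]]) %||% sprintf("g%02d", seq_len(n_genes))
  meta <- do.call(rbind, lapply(stages, function(s)
    data.frame(sample_id = paste0(series_name, "_", s, "_", seq_len(ncol(groups[[s]]))),
               cell_type = series_name, stage = s,
               replicate = seq_len(ncol(groups[[s]])))))
  vals <- do.call(cbind, groups)
  dimnames(vals) <- list(genes, meta$sample_id)
  series <- stats::setNames(list(stages), series_name)
  expression_matrix(vals, meta, series)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# separable four-shape log-profile mixture for clustering tests
four_shape_profiles <- function(n_per = 25, sd = 0.1, seed = 42, n_stages = 12) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n_stages)
  shapes <- list(up = 5 * t,
                 down = 5 * (1 - t),
                 peak = 5 * (1 - abs(2 * t - 1)),
                 valley = 5 * abs(2 * t - 1))
  m <- do.call(rbind, lapply(shapes, function(s)
    matrix(rep(s, n_per), nrow = n_per, byrow = TRUE) +
      matrix(rnorm(n_per * n_stages, 0, sd), n_per)))
  labels <- rep(names(shapes), each = n_per)
  rownames(m) <- sprintf("%s_%02d", labels, sequence(rep(n_per, 4)))
  fpkm <- pmax(2^m - 1, 0)
  colnames(fpkm) <- paste0("st", seq_len(n_stages))
  list(fpkm = fpkm, labels = stats::setNames(labels, rownames(m)))
}

# random gene sets over a small universe
rand_gene_sets <- function(seed, k = 3, universe = sprintf("g%02d", 1:20)) {
  set.seed(seed)
  lapply(stats::setNames(seq_len(k), paste0("set", seq_len(k))), function(i)
    sample(universe, sample(0:length(universe), 1)))
}

# random ligand-receptor instance: db of <= 30 pairs, 3 cell types
rand_lr_instance <- function(seed, n_pairs = 30, n_genes = 25) {
  set.seed(seed)
  genes <- sprintf("q%02d", seq_len(n_genes))
  db <- lr_database(sample(genes, n_pairs, replace = TRUE),
                    sample(genes, n_pairs, replace = TRUE))
  expressed <- lapply(stats::setNames(nm = c("OC", "GC", "CC")), function(ct)
    sample(genes, sample(0:n_genes, 1)))
  list(db = db, expressed = expressed)
}
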