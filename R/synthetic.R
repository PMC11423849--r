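## Deterministic synthetic-data generator with planted ground truth.
##
## Expression is generated on the analysis scale: each (gene, cell type,
## stage) has a signal value x on log2(FPKM + 1), replicates add Gaussian
## noise on that scale, and FPKM = max(2^x - 1, 0). Planted effects are
## therefore exact log2 offsets on the scale the pipeline tests on.

#' Synthetic-dataset configuration
#'
#' Defaults describe the study conditions the generator emulates: a
#' replicated multi-stage, multi-cell-type FPKM matrix with a burst of
#' differential expression planted between stages T3b and T4 (the
#' secondary-follicle transition), optional planted temporal profile
#' classes, and imprinted genes silent in oocytes but expressed in
#' granulosa cells.
#'
#' @param seed RNG seed; fully determines every generated dataset.
#' @param stage_series Stage series per cell type.
#' @param replicates Replicates per (cell type, stage) group.
#' @param n_genes Number of background genes.
#' @param base_log2_mean,base_log2_sd Baseline per-gene expression level
#'   distribution on the log2(FPKM + 1) scale.
#' @param noise_sd Replicate noise sd on the log2 scale.
#' @param planted_deg Data frame `cell_type`, `stage`, `n`, `log2fc`: `n`
#'   genes get a `log2fc` offset in `cell_type` from `stage` onward, so the
#'   adjacent comparison ending at `stage` carries the planted change.
#' @param planted_profiles Named counts over `CONT_UP`, `CONT_DOWN`,
#'   `FLUCTUATING`, `FLAT` temporal classes, planted in
#'   `profile_cell_type`.
#' @param profile_cell_type Cell type carrying the planted temporal
#'   classes.
#' @param profile_step Per-transition log2 step of the planted monotone
#'   profiles.
#' @param planted_imprinted Number of genes silent (FPKM < 1) at every
#'   oocyte stage but highly expressed in the somatic cell types.
#' @param planted_lr Data frame `cell_type`, `category`, `n` of planted
#'   ligand categories per cell type for [generate_lr_db()].
#' @param lr_cc_subset Construct cumulus (CC) dialogs so that every OC-CC
#'   pair is also an OC-GC pair (shared receptors expressed in both GC and
#'   CC); restricts CC's own heterologous/hybrid partners to GC.
#' @param n_cc_shared Number of OC-ligand pairs whose receptor is expressed
#'   in both GC and CC under `lr_cc_subset`.
#' @param embryo_stages Stage labels of the embryo series (reference
#'   first).
#' @param n_embryo_genes,planted_maternal Embryo-series size and number of
#'   planted maternal-effect genes.
#' @param decay_stage Stage at which planted maternal transcripts drop
#'   below half of the reference.
#' @param n_meth_genes Genes in the methylation annotation.
#' @param meth_window Promoter half-width used when placing CpGs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         stage_series = default_stage_series(),
                         replicates = 3,
                         n_genes = 200,
                         base_log2_mean = 3,
                         base_log2_sd = 1.5,
                         noise_sd = 0.1,
                         planted_deg = data.frame(
                           cell_type = c("OC", "OC", "GC", "GC"),
                           stage = "T4",
                           n = c(10, 10, 10, 10),
                           log2fc = c(2, -2, 2, -2)),
                         planted_profiles = c(CONT_UP = 0, CONT_DOWN = 0,
                                              FLUCTUATING = 0, FLAT = 0),
                         profile_cell_type = "OC",
                         profile_step = 1,
                         planted_imprinted = 10,
                         planted_lr = data.frame(
                           cell_type = rep(c("OC", "GC", "CC"), each = 4),
                           category = rep(c("HOMOLOGOUS", "HETEROLOGOUS",
                                            "HYBRID", "NONE"), 3),
                           n = 5),
                         lr_cc_subset = TRUE,
                         n_cc_shared = 3,
                         embryo_stages = c("MII", "zygote", "2cell", "4cell",
                                           "8cell", "morula"),
                         n_embryo_genes = 100,
                         planted_maternal = 30,
                         decay_stage = "2cell",
                         n_meth_genes = 20,
                         meth_window = 1000) {
  cfg <- list(seed = seed, stage_series = stage_series, replicates = replicates,
              n_genes = n_genes, base_log2_mean = base_log2_mean,
              base_log2_sd = base_log2_sd, noise_sd = noise_sd,
              planted_deg = planted_deg, planted_profiles = planted_profiles,
              profile_cell_type = profile_cell_type, profile_step = profile_step,
              planted_imprinted = planted_imprinted, planted_lr = planted_lr,
              lr_cc_subset = lr_cc_subset, n_cc_shared = n_cc_shared,
              embryo_stages = embryo_stages, n_embryo_genes = n_embryo_genes,
              planted_maternal = planted_maternal, decay_stage = decay_stage,
              n_meth_genes = n_meth_genes, meth_window = meth_window)
  n_special <- sum(planted_deg$n) + sum(planted_profiles) + planted_imprinted
  if (n_special > n_genes)
    stop("planted structures need ", n_special, " genes but n_genes = ", n_genes)
  if (!is.null(decay_stage) && !decay_stage %in% embryo_stages[-1])
    stop("decay_stage must be one of the later embryo stages")
  structure(cfg, class = "synth_config")
}

## deterministic down-up-down template over n transitions
fluct_template <- function(n_trans, step) {
  third <- max(1, floor(n_trans / 3))
  d <- rep(-step, n_trans)
  d[(third + 1):min(2 * third, n_trans)] <- step
  d
}

#' Generate a synthetic expression matrix with planted truth
#'
#' @param config A [synth_config()].
#' @return List with `matrix` (an `expr_matrix`) and `truth` (planted DEG
#'   genes per cell type with direction, temporal-class gene lists,
#'   imprinted genes, and the config echo).
#' @export
generate_expression <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  cells <- names(config$stage_series)

  ## carve out disjoint planted roles
  cursor <- 0
  take <- function(k) {
    if (k == 0) return(character())
    out <- genes[(cursor + 1):(cursor + k)]
    cursor <<- cursor + k
    out
  }
  deg_genes <- list(); deg_dir <- list()
  pd <- config$planted_deg
  if (!is.null(pd) && nrow(pd)) {
    for (i in seq_len(nrow(pd))) {
      g <- take(pd$n[i])
      key <- pd$cell_type[i]
      deg_genes[[key]] <- c(deg_genes[[key]], g)
      deg_dir[[key]] <- c(deg_dir[[key]],
                          stats::setNames(rep(ifelse(pd$log2fc[i] > 0, "UP", "DOWN"),
                                              length(g)), g))
    }
  }
  prof_genes <- lapply(config$planted_profiles, function(k) take(k))
  imprinted <- take(config$planted_imprinted)

  ## baseline level per gene; planted DEG genes get a floor of 2 on the
  ## log2 scale so the down-shifted group never collapses to zero FPKM
  base <- stats::rnorm(n, config$base_log2_mean, config$base_log2_sd)
  names(base) <- genes
  special_deg <- unlist(deg_genes)
  base[special_deg] <- pmax(base[special_deg], 2)
  base[imprinted] <- pmax(base[imprinted], 3)
  base <- pmax(base, 0.1)

  ## signal per (gene, cell, stage) on the log2(FPKM+1) scale
  signal <- list()
  for (ct in cells) {
    stages <- config$stage_series[[ct]]
    sig <- matrix(base, nrow = n, ncol = length(stages),
                  dimnames = list(genes, stages))
    if (!is.null(pd) && nrow(pd)) {
      idx <- 0
      for (i in seq_len(nrow(pd))) {
        g <- genes[(idx + 1):(idx + pd$n[i])]; idx <- idx + pd$n[i]
        if (pd$cell_type[i] != ct) next
        k <- match(pd$stage[i], stages)
        if (is.na(k)) next
        sig[g, k:length(stages)] <- sig[g, k:length(stages)] + pd$log2fc[i]
      }
    }
    if (ct == config$profile_cell_type) {
      n_trans <- length(stages) - 1
      templates <- list(
        CONT_UP = rep(config$profile_step, n_trans),
        CONT_DOWN = rep(-config$profile_step, n_trans),
        FLUCTUATING = fluct_template(n_trans, config$profile_step),
        FLAT = rep(0, n_trans))
      for (cl in names(templates)) {
        g <- prof_genes[[cl]]
        if (!length(g)) next
        vals <- cumsum(c(0, templates[[cl]]))
        start <- abs(min(vals)) + 1            # keep the whole track above 0
        sig[g, ] <- matrix(start + vals, nrow = length(g),
                           ncol = length(stages), byrow = TRUE)
      }
    }
    if (length(imprinted)) {
      if (ct == "OC") sig[imprinted, ] <- 0.1   # FPKM ~0.07: silent
      else sig[imprinted, ] <- matrix(base[imprinted], nrow = length(imprinted),
                                      ncol = length(stages))
    }
    sig <- pmax(sig, 0)
    signal[[ct]] <- sig
  }

  ## samples: noise on the log2 scale per replicate
  meta <- do.call(rbind, lapply(cells, function(ct) {
    expand.grid(cell_type = ct, stage = config$stage_series[[ct]],
                replicate = seq_len(config$replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  meta$sample_id <- paste(meta$cell_type, meta$stage, meta$replicate, sep = "_")
  meta <- meta[, c("sample_id", "cell_type", "stage", "replicate")]
  vals <- matrix(0, nrow = n, ncol = nrow(meta),
                 dimnames = list(genes, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    x <- signal[[meta$cell_type[j]]][, meta$stage[j]]
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
    vals[, j] <- pmax(2^pmax(x, 0) - 1, 0)
  }
  truth <- list(deg = deg_genes, deg_direction = deg_dir,
                profiles = prof_genes, imprinted = imprinted,
                config = config)
  list(matrix = expression_matrix(vals, meta, config$stage_series),
       truth = truth)
}

#' Generate a ligand-receptor database with planted categories
#'
#' Builds pairs and per-cell-type expression profiles so that
#' [classify_pair_genes()] must return the planted category for every
#' designated ligand gene. Heterologous and hybrid partners live in the
#' next cell type of the series (for CC under `lr_cc_subset`, in GC).
#' Under `lr_cc_subset`, `n_cc_shared` extra OC-ligand pairs get receptors
#' expressed in both GC and CC, making the OC-CC dialog pair set a strict
#' subset of the OC-GC set.
#'
#' @param config A [synth_config()].
#' @return List with `db` (an `lr_db`), `profiles` (named list of
#'   `stage_profiles` per cell type), `expressed` (named gene-set list at
#'   threshold 5), and `truth` (data frame `gene`, `role`, `cell_type`,
#'   `category` for every planted gene).
#' @export
generate_lr_db <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cells <- unique(config$planted_lr$cell_type)
  partner_of <- function(ct) {
    if (config$lr_cc_subset && ct == "CC") return("GC")
    setdiff(cells, ct)[1]
  }
  pairs <- list(); truth <- list()
  expressed <- stats::setNames(vector("list", length(cells)), cells)
  gene_counter <- 0
  new_gene <- function(prefix) {
    gene_counter <<- gene_counter + 1
    sprintf("%s%03d", prefix, gene_counter)
  }
  add_truth <- function(gene, role, ct, cat)
    truth[[length(truth) + 1L]] <<- data.frame(gene = gene, role = role,
                                               cell_type = ct, category = cat)
  express <- function(gene, ct) expressed[[ct]] <<- c(expressed[[ct]], gene)
  add_pair <- function(l, r) pairs[[length(pairs) + 1L]] <<- c(l, r)

  plr <- config$planted_lr
  for (i in seq_len(nrow(plr))) {
    ct <- plr$cell_type[i]; cat <- plr$category[i]
    for (k in seq_len(plr$n[i])) {
      L <- new_gene("Lig"); R <- new_gene("Rec")
      if (cat == "HOMOLOGOUS") {
        express(L, ct); express(R, ct); add_pair(L, R)
        add_truth(L, "LIGAND", ct, "HOMOLOGOUS")
        add_truth(R, "RECEPTOR", ct, "HOMOLOGOUS")
      } else if (cat == "HETEROLOGOUS") {
        t2 <- partner_of(ct)
        express(L, ct); express(R, t2); add_pair(L, R)
        add_truth(L, "LIGAND", ct, "HETEROLOGOUS")
        add_truth(R, "RECEPTOR", t2, "HETEROLOGOUS")
      } else if (cat == "HYBRID") {
        t2 <- partner_of(ct)
        R2 <- new_gene("Rec")
        express(L, ct); express(R, ct); express(R2, t2)
        add_pair(L, R); add_pair(L, R2)
        add_truth(L, "LIGAND", ct, "HYBRID")
        add_truth(R, "RECEPTOR", ct, "HOMOLOGOUS")
        add_truth(R2, "RECEPTOR", t2, "HETEROLOGOUS")
      } else if (cat == "NONE") {
        express(L, ct); add_pair(L, R)   # receptor expressed nowhere
        add_truth(L, "LIGAND", ct, "NONE")
      } else stop("unknown planted category: ", cat)
    }
  }
  if (config$lr_cc_subset && all(c("OC", "GC", "CC") %in% cells)) {
    for (k in seq_len(config$n_cc_shared)) {
      L <- new_gene("Lig"); R <- new_gene("Rec")
      express(L, "OC"); express(R, "GC"); express(R, "CC")
      add_pair(L, R)
      add_truth(L, "LIGAND", "OC", "HETEROLOGOUS")
      add_truth(R, "RECEPTOR", "GC", "HETEROLOGOUS")
      add_truth(R, "RECEPTOR", "CC", "HETEROLOGOUS")
    }
  }
  if (!length(pairs)) stop("planted_lr requests no pairs; nothing to generate")
  pm <- do.call(rbind, pairs)
  db <- lr_database(pm[, 1], pm[, 2])
  all_genes <- sort(unique(c(db$ligand, db$receptor)))
  profiles <- list()
  for (ct in cells) {
    stages <- config$stage_series[[ct]]
    m <- matrix(0.5, nrow = length(all_genes), ncol = length(stages),
                dimnames = list(all_genes, stages))
    on_genes <- unique(expressed[[ct]])
    if (length(on_genes)) m[on_genes, ] <- 10   # constant: expressed, DEG-neutral
    profiles[[ct]] <- stage_profiles(m, ct, stages)
  }
  list(db = db, profiles = profiles,
       expressed = lapply(profiles, expressed_genes, threshold = 5),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Generate an embryo expression series with planted maternal-effect genes
#'
#' Planted genes have reference (MII) FPKM well above 2 and drop below
#' one-tenth to one-third of the reference from the configured decay stage;
#' non-planted genes violate exactly one rule by construction: half have a
#' low reference (FPKM < 1.5) and half stay at or above 80% of the
#' reference at every later stage. Multiplicative log-normal noise of sd
#' `noise_sd` is applied to every value; at `noise_sd = 0` the flags are
#' exact by construction.
#'
#' @param config A [synth_config()].
#' @return List with `series` (an `embryo_series`) and `truth` (character
#'   vector of planted maternal-effect genes).
#' @export
generate_embryo_series <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n <- config$n_embryo_genes
  stages <- config$embryo_stages
  genes <- sprintf("E%04d", seq_len(n))
  n_mat <- config$planted_maternal
  if (n_mat > n) stop("planted_maternal exceeds n_embryo_genes")
  decay_idx <- match(config$decay_stage, stages)
  m <- matrix(0, n, length(stages), dimnames = list(genes, stages))
  is_mat <- seq_len(n) <= n_mat
  ref <- numeric(n)
  ref[is_mat] <- stats::runif(n_mat, 5, 100)
  rest <- which(!is_mat)
  low_ref <- rest[seq_along(rest) %% 2 == 1]
  stable <- setdiff(rest, low_ref)
  ref[low_ref] <- stats::runif(length(low_ref), 0, 1.5)
  ref[stable] <- stats::runif(length(stable), 5, 100)
  m[, 1] <- ref
  for (j in 2:length(stages)) {
    fac <- numeric(n)
    fac[is_mat] <- if (j >= decay_idx) stats::runif(n_mat, 0.05, 0.3)
                   else stats::runif(n_mat, 0.8, 1.2)
    fac[low_ref] <- stats::runif(length(low_ref), 0.2, 1.2)
    fac[stable] <- stats::runif(length(stable), 0.8, 1.2)
    m[, j] <- ref * fac
  }
  if (config$noise_sd > 0)
    m <- m * 2^stats::rnorm(length(m), 0, config$noise_sd)
  list(series = embryo_series(m, stages), truth = genes[is_mat])
}

#' Generate CpG methylation records with known promoter means
#'
#' Genes are laid out 10 kb apart on one chromosome so promoter windows
#' never overlap. Each gene gets 0--5 CpGs inside its +/- `meth_window`
#' promoter and 2 outside; the truth records each gene's exact in-window
#' mean (`NA` when no CpG falls inside).
#'
#' @param config A [synth_config()].
#' @return List with `cpgs` (data frame `chrom`, `position`, `level`),
#'   `annotation` (`gene`, `chrom`, `tss`, `strand`), and `truth`
#'   (data frame `gene`, `mean`, `n_cpgs`).
#' @export
generate_methylation <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  n <- config$n_meth_genes
  w <- config$meth_window
  annotation <- data.frame(gene = sprintf("M%03d", seq_len(n)),
                           chrom = "chr1",
                           tss = 5000 + (seq_len(n) - 1) * 10000,
                           strand = rep(c("+", "-"), length.out = n))
  cpgs <- list(); truth <- list()
  for (i in seq_len(n)) {
    tss <- annotation$tss[i]
    k_in <- sample(0:5, 1)
    inside <- if (k_in > 0)
      data.frame(chrom = "chr1",
                 position = tss + sample(seq(-w, w), k_in),
                 level = round(stats::runif(k_in), 3))
    outside <- data.frame(chrom = "chr1",
                          position = c(tss - w - sample(100:2000, 1),
                                       tss + w + sample(100:2000, 1)),
                          level = round(stats::runif(2), 3))
    cpgs[[i]] <- rbind(if (k_in > 0) inside, outside)
    truth[[i]] <- data.frame(gene = annotation$gene[i],
                             mean = if (k_in > 0) mean(inside$level) else NA_real_,
                             n_cpgs = k_in)
  }
  cpgs <- do.call(rbind, c(cpgs, make.row.names = FALSE))
  cpgs <- cpgs[order(cpgs$position), ]
  rownames(cpgs) <- NULL
  list(cpgs = cpgs, annotation = annotation,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits every standard file the pipeline consumes (expression + metadata
#' TSVs, ligand-receptor DB, embryo series, CpG and annotation TSVs) plus
#' `truth.json` with the planted ground truth.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly; the generated objects as attribute
#'   `"data"`.
#' @export
write_synthetic_dataset <- function(config = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- generate_expression(config)
  lr <- generate_lr_db(config)
  emb <- generate_embryo_series(config)
  met <- generate_methylation(config)
  ## fold the ligand-receptor genes into the expression matrix so the
  ## written dataset alone reproduces the planted dialog structure;
  ## their expression is replicate-constant, so the DEG scans are untouched
  meta <- expr$matrix$meta
  lr_genes <- rownames(lr$profiles[[1]]$profiles)
  lr_vals <- matrix(0.5, nrow = length(lr_genes), ncol = nrow(meta),
                    dimnames = list(lr_genes, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    p <- lr$profiles[[meta$cell_type[j]]]
    if (!is.null(p)) lr_vals[, j] <- p$profiles[lr_genes, meta$stage[j]]
  }
  full <- expression_matrix(rbind(expr$matrix$values, lr_vals), meta,
                            config$stage_series)
  write_expression_table(full,
                         file.path(dir, "expression.tsv"),
                         file.path(dir, "metadata.tsv"))
  write_lr_database(lr$db, file.path(dir, "lr_pairs.tsv"))
  emb_df <- data.frame(gene = rownames(emb$series$profiles),
                       emb$series$profiles, check.names = FALSE)
  write_tsv_file(emb_df, file.path(dir, "embryo.tsv"))
  write_tsv_file(met$cpgs, file.path(dir, "cpgs.tsv"))
  write_tsv_file(met$annotation, file.path(dir, "annotation.tsv"))
  truth <- list(deg = expr$truth$deg,
                deg_direction = expr$truth$deg_direction,
                profiles = expr$truth$profiles,
                imprinted = expr$truth$imprinted,
                lr_categories = lr$truth,
                maternal = emb$truth,
                methylation = met$truth,
                seed = config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  out <- dir
  attr(out, "data") <- list(expression = expr, lr = lr, embryo = emb,
                            methylation = met)
  invisible(out)
}
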