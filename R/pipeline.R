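## End-to-end orchestration: a single (YAML-serializable) run
## configuration drives filter -> replicate averaging -> DEG scans ->
## stage-specific / inheritance -> temporal clustering -> dialogs ->
## maternal/imprint -> methylation, writing deterministic TSV reports that
## all carry the config hash.

#' Default run configuration
#'
#' Every threshold echoes the pipeline default when unset: FPKM filter 1,
#' fold-change rule 2 / 0.5 at p < 0.05, dialog expression threshold
#' 5 FPKM, maternal rule reference > 2 with ratio < 0.5, SILENT/MILD/HIGH
#' cut points 1 and 5 FPKM, promoter window 1000 bp, pivot stage T4.
#'
#' @param ... Overrides, e.g. `expression = "expr.tsv"`,
#'   `outdir = "out"`, `n_perm = 200`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    expression = NULL, metadata = NULL, lr_db = NULL, embryo = NULL,
    cpgs = NULL, annotation = NULL, outdir = NULL,
    stage_series = default_stage_series(),
    min_fpkm = 1, fc_up = 2, fc_down = 0.5, alpha = 0.05, pseudocount = 0.01,
    lr_threshold = 5,
    maternal_ref_min = 2, maternal_ratio = 0.5,
    silent_max = 1, high_min = 5,
    promoter_window = 1000,
    pivot_stage = "T4",
    profile_c = 2, profile_m = 50, n_perm = 500,
    cluster_seed = 1, kmeans_seed = 1, maternal_k = 4)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file of `run_config` fields.
#' @return A `run_config` with defaults filled in for unset fields.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

## hash of the analytic configuration; the output location is excluded so
## identical analyses hash identically wherever they are written
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes every stage the inputs allow: expression filtering and
#' replicate averaging always; adjacent-stage and cross-cell-type DEG
#' scans with stage-specific, pivot-split and inheritance summaries;
#' temporal profile clustering per cell type with more than two stages;
#' dialog inference when a ligand-receptor DB is given; maternal-effect
#' identification and clustering when an embryo series is given; promoter
#' methylation when CpG + annotation files are given. All reports are
#' written under `outdir`, each carrying the config hash; the config
#' itself is serialized verbatim into the output directory. A stage
#' failure aborts with the stage name.
#'
#' @param config A [run_config()], a list of fields, or a YAML path.
#' @return Invisibly, a list of in-memory stage results (`matrix`,
#'   `profiles`, `adjacent`, `cross`, `clusters`, `dialogs`, `maternal`,
#'   `methylation`, `outdir`, `config_hash`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.null(config$outdir)) stop("config must set `outdir`")
  if (is.null(config$expression) || is.null(config$metadata))
    stop("config must set `expression` and `metadata` paths")
  for (f in c("expression", "metadata", "lr_db", "embryo", "cpgs", "annotation"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("input file for `", f, "` not found: ", config[[f]])

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- paste0("config_hash: ", hash)
  logfile <- file.path(outdir, "run.log")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon))
  logmsg <- function(...) writeLines(paste0(...), logcon)
  logmsg("config_hash: ", hash)
  yaml::write_yaml(unclass(config), file.path(outdir, "config_echo.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list(outdir = outdir, config_hash = hash)

  ## --- expression I/O, filter, averaging -------------------------------
  res$matrix <- stage("expression_io", {
    m <- read_expression_table(config$expression, config$metadata,
                               config$stage_series)
    logmsg("read ", nrow(m$values), " genes x ", ncol(m$values), " samples")
    f <- filter_low_expression(m, config$min_fpkm)
    logmsg("FPKM < ", config$min_fpkm, " filter removed ",
           nrow(m$values) - nrow(f$values), " genes; ", nrow(f$values), " kept")
    f
  })
  cells <- intersect(names(config$stage_series), unique(res$matrix$meta$cell_type))
  res$profiles <- stage("average_replicates", {
    p <- lapply(cells, function(ct) average_replicates(res$matrix, ct))
    names(p) <- cells
    p
  })

  ## --- DEG dynamics ----------------------------------------------------
  res$adjacent <- stage("deg_adjacent", {
    scans <- lapply(cells[vapply(config$stage_series[cells], length, 0L) >= 2],
                    function(ct) adjacent_stage_scan(
                      res$matrix, ct, pseudocount = config$pseudocount,
                      fc_up = config$fc_up, fc_down = config$fc_down,
                      alpha = config$alpha))
    names(scans) <- cells[vapply(config$stage_series[cells], length, 0L) >= 2]
    for (ct in names(scans)) {
      write_deg_reports(scans[[ct]], file.path(outdir, "deg"),
                        prefix = paste0("adjacent_", ct), header_lines = hdr)
      for (nm in names(scans[[ct]]))
        if (isTRUE(attr(scans[[ct]][[nm]], "single_replicate")))
          logmsg("single-replicate group in ", nm, "; p := 0, FC rule decides")
    }
    scans
  })
  res$stage_specific <- stage("stage_specific", {
    out <- list()
    for (ct in names(res$adjacent)) {
      scan <- res$adjacent[[ct]]
      hit <- grep(paste0(":", config$pivot_stage, "_vs_"), names(scan), value = TRUE)
      if (!length(hit)) next
      spec <- stage_specific_degs(scan, hit[1])
      split <- split_by_pivot(spec, res$profiles[[ct]], config$pivot_stage)
      logmsg(ct, ": ", length(spec), " pivot-specific DEGs (",
             length(split$before), " before / ", length(split$onward), " onward)")
      out[[ct]] <- list(genes = spec, split = split)
      write_tsv_file(data.frame(gene = spec,
                                side = ifelse(spec %in% split$before,
                                              "before", "onward")),
                     file.path(outdir, paste0("stage_specific_", ct, ".tsv")), hdr)
    }
    out
  })
  res$cross <- stage("deg_cross", {
    if (all(c("OC", "GC") %in% cells)) {
      scan <- cross_celltype_scan(res$matrix, "GC", "OC",
                                  pseudocount = config$pseudocount,
                                  fc_up = config$fc_up, fc_down = config$fc_down,
                                  alpha = config$alpha)
      write_deg_reports(scan, file.path(outdir, "deg"),
                        prefix = "cross_GC_vs_OC", header_lines = hdr)
      ref <- grep(paste0(":", config$pivot_stage, "$"), names(scan), value = TRUE)
      inh <- if (length(ref)) inheritance_analysis(scan, ref[1])
      if (!is.null(inh))
        write_tsv_file(inh$summary, file.path(outdir, "inheritance_GC_vs_OC.tsv"), hdr)
      list(scan = scan, inheritance = inh)
    }
  })

  ## --- temporal clustering ---------------------------------------------
  res$clusters <- stage("temporal_clustering", {
    out <- list()
    for (ct in cells) {
      if (length(config$stage_series[[ct]]) < 3) next
      cl <- cluster_timeseries(res$profiles[[ct]],
                               c = config$profile_c, m = config$profile_m,
                               n_perm = config$n_perm, alpha = config$alpha,
                               seed = config$cluster_seed)
      logmsg(ct, ": ", sum(cl$profile_table$significant),
             " significant profiles; ", length(cl$excluded),
             " zero-variance genes excluded")
      write_cluster_reports(cl, file.path(outdir, "clusters"),
                            prefix = paste0("cluster_", ct), header_lines = hdr)
      out[[ct]] <- cl
    }
    out
  })

  ## --- dialogs ----------------------------------------------------------
  if (!is.null(config$lr_db)) res$dialogs <- stage("dialog_inference", {
    db <- read_lr_database(config$lr_db)
    logmsg("LR DB: ", nrow(db), " pairs, ", attr(db, "n_ligands"), " ligands, ",
           attr(db, "n_receptors"), " receptors")
    expressed <- lapply(res$profiles, expressed_genes,
                        threshold = config$lr_threshold)
    edges <- active_dialogs(db, expressed)
    status <- classify_pair_genes(db, expressed, edges)
    edge_cells <- unique(c(edges$ligand_cell, edges$receptor_cell))
    overlap <- if (length(edge_cells) >= 2) dialog_overlap(edges)
    write_tsv_file(pair_category_counts(status),
                   file.path(outdir, "dialog_categories.tsv"), hdr)
    write_tsv_file(as.data.frame(edges), file.path(outdir, "dialog_edges.tsv"), hdr)
    export_network(edges, file.path(outdir, "dialog_network.sif"), "sif")
    if (!is.null(overlap) && !is.null(overlap$venn))
      write_tsv_file(data.frame(region = names(overlap$venn),
                                count = as.integer(overlap$venn)),
                     file.path(outdir, "dialog_overlap.tsv"), hdr)
    list(db = db, expressed = expressed, edges = edges, status = status,
         overlap = overlap)
  })

  ## --- maternal-effect genes -------------------------------------------
  if (!is.null(config$embryo)) res$maternal <- stage("maternal_effect", {
    emb <- read_tsv_file(config$embryo)
    m <- as.matrix(emb[, -1]); rownames(m) <- emb$gene
    series <- embryo_series(m)
    flags <- identify_maternal_effect(series, config$maternal_ref_min,
                                      config$maternal_ratio)
    flagged <- flags$gene[flags$is_maternal_effect]
    logmsg(length(flagged), " maternal-effect genes of ", nrow(flags))
    clusters <- if (length(flagged) >= config$maternal_k)
      cluster_maternal_genes(flagged, m, k = config$maternal_k,
                             seed = config$kmeans_seed)
    flags$cluster <- if (!is.null(clusters))
      ifelse(flags$gene %in% flagged, clusters[flags$gene], "unassigned")
      else "unassigned"
    write_tsv_file(flags, file.path(outdir, "maternal_effect.tsv"), hdr)
    list(series = series, flags = flags, clusters = clusters)
  })

  ## --- promoter methylation --------------------------------------------
  if (!is.null(config$cpgs) && !is.null(config$annotation))
    res$methylation <- stage("promoter_methylation", {
      cpgs <- read_cpg_bed(config$cpgs)
      ann <- read_tsv_file(config$annotation)
      summ <- promoter_methylation(cpgs, ann, window = config$promoter_window)
      write_tsv_file(summ, file.path(outdir, "promoter_methylation.tsv"), hdr)
      summ
    })

  logmsg("pipeline complete")
  invisible(res)
}
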