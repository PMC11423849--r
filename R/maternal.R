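## Maternal-effect gene identification from a preimplantation embryo
## series, four-group k-means clustering, imprinted-gene expression-status
## classification, promoter CpG methylation summarization, and a
## homolog-map overlap utility.

#' Construct an embryo expression series
#'
#' An ordered preimplantation series whose first stage is the reference
#' (typically MII), e.g. MII, zygote, 2-cell, 4-cell, 8-cell, morula.
#'
#' @param profiles Genes x stages numeric FPKM matrix.
#' @param stages Ordered stage labels; the first is the reference.
#' @return An `embryo_series` object.
#' @export
embryo_series <- function(profiles, stages = colnames(profiles)) {
  profiles <- as.matrix(profiles)
  if (length(stages) < 2) stop("an embryo series needs >= 2 stages")
  if (ncol(profiles) != length(stages))
    stop("profile width != number of stages")
  colnames(profiles) <- stages
  structure(list(stages = stages, profiles = profiles), class = "embryo_series")
}

#' @export
print.embryo_series <- function(x, ...) {
  cat(sprintf("embryo_series: %d genes; reference '%s', later stages %s\n",
              nrow(x$profiles), x$stages[1],
              paste(x$stages[-1], collapse = ", ")))
  invisible(x)
}

#' Identify maternal-effect genes
#'
#' A gene is flagged when its reference-stage (MII) FPKM is strictly above
#' `ref_min` and its expression at at least one later stage is strictly
#' below `ratio` times the reference, i.e. maternally deposited transcript
#' that is depleted during preimplantation development.
#'
#' @param series An `embryo_series` (reference stage first).
#' @param ref_min Reference FPKM must exceed this (default 2).
#' @param ratio Depletion threshold on stage/reference (default 0.5).
#' @return Data frame `gene`, `ref_fpkm`, `min_later_ratio`,
#'   `is_maternal_effect`. A zero-expression reference yields an infinite
#'   ratio and is never flagged.
#' @export
identify_maternal_effect <- function(series, ref_min = 2, ratio = 0.5) {
  stopifnot(inherits(series, "embryo_series"))
  ref <- series$profiles[, 1]
  later <- series$profiles[, -1, drop = FALSE]
  min_ratio <- ifelse(ref > 0, apply(later, 1, min) / ref, Inf)
  data.frame(gene = rownames(series$profiles),
             ref_fpkm = ref,
             min_later_ratio = min_ratio,
             is_maternal_effect = ref > ref_min & min_ratio < ratio,
             row.names = NULL)
}

#' Cluster maternal-effect genes into expression groups
#'
#' k-means on per-gene standardized `log2(FPKM + 1)` profiles (typically
#' the oocyte series concatenated with the embryo series), with a fixed
#' seed and labels `C1..Ck` assigned in order of descending cluster size.
#'
#' @param genes Genes to cluster (must be rows of `profiles`).
#' @param profiles Genes x stages numeric FPKM matrix.
#' @param k Number of groups (default 4).
#' @param seed RNG seed.
#' @param nstart Random restarts passed to [stats::kmeans()].
#' @return Named character vector gene -> label (`C1..Ck`).
#' @export
cluster_maternal_genes <- function(genes, profiles, k = 4, seed = 1, nstart = 10) {
  missing <- setdiff(genes, rownames(profiles))
  if (length(missing)) stop("gene(s) absent from profiles: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (length(genes) < k)
    stop("need at least k = ", k, " genes; got ", length(genes))
  m <- log2p1(as.matrix(profiles)[genes, , drop = FALSE])
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)      # flat genes stay centered at 0
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  sizes <- table(km$cluster)
  rank <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(k); relabel[as.integer(names(sizes))[rank]] <- seq_len(k)
  out <- paste0("C", relabel[km$cluster])
  names(out) <- genes
  out
}

#' Classify expression status of genes across stages
#'
#' Three-state call per (gene, stage): SILENT when FPKM is below
#' `silent_max`, HIGH when at or above `high_min`, MILD in between. With a
#' `pivot` stage, a per-gene flag records whether the gene is non-silent at
#' the pivot stage or any later stage (the "expressed from the pivot
#' onward" summary used for imprinted genes).
#'
#' @param profiles A `stage_profiles`.
#' @param genes Genes to classify; genes absent from the profiles are
#'   collected in `skipped`, not an error.
#' @param silent_max,high_min The two FPKM cut points.
#' @param pivot Optional pivot stage label.
#' @return List with `status` (data frame `gene`, `stage`, `fpkm`,
#'   `status`), `skipped`, and (if `pivot` given) `expressed_from_pivot`
#'   (named logical).
#' @export
classify_expression_status <- function(profiles, genes, silent_max = 1,
                                       high_min = 5, pivot = NULL) {
  stopifnot(inherits(profiles, "stage_profiles"))
  present <- intersect(genes, rownames(profiles$profiles))
  skipped <- setdiff(genes, present)
  m <- profiles$profiles[present, , drop = FALSE]
  status <- data.frame(
    gene = rep(present, times = length(profiles$stages)),
    stage = rep(profiles$stages, each = length(present)),
    fpkm = as.vector(m),
    row.names = NULL)
  status$status <- ifelse(status$fpkm < silent_max, "SILENT",
                          ifelse(status$fpkm >= high_min, "HIGH", "MILD"))
  out <- list(status = status, skipped = skipped)
  if (!is.null(pivot)) {
    k <- match(pivot, profiles$stages)
    if (is.na(k)) stop("pivot stage '", pivot, "' not in the profiles")
    sub <- m[, k:ncol(m), drop = FALSE]
    out$expressed_from_pivot <- apply(sub, 1, function(v) any(v >= silent_max))
  }
  out
}

#' Read a BED-like CpG methylation file
#'
#' @param path TSV with columns `chrom`, `position` (0-based), `level`
#'   (methylation fraction in `[0, 1]`).
#' @return Data frame of the three columns; malformed rows raise an error
#'   with the offending line number.
#' @export
read_cpg_bed <- function(path) {
  df <- read_tsv_file(path)
  miss <- setdiff(c("chrom", "position", "level"), names(df))
  if (length(miss)) stop("CpG file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$position) | df$position < 0 |
               !is.finite(df$level) | df$level < 0 | df$level > 1)
  if (length(bad))
    stop("malformed CpG record at line ", bad[1] + 1,
         " (position must be >= 0, level in [0, 1])")
  df
}

#' Mean promoter methylation per gene
#'
#' Averages CpG methylation levels over each gene's promoter, defined as
#' the closed, strand-independent window of `window` bp either side of the
#' TSS. Overlap assignment uses IRanges; a gene without CpGs in its window
#' gets `NA` with `n_cpgs = 0`.
#'
#' @param cpgs Data frame `chrom`, `position` (0-based), `level` in
#'   `[0, 1]`.
#' @param annotation Data frame `gene`, `chrom`, `tss`, `strand`.
#' @param window Half-width of the promoter window in bp (default 1000).
#' @return Data frame `gene`, `promoter_mean`, `n_cpgs`.
#' @export
promoter_methylation <- function(cpgs, annotation, window = 1000) {
  stopifnot(all(c("chrom", "position", "level") %in% names(cpgs)),
            all(c("gene", "chrom", "tss", "strand") %in% names(annotation)))
  if (any(cpgs$level < 0 | cpgs$level > 1))
    stop("methylation levels must lie in [0, 1]")
  means <- rep(NA_real_, nrow(annotation))
  ncpg <- integer(nrow(annotation))
  for (chr in unique(annotation$chrom)) {
    gi <- which(annotation$chrom == chr)
    ci <- which(cpgs$chrom == chr)
    if (!length(ci)) next
    prom <- IRanges::IRanges(start = annotation$tss[gi] - window,
                             end = annotation$tss[gi] + window)
    pos <- IRanges::IRanges(start = cpgs$position[ci], width = 1)
    hits <- IRanges::findOverlaps(prom, pos)
    if (length(hits)) {
      lv <- cpgs$level[ci][S4Vectors::subjectHits(hits)]
      grp <- S4Vectors::queryHits(hits)
      sums <- tapply(lv, grp, sum)
      cnts <- tapply(lv, grp, length)
      idx <- as.integer(names(sums))
      means[gi[idx]] <- as.numeric(sums / cnts)
      ncpg[gi[idx]] <- as.integer(cnts)
    }
  }
  data.frame(gene = annotation$gene, promoter_mean = means, n_cpgs = ncpg,
             row.names = NULL)
}

#' Overlap of two gene lists through a homolog map
#'
#' @param list_a,list_b Character vectors of gene symbols (e.g. mouse and
#'   human maternal-effect genes).
#' @param homolog_map Data frame with columns `gene_a`, `gene_b` mapping
#'   list-a symbols to list-b symbols.
#' @return List with `a_in_b` (genes of `list_a` whose mapped partner is in
#'   `list_b`), `b_in_a` (the symmetric variant), and the counts.
#' @export
homolog_overlap <- function(list_a, list_b, homolog_map) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(homolog_map)))
  a_in_b <- unique(homolog_map$gene_a[homolog_map$gene_a %in% list_a &
                                      homolog_map$gene_b %in% list_b])
  b_in_a <- unique(homolog_map$gene_b[homolog_map$gene_b %in% list_b &
                                      homolog_map$gene_a %in% list_a])
  list(a_in_b = a_in_b, b_in_a = b_in_a,
       n_a = length(unique(list_a)), n_b = length(unique(list_b)),
       n_overlap = length(a_in_b))
}
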