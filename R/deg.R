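## Differential expression between adjacent stages and between cell types,
## stage-specific DEG extraction, pivot splits, inheritance, Venn overlaps.
##
## The significance rule throughout is the fold-change + p-value criterion:
## a gene is a DEG when FC >= 2 or FC <= 0.5 and p < 0.05. The p-value comes
## from a two-sided Welch t-test on log2(FPKM + 1) across replicates.

#' Define a two-group comparison
#'
#' @param kind `"ADJACENT_STAGE"` (same cell type, consecutive stages) or
#'   `"CROSS_CELLTYPE"` (same stage, different cell types).
#' @param group_a,group_b Character vectors `c(cell_type, stage)`. Fold
#'   changes are oriented `group_b` over `group_a`: the later stage, or the
#'   first-named cell type, goes in `group_b`.
#' @param stage_series Optional stage-series list used to check that
#'   adjacent-stage comparisons really are consecutive.
#' @return A `comparison` object.
#' @export
comparison <- function(kind = c("ADJACENT_STAGE", "CROSS_CELLTYPE"),
                       group_a, group_b, stage_series = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(group_a) == 2, length(group_b) == 2)
  if (kind == "ADJACENT_STAGE") {
    if (group_a[1] != group_b[1])
      stop("ADJACENT_STAGE comparison must stay within one cell type")
    if (!is.null(stage_series)) {
      s <- stage_series[[group_a[1]]]
      ia <- match(group_a[2], s); ib <- match(group_b[2], s)
      if (is.na(ia) || is.na(ib) || ib - ia != 1L)
        stop("stages '", group_a[2], "' and '", group_b[2],
             "' are not consecutive in the '", group_a[1], "' series")
    }
  } else {
    if (group_a[2] != group_b[2])
      stop("CROSS_CELLTYPE comparison must compare two cell types at one stage")
    if (group_a[1] == group_b[1])
      stop("CROSS_CELLTYPE comparison needs two different cell types")
  }
  structure(list(kind = kind,
                 group_a = c(cell_type = unname(group_a[1]), stage = unname(group_a[2])),
                 group_b = c(cell_type = unname(group_b[1]), stage = unname(group_b[2]))),
            class = "comparison")
}

comparison_label <- function(cmp) {
  if (cmp$kind == "ADJACENT_STAGE")
    sprintf("%s:%s_vs_%s", cmp$group_a[["cell_type"]],
            cmp$group_b[["stage"]], cmp$group_a[["stage"]])
  else
    sprintf("%s_vs_%s:%s", cmp$group_b[["cell_type"]],
            cmp$group_a[["cell_type"]], cmp$group_a[["stage"]])
}

## Vectorized two-sided Welch t-test on rows of two matrices
## (log2(FPKM+1) replicate values). Degenerate cases:
##  - either group has a single replicate: p = 0 for every gene (the FC
##    rule alone decides; flagged by the caller)
##  - both groups constant: p = 1 if the means agree, else 0.
welch_p <- function(la, lb) {
  n1 <- ncol(la); n2 <- ncol(lb)
  m1 <- rowMeans(la); m2 <- rowMeans(lb)
  if (n1 < 2 || n2 < 2) return(rep(0, nrow(la)))
  v1 <- apply(la, 1, stats::var); v2 <- apply(lb, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(nrow(la))
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  ok <- !degen
  tstat <- (m2[ok] - m1[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  p
}

#' Test differential expression for one comparison
#'
#' Fold change is `(mean_b + pseudocount) / (mean_a + pseudocount)` on
#' replicate-mean FPKM; the p-value is a two-sided Welch t-test on
#' `log2(FPKM + 1)` across replicates. A gene is significant when
#' `fc >= fc_up` or `fc <= fc_down` and `p < alpha`. When either group has
#' a single replicate no t-test is possible: p is set to 0 so the
#' fold-change rule alone decides, and the result is flagged.
#'
#' @param x An `expr_matrix` (already low-expression filtered; the gene
#'   universe is whatever `x` contains).
#' @param cmp A [comparison()].
#' @param pseudocount Added to both group means before the ratio.
#' @param fc_up,fc_down,alpha The significance rule thresholds.
#' @param adjust Apply Benjamini-Hochberg adjustment to the p-values before
#'   the rule (off by default: the rule uses raw p < 0.05).
#' @return A `deg_set`: data frame with columns `gene`, `fc`, `p`,
#'   `direction` (UP/DOWN/NONE), `significant`; attributes `comparison`,
#'   `single_replicate`, `pseudocount`.
#' @export
test_differential <- function(x, cmp, pseudocount = 0.01,
                              fc_up = 2, fc_down = 0.5, alpha = 0.05,
                              adjust = FALSE) {
  stopifnot(inherits(x, "expr_matrix"), inherits(cmp, "comparison"))
  pick <- function(g) {
    ids <- x$meta$sample_id[x$meta$cell_type == g[["cell_type"]] &
                            x$meta$stage == g[["stage"]]]
    if (!length(ids))
      stop("empty group: no samples for ", g[["cell_type"]], " at ", g[["stage"]])
    x$values[, ids, drop = FALSE]
  }
  a <- pick(cmp$group_a); b <- pick(cmp$group_b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  fc <- (mb + pseudocount) / (ma + pseudocount)
  single <- ncol(a) < 2 || ncol(b) < 2
  p <- welch_p(log2p1(a), log2p1(b))
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  significant <- (fc >= fc_up | fc <= fc_down) & p < alpha
  direction <- ifelse(significant & fc >= fc_up, "UP",
                      ifelse(significant & fc <= fc_down, "DOWN", "NONE"))
  res <- data.frame(gene = rownames(x$values), fc = fc, p = p,
                    direction = direction, significant = significant,
                    row.names = NULL)
  structure(res, class = c("deg_set", "data.frame"),
            comparison = cmp, single_replicate = single,
            pseudocount = pseudocount,
            thresholds = c(fc_up = fc_up, fc_down = fc_down, alpha = alpha))
}

#' Significant genes of a DEG set
#' @param x A `deg_set`.
#' @return Character vector of significant gene symbols.
#' @export
significant_genes <- function(x) {
  stopifnot(inherits(x, "deg_set"))
  x$gene[x$significant]
}

#' @export
print.deg_set <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat(sprintf("deg_set %s: %d genes tested, %d significant (%d up, %d down)\n",
              comparison_label(cmp), nrow(x), sum(x$significant),
              sum(x$direction == "UP"), sum(x$direction == "DOWN")))
  if (isTRUE(attr(x, "single_replicate")))
    cat("note: single-replicate group; p set to 0, FC rule decides\n")
  invisible(x)
}

#' DEGs between every pair of consecutive stages of one cell type
#'
#' @inheritParams test_differential
#' @param cell_type Cell type whose configured series is scanned.
#' @param ... Passed to [test_differential()].
#' @return Named list of `deg_set`s, one per consecutive stage pair, in
#'   stage order; `group_a` is always the earlier stage.
#' @export
adjacent_stage_scan <- function(x, cell_type, ...) {
  series <- x$stage_series[[cell_type]]
  if (is.null(series) || length(series) < 2)
    stop("need >= 2 configured stages for '", cell_type, "'")
  out <- list()
  for (i in seq_len(length(series) - 1)) {
    cmp <- comparison("ADJACENT_STAGE",
                      c(cell_type, series[i]), c(cell_type, series[i + 1]),
                      stage_series = x$stage_series)
    out[[comparison_label(cmp)]] <- test_differential(x, cmp, ...)
  }
  out
}

#' DEGs between two cell types at each shared stage
#'
#' @inheritParams test_differential
#' @param numerator,denominator Cell types; fold change is oriented
#'   numerator over denominator (the numerator is `group_b`).
#' @param stages Stages to compare; defaults to the stages the two series
#'   share, in series order.
#' @param ... Passed to [test_differential()].
#' @return Named list of `deg_set`s, one per stage.
#' @export
cross_celltype_scan <- function(x, numerator, denominator, stages = NULL, ...) {
  sa <- x$stage_series[[denominator]]; sb <- x$stage_series[[numerator]]
  if (is.null(sa) || is.null(sb)) stop("both cell types need a configured series")
  if (is.null(stages)) stages <- sb[sb %in% sa]
  out <- list()
  for (s in stages) {
    cmp <- comparison("CROSS_CELLTYPE", c(denominator, s), c(numerator, s))
    out[[comparison_label(cmp)]] <- test_differential(x, cmp, ...)
  }
  out
}

#' Per-comparison DEG count summary
#'
#' The bar-plot analog: one row per comparison with the number of
#' significant, up- and down-regulated genes.
#'
#' @param scan Named list of `deg_set`s.
#' @return Data frame with columns `comparison`, `n_significant`, `n_up`,
#'   `n_down`.
#' @export
deg_count_summary <- function(scan) {
  data.frame(comparison = names(scan),
             n_significant = vapply(scan, function(d) sum(d$significant), 0L),
             n_up = vapply(scan, function(d) sum(d$direction == "UP"), 0L),
             n_down = vapply(scan, function(d) sum(d$direction == "DOWN"), 0L),
             row.names = NULL)
}

#' Stage-specific DEGs
#'
#' Significant genes of the target comparison minus the union of
#' significant genes of every other comparison in the scan (optionally plus
#' extra DEG sets to subtract, e.g. cross-cell-type ones).
#'
#' @param scan Named list of `deg_set`s.
#' @param target Name (or index) of the target comparison within `scan`.
#' @param extra Optional list of further `deg_set`s whose significant genes
#'   are also subtracted.
#' @return Character vector of target-specific significant genes.
#' @export
stage_specific_degs <- function(scan, target, extra = NULL) {
  if (is.character(target) && !target %in% names(scan))
    stop("target comparison '", target, "' is not in the scan")
  if (is.numeric(target) && (target < 1 || target > length(scan)))
    stop("target index out of range")
  idx <- if (is.character(target)) match(target, names(scan)) else as.integer(target)
  others <- c(scan[-idx], extra)
  setdiff(significant_genes(scan[[idx]]),
          unique(unlist(lapply(others, significant_genes))))
}

#' Split genes by expression weight before versus from a pivot stage
#'
#' A gene lands in `before` when its mean `log2(FPKM + 1)` over stages
#' strictly before the pivot exceeds its mean over stages at or after the
#' pivot, otherwise in `onward`. The two sets partition the input.
#'
#' @param genes Character vector of gene symbols (present in `profiles`).
#' @param profiles A `stage_profiles`.
#' @param pivot Pivot stage label; must not be the first stage.
#' @return List with elements `before` and `onward`.
#' @export
split_by_pivot <- function(genes, profiles, pivot) {
  stopifnot(inherits(profiles, "stage_profiles"))
  k <- match(pivot, profiles$stages)
  if (is.na(k)) stop("pivot stage '", pivot, "' not in the profile stages")
  if (k == 1) stop("pivot cannot be the first stage")
  genes <- intersect(genes, rownames(profiles$profiles))
  lg <- log2p1(profiles$profiles[genes, , drop = FALSE])
  before_mean <- rowMeans(lg[, seq_len(k - 1), drop = FALSE])
  onward_mean <- rowMeans(lg[, k:ncol(lg), drop = FALSE])
  list(before = genes[before_mean > onward_mean],
       onward = genes[before_mean <= onward_mean])
}

#' Inheritance of DEGs from a reference comparison
#'
#' For each comparison after the reference, splits its significant genes
#' into those inherited from (shared with) the reference and those arising
#' de novo.
#'
#' @param sets Named list of `deg_set`s in stage order.
#' @param reference Name of the reference comparison in `sets`.
#' @return List with `summary` (data frame: comparison, n_significant,
#'   n_inherited, n_de_novo) and `genes` (per comparison, the two gene
#'   lists).
#' @export
inheritance_analysis <- function(sets, reference) {
  if (!reference %in% names(sets))
    stop("reference comparison '", reference, "' is not in the set list")
  ref_idx <- match(reference, names(sets))
  ref_genes <- significant_genes(sets[[reference]])
  later <- names(sets)[seq_along(sets) > ref_idx]
  genes <- lapply(sets[later], function(d) {
    sig <- significant_genes(d)
    list(inherited = intersect(sig, ref_genes),
         de_novo = setdiff(sig, ref_genes))
  })
  summary <- data.frame(
    comparison = later,
    n_significant = vapply(sets[later], function(d) sum(d$significant), 0L),
    n_inherited = vapply(genes, function(g) length(g$inherited), 0L),
    n_de_novo = vapply(genes, function(g) length(g$de_novo), 0L),
    row.names = NULL)
  list(summary = summary, genes = genes, reference = reference)
}

#' Exact Venn region counts for two or three gene sets
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector of disjoint region counts; names are
#'   set-name combinations joined by `&`. Counts sum to the union size.
#' @export
overlap_venn <- function(sets) {
  if (!length(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  if (length(sets) < 2 || length(sets) > 3)
    stop("overlap_venn takes 2 or 3 sets")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  code <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  regions <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  counts <- table(factor(code, levels = regions))
  out <- as.integer(counts); names(out) <- regions
  out
}

#' Write per-comparison DEG tables and a count summary
#'
#' @param scan Named list of `deg_set`s.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param header_lines Optional comment lines for every file.
#' @return Paths written, invisibly.
#' @export
write_deg_reports <- function(scan, dir, prefix = "deg", header_lines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(scan)) {
    d <- scan[[nm]]
    df <- data.frame(gene = d$gene, comparison = nm, fc = d$fc, p = d$p,
                     direction = d$direction, significant = d$significant)
    path <- file.path(dir, paste0(prefix, "_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv"))
    write_tsv_file(df, path, header_lines)
    paths <- c(paths, path)
  }
  sp <- file.path(dir, paste0(prefix, "_counts.tsv"))
  write_tsv_file(deg_count_summary(scan), sp, header_lines)
  invisible(c(paths, sp))
}
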