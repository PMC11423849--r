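## Ligand-receptor dialog inference: database parsing, the FPKM >= 5
## expression rule, active-dialog enumeration, the four-way
## homologous/heterologous/hybrid/none gene classification and network
## export. Gene symbols are compared case-insensitively (uppercased) with
## the original case preserved in all outputs.

norm_symbol <- function(x) toupper(trimws(x))

#' Read a ligand-receptor pair database
#'
#' @param path TSV with columns `ligand` and `receptor`.
#' @return An `lr_db`: data frame of unique pairs (original-case symbols,
#'   deduplicated on uppercased pairs) with the unique ligand and receptor
#'   counts attached as attributes.
#' @export
read_lr_database <- function(path) {
  df <- read_tsv_file(path)
  miss <- setdiff(c("ligand", "receptor"), names(df))
  if (length(miss))
    stop("ligand-receptor TSV lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("ligand-receptor database is empty")
  lr_database(df$ligand, df$receptor)
}

#' Construct a ligand-receptor database from vectors
#'
#' @param ligand,receptor Parallel character vectors of gene symbols.
#' @return An `lr_db`.
#' @export
lr_database <- function(ligand, receptor) {
  key <- paste(norm_symbol(ligand), norm_symbol(receptor))
  keep <- !duplicated(key)
  db <- data.frame(ligand = as.character(ligand)[keep],
                   receptor = as.character(receptor)[keep],
                   row.names = NULL)
  structure(db, class = c("lr_db", "data.frame"),
            n_ligands = length(unique(norm_symbol(db$ligand))),
            n_receptors = length(unique(norm_symbol(db$receptor))))
}

#' @export
print.lr_db <- function(x, ...) {
  cat(sprintf("lr_db: %d unique pairs, %d ligands, %d receptors\n",
              nrow(x), attr(x, "n_ligands"), attr(x, "n_receptors")))
  invisible(x)
}

#' Write a ligand-receptor database to TSV
#' @param db An `lr_db`.
#' @param path Output path.
#' @export
write_lr_database <- function(db, path) {
  write_tsv_file(data.frame(ligand = db$ligand, receptor = db$receptor), path)
}

#' Genes expressed in a stage-profile set
#'
#' A gene counts as expressed when its maximal replicate-mean FPKM over the
#' stage series reaches the threshold (default 5 FPKM at at least one
#' stage).
#'
#' @param profiles A `stage_profiles`.
#' @param threshold Minimum peak FPKM.
#' @return Character vector of expressed gene symbols.
#' @export
expressed_genes <- function(profiles, threshold = 5) {
  stopifnot(inherits(profiles, "stage_profiles"))
  rownames(profiles$profiles)[apply(profiles$profiles, 1, max) >= threshold]
}

#' Enumerate active ligand-receptor dialogs
#'
#' For every database pair and every ordered cell-type combination
#' (including within-type), an edge exists when the ligand gene is
#' expressed in the source cell type and the receptor gene in the target
#' cell type.
#'
#' @param db An `lr_db`.
#' @param expressed Named list: cell type -> character vector of expressed
#'   genes (e.g. from [expressed_genes()]).
#' @return A `dialog_edges` data frame: `ligand`, `ligand_cell`,
#'   `receptor`, `receptor_cell`.
#' @export
active_dialogs <- function(db, expressed) {
  stopifnot(inherits(db, "lr_db"), length(expressed) >= 1)
  cells <- names(expressed)
  exp_norm <- lapply(expressed, norm_symbol)
  lig <- norm_symbol(db$ligand); rec <- norm_symbol(db$receptor)
  out <- list()
  for (a in cells) for (b in cells) {
    hit <- lig %in% exp_norm[[a]] & rec %in% exp_norm[[b]]
    if (any(hit))
      out[[paste(a, b)]] <- data.frame(ligand = db$ligand[hit], ligand_cell = a,
                                       receptor = db$receptor[hit], receptor_cell = b)
  }
  edges <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
           else data.frame(ligand = character(), ligand_cell = character(),
                           receptor = character(), receptor_cell = character())
  structure(edges, class = c("dialog_edges", "data.frame"))
}

#' Classify expressed pair-member genes per cell type
#'
#' For each expressed gene that occurs in at least one database pair, in
#' each cell type where it is expressed and each role it plays there:
#' HOMOLOGOUS when all of its dialogs from that cell type stay within the
#' cell type, HETEROLOGOUS when all leave it, HYBRID when both kinds
#' exist, and NONE when the gene participates in no dialog although
#' expressed (no partner is expressed in any cell type).
#'
#' @param db An `lr_db`.
#' @param expressed Named list cell type -> expressed genes.
#' @param edges Dialog edges from [active_dialogs()] on the same inputs.
#' @return Data frame `gene`, `role` (LIGAND/RECEPTOR), `cell_type`,
#'   `category`.
#' @export
classify_pair_genes <- function(db, expressed, edges) {
  lig <- norm_symbol(db$ligand); rec <- norm_symbol(db$receptor)
  e_lig <- norm_symbol(edges$ligand); e_rec <- norm_symbol(edges$receptor)
  res <- list()
  for (ct in names(expressed)) {
    genes <- expressed[[ct]]
    gn <- norm_symbol(genes)
    for (i in seq_along(genes)) {
      g <- gn[i]
      if (g %in% lig) {
        partner_cells <- edges$receptor_cell[e_lig == g & edges$ligand_cell == ct]
        res[[length(res) + 1L]] <- data.frame(
          gene = genes[i], role = "LIGAND", cell_type = ct,
          category = edge_category(partner_cells, ct))
      }
      if (g %in% rec) {
        partner_cells <- edges$ligand_cell[e_rec == g & edges$receptor_cell == ct]
        res[[length(res) + 1L]] <- data.frame(
          gene = genes[i], role = "RECEPTOR", cell_type = ct,
          category = edge_category(partner_cells, ct))
      }
    }
  }
  if (!length(res))
    return(data.frame(gene = character(), role = character(),
                      cell_type = character(), category = character()))
  do.call(rbind, c(res, make.row.names = FALSE))
}

edge_category <- function(partner_cells, ct) {
  if (!length(partner_cells)) return("NONE")
  within <- any(partner_cells == ct)
  between <- any(partner_cells != ct)
  if (within && between) "HYBRID" else if (within) "HOMOLOGOUS" else "HETEROLOGOUS"
}

#' Per-category counts of pair-member genes (bar-plot analog)
#'
#' @param status Data frame from [classify_pair_genes()].
#' @return Data frame `cell_type`, `role`, `category`, `count` covering all
#'   combinations (zeros included).
#' @export
pair_category_counts <- function(status) {
  lv <- c("HOMOLOGOUS", "HETEROLOGOUS", "HYBRID", "NONE")
  cells <- unique(status$cell_type)
  tab <- as.data.frame(table(
    cell_type = factor(status$cell_type, levels = cells),
    role = factor(status$role, levels = c("LIGAND", "RECEPTOR")),
    category = factor(status$category, levels = lv)))
  names(tab)[4] <- "count"
  tab$count <- as.integer(tab$count)
  tab
}

#' Overlap of ligand-receptor pairs between cell-type pairs
#'
#' Projects the directed dialog edges onto unordered cell-type pairs: for
#' each pair of distinct cell types, the set of ligand-receptor gene pairs
#' active between them in either direction. Venn region counts are then
#' exact.
#'
#' @param edges A `dialog_edges` data frame.
#' @param include_within Also form per-cell-type (within-type) sets.
#' @return List with `sets` (named list of "LIGAND->RECEPTOR" pair keys per
#'   cell-type pair) and `venn` (region counts from [overlap_venn()],
#'   `NULL` when fewer than 2 or more than 3 sets).
#' @export
dialog_overlap <- function(edges, include_within = FALSE) {
  cells <- sort(unique(c(edges$ligand_cell, edges$receptor_cell)))
  if (length(cells) < 2 && !include_within)
    stop("dialog_overlap needs edges spanning >= 2 cell types")
  pairkey <- paste0(norm_symbol(edges$ligand), "->", norm_symbol(edges$receptor))
  sets <- list()
  combos <- utils::combn(cells, 2, simplify = FALSE)
  if (include_within) combos <- c(combos, lapply(cells, function(ct) c(ct, ct)))
  for (cc in combos) {
    hit <- (edges$ligand_cell == cc[1] & edges$receptor_cell == cc[2]) |
           (edges$ligand_cell == cc[2] & edges$receptor_cell == cc[1])
    sets[[paste(cc[1], cc[2], sep = "-")]] <- unique(pairkey[hit])
  }
  venn <- if (length(sets) >= 2 && length(sets) <= 3) overlap_venn(sets) else NULL
  list(sets = sets, venn = venn)
}

node_id <- function(gene, cell, role) paste(gene, cell, role, sep = "|")

#' Export a dialog network
#'
#' Writes the directed ligand -> receptor network. Nodes are
#' (gene, cell type, role) endpoints encoded `gene|cell|role`; SIF rows are
#' `source<TAB>lr<TAB>target`, and the GraphML export carries `gene`,
#' `cell_type` and `role` node attributes.
#'
#' @param edges A `dialog_edges` data frame.
#' @param path Output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  src <- node_id(edges$ligand, edges$ligand_cell, "LIGAND")
  dst <- node_id(edges$receptor, edges$receptor_cell, "RECEPTOR")
  if (format == "sif") {
    writeLines(paste(src, "lr", dst, sep = "\t"), path)
  } else {
    nodes <- unique(data.frame(
      id = c(src, dst),
      gene = c(edges$ligand, edges$receptor),
      cell = c(edges$ligand_cell, edges$receptor_cell),
      role = rep(c("LIGAND", "RECEPTOR"), each = nrow(edges))))
    xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             '  <key id="gene" for="node" attr.name="gene" attr.type="string"/>',
             '  <key id="cell_type" for="node" attr.name="cell_type" attr.type="string"/>',
             '  <key id="role" for="node" attr.name="role" attr.type="string"/>',
             '  <graph id="dialogs" edgedefault="directed">',
             sprintf(paste0('    <node id="%s"><data key="gene">%s</data>',
                            '<data key="cell_type">%s</data>',
                            '<data key="role">%s</data></node>'),
                     nodes$id, nodes$gene, nodes$cell, nodes$role),
             sprintf('    <edge source="%s" target="%s"/>', src, dst),
             '  </graph>', '</graphml>')
    writeLines(xml, path)
  }
  invisible(path)
}

#' Read a SIF network back into dialog edges
#'
#' Inverse of [export_network()] for the SIF format.
#'
#' @param path SIF file written by [export_network()].
#' @return A `dialog_edges` data frame.
#' @export
read_sif_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  src <- vapply(parts, `[`, "", 1); dst <- vapply(parts, `[`, "", 3)
  sp <- function(v, k) vapply(strsplit(v, "|", fixed = TRUE), `[`, "", k)
  structure(data.frame(ligand = sp(src, 1), ligand_cell = sp(src, 2),
                       receptor = sp(dst, 1), receptor_cell = sp(dst, 2)),
            class = c("dialog_edges", "data.frame"))
}
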