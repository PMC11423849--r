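# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain loops and direct formula evaluation only.

oracle_rule <- function(fc, p, fc_up = 2, fc_down = 0.5, alpha = 0.05) {
  (fc >= fc_up | fc <= fc_down) & p < alpha
}

# per-gene two-sided Welch test through stats::t.test on log2(FPKM+1)
oracle_welch <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    la <- log2(a[i, ] + 1); lb <- log2(b[i, ] + 1)
    if (stats::sd(la) == 0 && stats::sd(lb) == 0)
      return(if (mean(la) == mean(lb)) 1 else 0)
    stats::t.test(lb, la, var.equal = FALSE)$p.value
  }, numeric(1))
}

oracle_venn <- function(sets) {
  sets <- lapply(sets, unique)
  out <- integer(0)
  for (k in seq_along(sets)) {
    for (combo in utils::combn(names(sets), k, simplify = FALSE)) {
      inside <- Reduce(intersect, sets[combo])
      outside <- unique(unlist(sets[setdiff(names(sets), combo)]))
      out[paste(combo, collapse = "&")] <- length(setdiff(inside, outside))
    }
  }
  out
}

# triple loop over pairs x source cell x target cell
oracle_active <- function(db, expressed) {
  rows <- list()
  for (i in seq_len(nrow(db))) {
    for (a in names(expressed)) {
      for (b in names(expressed)) {
        if (toupper(db$ligand[i]) %in% toupper(expressed[[a]]) &&
            toupper(db$receptor[i]) %in% toupper(expressed[[b]]))
          rows[[length(rows) + 1]] <- c(toupper(db$ligand[i]), a,
                                        toupper(db$receptor[i]), b)
      }
    }
  }
  if (!length(rows)) return(character(0))
  sort(unique(vapply(rows, paste, "", collapse = "|")))
}

# per-gene category by enumerating partner cells pair by pair
oracle_classify <- function(db, expressed) {
  rows <- list()
  for (ct in names(expressed)) {
    for (g in expressed[[ct]]) {
      for (role in c("LIGAND", "RECEPTOR")) {
        own <- if (role == "LIGAND") toupper(db$ligand) else toupper(db$receptor)
        other <- if (role == "LIGAND") toupper(db$receptor) else toupper(db$ligand)
        if (!toupper(g) %in% own) next
        partner_cells <- character(0)
        for (i in which(own == toupper(g))) {
          for (ct2 in names(expressed))
            if (other[i] %in% toupper(expressed[[ct2]]))
              partner_cells <- c(partner_cells, ct2)
        }
        cat_ <- if (!length(partner_cells)) "NONE"
                else if (all(partner_cells == ct)) "HOMOLOGOUS"
                else if (all(partner_cells != ct)) "HETEROLOGOUS"
                else "HYBRID"
        rows[[length(rows) + 1]] <- data.frame(gene = toupper(g), role = role,
                                               cell_type = ct, category = cat_)
      }
    }
  }
  if (!length(rows)) return(NULL)
  unique(do.call(rbind, rows))
}

# O(genes x cpgs) scan
oracle_promoter <- function(cpgs, annotation, window = 1000) {
  means <- rep(NA_real_, nrow(annotation)); ns <- integer(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    lv <- c()
    for (j in seq_len(nrow(cpgs))) {
      if (cpgs$chrom[j] == annotation$chrom[i] &&
          abs(cpgs$position[j] - annotation$tss[i]) <= window)
        lv <- c(lv, cpgs$level[j])
    }
    ns[i] <- length(lv)
    if (length(lv)) means[i] <- sum(lv) / length(lv)
  }
  data.frame(gene = annotation$gene, promoter_mean = means, n_cpgs = ns)
}

oracle_maternal <- function(profiles, ref_min = 2, ratio = 0.5) {
  vapply(seq_len(nrow(profiles)), function(i) {
    ref <- profiles[i, 1]
    ref > ref_min && any(profiles[i, -1] < ratio * ref)
  }, logical(1))
}

oracle_status <- function(fpkm, silent_max = 1, high_min = 5) {
  vapply(fpkm, function(v)
    if (v < silent_max) "SILENT" else if (v >= high_min) "HIGH" else "MILD",
    character(1))
}

edges_key <- function(edges) {
  if (!nrow(edges)) return(character(0))
  sort(unique(paste(toupper(edges$ligand), edges$ligand_cell,
                    toupper(edges$receptor), edges$receptor_cell, sep = "|")))
}
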