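test_that("ligand-receptor database parsing dedups and round-trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "lr.tsv")
  writeLines(c("ligand\treceptor", "A\tB", "a\tb", "A\tC"), p)
  db <- read_lr_database(p)
  expect_equal(nrow(db), 2)                       # (A,B) duplicated as (a,b)
  expect_equal(attr(db, "n_ligands"), 1)
  expect_equal(attr(db, "n_receptors"), 2)
  p2 <- file.path(dir, "lr2.tsv")
  write_lr_database(db, p2)
  db2 <- read_lr_database(p2)
  expect_equal(db2$ligand, db$ligand)
  expect_equal(db2$receptor, db$receptor)

  writeLines("ligand\tother", p)
  expect_error(read_lr_database(p), "receptor")
  writeLines("ligand\treceptor", p)
  expect_error(read_lr_database(p), "empty")
})

test_that("expression rule: peak FPKM at any stage reaches the threshold", {
  m <- rbind(on = c(0, 0, 6, 0), off = c(4.9, 4.9, 4.9, 4.9), edge = c(5, 0, 0, 0))
  p <- stage_profiles(m, "OC", paste0("s", 1:4))
  expect_setequal(expressed_genes(p), c("on", "edge"))
  # raising the threshold never enlarges the set
  for (thr in c(1, 5, 6, 10))
    expect_true(all(expressed_genes(p, thr * 2) %in% expressed_genes(p, thr)))
})

test_that("active dialogs match the exhaustive triple-loop oracle", {
  db <- lr_database(c("L1", "L2"), c("R1", "R2"))
  # ligand only in OC, receptor only in GC -> exactly one OC->GC edge
  e <- active_dialogs(db, list(OC = "L1", GC = "R1"))
  expect_equal(nrow(e), 1)
  expect_equal(unname(unlist(e[1, ])), c("L1", "OC", "R1", "GC"))
  # both genes in GC only -> one GC->GC edge
  e2 <- active_dialogs(db, list(OC = character(0), GC = c("L2", "R2")))
  expect_equal(nrow(e2), 1)
  expect_equal(e2$ligand_cell, "GC")
  expect_equal(e2$receptor_cell, "GC")

  for (seed in 1:40) {
    inst <- rand_lr_instance(seed)
    edges <- active_dialogs(inst$db, inst$expressed)
    expect_equal(edges_key(edges), oracle_active(inst$db, inst$expressed))
    # every endpoint passes the expression rule in its cell type
    if (nrow(edges)) {
      expect_true(all(mapply(function(g, ct) g %in% inst$expressed[[ct]],
                             edges$ligand, edges$ligand_cell)))
      expect_true(all(mapply(function(g, ct) g %in% inst$expressed[[ct]],
                             edges$receptor, edges$receptor_cell)))
    }
  }
})

test_that("adding an expressed gene never removes a dialog edge", {
  inst <- rand_lr_instance(99)
  base_edges <- edges_key(active_dialogs(inst$db, inst$expressed))
  grown <- inst$expressed
  extra <- setdiff(unique(c(inst$db$ligand, inst$db$receptor)), grown$OC)
  grown$OC <- c(grown$OC, extra[1:5])
  grown_edges <- edges_key(active_dialogs(inst$db, grown))
  expect_true(all(base_edges %in% grown_edges))
})

test_that("pair-gene classification matches per-gene enumeration and partitions", {
  # hand-built cases for each category
  db <- lr_database(c("L1", "L2", "L3", "L3", "L4"),
                    c("R1", "R2", "R3", "R4", "R9"))
  expressed <- list(OC = c("L2"), GC = c("L1", "R1", "L3", "R3", "L4"),
                    CC = c("R2", "R4"))
  edges <- active_dialogs(db, expressed)
  st <- classify_pair_genes(db, expressed, edges)
  pick <- function(g, ct) st$category[st$gene == g & st$cell_type == ct]
  expect_equal(pick("L1", "GC"), "HOMOLOGOUS")    # only partner R1 in GC
  expect_equal(pick("L2", "OC"), "HETEROLOGOUS")  # only partner R2 in CC
  expect_equal(pick("L3", "GC"), "HYBRID")        # R3 in GC, R4 in CC
  expect_equal(pick("L4", "GC"), "NONE")          # R9 expressed nowhere
  # every expressed pair-member gene gets exactly one category per role
  expect_equal(anyDuplicated(st[, c("gene", "role", "cell_type")]), 0L)

  for (seed in 41:80) {
    inst <- rand_lr_instance(seed)
    edges <- active_dialogs(inst$db, inst$expressed)
    got <- classify_pair_genes(inst$db, inst$expressed, edges)
    ora <- oracle_classify(inst$db, inst$expressed)
    if (is.null(ora)) { expect_equal(nrow(got), 0); next }
    got$gene <- toupper(got$gene)
    key <- function(d) paste(d$gene, d$role, d$cell_type)
    got <- got[order(key(got)), ]; ora <- ora[order(key(ora)), ]
    expect_equal(got$category, ora$category)
    expect_equal(key(got), key(ora))
  }
})

test_that("dialog overlap projects to unordered pairs with exact Venn counts", {
  db <- lr_database(c("L1", "L2", "L3"), c("R1", "R2", "R3"))
  expressed <- list(OC = c("L1", "L2", "L3"), GC = c("R1", "R2"), CC = c("R1"))
  ov <- dialog_overlap(active_dialogs(db, expressed))
  expect_setequal(ov$sets[["GC-OC"]], c("L1->R1", "L2->R2"))
  expect_setequal(ov$sets[["CC-OC"]], "L1->R1")
  expect_equal(unname(ov$venn["CC-OC"]), 0L)           # CC-OC is a subset of GC-OC
  expect_equal(unname(ov$venn["CC-OC&GC-OC"]), 1L)
  # disjoint and identical set behavior via the generic Venn
  expect_equal(sum(ov$venn), length(unique(unlist(ov$sets))))
  n_checked <- 0
  for (seed in 81:100) {
    inst <- rand_lr_instance(seed)
    e2 <- active_dialogs(inst$db, inst$expressed)
    if (length(unique(c(e2$ligand_cell, e2$receptor_cell))) < 2) next
    ov2 <- dialog_overlap(e2)
    if (is.null(ov2$venn)) next
    expect_equal(ov2$venn[names(oracle_venn(ov2$sets))], oracle_venn(ov2$sets))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("network export round-trips through SIF and writes valid GraphML", {
  db <- lr_database(c("Tgfb2", "Kitl"), c("Tgfbr2", "Kit"))
  expressed <- list(OC = c("Tgfb2", "Kit"), GC = c("Kitl", "Tgfbr2"))
  edges <- active_dialogs(db, expressed)
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif")
  export_network(edges, sif, "sif")
  back <- read_sif_network(sif)
  expect_equal(edges_key(back), edges_key(edges))
  # node count = distinct (gene, cell type, role) endpoints
  lines <- readLines(sif)
  nodes <- unique(unlist(lapply(strsplit(lines, "\t"), `[`, c(1, 3))))
  expect_equal(length(nodes),
               length(unique(c(paste(edges$ligand, edges$ligand_cell, "LIGAND"),
                               paste(edges$receptor, edges$receptor_cell, "RECEPTOR")))))
  skip_if_not_installed("xml2")
  gml <- file.path(dir, "net.graphml")
  export_network(edges, gml, "graphml")
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)), nrow(edges))
  roles <- xml2::xml_text(xml2::xml_find_all(doc, "//d1:data[@key='role']", ns))
  expect_setequal(unique(roles), c("LIGAND", "RECEPTOR"))
})
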