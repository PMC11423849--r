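make_two_group <- function(a_rows, b_rows, genes = NULL) {
  a <- do.call(rbind, a_rows); b <- do.call(rbind, b_rows)
  rownames(a) <- genes %||% sprintf("g%02d", seq_len(nrow(a)))
  group_expr(list(S1 = a, S2 = b))
}
cmp_s12 <- function() comparison("ADJACENT_STAGE", c("OC", "S1"), c("OC", "S2"))

test_that("the fold-change + p-value rule decides significance", {
  # means 10 vs 40 with ~1% CV: forced UP; 10 vs 15: FC below 2, never a DEG
  x <- make_two_group(list(c(9.9, 10, 10.1), c(9.9, 10, 10.1)),
                      list(c(39.6, 40, 40.4), c(14.8, 15, 15.2)))
  d <- test_differential(x, cmp_s12())
  expect_equal(d$direction, c("UP", "NONE"))
  expect_true(d$significant[1] && !d$significant[2])
  expect_equal(d$fc[1], (40 + 0.01) / (10 + 0.01), tolerance = 1e-6)

  # the rule is recomputable from (fc, p) for every record
  set.seed(21)
  big <- make_two_group(asplit(matrix(runif(150, 0, 30), 50), 1),
                        asplit(matrix(runif(150, 0, 30), 50), 1))
  db <- test_differential(big, cmp_s12())
  expect_equal(db$significant, unname(oracle_rule(db$fc, db$p)))
  expect_equal(db$direction == "UP", unname(db$significant & db$fc >= 2))
  expect_equal(db$direction == "DOWN", unname(db$significant & db$fc <= 0.5))
})

test_that("Welch p-values agree with stats::t.test gene by gene", {
  set.seed(22)
  a <- matrix(runif(40 * 3, 0, 50), 40)
  b <- matrix(runif(40 * 4, 0, 50), 40)
  x <- group_expr(list(S1 = a, S2 = b))
  d <- test_differential(x, cmp_s12())
  expect_equal(d$p, oracle_welch(a, b), tolerance = 1e-12)
})

test_that("swapping the groups flips direction and inverts the fold change", {
  set.seed(23)
  a <- matrix(runif(30 * 3, 1, 60), 30); b <- a * rep(c(5, 1, 0.1), each = 10)
  x <- group_expr(list(S1 = a, S2 = b))
  fwd <- test_differential(x, cmp_s12(), pseudocount = 0)
  rev <- test_differential(x, comparison("ADJACENT_STAGE", c("OC", "S2"), c("OC", "S1"),
                                         list(OC = c("S2", "S1"))), pseudocount = 0)
  expect_equal(rev$fc, 1 / fwd$fc)
  expect_equal(rev$direction[fwd$direction == "UP"],
               rep("DOWN", sum(fwd$direction == "UP")))
  expect_equal(rev$direction[fwd$direction == "DOWN"],
               rep("UP", sum(fwd$direction == "DOWN")))
})

test_that("single-replicate groups fall back to the fold-change rule with p = 0", {
  x <- make_two_group(list(c(10), c(10)), list(c(45), c(12)))
  d <- test_differential(x, cmp_s12())
  expect_true(attr(d, "single_replicate"))
  expect_equal(d$p, c(0, 0))
  expect_equal(d$direction, c("UP", "NONE"))
  # empty group is a hard error
  expect_error(test_differential(x, comparison("CROSS_CELLTYPE",
                                               c("GC", "S1"), c("OC", "S1"))),
               "empty group")
})

test_that("planted comparison is recovered exactly and matches the rule oracle", {
  cfg <- synth_config(seed = 7, noise_sd = 0.1,
                      planted_deg = data.frame(cell_type = "OC", stage = "T4",
                                               n = c(10, 10), log2fc = c(2, -2)),
                      planted_imprinted = 0)
  s <- generate_expression(cfg)
  m <- filter_low_expression(s$matrix)
  d <- test_differential(m, comparison("ADJACENT_STAGE", c("OC", "T3b"), c("OC", "T4")))
  expect_setequal(significant_genes(d), s$truth$deg$OC)
  expect_equal(d$significant, unname(oracle_rule(d$fc, d$p)))
})

test_that("adjacent scan covers every consecutive pair and finds the planted burst", {
  s <- generate_expression(synth_config(seed = 2))
  m <- filter_low_expression(s$matrix)
  scan <- adjacent_stage_scan(m, "OC")
  expect_length(scan, 8)           # nine stages -> eight comparisons
  expect_named(scan, c("OC:T2_vs_T1", "OC:T3a_vs_T2", "OC:T3b_vs_T3a",
                       "OC:T4_vs_T3b", "OC:T5a_vs_T4", "OC:T5b_vs_T5a",
                       "OC:T6_vs_T5b", "OC:T7_vs_T6"))
  counts <- deg_count_summary(scan)
  expect_equal(counts$comparison[which.max(counts$n_significant)], "OC:T4_vs_T3b")
  gc_counts <- deg_count_summary(adjacent_stage_scan(m, "GC"))
  expect_equal(gc_counts$comparison[which.max(gc_counts$n_significant)], "GC:T4_vs_T3b")

  # identical expression at all stages -> all significant sets empty
  flat <- group_expr(list(S1 = matrix(5, 3, 2), S2 = matrix(5, 3, 2)))
  expect_equal(sum(deg_count_summary(adjacent_stage_scan(flat, "OC"))$n_significant), 0L)
})

test_that("stage-specific DEGs equal the brute-force set difference", {
  # random scan: 5 comparisons over 50 genes, significance assigned directly
  set.seed(24)
  genes <- sprintf("g%02d", 1:50)
  fake_scan <- lapply(stats::setNames(1:5, paste0("c", 1:5)), function(i) {
    sig <- sample(genes, sample(5:20, 1))
    structure(data.frame(gene = genes, fc = ifelse(genes %in% sig, 4, 1),
                         p = ifelse(genes %in% sig, 0.001, 0.9),
                         direction = ifelse(genes %in% sig, "UP", "NONE"),
                         significant = genes %in% sig),
              class = c("deg_set", "data.frame"))
  })
  for (target in names(fake_scan)) {
    expected <- setdiff(fake_scan[[target]]$gene[fake_scan[[target]]$significant],
                        unique(unlist(lapply(fake_scan[setdiff(names(fake_scan), target)],
                                             function(d) d$gene[d$significant]))))
    got <- stage_specific_degs(fake_scan, target)
    expect_setequal(got, expected)
    expect_true(all(got %in% significant_genes(fake_scan[[target]])))
  }
  expect_error(stage_specific_degs(fake_scan, "nope"), "not in the scan")
})

test_that("pivot split partitions genes by pre/post expression weight", {
  m <- rbind(early = c(10, 10, 10, 0, 0), late = c(0, 0, 0, 10, 10))
  p <- stage_profiles(m, "OC", paste0("s", 1:5))
  sp <- split_by_pivot(c("early", "late"), p, "s4")
  expect_equal(sp$before, "early")
  expect_equal(sp$onward, "late")
  # partition property on random input
  set.seed(25)
  rm_ <- matrix(runif(200, 0, 20), 40, 5,
                dimnames = list(sprintf("r%02d", 1:40), paste0("s", 1:5)))
  rp <- stage_profiles(rm_, "OC")
  rs <- split_by_pivot(rownames(rm_), rp, "s3")
  expect_length(intersect(rs$before, rs$onward), 0)
  expect_setequal(c(rs$before, rs$onward), rownames(rm_))
  expect_error(split_by_pivot("r01", rp, "s1"), "first stage")
})

test_that("inheritance splits later DEG sets against the reference exactly", {
  mk <- function(sig, genes = sprintf("g%02d", 1:30))
    structure(data.frame(gene = genes, fc = 1, p = 1, direction = "NONE",
                         significant = genes %in% sig),
              class = c("deg_set", "data.frame"))
  ref <- sprintf("g%02d", 1:10)
  sets <- list(T4 = mk(ref), T5 = mk(ref), T6 = mk(sprintf("g%02d", 21:25)),
               T7 = mk(sprintf("g%02d", c(3, 9, 22, 28))))
  inh <- inheritance_analysis(sets, "T4")
  expect_equal(inh$summary$n_de_novo[inh$summary$comparison == "T5"], 0L)
  expect_equal(inh$summary$n_inherited[inh$summary$comparison == "T6"], 0L)
  expect_setequal(inh$genes$T7$inherited, c("g03", "g09"))
  expect_setequal(inh$genes$T7$de_novo, c("g22", "g28"))
  # partition: inherited + de novo = significant
  for (nm in names(inh$genes))
    expect_equal(inh$summary$n_inherited[inh$summary$comparison == nm] +
                 inh$summary$n_de_novo[inh$summary$comparison == nm],
                 sum(sets[[nm]]$significant))
  expect_error(inheritance_analysis(sets, "T3"), "not in the set list")
})

test_that("Venn region counts equal exhaustive membership enumeration", {
  expect_equal(overlap_venn(list(A = c("a", "b"), B = c("b", "c"))),
               c("A" = 1L, "B" = 1L, "A&B" = 1L))
  same <- list(A = c("x", "y"), B = c("x", "y"))
  v <- overlap_venn(same)
  expect_equal(unname(v["A&B"]), 2L)
  expect_equal(sum(v), 2L)
  for (seed in 1:25) {
    sets <- rand_gene_sets(seed)
    got <- overlap_venn(sets)
    ora <- oracle_venn(sets)
    expect_equal(got[names(ora)], ora)
    expect_equal(sum(got), length(unique(unlist(sets))))
  }
})
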