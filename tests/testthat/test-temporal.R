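test_that("model-profile enumeration has the right size and no duplicates", {
  # 3 stages, c = 1: 3^2 - 1 = 8 non-flat candidates
  all8 <- generate_model_profiles(3, c = 1, m = 8)
  expect_equal(nrow(all8$deltas), 8)
  expect_equal(anyDuplicated(apply(all8$deltas, 1, paste, collapse = ",")), 0L)
  expect_error(generate_model_profiles(3, c = 1, m = 9), "8")
  # values are cumulative sums starting at 0 with bounded steps
  mp <- generate_model_profiles(5, c = 2, m = 20)
  expect_true(all(mp$values[, 1] == 0))
  expect_true(all(abs(mp$values[, -1] - mp$values[, -5]) <= 2))
  expect_equal(mp$values[, -1] - mp$values[, -5], unname(mp$deltas))
})

test_that("greedy selection follows the deterministic first-pick and max-min rule", {
  mp <- generate_model_profiles(4, c = 1, m = 5)
  # independent reconstruction of the candidate space
  grid <- as.matrix(expand.grid(rep(list(-1:1), 3)))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]
  vals <- cbind(0, t(apply(grid, 1, cumsum)))
  D <- 1 - stats::cor(t(vals))
  key <- function(m) apply(m, 1, paste, collapse = ",")
  sel <- match(key(mp$deltas), key(unname(grid)))
  # first pick: largest |final value|, lexicographic ties
  finals <- abs(vals[, 4])
  expect_equal(sel[1], which(finals == max(finals))[1])
  # every later pick maximizes the min distance to the already-selected set
  for (k in 2:5) {
    cand_min <- apply(D[, sel[1:(k - 1)], drop = FALSE], 1, min)
    cand_min[sel[1:(k - 1)]] <- -Inf
    expect_equal(cand_min[sel[k]], max(cand_min), tolerance = 1e-12)
    expect_equal(sel[k], which(cand_min > max(cand_min) - 1e-12)[1])
  }
  # determinism: regeneration is bit-identical
  expect_identical(mp, generate_model_profiles(4, c = 1, m = 5))
})

test_that("genes are assigned to their best-correlated profile", {
  mp <- generate_model_profiles(6, c = 1, m = 10)
  stages <- paste0("s", 1:6)
  # a gene whose shifted log series equals a profile's values exactly
  target <- mp$values[4, ]
  fpkm <- rbind(exact = 2^(target + 3) - 1,
                flat = rep(7, 6))
  colnames(fpkm) <- stages
  asg <- assign_genes(mp, stage_profiles(fpkm, "OC"))
  expect_equal(asg$assignments$profile_id[asg$assignments$gene == "exact"], 4L)
  expect_equal(asg$assignments$correlation[asg$assignments$gene == "exact"], 1)
  expect_equal(asg$excluded, "flat")

  # 20 random genes vs a brute-force correlation argmax
  set.seed(31)
  rand <- matrix(2^matrix(rnorm(120, 3, 1), 20), 20,
                 dimnames = list(sprintf("r%02d", 1:20), stages)) - 1
  rand[rand < 0] <- 0
  got <- assign_genes(mp, stage_profiles(rand, "OC"))$assignments
  for (i in seq_len(nrow(got))) {
    series <- log2(rand[got$gene[i], ] + 1)
    cors <- apply(mp$values, 1, function(v) suppressWarnings(stats::cor(series, v)))
    expect_equal(got$profile_id[i], which.max(cors))
    expect_equal(got$correlation[i], max(cors), tolerance = 1e-12)
  }
  # empty gene set is allowed
  expect_equal(nrow(assign_genes(mp, stage_profiles(rand, "OC"),
                                 genes = character(0))$assignments), 0L)
})

test_that("permutation significance behaves at the extremes and is seed-stable", {
  mp <- generate_model_profiles(6, c = 1, m = 10)
  stages <- paste0("s", 1:6)
  # all genes identical to one profile: smallest attainable raw p
  one <- mp$values[2, ]
  fpkm <- matrix(rep(2^(one + 3) - 1, 30), 30, byrow = TRUE,
                 dimnames = list(sprintf("id%02d", 1:30), stages))
  res <- profile_significance(mp, stage_profiles(fpkm, "OC"),
                              n_perm = 150, seed = 4)
  expect_equal(res$profile_table$p_raw[2], 1 / 151)
  # a profile with zero observed count can never beat its null
  expect_true(all(res$profile_table$p_raw[res$profile_table$count == 0] > 0.5))
  # fixed seed fixes everything bit-for-bit
  res2 <- profile_significance(mp, stage_profiles(fpkm, "OC"),
                               n_perm = 150, seed = 4)
  expect_identical(res$profile_table, res2$profile_table)
})

test_that("pure-noise data stays within the calibration bound", {
  mp <- generate_model_profiles(6, c = 2, m = 50)
  set.seed(32)
  noise <- matrix(2^rnorm(200 * 6, 3, 1) - 1, 200, 6,
                  dimnames = list(sprintf("n%03d", 1:200), paste0("s", 1:6)))
  noise[noise < 0] <- 0
  res <- categorize(profile_significance(mp, stage_profiles(noise, "OC"),
                                         n_perm = 200, seed = 9), mp)
  sig_ids <- res$profile_table$profile_id[res$profile_table$significant]
  frac <- mean(res$assignments$profile_id %in% sig_ids)
  n <- nrow(res$assignments)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("profile categories follow the delta-sign rule and fractions sum to 1", {
  mp <- generate_model_profiles(4, c = 2, m = 10)
  fake <- list(assignments = data.frame(gene = sprintf("g%d", 1:10),
                                        profile_id = rep(1:5, 2),
                                        correlation = 1),
               excluded = character(0),
               profile_table = data.frame(profile_id = 1:10,
                                          deltas = apply(mp$deltas, 1, paste, collapse = ","),
                                          count = c(rep(2, 5), rep(0, 5)),
                                          p_raw = 0.001, p_corrected = 0.01,
                                          significant = c(rep(TRUE, 5), rep(FALSE, 5))),
               n_perm = 100, alpha = 0.05, seed = 1)
  class(fake) <- "cluster_result"
  out <- categorize(fake, mp)
  d <- mp$deltas
  for (i in 1:10) {
    expected <- if (!out$profile_table$significant[i]) "NON_SIGNIFICANT"
      else if (all(d[i, ] >= 0) && any(d[i, ] > 0)) "CONT_UP"
      else if (all(d[i, ] <= 0) && any(d[i, ] < 0)) "CONT_DOWN"
      else "FLUCTUATING"
    expect_equal(out$profile_table$category[i], expected)
  }
  expect_equal(sum(out$fractions), 1)
  # CONT_UP and CONT_DOWN profile sets are disjoint by construction
  expect_length(intersect(which(out$profile_table$category == "CONT_UP"),
                          which(out$profile_table$category == "CONT_DOWN")), 0)
})

test_that("planted monotone trends are recovered into monotone categories", {
  mp <- generate_model_profiles(9, c = 2, m = 50)
  set.seed(33)
  up <- t(sapply(1:100, function(i) cumsum(rep(1, 9)) + rnorm(9, 0, 0.2)))
  fpkm <- pmax(2^up - 1, 0)
  dimnames(fpkm) <- list(sprintf("u%03d", 1:100), default_stage_series()$OC)
  res <- categorize(profile_significance(mp, stage_profiles(fpkm, "OC"),
                                         n_perm = 2000, seed = 10), mp)
  up_ids <- res$profile_table$profile_id[res$profile_table$category == "CONT_UP"]
  expect_gte(mean(res$assignments$profile_id %in% up_ids), 0.95)
})
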