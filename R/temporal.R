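## Short time-series profile clustering in the STEM style: integer-step
## model profiles, correlation-based gene assignment, permutation
## significance with Bonferroni correction, and four-way categorization
## (continuously up / continuously down / fluctuating / non-significant).

## z-score matrix rows; rows with zero variance come back as NA rows.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  z <- (m - mu) / s
  z[s == 0, ] <- NA_real_
  z
}

#' Generate integer-step model expression profiles
#'
#' Enumerates every delta sequence in `[-c, c]^(n_stages - 1)`, drops the
#' flat (all-zero) profile, and greedily selects `m` maximally spread
#' profiles under the distance `1 - Pearson(values)`, where values are the
#' cumulative sums starting at 0. The first pick is the profile with the
#' largest absolute final value (ties: lexicographically smallest delta
#' sequence); later picks maximize the minimum distance to the selected
#' set, with the same tie-break. The procedure is fully deterministic.
#'
#' @param n_stages Number of stages (>= 3).
#' @param c Maximum unit change between consecutive stages.
#' @param m Number of profiles to select.
#' @return A `model_profiles` object: list with `deltas` (m x (n_stages-1)
#'   integer matrix), `values` (m x n_stages, cumulative sums), ids
#'   `1..m` in selection order, and the parameters.
#' @export
generate_model_profiles <- function(n_stages, c = 2, m = 50) {
  stopifnot(n_stages >= 3, c >= 1, m >= 1)
  steps <- (-c):c
  grid <- as.matrix(expand.grid(rep(list(steps), n_stages - 1)))
  colnames(grid) <- NULL
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]      # drop flat
  ord <- do.call(order, as.data.frame(grid))                # lexicographic
  grid <- grid[ord, , drop = FALSE]
  n_cand <- nrow(grid)
  if (m > n_cand)
    stop("m = ", m, " exceeds the number of distinct non-flat profiles (", n_cand, ")")
  values <- cbind(0, t(apply(grid, 1, cumsum)))
  z <- zscore_rows(values)                                   # all rows non-flat

  first <- which.max(abs(values[, n_stages]))                # lexicographic ties: which.max
  selected <- first
  mindist <- 1 - as.vector(z %*% z[first, ]) / (n_stages - 1)
  mindist[first] <- -Inf
  while (length(selected) < m) {
    nxt <- which.max(mindist)
    selected <- c(selected, nxt)
    d <- 1 - as.vector(z %*% z[nxt, ]) / (n_stages - 1)
    mindist <- pmin(mindist, d)
    mindist[nxt] <- -Inf
  }
  structure(list(deltas = grid[selected, , drop = FALSE],
                 values = values[selected, , drop = FALSE],
                 id = seq_len(m), n_stages = n_stages, c = c, m = m),
            class = "model_profiles")
}

#' @export
print.model_profiles <- function(x, ...) {
  cat(sprintf("model_profiles: %d profiles over %d stages (c = %d)\n",
              x$m, x$n_stages, x$c))
  invisible(x)
}

#' Assign genes to their best-correlated model profile
#'
#' Each gene's series is taken as `log2(FPKM + 1)` shifted to start at 0
#' (first-stage value subtracted) and assigned to the model profile with
#' maximal Pearson correlation of value vectors; ties go to the lowest
#' profile id. Genes whose transformed series has zero variance cannot be
#' correlated and are excluded with a flag.
#'
#' @param profiles A `model_profiles` with `n_stages` equal to the series
#'   length.
#' @param series A `stage_profiles`.
#' @param genes Optional subset of genes to assign (default: all).
#' @return A `profile_assignment`: list with `assignments` (data frame
#'   `gene`, `profile_id`, `correlation`) and `excluded` (zero-variance
#'   genes).
#' @export
assign_genes <- function(profiles, series, genes = NULL) {
  stopifnot(inherits(profiles, "model_profiles"), inherits(series, "stage_profiles"))
  if (profiles$n_stages != length(series$stages))
    stop("profiles span ", profiles$n_stages, " stages but the series has ",
         length(series$stages))
  mat <- series$profiles
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(mat))
    if (length(missing)) stop("gene(s) absent from the series: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    mat <- mat[genes, , drop = FALSE]
  }
  if (nrow(mat) == 0)
    return(structure(list(assignments = data.frame(gene = character(),
                                                   profile_id = integer(),
                                                   correlation = numeric()),
                          excluded = character()),
                     class = "profile_assignment"))
  lg <- log2p1(mat)
  lg <- lg - lg[, 1]                       # anchor at 0 like the model profiles
  zg <- zscore_rows(lg)
  flat <- is.na(zg[, 1])
  excluded <- rownames(mat)[flat]
  zg <- zg[!flat, , drop = FALSE]
  zp <- zscore_rows(profiles$values)
  cors <- zg %*% t(zp) / (ncol(lg) - 1)    # genes x profiles
  best <- max.col(cors, ties.method = "first")
  structure(list(assignments = data.frame(gene = rownames(zg),
                                          profile_id = profiles$id[best],
                                          correlation = cors[cbind(seq_len(nrow(cors)), best)],
                                          row.names = NULL),
                 excluded = excluded),
            class = "profile_assignment")
}

#' Permutation significance of profile gene counts
#'
#' The null permutes each gene's stage order independently in every
#' iteration and re-assigns all genes; a profile's raw p-value is the
#' add-one-smoothed fraction of permutations whose assigned count reaches
#' the observed count, Bonferroni-corrected across the `m` profiles.
#'
#' @param profiles A `model_profiles`.
#' @param series A `stage_profiles`.
#' @param assignment Observed assignment (computed if not supplied).
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level applied to the corrected p-value.
#' @param seed RNG seed; fixes the result bit-for-bit.
#' @return A `cluster_result`: list with `assignments`, `profile_table`
#'   (profile_id, deltas, count, p_raw, p_corrected, significant),
#'   `excluded`, and the parameters.
#' @export
profile_significance <- function(profiles, series,
                                 assignment = assign_genes(profiles, series),
                                 n_perm = 500, alpha = 0.05, seed = 1) {
  stopifnot(n_perm >= 100)
  obs <- tabulate(match(assignment$assignments$profile_id, profiles$id),
                  nbins = profiles$m)
  genes <- assignment$assignments$gene
  lg <- log2p1(series$profiles[genes, , drop = FALSE])
  n_stage <- ncol(lg)
  zp <- zscore_rows(profiles$values)
  exceed <- integer(profiles$m)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (b in seq_len(n_perm)) {
    perm <- t(apply(lg, 1, function(v) v[sample.int(n_stage)]))
    zg <- zscore_rows(perm)
    ok <- !is.na(zg[, 1])
    cnt <- integer(profiles$m)
    if (any(ok)) {
      cors <- zg[ok, , drop = FALSE] %*% t(zp) / (n_stage - 1)
      best <- max.col(cors, ties.method = "first")
      cnt <- tabulate(best, nbins = profiles$m)
    }
    exceed <- exceed + (cnt >= obs)
  }
  p_raw <- (exceed + 1) / (n_perm + 1)
  p_corr <- pmin(1, p_raw * profiles$m)
  tab <- data.frame(profile_id = profiles$id,
                    deltas = apply(profiles$deltas, 1, paste, collapse = ","),
                    count = obs, p_raw = p_raw, p_corrected = p_corr,
                    significant = p_corr <= alpha,
                    row.names = NULL)
  structure(list(assignments = assignment$assignments,
                 excluded = assignment$excluded,
                 profile_table = tab,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "cluster_result")
}

#' Categorize model profiles into the four temporal patterns
#'
#' A significant profile with all deltas `>= 0` (at least one positive) is
#' continuously up; all `<= 0` (at least one negative) continuously down;
#' any other significant profile is fluctuating; non-significant profiles
#' are their own category. Gene-level fractions are taken over all
#' clustered genes and sum to 1.
#'
#' @param result A `cluster_result`.
#' @param profiles The `model_profiles` the result was built from.
#' @return The `cluster_result` with `profile_table$category` and
#'   `fractions` (named over CONT_UP, CONT_DOWN, FLUCTUATING,
#'   NON_SIGNIFICANT) added.
#' @export
categorize <- function(result, profiles) {
  stopifnot(inherits(result, "cluster_result"), inherits(profiles, "model_profiles"))
  d <- profiles$deltas
  up <- apply(d, 1, function(r) all(r >= 0) && any(r > 0))
  down <- apply(d, 1, function(r) all(r <= 0) && any(r < 0))
  sig <- result$profile_table$significant
  category <- ifelse(!sig, "NON_SIGNIFICANT",
                     ifelse(up, "CONT_UP", ifelse(down, "CONT_DOWN", "FLUCTUATING")))
  result$profile_table$category <- category
  gene_cat <- category[match(result$assignments$profile_id, profiles$id)]
  lv <- c("CONT_UP", "CONT_DOWN", "FLUCTUATING", "NON_SIGNIFICANT")
  n <- length(gene_cat)
  result$fractions <- if (n) table(factor(gene_cat, levels = lv)) / n
                      else table(factor(character(), levels = lv))
  result$fractions <- as.numeric(result$fractions)
  names(result$fractions) <- lv
  result
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d genes over %d profiles; %d significant profiles (alpha = %g, %d permutations)\n",
              nrow(x$assignments), nrow(x$profile_table),
              sum(x$profile_table$significant), x$alpha, x$n_perm))
  if (!is.null(x$fractions)) {
    cat("gene fractions:\n")
    print(round(x$fractions, 4))
  }
  invisible(x)
}

#' One-call temporal clustering of a stage series
#'
#' Convenience wrapper: generates model profiles, assigns genes, runs the
#' permutation test and categorizes.
#'
#' @inheritParams profile_significance
#' @inheritParams generate_model_profiles
#' @param genes Optional gene subset.
#' @return A categorized `cluster_result` with the `model_profiles`
#'   attached as `$profiles`.
#' @export
cluster_timeseries <- function(series, c = 2, m = 50, genes = NULL,
                               n_perm = 500, alpha = 0.05, seed = 1) {
  profiles <- generate_model_profiles(length(series$stages), c = c, m = m)
  asg <- assign_genes(profiles, series, genes = genes)
  res <- profile_significance(profiles, series, assignment = asg,
                              n_perm = n_perm, alpha = alpha, seed = seed)
  res <- categorize(res, profiles)
  res$profiles <- profiles
  res
}

#' Write cluster reports
#'
#' @param result A categorized `cluster_result`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param header_lines Optional comment lines.
#' @export
write_cluster_reports <- function(result, dir, prefix = "cluster",
                                  header_lines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(result$assignments,
                 file.path(dir, paste0(prefix, "_genes.tsv")), header_lines)
  write_tsv_file(result$profile_table,
                 file.path(dir, paste0(prefix, "_profiles.tsv")), header_lines)
  invisible(dir)
}
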