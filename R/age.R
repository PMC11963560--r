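#' Global CpG methylation comparison across age groups
#'
#' Computes each sample's global mean CpG level, averages within groups, and
#' runs two-sided rank-sum tests between every pair of groups. A pairwise
#' test involving a single-sample group is reported as not applicable
#' (`p_value = NA`, `applicable = FALSE`) rather than attempted.
#'
#' @param tables named list of `cgmap` data.frames (names = sample ids).
#' @param metadata data.frame with `sample_id` and `group` columns.
#' @param context dinucleotide class (default `"CG"`).
#' @return list: `sample_means` (data.frame), `group_means` (named vector),
#'   `pairwise` (data.frame with `group_a`, `group_b`, `difference`,
#'   `p_value`, `applicable`).
#' @export
group_global_comparison <- function(tables, metadata, context = "CG") {
  metadata <- as.data.frame(metadata)
  stopifnot(all(metadata$sample_id %in% names(tables)))
  groups <- unique(as.character(metadata$group))
  if (length(groups) < 2L) fail("need at least two groups")
  sm <- data.frame(sample_id = metadata$sample_id,
                   group = as.character(metadata$group),
                   mean_level = vapply(metadata$sample_id, function(s) {
                     tab <- tables[[s]]
                     mean_or_na(tab$level[tab$dinuc == context])
                   }, numeric(1)), stringsAsFactors = FALSE)
  gmeans <- vapply(groups, function(g) mean(sm$mean_level[sm$group == g]),
                   numeric(1))
  pairs <- utils::combn(groups, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    xa <- sm$mean_level[sm$group == ga]
    xb <- sm$mean_level[sm$group == gb]
    applicable <- length(xa) > 1L && length(xb) > 1L
    p <- if (applicable) compare_context_distributions(xa, xb)$p_value else NA_real_
    data.frame(group_a = ga, group_b = gb,
               difference = mean(xa) - mean(xb), p_value = p,
               applicable = applicable, stringsAsFactors = FALSE)
  }))
  list(sample_means = sm, group_means = gmeans, pairwise = pw)
}

#' Per-position permutation test of group mean differences
#'
#' For each position (row), the observed statistic is the group A mean minus
#' the group B mean. Sample labels are then permuted jointly across all
#' positions (one relabeling per draw, group sizes fixed) and the two-tailed
#' empirical p-value at each position is the proportion of permuted absolute
#' differences at least as extreme as the observed one. Permutations are
#' sampled with replacement from the label-assignment space. Positions with
#' missing values are skipped and reported.
#'
#' @param profiles numeric matrix, positions x samples, with column names.
#' @param group_a,group_b character vectors of sample (column) names; must
#'   together cover disjoint, non-empty column sets.
#' @param n_permutations number of label permutations (default 100000).
#' @param seed integer seed (required).
#' @param alpha per-position significance level used for flagging
#'   (default 0.05).
#' @param p_correction `"none"` reports the plain proportion b/n (so p can be
#'   0); `"add_one"` reports (b + 1) / (n + 1), which cannot be 0.
#' @param block permutations are processed in blocks of this size to bound
#'   memory.
#' @return object of class `permutation_result`: data.frame `table` with
#'   `position`, `delta_obs`, `p_value`, `significant`; plus `n_permutations`,
#'   `seed`, `group_sizes`, `skipped` (positions with missing data).
#' @export
permutation_test_positions <- function(profiles, group_a, group_b,
                                       n_permutations = 100000L, seed,
                                       alpha = 0.05,
                                       p_correction = c("none", "add_one"),
                                       block = 10000L) {
  p_correction <- match.arg(p_correction)
  if (missing(seed) || is.null(seed)) fail("a seed is required")
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles))) fail("profiles must have sample column names")
  if (length(group_a) == 0L || length(group_b) == 0L) fail("empty group")
  if (anyDuplicated(c(group_a, group_b))) fail("groups overlap")
  if (!all(c(group_a, group_b) %in% colnames(profiles)))
    fail("group sample missing from profile columns")
  x <- profiles[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a)
  nb <- length(group_b)
  n <- na + nb

  complete <- rowSums(is.na(x)) == 0L
  skipped <- which(!complete)
  xc <- x[complete, , drop = FALSE]
  npos <- nrow(xc)

  w_obs <- c(rep(1 / na, na), rep(-1 / nb, nb))
  delta_obs <- as.numeric(xc %*% w_obs)

  set.seed(seed)
  exceed <- numeric(npos)
  done <- 0L
  while (done < n_permutations) {
    m <- min(block, n_permutations - done)
    ## one column per permutation: +1/na on the na samples drawn into group A
    W <- vapply(seq_len(m), function(i) {
      idx <- sample.int(n, na)
      w <- rep(-1 / nb, n)
      w[idx] <- 1 / na
      w
    }, numeric(n))
    d_perm <- abs(xc %*% W)
    ## "as extreme as" must count exact ties (e.g. the identity relabeling);
    ## different BLAS paths can disagree in the last ulp, so compare with a
    ## tolerance far below any data resolution
    exceed <- exceed + rowSums(d_perm >= abs(delta_obs) - 1e-12)
    done <- done + m
  }
  p <- if (p_correction == "none") exceed / n_permutations
       else (exceed + 1) / (n_permutations + 1)

  tab <- data.frame(position = which(complete), delta_obs = delta_obs,
                    p_value = p, significant = p < alpha)
  structure(list(table = tab, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alpha = alpha,
                 group_sizes = c(a = na, b = nb), skipped = skipped,
                 p_correction = p_correction),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation_result: %d positions, %d vs %d samples, ",
                     "%d permutations (seed %d)\n  %d position(s) with p < %g",
                     "%s\n"),
              nrow(x$table), x$group_sizes["a"], x$group_sizes["b"],
              x$n_permutations, x$seed, sum(x$table$significant), x$alpha,
              if (length(x$skipped)) sprintf("; %d skipped (missing values)",
                                             length(x$skipped)) else ""))
  invisible(x)
}

#' Two-dimensional UMAP embedding of samples
#'
#' Embeds the samples (columns) of a complete methylation matrix with UMAP.
#' Deterministic for a fixed seed (single-threaded).
#'
#' @param mat a complete [methylation_matrix()] (impute first), or a plain
#'   sites x samples numeric matrix.
#' @param n_neighbors UMAP neighbourhood size (default 5; must be below the
#'   number of samples).
#' @param seed integer seed (required).
#' @return matrix of sample coordinates (samples x 2, rownames = sample ids).
#' @export
embed_samples <- function(mat, n_neighbors = 5L, seed) {
  if (missing(seed) || is.null(seed)) fail("a seed is required")
  v <- if (inherits(mat, "methylation_matrix")) mat$values else as.matrix(mat)
  if (anyNA(v)) fail("matrix has missing values; impute before embedding")
  n <- ncol(v)
  if (n < n_neighbors + 1L)
    fail("need at least n_neighbors + 1 = %d samples, have %d; reduce n_neighbors",
         n_neighbors + 1L, n)
  set.seed(seed)
  emb <- uwot::umap(t(v), n_neighbors = n_neighbors, n_threads = 1,
                    n_sgd_threads = 1)
  rownames(emb) <- colnames(v)
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

#' Leave-one-out cross-validated Lasso epigenetic clock
#'
#' For each sample in turn, fits an L1-penalized linear regression of age on
#' methylation levels using the remaining samples (the penalty chosen by an
#' inner leave-one-out CV over `penalty_grid` on the training fold) and
#' predicts the held-out sample's age. Reports held-out predictions, the
#' Pearson correlation between predicted and actual ages, and the sites
#' selected by a final full-data fit.
#'
#' The clock-validity `p_value` is one-sided for positive association: a
#' clock has predictive skill only when predicted and actual ages correlate
#' positively. Under a null (age-uninformative) matrix, leave-one-out
#' cross-validation of a penalized model is known to produce spurious
#' negative correlations -- folds that shrink to the intercept predict
#' `mean(ages[-i])`, which is perfectly anti-correlated with the held-out
#' age -- so a two-sided test (also reported, as `p_two_sided`) can flag a
#' useless clock as "significant". The one-sided test treats that
#' anti-correlation as what it is: absence of predictive skill.
#'
#' @param mat a complete [methylation_matrix()] or sites x samples matrix.
#' @param ages_days numeric ages (one per sample, same order as columns);
#'   at least two distinct values.
#' @param penalty_grid candidate Lasso penalties (decreasing); default a log
#'   grid from 10 to 0.001.
#' @param seed optional; the fit itself is deterministic, the seed is stored
#'   for provenance.
#' @return object of class `methylation_clock` with elements `predictions`
#'   (data.frame `sample`, `age`, `predicted`), `r`, `p_value`,
#'   `selected_sites`, `lambda`.
#' @export
fit_clock_loocv <- function(mat, ages_days,
                            penalty_grid = 10^seq(1, -3, length.out = 40),
                            seed = NULL) {
  v <- if (inherits(mat, "methylation_matrix")) mat$values else as.matrix(mat)
  sites <- if (inherits(mat, "methylation_matrix")) mat$sites else NULL
  if (anyNA(v)) fail("matrix has missing values; impute first")
  n <- ncol(v)
  if (n < 3L) fail("need at least 3 samples for a leave-one-out clock")
  if (length(ages_days) != n) fail("one age per sample required")
  if (length(unique(ages_days)) < 2L) fail("ages are all equal; clock undefined")
  X <- t(v)  # samples x sites
  ages <- as.numeric(ages_days)
  lambda <- sort(penalty_grid, decreasing = TRUE)

  inner_cv_lambda <- function(Xtr, ytr) {
    ntr <- nrow(Xtr)
    err <- matrix(NA_real_, ntr, length(lambda))
    for (j in seq_len(ntr)) {
      fit <- glmnet::glmnet(Xtr[-j, , drop = FALSE], ytr[-j], alpha = 1,
                            lambda = lambda)
      pred <- stats::predict(fit, Xtr[j, , drop = FALSE], s = lambda)
      err[j, ] <- (as.numeric(pred) - ytr[j])^2
    }
    lambda[which.min(colMeans(err))]
  }

  preds <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- ages[-i]
    lam <- inner_cv_lambda(Xtr, ytr)
    fit <- glmnet::glmnet(Xtr, ytr, alpha = 1, lambda = lambda)
    preds[i] <- as.numeric(stats::predict(fit, X[i, , drop = FALSE], s = lam))
  }

  ct <- if (sd(preds) > 0) cor.test(preds, ages, alternative = "greater") else NULL
  ct2 <- if (sd(preds) > 0) cor.test(preds, ages) else NULL
  lam_full <- inner_cv_lambda(X, ages)
  fit_full <- glmnet::glmnet(X, ages, alpha = 1, lambda = lambda)
  beta <- as.matrix(coef(fit_full, s = lam_full))[-1, 1]
  sel <- which(beta != 0)
  selected <- if (!is.null(sites)) cbind(sites[sel, , drop = FALSE],
                                         coefficient = beta[sel])
              else data.frame(site = sel, coefficient = beta[sel])

  structure(list(
    predictions = data.frame(sample = colnames(v) %||% paste0("s", seq_len(n)),
                             age = ages, predicted = preds),
    r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
    p_value = if (is.null(ct)) NA_real_ else ct$p.value,
    p_two_sided = if (is.null(ct2)) NA_real_ else ct2$p.value,
    selected_sites = selected, lambda = lam_full,
    penalty_grid = lambda, seed = seed),
    class = "methylation_clock")
}

#' @export
print.methylation_clock <- function(x, ...) {
  cat(sprintf(paste0("Lasso LOOCV epigenetic clock: %d samples, %d selected ",
                     "site(s) at lambda = %.4g\n  held-out r(predicted, actual)",
                     " = %.3f (p = %.3g)\n"),
              nrow(x$predictions), nrow(x$selected_sites), x$lambda,
              x$r, x$p_value))
  invisible(x)
}

#' @export
coef.methylation_clock <- function(object, ...) object$selected_sites

#' @export
predict.methylation_clock <- function(object, ...) object$predictions

#' @export
plot.methylation_clock <- function(x, ...) {
  p <- x$predictions
  plot(p$age, p$predicted, xlab = "chronological age (days)",
       ylab = "predicted age (days)",
       main = sprintf("LOOCV clock, r = %.2f", x$r), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Per-gene linear regression of methylation on age
#'
#' Ordinary least squares of each gene's mean methylation level on age, with
#' two-sided slope p-values and Benjamini-Hochberg adjustment across genes.
#' Constant genes are reported with slope 0 and p = 1, flagged degenerate.
#'
#' @param gene_means numeric matrix, genes x samples (rownames = gene ids).
#' @param ages_days numeric ages, one per sample; at least two distinct.
#' @return data.frame: `gene_id`, `slope`, `intercept`, `p_value`, `q_value`,
#'   `degenerate`.
#' @export
gene_age_regression <- function(gene_means, ages_days) {
  gene_means <- as.matrix(gene_means)
  n <- ncol(gene_means)
  if (length(ages_days) != n) fail("one age per sample required")
  if (n < 3L) fail("need at least 3 samples")
  if (length(unique(ages_days)) < 2L) fail("ages are constant")
  ages <- as.numeric(ages_days)
  out <- do.call(rbind, lapply(seq_len(nrow(gene_means)), function(i) {
    y <- gene_means[i, ]
    ok <- !is.na(y)
    if (sum(ok) < 3L || sd(y[ok]) == 0) {
      return(data.frame(slope = 0, intercept = mean_or_na(y[ok]),
                        p_value = 1, degenerate = TRUE))
    }
    x <- ages[ok]; yv <- y[ok]
    xcent <- x - mean(x)
    slope <- sum(xcent * yv) / sum(xcent^2)
    intercept <- mean(yv) - slope * mean(x)
    resid <- yv - intercept - slope * x
    df <- sum(ok) - 2L
    se <- sqrt(sum(resid^2) / df / sum(xcent^2))
    tval <- if (se == 0) Inf else slope / se
    p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
    data.frame(slope = slope, intercept = intercept, p_value = p,
               degenerate = FALSE)
  }))
  out <- cbind(gene_id = rownames(gene_means) %||% paste0("gene", seq_len(nrow(gene_means))),
               out, stringsAsFactors = FALSE)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[, c("gene_id", "slope", "intercept", "p_value", "q_value", "degenerate")]
}
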