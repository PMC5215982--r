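#' Rank genes by SVM recursive feature elimination
#'
#' Trains a linear maximum-margin classifier on the surviving genes,
#' removes the gene(s) with the smallest squared weight, and repeats until
#' no gene remains; the reversed elimination order gives the ranks (rank 1
#' = eliminated last = most important). Genes are standardized to mean 0 /
#' SD 1 across samples before fitting; a gene with zero variance gets
#' weight 0 and is eliminated first. Ties on the squared weight are broken
#' by removing the lexicographically smallest gene ID, so the ranking is
#' deterministic.
#'
#' @param expr An [expression_matrix()] or a numeric genes x samples matrix
#'   with rownames.
#' @param labels Per-sample +1/-1 labels; taken from `expr` when omitted.
#' @param step Genes eliminated per iteration: an integer >= 1, or a
#'   fraction in (0, 1) removing that share of the surviving genes (at
#'   least one) per iteration — a faster approximation for large panels.
#' @param cost Soft-margin cost parameter of the linear SVM.
#' @return Integer ranks named by gene ID (1 = most important).
#' @export
svm_rfe_rank <- function(expr, labels = NULL, step = 1, cost = 1) {
  v <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (is.null(labels) && inherits(expr, "expression_matrix"))
    labels <- expr$labels
  if (is.null(labels)) stop("labels required")
  if (!all(is.finite(v))) stop("expression values must be finite")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in `labels`")
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%04d", seq_len(nrow(v)))
  y <- factor(labels, levels = c(-1, 1))
  X <- t(v)
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0  # constant genes carry no signal
  elim <- character(0)
  surviving <- sort(rownames(v))
  while (length(surviving) > 0L) {
    if (length(surviving) == 1L) {
      elim <- c(elim, surviving)
      break
    }
    fit <- e1071::svm(X[, surviving, drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE)
    w2 <- as.vector(crossprod(fit$coefs, fit$SV))^2
    names(w2) <- colnames(fit$SV)
    w2 <- w2[surviving]
    k <- if (step < 1) max(1L, floor(step * length(surviving)))
         else min(as.integer(step), length(surviving) - 1L)
    # order ascending by weight, then by gene ID (surviving is sorted)
    drop_idx <- order(w2)[seq_len(k)]
    dropped <- surviving[drop_idx][order(w2[drop_idx], decreasing = FALSE)]
    elim <- c(elim, dropped)
    surviving <- setdiff(surviving, dropped)
  }
  ranks <- stats::setNames(rev(seq_along(elim)), elim)
  ranks[rownames(v)]
}

#' Bootstrap rank-score table
#'
#' Draws `n_boot` bootstrap resamples of the samples (with replacement,
#' stratified within class so both classes always appear), runs
#' [svm_rfe_rank()] on each, and converts the rank p of each gene to its
#' rank score `(N + 1 - p) / N`, where N is the total gene count, so the
#' best rank scores 1 and the worst 1/N.
#'
#' @inheritParams svm_rfe_rank
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer seed for the resampling.
#' @return A `rank_score_table`: numeric G x n_boot matrix of rank scores
#'   with attributes `N` and `n_boot`.
#' @export
bootstrap_rank_scores <- function(expr, labels = NULL, n_boot = 100,
                                  seed = NULL, step = 1, cost = 1) {
  if (n_boot < 2L) stop("n_boot must be >= 2")
  v <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (is.null(labels) && inherits(expr, "expression_matrix"))
    labels <- expr$labels
  if (is.null(labels)) stop("labels required")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in `labels`")
  N <- nrow(v)
  idx_by_class <- split(seq_along(labels), labels)
  with_seed(seed, {
    scores <- matrix(NA_real_, N, n_boot,
                     dimnames = list(rownames(v), NULL))
    for (j in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_class, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      p <- svm_rfe_rank(v[, take, drop = FALSE], labels[take],
                        step = step, cost = cost)
      scores[, j] <- (N + 1 - p) / N
    }
    structure(scores, N = N, n_boot = n_boot, class = "rank_score_table")
  })
}

#' Test each gene's informativeness from its bootstrap rank scores
#'
#' The rank-score distribution of an uninformative gene is symmetric about
#' the median of the rank-score support, Q = (N + 1) / (2N). For each gene
#' the one-sided signed-rank test ([signed_rank_test()]) is applied to its
#' bootstrap rank scores with center Q; small p-values indicate genes
#' consistently ranked near the top. A gene whose scores all equal Q is
#' reported with `p_value = NA` and a note rather than aborting the batch.
#'
#' @param table A `rank_score_table` from [bootstrap_rank_scores()].
#' @return Data frame with columns `gene_id`, `mean_rank_score`, `t_plus`,
#'   `z`, `p_value`, `n_effective`, `p_adjusted` (Benjamini-Hochberg) and
#'   `note`.
#' @export
test_gene_informativeness <- function(table) {
  stopifnot(inherits(table, "rank_score_table"))
  N <- attr(table, "N")
  Q <- (N + 1) / (2 * N)
  res <- lapply(rownames(table), function(g) {
    out <- tryCatch(signed_rank_test(table[g, ], Q), error = function(e) e)
    if (inherits(out, "error"))
      data.frame(gene_id = g, mean_rank_score = mean(table[g, ]),
                 t_plus = NA_real_, z = NA_real_, p_value = NA_real_,
                 n_effective = 0L, note = conditionMessage(out))
    else
      data.frame(gene_id = g, mean_rank_score = mean(table[g, ]),
                 t_plus = out$t_plus, z = out$z, p_value = out$p_value,
                 n_effective = out$n_effective, note = NA_character_)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}

#' Per-gene Welch two-sample t-test p-values
#'
#' Unequal-variance two-sided t-test of each gene between the +1 and -1
#' classes, vectorized over genes. A gene with zero variance in both
#' classes gets p = 1 when the class means are equal and p = 0 otherwise.
#'
#' @inheritParams svm_rfe_rank
#' @return Named numeric vector of two-sided p-values.
#' @export
welch_t_pvalues <- function(expr, labels = NULL) {
  v <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (is.null(labels) && inherits(expr, "expression_matrix"))
    labels <- expr$labels
  g1 <- v[, labels == 1, drop = FALSE]
  g2 <- v[, labels == -1, drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per class")
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1L, stats::var); v2 <- apply(g2, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

#' Gene selection from the two significance axes
#'
#' A gene is selected when both `-log10` p-values clear their thresholds:
#' the bootstrap signed-rank p at `x_threshold` (default 2.5) and the
#' Welch t-test p at `y_threshold` (default 4); boundaries are inclusive.
#' Zero p-values are floored at the smallest positive double before the
#' logarithm.
#'
#' @param results_boot Data frame from [test_gene_informativeness()].
#' @param results_t Named p-value vector from [welch_t_pvalues()] (or a
#'   data frame with `gene_id` and `p_value`).
#' @param x_threshold Threshold on `-log10` of the bootstrap p-value.
#' @param y_threshold Threshold on `-log10` of the t-test p-value.
#' @return Data frame with `gene_id`, `neglog10_p_boot`, `neglog10_p_t`
#'   and `selected`.
#' @export
gene_selection <- function(results_boot, results_t,
                           x_threshold = 2.5, y_threshold = 4) {
  if (is.data.frame(results_t))
    results_t <- stats::setNames(results_t$p_value, results_t$gene_id)
  if (!setequal(results_boot$gene_id, names(results_t)))
    stop("gene sets of the two result tables differ")
  pt_ <- results_t[results_boot$gene_id]
  floor_p <- function(p) pmax(p, .Machine$double.xmin)
  nlb <- -log10(floor_p(results_boot$p_value))
  nlt <- -log10(floor_p(pt_))
  data.frame(gene_id = results_boot$gene_id,
             neglog10_p_boot = nlb, neglog10_p_t = unname(nlt),
             selected = !is.na(nlb) & nlb >= x_threshold & nlt >= y_threshold)
}
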