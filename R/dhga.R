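#' Subsample weighted gene scores
#'
#' Draws `S` random subsamples of `m` of the `M` samples (without
#' replacement within a subsample by default), rebuilds the weighted
#' co-expression network on each, and records every gene's weighted gene
#' score. Also computes the full-data network's scores and their mean
#' `mu`, the average connection degree of the complete network that
#' serves as the null center for the hub test. A gene whose expression is
#' constant within a subsample contributes zero similarity there.
#'
#' @param expr An [expression_matrix()] or genes x samples matrix.
#' @param beta Soft-threshold power.
#' @param S Number of subsamples.
#' @param m Samples per subsample (3 <= m <= M); defaults to
#'   `ceiling(0.7 * M)`.
#' @param seed Integer seed.
#' @param replace Draw samples with replacement within a subsample.
#' @return An object of class `subsample_wgs`: list with `wgs_matrix`
#'   (S x G), `wgs_full`, `mu`, `m`, `S`, `beta`.
#' @export
subsample_wgs <- function(expr, beta, S = 500, m = NULL, seed = NULL,
                          replace = FALSE) {
  v <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%04d", seq_len(nrow(v)))
  M <- ncol(v)
  if (is.null(m)) m <- ceiling(0.7 * M)
  if (m < 3L) stop("m must be >= 3 (correlation degenerate below)")
  if (m > M) stop("m must be <= number of samples")
  if (S < 2L) stop("S must be >= 2")
  wgs_of <- function(cols) {
    sub <- v[, cols, drop = FALSE]
    s <- suppressWarnings(abs(stats::cor(t(sub))))
    s[!is.finite(s)] <- 0
    diag(s) <- 1
    weighted_gene_score(adjacency_matrix(s, beta))
  }
  wgs_full <- wgs_of(seq_len(M))
  with_seed(seed, {
    wgs_matrix <- t(vapply(seq_len(S), function(k)
      wgs_of(sample.int(M, m, replace = replace)),
      numeric(nrow(v))))
    colnames(wgs_matrix) <- rownames(v)
    structure(list(wgs_matrix = wgs_matrix, wgs_full = wgs_full,
                   mu = mean(wgs_full), m = m, S = S, beta = beta),
              class = "subsample_wgs")
  })
}

#' @export
print.subsample_wgs <- function(x, ...) {
  cat("Subsample connectivity:", x$S, "subsamples of", x$m, "samples,",
      ncol(x$wgs_matrix), "genes, beta =", x$beta, "\n")
  cat("  mean connectivity of full network (mu):", signif(x$mu, 4), "\n")
  invisible(x)
}

#' Hub-gene significance test
#'
#' For each gene, the one-sided signed-rank test ([signed_rank_test()]) is
#' applied to its subsample connectivity values centered at `mu`, the mean
#' connectivity of the complete network: a small p-value means the gene's
#' connectivity consistently exceeds the network average, i.e. the gene is
#' a hub. The classical indicator rule (connectivity above the average,
#' `wgs_full > mu`) is evaluated alongside for comparison. A gene whose
#' subsample scores all equal `mu` is reported with p = 1 and a degenerate
#' flag.
#'
#' @param sub A `subsample_wgs` object.
#' @return Data frame of class `hub_test` with columns `gene_id`,
#'   `wgs_full`, `w_plus`, `z`, `p_value`, `p_adjusted`, `n_effective`,
#'   `degenerate`, `hub_existing`.
#' @export
hub_significance <- function(sub) {
  stopifnot(inherits(sub, "subsample_wgs"))
  genes <- colnames(sub$wgs_matrix)
  res <- lapply(genes, function(g) {
    out <- tryCatch(signed_rank_test(sub$wgs_matrix[, g], sub$mu),
                    error = function(e) e)
    if (inherits(out, "error"))
      data.frame(gene_id = g, wgs_full = sub$wgs_full[g],
                 w_plus = NA_real_, z = NA_real_, p_value = 1,
                 n_effective = 0L, degenerate = TRUE)
    else
      data.frame(gene_id = g, wgs_full = sub$wgs_full[g],
                 w_plus = out$t_plus, z = out$z, p_value = out$p_value,
                 n_effective = out$n_effective, degenerate = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$hub_existing <- res$wgs_full > sub$mu
  rownames(res) <- NULL
  class(res) <- c("hub_test", "data.frame")
  res
}

#' Differential hub gene classification
#'
#' Classifies each gene from its hub-test p-values under two conditions:
#' hub in both (`housekeeping_hub`), hub only under stress
#' (`unique_hub_stress`), hub only under control (`unique_hub_control`),
#' or `non_hub`. A gene is a hub for a condition when its p-value is
#' strictly below `alpha`.
#'
#' @param stress,control `hub_test` results for the two conditions over
#'   the same gene set.
#' @param alpha Significance level (default 1e-10).
#' @return Data frame with `gene_id`, `p_stress`, `p_control`, `category`.
#' @export
classify_dhga <- function(stress, control, alpha = 1e-10) {
  if (!setequal(stress$gene_id, control$gene_id))
    stop("gene sets of the two conditions differ")
  control <- control[match(stress$gene_id, control$gene_id), ]
  hs <- stress$p_value < alpha
  hc <- control$p_value < alpha
  category <- ifelse(hs & hc, "housekeeping_hub",
              ifelse(hs, "unique_hub_stress",
              ifelse(hc, "unique_hub_control", "non_hub")))
  data.frame(gene_id = stress$gene_id, p_stress = stress$p_value,
             p_control = control$p_value, category = category)
}

#' Compare hub counts between the indicator rule and the significance test
#'
#' Counts (and percentages of the gene set) flagged as hubs by the
#' classical above-average indicator rule and by the significance test at
#' each requested alpha.
#'
#' @param results A `hub_test` data frame.
#' @param alphas Significance levels for the proposed rule.
#' @return Data frame with `rule`, `alpha`, `n_hub`, `pct_hub`.
#' @export
hub_count_comparison <- function(results, alphas = c(1e-5, 1e-10)) {
  if (!nrow(results)) stop("empty results")
  G <- nrow(results)
  rows <- data.frame(rule = "existing", alpha = NA_real_,
                     n_hub = sum(results$hub_existing),
                     pct_hub = 100 * sum(results$hub_existing) / G)
  for (a in alphas)
    rows <- rbind(rows, data.frame(rule = "proposed", alpha = a,
                                   n_hub = sum(results$p_value < a),
                                   pct_hub = 100 * sum(results$p_value < a) / G))
  rows
}

#' Differential hub gene analysis across two conditions
#'
#' Fits the full hub-gene pipeline for a two-condition experiment: per
#' condition, subsample connectivity ([subsample_wgs()]) and the hub
#' significance test ([hub_significance()]); then the differential
#' classification ([classify_dhga()]) and the hub-count comparison.
#'
#' @param expr An [expression_matrix()] carrying +1/-1 labels, or a list
#'   `list(stress = , control = )` of two expression objects.
#' @param beta Soft-threshold power.
#' @param S,m,replace Passed to [subsample_wgs()].
#' @param seed Integer seed (stress uses `seed`, control `seed + 1`).
#' @param alpha Significance level for the classification.
#' @param alphas Levels for the hub-count comparison.
#' @return An object of class `dhga` with elements `stress`, `control`
#'   (hub_test tables), `classification`, `counts` (per-condition
#'   comparison) and `alpha`.
#' @examples
#' sim <- simulate_modular(30, 40, c(10, 10), seed = 1)
#' st <- subset_samples(sim$expr, 1:20)
#' ct <- subset_samples(sim$expr, 21:40)
#' fit <- dhga(list(stress = st, control = ct), beta = 6, S = 25, seed = 1,
#'             alpha = 0.01)
#' print(fit)
#' @export
dhga <- function(expr, beta, S = 500, m = NULL, seed = NULL,
                 replace = FALSE, alpha = 1e-10, alphas = c(1e-5, 1e-10)) {
  if (inherits(expr, "expression_matrix")) {
    if (is.null(expr$labels)) stop("expression object must carry labels")
    conds <- list(stress = subset_samples(expr, expr$labels == 1),
                  control = subset_samples(expr, expr$labels == -1))
  } else conds <- expr
  stopifnot(all(c("stress", "control") %in% names(conds)))
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  sub_s <- subsample_wgs(conds$stress, beta, S = S, m = m, seed = seed,
                         replace = replace)
  sub_c <- subsample_wgs(conds$control, beta, S = S, m = m, seed = seed2,
                         replace = replace)
  hub_s <- hub_significance(sub_s)
  hub_c <- hub_significance(sub_c)
  cls <- classify_dhga(hub_s, hub_c, alpha = alpha)
  counts <- rbind(cbind(condition = "stress",
                        hub_count_comparison(hub_s, alphas)),
                  cbind(condition = "control",
                        hub_count_comparison(hub_c, alphas)))
  structure(list(stress = hub_s, control = hub_c, classification = cls,
                 counts = counts, alpha = alpha, call = match.call()),
            class = "dhga")
}

#' @export
print.dhga <- function(x, ...) {
  cat("Differential hub gene analysis (alpha =", format(x$alpha), ")\n")
  tb <- table(factor(x$classification$category,
                     levels = c("housekeeping_hub", "unique_hub_stress",
                                "unique_hub_control", "non_hub")))
  print(tb)
  invisible(x)
}

#' @export
summary.dhga <- function(object, ...) {
  print(object)
  cat("\nHub counts, indicator rule vs significance test:\n")
  print(object$counts, row.names = FALSE)
  invisible(object$counts)
}

#' Write the DHGA node list as TSV
#'
#' Node attributes for network viewers: gene, full-network connectivity,
#' per-condition p-values and the differential category.
#'
#' @param fit A `dhga` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_list <- function(fit, path) {
  stopifnot(inherits(fit, "dhga"))
  df <- fit$classification
  df$wgs_stress <- fit$stress$wgs_full[match(df$gene_id, fit$stress$gene_id)]
  df$wgs_control <- fit$control$wgs_full[match(df$gene_id, fit$control$gene_id)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
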