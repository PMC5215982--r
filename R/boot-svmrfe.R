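#' Bootstrap SVM-RFE gene selection
#'
#' Fits the full bootstrap SVM-RFE selection procedure: genes are ranked by
#' linear SVM recursive feature elimination in each of `n_boot` bootstrap
#' resamples, ranks are converted to rank scores, each gene's scores are
#' tested against the uninformative-gene median by the one-sided
#' signed-rank statistic, and genes are selected when both the bootstrap
#' p-value and a per-gene Welch t-test p-value clear the selection-plot
#' thresholds.
#'
#' @inheritParams bootstrap_rank_scores
#' @param x_threshold,y_threshold Selection thresholds on `-log10` of the
#'   bootstrap and t-test p-values (defaults 2.5 and 4).
#' @return An object of class `boot_svmrfe` with elements `table` (per-gene
#'   results including `selected`), `rank_scores`, the thresholds, and the
#'   call. Methods: [print.boot_svmrfe()], [summary.boot_svmrfe()],
#'   [plot.boot_svmrfe()], `coef` (named `-log10` bootstrap p-values).
#' @examples
#' sim <- simulate_two_class(40, 10, 5, effect = 2, seed = 1)
#' fit <- boot_svmrfe(sim$expr, n_boot = 20, seed = 1)
#' summary(fit)
#' @export
boot_svmrfe <- function(expr, labels = NULL, n_boot = 100, seed = NULL,
                        step = 1, cost = 1,
                        x_threshold = 2.5, y_threshold = 4) {
  scores <- bootstrap_rank_scores(expr, labels, n_boot = n_boot, seed = seed,
                                  step = step, cost = cost)
  boot_res <- test_gene_informativeness(scores)
  t_p <- welch_t_pvalues(expr, labels)
  sel <- gene_selection(boot_res, t_p, x_threshold, y_threshold)
  tab <- merge(boot_res, sel, by = "gene_id", sort = FALSE)
  tab$p_t <- unname(t_p[tab$gene_id])
  structure(list(table = tab, rank_scores = scores,
                 x_threshold = x_threshold, y_threshold = y_threshold,
                 n_boot = n_boot, call = match.call()),
            class = "boot_svmrfe")
}

#' @export
print.boot_svmrfe <- function(x, ...) {
  cat("Bootstrap SVM-RFE gene selection\n")
  cat("  genes:", nrow(x$table), "  bootstraps:", x$n_boot, "\n")
  cat("  selected:", sum(x$table$selected),
      sprintf("(thresholds -log10 p >= %g and %g)\n",
              x$x_threshold, x$y_threshold))
  invisible(x)
}

#' @export
summary.boot_svmrfe <- function(object, ...) {
  tab <- object$table[order(object$table$p_value), ]
  cat("Bootstrap SVM-RFE gene selection:", sum(tab$selected), "of",
      nrow(tab), "genes selected\n\nTop genes by bootstrap p-value:\n")
  print(utils::head(tab[, c("gene_id", "mean_rank_score", "t_plus", "z",
                            "p_value", "selected")], 10), row.names = FALSE)
  invisible(tab)
}

#' @export
coef.boot_svmrfe <- function(object, ...) {
  stats::setNames(object$table$neglog10_p_boot, object$table$gene_id)
}

#' Gene selection plot
#'
#' Scatter of `-log10` t-test p-values (vertical) against `-log10`
#' bootstrap signed-rank p-values (horizontal), with the two selection
#' thresholds drawn as dashed lines and selected genes highlighted.
#'
#' @param x A `boot_svmrfe` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.boot_svmrfe <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$neglog10_p_boot, tab$neglog10_p_t,
                 col = ifelse(tab$selected, "forestgreen", "steelblue"),
                 pch = ifelse(tab$selected, 19, 1),
                 xlab = expression(-log[10] ~ "p (bootstrap SVM-RFE)"),
                 ylab = expression(-log[10] ~ "p (t-test)"), ...)
  graphics::abline(v = x$x_threshold, h = x$y_threshold, lty = 2,
                   col = "grey40")
  invisible(x)
}

#' Write a gene-selection result table as TSV
#'
#' @param fit A `boot_svmrfe` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(fit, path) {
  stopifnot(inherits(fit, "boot_svmrfe"))
  cols <- c("gene_id", "mean_rank_score", "t_plus", "z", "p_value",
            "p_adjusted", "neglog10_p_boot", "neglog10_p_t", "selected")
  utils::write.table(fit$table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
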