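#' Absolute-correlation similarity matrix
#'
#' Co-expression similarity between every pair of genes as the absolute
#' value of the Pearson correlation of their expression profiles across
#' samples. Symmetric, unit diagonal, entries in `[0, 1]`.
#'
#' @param expr An [expression_matrix()] or numeric genes x samples matrix.
#' @return G x G similarity matrix.
#' @export
similarity_matrix <- function(expr) {
  v <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (ncol(v) < 3L) stop("need at least 3 samples for correlations")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance genes: ",
         paste(rownames(v)[sds == 0], collapse = ", "))
  s <- abs(stats::cor(t(v)))
  diag(s) <- 1
  s
}

#' Soft-threshold adjacency
#'
#' Raises each similarity entry to the power `beta`. The diagonal is set to
#' zero so connectivity is a plain row sum.
#'
#' @param similarity Similarity matrix from [similarity_matrix()].
#' @param beta Soft-threshold power (>= 1).
#' @return Adjacency matrix with zero diagonal.
#' @export
adjacency_matrix <- function(similarity, beta) {
  if (length(beta) != 1L || beta < 1) stop("beta must be >= 1")
  a <- similarity^beta
  diag(a) <- 0
  a
}

#' Weighted gene score (weighted connectivity)
#'
#' The weighted gene score of gene i is the sum of its adjacency weights to
#' all other genes — its total weighted connectivity in the network.
#'
#' @param adjacency Adjacency matrix with zero diagonal.
#' @return Named numeric vector of per-gene scores.
#' @export
weighted_gene_score <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  rowSums(a)
}

#' Scale-free fit of a connectivity distribution
#'
#' Bins the connectivity vector into `n_bins` equal-width bins and
#' regresses `log10` of the bin frequency on `log10` of the mean
#' connectivity per bin; a scale-free (power-law) degree distribution is
#' linear on this scale with a negative slope.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of equal-width bins.
#' @return List with `r_squared`, `slope` and `n_bins_used` (`NA`s when
#'   fewer than 3 usable bins).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) - min(k) <= 0)
    return(list(r_squared = NA_real_, slope = NA_real_, n_bins_used = 0L))
  cuts <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = cuts, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & is.finite(log10(mean_k)) & mean_k > 0
  if (sum(ok) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_,
                n_bins_used = sum(ok)))
  fit <- stats::lm(log10(freq[ok] / length(k)) ~ log10(mean_k[ok]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]), n_bins_used = sum(ok))
}

#' Choose the soft-threshold power by the scale-free criterion
#'
#' For each candidate power, computes the weighted connectivity of every
#' gene and the scale-free fit of its distribution ([scale_free_fit()]).
#' The chosen power is the smallest candidate whose fit reaches
#' `r2_cut` with a negative slope; if none qualifies, the candidate with
#' the highest R-squared is returned with `qualified = FALSE` and a
#' warning.
#'
#' @param expr An [expression_matrix()] or genes x samples matrix.
#' @param beta_grid Candidate integer powers.
#' @param r2_cut Scale-free fit index cut-off.
#' @param n_bins Bins for the log-log regression.
#' @return An object of class `soft_threshold_fit`: list with `beta` (the
#'   chosen power), `qualified`, and `fits` (a data frame with one row per
#'   candidate: `beta`, `r_squared`, `slope`, `mean_connectivity`).
#' @export
pick_soft_threshold <- function(expr, beta_grid = 1:20, r2_cut = 0.85,
                                n_bins = 10) {
  if (!length(beta_grid)) stop("beta_grid must be non-empty")
  s <- similarity_matrix(expr)
  fits <- lapply(beta_grid, function(b) {
    k <- weighted_gene_score(adjacency_matrix(s, b))
    f <- scale_free_fit(k, n_bins = n_bins)
    data.frame(beta = b, r_squared = f$r_squared, slope = f$slope,
               mean_connectivity = mean(k))
  })
  fits <- do.call(rbind, fits)
  good <- !is.na(fits$r_squared) & fits$r_squared >= r2_cut & fits$slope < 0
  if (any(good)) {
    beta <- fits$beta[which(good)[1L]]
    qualified <- TRUE
  } else {
    if (all(is.na(fits$r_squared)))
      stop("no candidate power produced a usable scale-free fit")
    beta <- fits$beta[which.max(fits$r_squared)]
    qualified <- FALSE
    warning("no power reached the scale-free criterion; returning the ",
            "best-fitting power ", beta)
  }
  structure(list(beta = beta, qualified = qualified, fits = fits,
                 r2_cut = r2_cut), class = "soft_threshold_fit")
}

#' @export
print.soft_threshold_fit <- function(x, ...) {
  cat("Soft-threshold selection: beta =", x$beta,
      if (x$qualified) sprintf("(scale-free R^2 >= %g)", x$r2_cut)
      else "(criterion not reached; best available fit)", "\n")
  print(x$fits, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Topological overlap matrix
#'
#' Unsigned topological overlap of an adjacency matrix:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal. Values lie in `[0, 1]` when the adjacency does.
#'
#' @param adjacency Adjacency matrix with zero diagonal.
#' @return TOM matrix.
#' @export
tom_matrix <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by topological-overlap clustering
#'
#' Average-linkage hierarchical clustering on the topological-overlap
#' dissimilarity `1 - TOM`, cut at a fixed height; clusters smaller than
#' `min_module_size` are merged into the unassigned module `"grey"`.
#' Non-grey modules are labelled by colour in decreasing size order
#' (turquoise, blue, brown, ...), falling back to numbered labels.
#'
#' @param adjacency Adjacency matrix with zero diagonal and gene rownames.
#' @param min_module_size Minimum genes per retained module.
#' @param cut_height Tree cut height on the dissimilarity scale.
#' @return Named character vector mapping gene ID to module label.
#' @export
detect_modules <- function(adjacency, min_module_size = 20,
                           cut_height = 0.25) {
  if (nrow(adjacency) < min_module_size)
    stop("fewer genes than min_module_size")
  tom <- tom_matrix(adjacency)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- rep("grey", length(cl))
  names(lab) <- rownames(adjacency)
  if (!length(keep)) {
    warning("no module reached min_module_size; all genes assigned grey")
    return(lab)
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan")
  mod_names <- c(palette, paste0("module", seq_len(max(0,
                 length(keep) - length(palette)))))[seq_along(keep)]
  for (i in seq_along(keep)) lab[cl == as.integer(keep[i])] <- mod_names[i]
  lab
}

#' Fit a weighted gene co-expression network
#'
#' Convenience fitting function running the whole network construction:
#' absolute-correlation similarity, soft-threshold power selection (unless
#' `beta` is given), adjacency, weighted gene scores, and module
#' detection.
#'
#' @inheritParams pick_soft_threshold
#' @param beta Soft-threshold power; chosen by [pick_soft_threshold()]
#'   when `NULL`.
#' @param detect Logical; run module detection.
#' @param min_module_size,cut_height Passed to [detect_modules()].
#' @return An object of class `gcn` with elements `similarity`, `beta`,
#'   `power_fit` (when selected), `adjacency`, `wgs` and `modules`.
#' @examples
#' sim <- simulate_modular(60, 40, c(20, 20), seed = 1)
#' net <- gcn(sim$expr, beta = 6, min_module_size = 10)
#' print(net)
#' @export
gcn <- function(expr, beta = NULL, beta_grid = 1:20, r2_cut = 0.85,
                detect = TRUE, min_module_size = 20, cut_height = 0.25) {
  s <- similarity_matrix(expr)
  power_fit <- NULL
  if (is.null(beta)) {
    power_fit <- pick_soft_threshold(expr, beta_grid, r2_cut)
    beta <- power_fit$beta
  }
  a <- adjacency_matrix(s, beta)
  wgs <- weighted_gene_score(a)
  modules <- if (detect && nrow(a) >= min_module_size)
    detect_modules(a, min_module_size, cut_height) else NULL
  structure(list(similarity = s, beta = beta, power_fit = power_fit,
                 adjacency = a, wgs = wgs, modules = modules,
                 call = match.call()), class = "gcn")
}

#' @export
print.gcn <- function(x, ...) {
  cat("Weighted gene co-expression network:", nrow(x$adjacency),
      "genes, beta =", x$beta, "\n")
  cat("  mean connectivity:", signif(mean(x$wgs), 4), "\n")
  if (!is.null(x$modules)) {
    tb <- sort(table(x$modules), decreasing = TRUE)
    cat("  modules:", paste(sprintf("%s (%d)", names(tb), tb),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.gcn <- function(x, ...) {
  graphics::hist(x$wgs, breaks = 30, col = "grey80",
                 main = "Weighted connectivity distribution",
                 xlab = "weighted gene score", ...)
  invisible(x)
}

#' Export a weighted edge list
#'
#' Writes the upper triangle of the adjacency as a TSV with columns
#' `gene_a`, `gene_b`, `weight`, keeping edges with weight at least
#' `floor`.
#'
#' @param adjacency Adjacency matrix (or a `gcn` object).
#' @param path Output path.
#' @param floor Minimum weight retained.
#' @return The edge data frame, invisibly.
#' @export
write_edge_list <- function(adjacency, path, floor = 0.02) {
  if (inherits(adjacency, "gcn")) adjacency <- adjacency$adjacency
  ut <- which(upper.tri(adjacency) & adjacency >= floor, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(adjacency)[ut[, 1L]],
                      gene_b = colnames(adjacency)[ut[, 2L]],
                      weight = adjacency[ut])
  edges <- edges[order(edges$weight, decreasing = TRUE), ]
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}

#' Export a network in SIF format
#'
#' Simple interaction format for network viewers: one
#' `source <relation> target` line per retained edge.
#'
#' @param edges Data frame with the first two columns naming the nodes of
#'   each edge (e.g. from [write_edge_list()] or [build_min()]).
#' @param path Output path.
#' @param relation Relation label written between the nodes.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, relation = "coexp") {
  lines <- paste(edges[[1L]], relation, edges[[2L]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
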