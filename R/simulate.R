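## Synthetic-data generators with known ground truth. Each returns the
## expression object plus a `truth` element so tests validate recovery
## against the planted structure rather than reverse-engineering it.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Simulate a two-class expression experiment with planted informative genes
#'
#' Background genes are i.i.d. Normal(`baseline`, 1) in both classes; the
#' first `n_informative` genes are shifted upward by `effect` standard
#' deviations in the +1 (stress) class. Samples are balanced across classes.
#'
#' @param G Number of genes.
#' @param m_per_class Samples per class (>= 2).
#' @param n_informative Number of planted informative genes (<= G).
#' @param effect Mean shift of informative genes in the +1 class, in SD units.
#' @param seed Integer seed; the same seed reproduces the data bitwise.
#' @param baseline Baseline log2 expression level; the default 8 sits in the
#'   usual intensity range of normalized arrays so the data pass
#'   [filter_samples()] at its defaults.
#' @return A list with elements `expr` (an [expression_matrix()] with labels)
#'   and `truth` (list with `informative_genes`).
#' @export
simulate_two_class <- function(G, m_per_class, n_informative, effect,
                               seed = NULL, baseline = 8) {
  if (n_informative > G) stop("n_informative must be <= G")
  if (m_per_class < 2L) stop("m_per_class must be >= 2")
  M <- 2L * m_per_class
  gene_ids <- sprintf("g%04d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(M))
  labels <- rep(c(1, -1), each = m_per_class)
  with_seed(seed, {
    v <- matrix(stats::rnorm(G * M, mean = baseline, sd = 1), G, M,
                dimnames = list(gene_ids, sample_ids))
    if (n_informative > 0L)
      v[seq_len(n_informative), labels == 1] <-
        v[seq_len(n_informative), labels == 1] + effect
    list(expr = expression_matrix(v, labels = labels),
         truth = list(informative_genes = gene_ids[seq_len(n_informative)]))
  })
}

#' Simulate modular expression with planted hub genes
#'
#' A latent-factor model: each module d has a standard-normal factor across
#' samples; member genes load on it with `loading_member` plus Gaussian
#' noise, while the first gene of each module (the planted hub) loads with
#' `loading_hub`. Genes beyond the modules are pure noise.
#'
#' @param G Total genes.
#' @param M Samples.
#' @param module_sizes Integer vector of module sizes (each >= 2,
#'   sum <= G).
#' @param loading_hub,loading_member Factor loadings in `[0, 1]` with
#'   `loading_member <= loading_hub`.
#' @param noise_sd Gene-level Gaussian noise SD.
#' @param seed Integer seed.
#' @param baseline Baseline expression added to every gene.
#' @return A list with `expr` (an [expression_matrix()]) and `truth` (list
#'   with `module_of` named character vector, non-modular genes "grey", and
#'   `hub_genes`).
#' @export
simulate_modular <- function(G, M, module_sizes, loading_hub = 0.95,
                             loading_member = 0.6, noise_sd = 1,
                             seed = NULL, baseline = 8) {
  if (any(module_sizes < 2L)) stop("every module size must be >= 2")
  if (sum(module_sizes) > G) stop("sum(module_sizes) must be <= G")
  if (!(loading_member >= 0 && loading_member <= loading_hub &&
        loading_hub <= 1))
    stop("need 0 <= loading_member <= loading_hub <= 1")
  gene_ids <- sprintf("g%04d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(M))
  D <- length(module_sizes)
  module_of <- rep("grey", G)
  names(module_of) <- gene_ids
  with_seed(seed, {
    v <- matrix(stats::rnorm(G * M, sd = noise_sd), G, M,
                dimnames = list(gene_ids, sample_ids))
    hubs <- character(D)
    at <- 1L
    for (d in seq_len(D)) {
      idx <- at:(at + module_sizes[d] - 1L)
      f <- stats::rnorm(M)
      load <- c(loading_hub, rep(loading_member, module_sizes[d] - 1L))
      v[idx, ] <- v[idx, ] + outer(load, f)
      module_of[idx] <- paste0("mod", d)
      hubs[d] <- gene_ids[idx[1L]]
      at <- at + module_sizes[d]
    }
    v <- v + baseline
    list(expr = expression_matrix(v),
         truth = list(module_of = module_of, hub_genes = hubs))
  })
}

#' Simulate lagged-regression module time courses
#'
#' Generates D module series over T time points under a first-order lagged
#' linear model: each target module's value at time t is an intercept plus
#' the sum of `coefficient * regulator(t - 1)` over its planted incoming
#' edges, plus Normal(0, `noise_sd`^2) noise. Initial values are standard
#' normal.
#'
#' @param D Number of modules (>= 2).
#' @param T_points Number of time points (>= 3).
#' @param true_edges Data frame with columns `regulator`, `target` (module
#'   indices in 1..D) and `coefficient`; may have zero rows.
#' @param noise_sd Innovation noise SD.
#' @param seed Integer seed.
#' @param beta0 Common intercept.
#' @return A list with `series` (a [module_series()] with time in hours
#'   0..T-1) and `truth` (the `true_edges` table with module labels).
#' @export
simulate_module_series <- function(D, T_points, true_edges = NULL,
                                   noise_sd = 0.2, seed = NULL, beta0 = 0) {
  if (D < 2L) stop("D must be >= 2")
  if (T_points < 3L) stop("T_points must be >= 3")
  if (is.null(true_edges))
    true_edges <- data.frame(regulator = integer(), target = integer(),
                             coefficient = numeric())
  stopifnot(all(c("regulator", "target", "coefficient") %in%
                  names(true_edges)))
  if (nrow(true_edges) &&
      (any(true_edges$regulator > D) || any(true_edges$target > D) ||
       any(true_edges$regulator < 1) || any(true_edges$target < 1)))
    stop("edge references a module index outside 1..D")
  if (nrow(true_edges) && !all(is.finite(true_edges$coefficient)))
    stop("edge coefficients must be finite")
  labels <- paste0("mod", seq_len(D))
  with_seed(seed, {
    v <- matrix(0, D, T_points, dimnames = list(labels, NULL))
    v[, 1L] <- stats::rnorm(D)
    for (t in 2:T_points) {
      drift <- rep(beta0, D)
      if (nrow(true_edges))
        for (e in seq_len(nrow(true_edges)))
          drift[true_edges$target[e]] <- drift[true_edges$target[e]] +
            true_edges$coefficient[e] * v[true_edges$regulator[e], t - 1L]
      v[, t] <- drift + stats::rnorm(D, sd = noise_sd)
    }
    truth <- true_edges
    truth$regulator_label <- labels[truth$regulator]
    truth$target_label <- labels[truth$target]
    list(series = module_series(v, time_h = seq_len(T_points) - 1),
         truth = truth)
  })
}

#' Write simulation ground truth as TSV files
#'
#' Writes whichever truth components are present: `informative_genes`
#' (one ID per line under a header), `module_of` (gene_id, module),
#' `hub_genes`, and `true_edges`.
#'
#' @param truth A `truth` list as returned by the simulators.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$informative_genes))
    w(data.frame(gene_id = truth$informative_genes), "informative_genes.tsv")
  if (!is.null(truth$module_of))
    w(data.frame(gene_id = names(truth$module_of),
                 module = unname(truth$module_of)), "module_of.tsv")
  if (!is.null(truth$hub_genes))
    w(data.frame(gene_id = truth$hub_genes), "hub_genes.tsv")
  if (!is.null(truth$regulator))
    w(as.data.frame(truth), "true_edges.tsv")
  invisible(dir)
}
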