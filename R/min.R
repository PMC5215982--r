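#' Module time-series container
#'
#' @param values Numeric D x T matrix of module expression (modules in
#'   rows) with module labels as rownames.
#' @param time_h Strictly increasing time points in hours, one per column.
#' @return An object of class `module_series`.
#' @export
module_series <- function(values, time_h) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (ncol(values) != length(time_h))
    stop("one time point per column required")
  if (ncol(values) < 3L) stop("need at least 3 time points")
  if (any(diff(time_h) <= 0)) stop("time points must be strictly increasing")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("mod", seq_len(nrow(values)))
  structure(list(values = values, time_h = as.numeric(time_h),
                 module_labels = rownames(values)), class = "module_series")
}

#' @export
print.module_series <- function(x, ...) {
  cat("Module series:", nrow(x$values), "modules x", ncol(x$values),
      "time points over [", min(x$time_h), ",", max(x$time_h), "] h\n")
  invisible(x)
}

#' Aggregate gene expression into module expression series
#'
#' The expression level of a module at a time point is the arithmetic mean
#' of its member genes; replicate samples at the same nominal time point
#' are averaged first. The grey (unassigned) module is kept as an ordinary
#' unit.
#'
#' @param expr An [expression_matrix()] whose samples carry time points.
#' @param modules Named character vector gene ID -> module label (e.g.
#'   from [detect_modules()]).
#' @return A [module_series()] with one row per module.
#' @export
module_expression <- function(expr, modules) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(expr$time_h)) stop("samples must carry time points")
  labels <- unique(modules)
  members <- lapply(labels, function(l)
    intersect(names(modules)[modules == l], rownames(expr$values)))
  names(members) <- labels
  empty <- labels[lengths(members) == 0L]
  if (length(empty))
    stop("module(s) with zero member genes in the matrix: ",
         paste(empty, collapse = ", "))
  times <- sort(unique(expr$time_h))
  vals <- t(vapply(labels, function(l) {
    gene_means <- colMeans(expr$values[members[[l]], , drop = FALSE])
    vapply(times, function(t0) mean(gene_means[expr$time_h == t0]),
           numeric(1))
  }, numeric(length(times))))
  rownames(vals) <- labels
  module_series(vals, times)
}

#' Interpolate module series onto a uniform time grid
#'
#' Natural cubic spline through the observed (time, value) knots of each
#' module, evaluated on a uniform grid of `n_points` between the first and
#' last observed time (grid endpoints coincide with the observed
#' endpoints). Interpolation, not smoothing: observed knots are
#' reproduced exactly.
#'
#' @param series A [module_series()].
#' @param n_points Grid size (default 50).
#' @return A [module_series()] on the uniform grid.
#' @export
interpolate_series <- function(series, n_points = 50) {
  stopifnot(inherits(series, "module_series"))
  if (anyDuplicated(series$time_h)) stop("duplicate time points")
  grid <- seq(min(series$time_h), max(series$time_h),
              length.out = n_points)
  vals <- t(apply(series$values, 1L, function(y)
    stats::spline(series$time_h, y, xout = grid, method = "natural")$y))
  rownames(vals) <- series$module_labels
  module_series(vals, grid)
}

#' Lagged regression design for one target module
#'
#' Response is the target module at time steps 2..T; predictors are all
#' other modules at steps 1..T-1 (the target never predicts itself).
#'
#' @param series A [module_series()] (typically interpolated).
#' @param target Target module label or index.
#' @return List with `response` (length T-1) and `predictors`
#'   ((T-1) x (D-1) matrix with module-label colnames).
#' @export
lagged_design <- function(series, target) {
  stopifnot(inherits(series, "module_series"))
  v <- series$values
  if (nrow(v) < 2L) stop("need at least 2 modules")
  if (is.character(target)) target <- match(target, rownames(v))
  if (is.na(target) || target < 1 || target > nrow(v))
    stop("unknown target module")
  T_ <- ncol(v)
  list(response = v[target, 2:T_],
       predictors = t(v[-target, 1:(T_ - 1L), drop = FALSE]))
}

bic_gauss <- function(rss, n, n_par) {
  # Gaussian BIC with sigma^2 profiled out; rss floored to keep the
  # noise-free limit finite while preserving model ordering
  rss <- max(rss, 1e-300)
  n * log(rss / n) + n_par * log(n)
}

fit_rss <- function(y, X) {
  # X includes the intercept column; returns NULL on rank deficiency
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Posterior inclusion probabilities by Bayesian model averaging
#'
#' Weights candidate regression models of the response on subsets of the
#' predictors by `exp(-BIC / 2)` (Gaussian BIC, noise variance profiled
#' out) times an independent-inclusion model prior, normalized over the
#' evaluated models after discarding models far outside Occam's window. A
#' predictor's posterior inclusion probability is the total weight of
#' models containing it; its model-averaged coefficient counts excluding
#' models as zero. With at most 15 predictors all subsets up to
#' `max_model_size` are enumerated (the reference behavior); above that an
#' iterative windowed scheme is used: predictors are ranked by absolute
#' marginal correlation with the response, processed `window` at a time,
#' and carried forward while their running posterior stays at or above
#' 0.05.
#'
#' @param response Numeric response vector.
#' @param predictors Numeric matrix, one column per candidate predictor.
#' @param max_model_size Largest subset enumerated (default
#'   `min(ncol(predictors), 8)`).
#' @param window Window size of the iterative scheme.
#' @param occam_or Occam's-window odds ratio: models whose posterior odds
#'   against the best model exceed `occam_or` are discarded before
#'   normalization (default 20, the customary value); `Inf` keeps every
#'   enumerated model.
#' @param prior_inclusion Prior probability that any given predictor
#'   enters the model, applied independently per predictor. The default
#'   0.05 encodes the sparsity expected of transcriptional regulatory
#'   networks (roughly one true regulator among twenty candidates); 0.5
#'   recovers the uniform prior over models.
#' @return Data frame with `predictor`, `posterior`, `coefficient`.
#' @export
bma_posteriors <- function(response, predictors, max_model_size = NULL,
                           window = 30, occam_or = 20,
                           prior_inclusion = 0.05) {
  predictors <- as.matrix(predictors)
  if (is.null(colnames(predictors)))
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  n <- length(response)
  if (n < 3L) stop("need at least 3 observations")
  p <- ncol(predictors)
  if (p < 1L) stop("need at least 1 predictor")
  if (is.null(max_model_size)) max_model_size <- min(p, 8L)
  if (prior_inclusion <= 0 || prior_inclusion >= 1)
    stop("prior_inclusion must be in (0, 1)")
  if (p <= 15L)
    return(bma_enumerate(response, predictors, max_model_size, occam_or,
                         prior_inclusion))
  bma_iterative(response, predictors, max_model_size, window, occam_or,
                prior_inclusion)
}

bma_enumerate <- function(y, X, max_model_size, occam_or = 20,
                          prior_inclusion = 0.05) {
  p <- ncol(X)
  n <- length(y)
  subsets <- list(integer(0))
  for (k in seq_len(min(max_model_size, p)))
    subsets <- c(subsets, utils::combn(p, k, simplify = FALSE))
  ic <- rep(NA_real_, length(subsets))
  coefs <- vector("list", length(subsets))
  n_skipped <- 0L
  # -2 * log prior of each model under independent inclusion, so `ic`
  # is on the -2*log(posterior) scale up to a constant
  log_odds <- log(prior_inclusion) - log(1 - prior_inclusion)
  for (i in seq_along(subsets)) {
    Xi <- cbind(`(Intercept)` = 1, X[, subsets[[i]], drop = FALSE])
    f <- fit_rss(y, Xi)
    if (is.null(f)) { n_skipped <- n_skipped + 1L; next }
    ic[i] <- bic_gauss(f$rss, n, length(subsets[[i]]) + 2L) -
      2 * length(subsets[[i]]) * log_odds
    coefs[[i]] <- f$coef
  }
  if (n_skipped > 0L)
    warning(n_skipped, " rank-deficient model(s) skipped")
  usable <- !is.na(ic)
  if (!any(usable)) stop("all candidate models degenerate")
  # Occam's window, both rules: drop models much worse than the best, and
  # drop any model that one of its own submodels supports better
  ok1 <- usable & (ic - min(ic, na.rm = TRUE)) <= 2 * log(occam_or)
  masks <- vapply(subsets, function(s) sum(bitwShiftL(1L, s - 1L)), 0)
  usable <- ok1
  for (i in which(ok1)) {
    sub_better <- ok1 &
      bitwAnd(masks, masks[i]) == masks & masks != masks[i] & ic <= ic[i]
    if (any(sub_better, na.rm = TRUE)) usable[i] <- FALSE
  }
  w <- exp(-(ic[usable] - min(ic[usable])) / 2)
  w <- w / sum(w)
  post <- numeric(p)
  cf <- numeric(p)
  us <- which(usable)
  for (j in seq_along(us)) {
    s <- subsets[[us[j]]]
    post[s] <- post[s] + w[j]
    if (length(s)) cf[s] <- cf[s] + w[j] * coefs[[us[j]]][-1L]
  }
  data.frame(predictor = colnames(X), posterior = post, coefficient = cf)
}

bma_iterative <- function(y, X, max_model_size, window, occam_or = 20,
                          prior_inclusion = 0.05) {
  queue <- order(abs(stats::cor(X, y)), decreasing = TRUE)
  active <- integer(0)
  post_all <- numeric(ncol(X))
  coef_all <- numeric(ncol(X))
  repeat {
    take <- min(window - length(active), length(queue))
    if (take > 0L) {
      active <- c(active, queue[seq_len(take)])
      queue <- queue[-seq_len(take)]
    }
    res <- bma_enumerate(y, X[, active, drop = FALSE],
                         min(max_model_size, length(active)), occam_or,
                         prior_inclusion)
    post_all[active] <- res$posterior
    coef_all[active] <- res$coefficient
    keep <- active[res$posterior >= 0.05]
    changed <- length(keep) != length(active)
    active <- keep
    if (!length(queue) && !changed) break       # stable, nothing left
    if (take == 0L && !changed) break           # window saturated
    if (!length(active) && !length(queue)) break
  }
  data.frame(predictor = colnames(X), posterior = post_all,
             coefficient = coef_all)
}

#' Threshold BMA posteriors into a directed module network
#'
#' Keeps the directed edges regulator -> target whose posterior inclusion
#' probability is at least `threshold` (default 0.2) and orders them by
#' descending posterior.
#'
#' @param posteriors Data frame with columns `regulator`, `target`,
#'   `posterior`, `coefficient` covering the ordered module pairs.
#' @param threshold Minimum posterior retained.
#' @return The retained edges, sorted by descending posterior.
#' @export
build_min <- function(posteriors, threshold = 0.2) {
  stopifnot(all(c("regulator", "target", "posterior") %in%
                  names(posteriors)))
  edges <- posteriors[posteriors$posterior >= threshold, , drop = FALSE]
  edges <- edges[order(edges$posterior, decreasing = TRUE), ]
  rownames(edges) <- NULL
  edges
}

#' Fit a module interaction network
#'
#' The full directed-network procedure: (optionally) interpolate the
#' module series to a uniform grid, then for every target module fit the
#' first-order lagged regression on all other modules by Bayesian model
#' averaging ([bma_posteriors()]) and keep edges whose posterior inclusion
#' probability clears `threshold`.
#'
#' @param series A [module_series()] (e.g. from [module_expression()] or
#'   [simulate_module_series()]).
#' @param threshold Posterior threshold for retained edges.
#' @param n_points Interpolation grid size; `NULL` skips interpolation
#'   (use when the series is already on a uniform grid).
#' @param max_model_size,window,occam_or,prior_inclusion Passed to
#'   [bma_posteriors()].
#' @param standardize Center and scale each module series before the
#'   regressions (affects intercepts only under pure scaling).
#' @return An object of class `module_network` with `edges` (retained),
#'   `posteriors` (all ordered pairs), `threshold`, `series`.
#' @examples
#' edges <- data.frame(regulator = 1, target = 2, coefficient = 0.9)
#' sim <- simulate_module_series(4, 30, edges, noise_sd = 0.1, seed = 1)
#' net <- fit_min(sim$series, n_points = NULL)
#' net$edges
#' @export
fit_min <- function(series, threshold = 0.2, n_points = 50,
                    max_model_size = NULL, window = 30, occam_or = 20,
                    prior_inclusion = 0.05, standardize = TRUE) {
  stopifnot(inherits(series, "module_series"))
  if (!is.null(n_points)) series <- interpolate_series(series, n_points)
  v <- series$values
  if (standardize) {
    sds <- apply(v, 1L, stats::sd)
    sds[sds == 0] <- 1  # constant modules left centered only
    v <- (v - rowMeans(v)) / sds
    series$values <- v
  }
  labels <- rownames(v)
  all_posts <- lapply(labels, function(tg) {
    d <- lagged_design(series, tg)
    res <- bma_posteriors(d$response, d$predictors,
                          max_model_size = max_model_size, window = window,
                          occam_or = occam_or,
                          prior_inclusion = prior_inclusion)
    data.frame(regulator = res$predictor, target = tg,
               posterior = res$posterior, coefficient = res$coefficient)
  })
  posteriors <- do.call(rbind, all_posts)
  edges <- build_min(posteriors, threshold)
  structure(list(edges = edges, posteriors = posteriors,
                 threshold = threshold, series = series,
                 call = match.call()), class = "module_network")
}

#' @export
print.module_network <- function(x, ...) {
  cat("Module interaction network:", nrow(x$series$values), "modules,",
      nrow(x$edges), "edges at posterior >=", x$threshold, "\n")
  if (nrow(x$edges))
    print(utils::head(x$edges, 10), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a module-network edge list as TSV
#'
#' @param net A `module_network` object (or an edge data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_min <- function(net, path) {
  edges <- if (inherits(net, "module_network")) net$edges else net
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
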