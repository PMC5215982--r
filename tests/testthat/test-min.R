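test_that("module expression is the member mean with replicate averaging", {
  v <- rbind(g1 = c(2, 4, 6, 8, 10, 12), g2 = c(4, 6, 8, 10, 12, 14),
             g3 = c(0, 0, 1, 1, 2, 2))
  colnames(v) <- paste0("s", 1:6)
  expr <- expression_matrix(v, time_h = c(0, 0, 2, 2, 4, 4))
  modules <- c(g1 = "blue", g2 = "blue", g3 = "grey")
  ms <- module_expression(expr, modules)
  # blue at t=0: mean over genes then replicates -> mean(c(3, 5)) = 4
  expect_equal(unname(ms$values["blue", ]), c(4, 8, 12))
  # single-gene (grey) module equals that gene's series
  expect_equal(unname(ms$values["grey", ]), c(0, 1, 2))
  expect_equal(ms$time_h, c(0, 2, 4))
  expect_error(module_expression(expr, c(modules, gX = "red")), "red")
})

test_that("spline interpolation is exact at knots and on straight lines", {
  t_obs <- c(0, 2, 12, 48, 72)
  line <- module_series(rbind(a = 2 * t_obs + 1, b = -t_obs), t_obs)
  out <- interpolate_series(line, n_points = 50)
  expect_length(out$time_h, 50)
  expect_equal(range(out$time_h), c(0, 72))
  expect_equal(unname(out$values["a", ]), 2 * out$time_h + 1,
               tolerance = 1e-9)

  set.seed(1)
  wiggly <- module_series(matrix(stats::rnorm(10), 2, 5), t_obs)
  out2 <- interpolate_series(wiggly, n_points = 50)
  at_knots <- vapply(t_obs, function(t0)
    which.min(abs(out2$time_h - t0)), integer(1))
  # 0 and 72 are on the grid exactly; interior knots need re-evaluation
  for (i in 1:2) {
    sp <- stats::spline(t_obs, wiggly$values[i, ], xout = t_obs,
                        method = "natural")$y
    expect_equal(unname(sp), unname(wiggly$values[i, ]), tolerance = 1e-9)
  }
  expect_equal(out2$values[, 1], wiggly$values[, 1])
  expect_equal(out2$values[, 50], wiggly$values[, 5])
})

test_that("lagged design has the stated shape and excludes the target", {
  sim <- simulate_module_series(19, 50, NULL, seed = 2)
  d <- lagged_design(sim$series, "mod3")
  expect_length(d$response, 49)
  expect_equal(dim(d$predictors), c(49, 18))
  expect_false("mod3" %in% colnames(d$predictors))
  expect_equal(unname(d$response), unname(sim$series$values["mod3", 2:50]))
  expect_equal(unname(d$predictors[, "mod1"]),
               unname(sim$series$values["mod1", 1:49]))
})

test_that("BMA posteriors equal the independent enumeration oracle", {
  set.seed(3)
  for (rep in 1:3) {
    n <- 30
    X <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("x1", "x2", "x3")))
    y <- 0.8 * X[, 1] + stats::rnorm(n, sd = 0.5)
    got <- bma_posteriors(y, X)
    want <- oracle_bma(y, X)
    expect_equal(got$posterior, want$posterior, tolerance = 1e-9)
    expect_equal(got$coefficient, want$coefficient, tolerance = 1e-9)
  }
  # larger predictor set, still exhaustive
  set.seed(4)
  X <- matrix(stats::rnorm(40 * 8), 40, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  y <- X[, 2] - 0.5 * X[, 5] + stats::rnorm(40, sd = 0.3)
  expect_equal(bma_posteriors(y, X)$posterior,
               oracle_bma(y, X)$posterior, tolerance = 1e-9)
})

test_that("a noise-free generating predictor reaches posterior one", {
  set.seed(5)
  X <- matrix(stats::rnorm(90), 30, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, "a"]
  res <- bma_posteriors(y, X)
  expect_equal(res$posterior[res$predictor == "a"], 1, tolerance = 1e-6)
  expect_gt(res$posterior[res$predictor == "a"],
            max(res$posterior[res$predictor != "a"]))
})

test_that("pure-noise predictors rarely reach high posteriors", {
  set.seed(6)
  maxima <- replicate(20, {
    X <- matrix(stats::rnorm(49 * 9), 49, 9)
    colnames(X) <- paste0("x", 1:9)
    y <- stats::rnorm(49)
    max(bma_posteriors(y, X)$posterior)
  })
  expect_lt(mean(maxima >= 0.5), 0.25)
})

test_that("collinear predictors are skipped with a warning", {
  set.seed(7)
  x <- stats::rnorm(20)
  X <- cbind(a = x, b = x, c = stats::rnorm(20))
  y <- x + stats::rnorm(20, sd = 0.1)
  expect_warning(res <- bma_posteriors(y, X), "rank-deficient")
  expect_true(all(res$posterior >= 0 & res$posterior <= 1))
})

test_that("the iterative path broadly agrees with enumeration rankings", {
  set.seed(8)
  n <- 60; p <- 18
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", 1:p)))
  y <- X[, 3] * 0.9 + X[, 11] * 0.7 + stats::rnorm(n, sd = 0.4)
  res <- bma_posteriors(y, X, window = 8)   # forces the iterative path
  top <- res$predictor[order(res$posterior, decreasing = TRUE)][1:2]
  expect_setequal(top, c("x3", "x11"))
  expect_true(all(res$posterior >= 0 & res$posterior <= 1))
})

test_that("edge thresholding keeps the requested density extremes", {
  pairs <- expand.grid(regulator = paste0("m", 1:4),
                       target = paste0("m", 1:4),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  set.seed(9)
  pairs$posterior <- stats::runif(nrow(pairs))
  pairs$coefficient <- stats::rnorm(nrow(pairs))
  expect_equal(nrow(build_min(pairs, 0)), 4 * 3)
  expect_equal(nrow(build_min(pairs, 1 + 1e-9)), 0)
  kept <- build_min(pairs, 0.5)
  expect_true(all(diff(kept$posterior) <= 0))
  expect_true(all(kept$posterior >= 0.5))
})

test_that("planted lagged edges are recovered through the full fit", {
  edges <- planted_edges_3()
  tp <- fp <- fn <- 0
  for (seed in 1:3) {
    sim <- simulate_module_series(10, 50, edges, noise_sd = 0.2,
                                  seed = seed)
    net <- fit_min(sim$series, n_points = NULL)
    got <- edge_key(net$edges$regulator, net$edges$target)
    want <- edge_key(sim$truth$regulator_label, sim$truth$target_label)
    tp <- tp + sum(got %in% want)
    fp <- fp + sum(!got %in% want)
    fn <- fn + sum(!want %in% got)
  }
  expect_gte(tp / (tp + fp), 0.7)
  expect_gte(tp / (tp + fn), 0.8)
})

test_that("module network fit is deterministic and exportable", {
  sim <- simulate_module_series(6, 30, planted_edges_3(), noise_sd = 0.2,
                                seed = 12)
  a <- fit_min(sim$series, n_points = NULL)
  b <- fit_min(sim$series, n_points = NULL)
  expect_identical(a$edges, b$edges)
  d <- withr::local_tempdir()
  write_min(a, file.path(d, "min.tsv"))
  back <- utils::read.delim(file.path(d, "min.tsv"))
  expect_equal(nrow(back), nrow(a$edges))
})
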