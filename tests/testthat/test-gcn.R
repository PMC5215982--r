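test_that("similarity is absolute correlation with the right degeneracies", {
  set.seed(1)
  base <- stats::rnorm(30)
  v <- rbind(a = base, dup = base, neg = -base,
             noise = stats::rnorm(30))
  colnames(v) <- paste0("s", 1:30)
  s <- similarity_matrix(v)
  expect_equal(s["a", "dup"], 1)
  expect_equal(s["a", "neg"], 1)   # sign is discarded
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, t(s))

  v2 <- rbind(v, flat = rep(3, 30))
  expect_error(similarity_matrix(v2), "flat")
})

test_that("independent long profiles have near-zero similarity", {
  set.seed(2)
  v <- matrix(stats::rnorm(2 * 1000), 2, 1000,
              dimnames = list(c("x", "y"), NULL))
  colnames(v) <- paste0("s", 1:1000)
  expect_lt(similarity_matrix(v)["x", "y"], 0.1)
})

test_that("adjacency is the elementwise soft power with zero diagonal", {
  s <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  a <- adjacency_matrix(s, 8)
  expect_equal(a["a", "b"], 0.43046721)
  expect_equal(diag(a), c(a = 0, b = 0))
  a1 <- adjacency_matrix(s, 1)
  expect_equal(a1["a", "b"], 0.9)
  expect_error(adjacency_matrix(s, 0.5), ">= 1")
  # 0 and 1 are fixed points of every power
  s01 <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 1), 3, 3)
  expect_equal(adjacency_matrix(s01, 7)[upper.tri(s01)],
               s01[upper.tri(s01)])
})

test_that("adjacency decreases monotonically in beta", {
  set.seed(3)
  s <- abs(stats::cor(matrix(stats::rnorm(200), 20, 10)))
  prev <- adjacency_matrix(s, 1)
  for (b in 2:6) {
    cur <- adjacency_matrix(s, b)
    expect_true(all(cur <= prev + 1e-15))
    prev <- cur
  }
})

test_that("weighted gene score equals the brute-force double loop", {
  s <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  s["a", "b"] <- s["b", "a"] <- 0.5
  s["a", "c"] <- s["c", "a"] <- 0.8
  diag(s) <- 1
  wgs <- weighted_gene_score(adjacency_matrix(s, 2))
  expect_equal(wgs, c(a = 0.25 + 0.64, b = 0.25, c = 0.64))

  set.seed(4)
  v <- matrix(stats::rnorm(15 * 12), 15, 12,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("s%02d", 1:12)))
  a <- adjacency_matrix(similarity_matrix(v), 4)
  brute <- vapply(seq_len(15), function(i) {
    tot <- 0
    for (j in seq_len(15)) if (j != i) tot <- tot + a[i, j]
    tot
  }, numeric(1))
  expect_equal(unname(weighted_gene_score(a)), brute)

  # complete graph of similarity 1: every gene connects fully
  ones <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_equal(unname(weighted_gene_score(adjacency_matrix(ones, 3))),
               rep(4, 5))
})

test_that("WGS permutes with the genes", {
  set.seed(5)
  v <- matrix(stats::rnorm(100), 10, 10,
              dimnames = list(letters[1:10], paste0("s", 1:10)))
  a <- adjacency_matrix(similarity_matrix(v), 3)
  wgs <- weighted_gene_score(a)
  perm <- sample(10)
  expect_equal(weighted_gene_score(a[perm, perm]), wgs[perm])
})

test_that("an exact power-law connectivity profile fits with R^2 near 1", {
  # construct k values whose binned log-log frequency is exactly linear
  k <- rep(2^(0:5), times = round(1000 * 2^(5:0) / 63))
  f <- scale_free_fit(k + stats::runif(length(k), 0, 1e-6), n_bins = 40)
  expect_gt(f$r_squared, 0.95)
  expect_lt(f$slope, 0)
})

test_that("soft-threshold selection finds a scale-free power on module data", {
  sim <- simulate_modular(100, 50, rep(20, 4), loading_hub = 0.95,
                          loading_member = 0.6, noise_sd = 1, seed = 41)
  fit <- pick_soft_threshold(sim$expr, 1:20, r2_cut = 0.8)
  expect_s3_class(fit, "soft_threshold_fit")
  expect_true(fit$qualified)
  row <- fit$fits[fit$fits$beta == fit$beta, ]
  expect_gte(row$r_squared, 0.8)
  expect_lt(row$slope, 0)
  # mean connectivity decreases in beta
  expect_true(all(diff(fit$fits$mean_connectivity) < 0))
})

test_that("singleton grids return their only power with the right flag", {
  sim <- simulate_modular(40, 30, c(15, 15), seed = 42)
  fit <- suppressWarnings(pick_soft_threshold(sim$expr, beta_grid = 8,
                                              r2_cut = 0.999))
  expect_equal(fit$beta, 8)
  expect_false(fit$qualified)
})

test_that("TOM stays within [0,1] and separates perfect blocks", {
  set.seed(6)
  a <- adjacency_matrix(abs(stats::cor(matrix(stats::rnorm(300), 30, 10))), 3)
  tom <- tom_matrix(a)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))

  # two blocks of identical genes: within-block s = 1, between = 0
  blocks <- matrix(0, 10, 10,
                   dimnames = list(sprintf("g%02d", 1:10), NULL))
  colnames(blocks) <- sprintf("g%02d", 1:10)
  blocks[1:5, 1:5] <- 1
  blocks[6:10, 6:10] <- 1
  mods <- detect_modules(adjacency_matrix(blocks, 4), min_module_size = 4,
                         cut_height = 0.5)
  expect_equal(length(unique(mods)), 2)
  expect_equal(length(unique(mods[1:5])), 1)
  expect_equal(length(unique(mods[6:10])), 1)
})

test_that("planted modules are recovered and noise stays grey", {
  sim <- simulate_modular(100, 60, rep(20, 4), loading_hub = 0.95,
                          loading_member = 0.6, noise_sd = 0.5, seed = 43)
  a <- adjacency_matrix(similarity_matrix(sim$expr), 6)
  mods <- detect_modules(a, min_module_size = 10, cut_height = 0.95)
  ari <- mclust::adjustedRandIndex(mods, sim$truth$module_of)
  expect_gte(ari, 0.8)

  noise <- simulate_modular(60, 40, c(2, 2), loading_hub = 0,
                            loading_member = 0, seed = 44)
  a0 <- adjacency_matrix(similarity_matrix(noise$expr), 6)
  mods0 <- suppressWarnings(detect_modules(a0, min_module_size = 10,
                                           cut_height = 0.25))
  expect_gt(mean(mods0 == "grey"), 0.5)
})

test_that("gcn fit object carries network summaries and exports", {
  sim <- simulate_modular(60, 40, c(20, 20), noise_sd = 0.5, seed = 45)
  net <- gcn(sim$expr, beta = 6, min_module_size = 10, cut_height = 0.97)
  expect_setequal(setdiff(unique(net$modules), "grey"),
                  c("turquoise", "blue"))
  expect_s3_class(net, "gcn")
  expect_equal(net$wgs, weighted_gene_score(net$adjacency))
  expect_output(print(net), "beta = 6")
  d <- withr::local_tempdir()
  edges <- write_edge_list(net, file.path(d, "edges.tsv"), floor = 0.05)
  expect_true(all(edges$weight >= 0.05))
  write_sif(edges, file.path(d, "net.sif"))
  sif <- readLines(file.path(d, "net.sif"))
  expect_length(sif, nrow(edges))
})
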