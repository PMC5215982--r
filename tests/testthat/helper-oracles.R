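# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration loops, stats::BIC on lm objects,
# rank-sum AUC by direct pair counting.

# Exact one-sided signed-rank p by enumerating every sign assignment.
oracle_signed_rank_p <- function(values, center) {
  r <- values - center
  r <- r[r != 0]
  n <- length(r)
  rk <- rank(abs(r))
  obs <- sum(rk[r > 0])
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(rk[signs == 1L]) >= obs) count <- count + 1L
  }
  count / 2^n
}

# AUC for scores (higher = more positive) by counting concordant pairs.
oracle_auc <- function(score_pos, score_neg) {
  wins <- 0
  for (a in score_pos) wins <- wins + sum(a > score_neg) +
      0.5 * sum(a == score_neg)
  wins / (length(score_pos) * length(score_neg))
}

# Full BMA enumeration with stats::BIC on lm fits, the sparse inclusion
# prior, and both Occam's-window rules, written with set operations rather
# than bit masks.
oracle_bma <- function(y, X, max_model_size = min(ncol(X), 8),
                       occam_or = 20, prior_inclusion = 0.05) {
  p <- ncol(X)
  subsets <- list(integer(0))
  for (k in seq_len(max_model_size))
    subsets <- c(subsets, utils::combn(p, k, simplify = FALSE))
  log_odds <- log(prior_inclusion / (1 - prior_inclusion))
  score <- numeric(length(subsets))
  coefs <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    df <- data.frame(y = y)
    if (length(s)) df <- cbind(df, as.data.frame(X[, s, drop = FALSE]))
    fit <- stats::lm(y ~ ., data = df)
    score[i] <- stats::BIC(fit) - 2 * length(s) * log_odds
    cf <- numeric(p)
    if (length(s)) cf[s] <- stats::coef(fit)[-1]
    coefs[[i]] <- cf
  }
  keep <- (score - min(score)) <= 2 * log(occam_or)
  for (i in which(keep)) {
    for (j in seq_along(subsets)) {
      if (j != i && keep[j] &&
          all(subsets[[j]] %in% subsets[[i]]) &&
          length(subsets[[j]]) < length(subsets[[i]]) &&
          score[j] <= score[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  w <- exp(-(score[keep] - min(score[keep])) / 2)
  w <- w / sum(w)
  post <- numeric(p)
  cf <- numeric(p)
  kept <- which(keep)
  for (j in seq_along(kept)) {
    s <- subsets[[kept[j]]]
    post[s] <- post[s] + w[j]
    cf <- cf + w[j] * coefs[[kept[j]]]
  }
  data.frame(predictor = colnames(X), posterior = post, coefficient = cf)
}

# Small planted-edge series configuration reused by recovery tests.
planted_edges_3 <- function() {
  data.frame(regulator = c(1, 2, 3), target = c(4, 5, 6), coefficient = 0.8)
}

edge_key <- function(reg, tgt) paste(reg, tgt, sep = "->")
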