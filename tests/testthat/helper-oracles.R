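# Independent brute-force oracles used to verify the implementations.

# binomial upper tail by direct binomial-coefficient summation
oracle_binom_tail <- function(k_from, n, p0 = 0.5) {
  if (k_from > n) return(0)
  ks <- k_from:n
  sum(choose(n, ks) * p0^ks * (1 - p0)^(n - ks))
}

# Benjamini-Hochberg step-up by the definitional min-over-tail formula
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    tail_ranks <- rank_i:m
    q[i] <- min(1, min(p[ord[tail_ranks]] * m / tail_ranks))
  }
  q
}

# brute-force KNN imputation: per missing cell, explicit loops over
# candidate donor observations and co-observed genes
oracle_knn <- function(v, k) {
  out <- v
  n_obs <- ncol(v)
  for (g in seq_len(nrow(v))) for (o in seq_len(n_obs)) {
    if (!is.na(v[g, o])) next
    donors <- setdiff(which(!is.na(v[g, ])), o)
    d <- vapply(donors, function(j) {
      shared <- which(!is.na(v[, o]) & !is.na(v[, j]))
      sqrt(mean((v[shared, o] - v[shared, j])^2))
    }, 0)
    nn <- donors[order(d)[seq_len(k)]]
    out[g, o] <- mean(v[g, nn])
  }
  out
}

# naive Ward agglomeration via the Lance-Williams update on squared
# Euclidean distances; returns cluster labels for every k
oracle_ward_partitions <- function(features) {
  n <- nrow(features)
  d <- as.matrix(stats::dist(features))
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- seq_len(n)
  partitions <- list()
  labels <- seq_len(n)
  partitions[[n]] <- labels
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    # Lance-Williams for ward.D2 on the remaining clusters
    for (kk in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[kk]
      d[i, kk] <- d[kk, i] <- sqrt(((ni + nk) * d[i, kk]^2 +
                                      (nj + nk) * d[j, kk]^2 -
                                      nk * d[i, j]^2) / (ni + nj + nk))
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
    labels <- integer(n)
    for (ci in seq_along(active)) labels[members[[active[ci]]]] <- ci
    partitions[[length(active)]] <- labels
  }
  partitions
}

# two partitions identical up to relabelling? (compare canonical forms:
# clusters renumbered by first appearance)
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# independent Wald interval expression (written separately from the
# implementation): logit-scale interval through the logistic function
oracle_wald_ci <- function(k, n) {
  p <- k / n
  half <- stats::qnorm(0.975) * sqrt(1 / k + 1 / (n - k))
  1 / (1 + exp(-(log(p / (1 - p)) + c(-1, 1) * half)))
}
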