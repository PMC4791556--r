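# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (loops, O(n^3) agglomeration) and share no code with the
# package internals.

rand_geno <- function(n, m, miss = 0.1, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  calls[runif(n * m) < miss] <- NA
  genotype_matrix(calls)
}

# per-column allele frequency by explicit loop
bf_freq <- function(calls) {
  sapply(seq_len(ncol(calls)), function(j) {
    x <- calls[, j]; x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else sum(x) / (2 * length(x))
  })
}

bf_nei <- function(calls) {
  p <- bf_freq(calls); p <- p[!is.na(p)]
  mean(sapply(p, function(pp) 1 - pp^2 - (1 - pp)^2))
}

bf_shannon <- function(calls) {
  p <- bf_freq(calls); p <- p[!is.na(p)]
  mean(sapply(p, function(pp) {
    s <- 0
    for (q in c(pp, 1 - pp)) if (q > 0) s <- s - q * log(q)
    s
  }))
}

# pairwise simple-matching distance by double loop
bf_smd <- function(calls) {
  n <- nrow(calls)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    d[i, j] <- if (!any(ok)) NA else 1 - sum(calls[i, ok] == calls[j, ok]) / sum(ok)
  }
  diag(d) <- 0
  d
}

# naive complete-linkage agglomerator: returns the partition at k groups
bf_complete_linkage <- function(d, k) {
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(groups)) for (b in seq_len(a - 1)) {
      dd <- max(d[groups[[a]], groups[[b]]])
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[1]]])
    groups[[best[1]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(groups)) lab[groups[[i]]] <- i
  lab
}

# canonical relabeling so partitions can be compared directly
canon <- function(lab) match(lab, unique(lab))

# independent largest-remainder apportionment (sort-based)
bf_apportion <- function(ideal, total, cap = rep(Inf, length(ideal))) {
  q <- pmin(floor(ideal), cap)
  while (sum(q) < total) {
    rem <- ideal - floor(ideal)
    rem[q >= cap] <- -Inf
    o <- order(-rem, seq_along(rem))
    q[o[1]] <- q[o[1]] + 1
    ideal[o[1]] <- floor(ideal[o[1]])  # consumed its remainder
  }
  as.integer(q)
}

# brute-force rare-allele scan: list of "marker allele" keys
bf_rare_keys <- function(calls, threshold = 0.05) {
  keys <- character(0)
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]; x <- x[!is.na(x)]
    if (length(x) == 0) next
    p_alt <- sum(x) / (2 * length(x))
    for (al in c("ref", "alt")) {
      f <- if (al == "alt") p_alt else 1 - p_alt
      if (f > 0 && f < threshold)
        keys <- c(keys, paste(colnames(calls)[j], al))
    }
  }
  keys
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# three well-separated Gaussian clusters in 3 dimensions
planted_gaussians <- function(seed, n_per = 100, shift = 6) {
  set.seed(seed)
  x <- matrix(rnorm(3 * n_per * 3), ncol = 3)
  x[n_per + seq_len(n_per), ] <- x[n_per + seq_len(n_per), ] + shift
  x[2 * n_per + seq_len(n_per), 2] <- x[2 * n_per + seq_len(n_per), 2] + shift
  list(x = x, truth = rep(1:3, each = n_per))
}

# fraction of the complete set's rare alleles present in an accession subset
rare_retention <- function(g, ids, rare) {
  sub <- g$calls[ids, match(rare$marker_id, colnames(g$calls)), drop = FALSE]
  alt <- colSums(sub >= 1, na.rm = TRUE) > 0
  ref <- colSums(sub <= 1, na.rm = TRUE) > 0
  100 * mean(ifelse(rare$allele == "alt", alt, ref))
}
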