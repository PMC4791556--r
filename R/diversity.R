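#' Per-marker allele frequencies
#'
#' Alternate-allele frequency per marker over the non-missing calls of the
#' chosen accession subset: `p_alt = sum(dosage) / (2 * n_called)`. Markers
#' with zero calls are flagged (`p_alt` and `maf` are `NA`) and excluded from
#' any downstream average.
#'
#' @param g a [genotype_matrix()].
#' @param subset accession IDs (or row index) to use; default all.
#' @return `data.frame` with columns `marker_id`, `n_called`, `p_alt`, `maf`.
#' @export
allele_frequencies <- function(g, subset = NULL) {
  calls <- g$calls
  if (!is.null(subset)) calls <- calls[subset, , drop = FALSE]
  if (nrow(calls) == 0) stop("empty accession subset")
  n_called <- nrow(calls) - colSums(is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  data.frame(marker_id = colnames(calls), n_called = n_called,
             p_alt = unname(p), maf = unname(pmin(p, 1 - p)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Allele-frequency spectrum classes
#'
#' Classifies the alternate-allele frequency (not the folded MAF) of every
#' marker into `below` \[0, lo), `within` \[lo, hi\] and `above` (hi, 1\];
#' markers without calls are left unclassified. Percentages are over the
#' classified markers.
#'
#' @param f output of [allele_frequencies()] (or a bare numeric vector of
#'   frequencies).
#' @param breaks two ordered cut points, default `c(0.05, 0.95)`.
#' @return list with integer `counts` and numeric `percent`, each named
#'   `below`/`within`/`above`, plus `n_classified`.
#' @export
maf_spectrum <- function(f, breaks = c(0.05, 0.95)) {
  stopifnot(length(breaks) == 2, breaks[1] <= breaks[2])
  p <- if (is.data.frame(f)) f$p_alt else as.numeric(f)
  p <- p[!is.na(p)]
  counts <- c(below = sum(p < breaks[1]),
              within = sum(p >= breaks[1] & p <= breaks[2]),
              above = sum(p > breaks[2]))
  list(counts = counts, percent = 100 * counts / sum(counts),
       n_classified = sum(counts))
}

# mean over markers of a per-marker diversity h(p), skipping no-call markers
.marker_diversity <- function(g, subset, h) {
  f <- allele_frequencies(g, subset)
  p <- f$p_alt[!is.na(f$p_alt)]
  if (length(p) == 0) stop("no callable markers in subset")
  v <- h(p)
  c(mean = mean(v), sd = stats::sd(v))
}

.nei_h <- function(p) 1 - (p^2 + (1 - p)^2)
.shannon_h <- function(p) {
  q <- 1 - p
  term <- function(x) ifelse(x > 0, -x * log(x), 0)
  term(p) + term(q)
}

#' Nei's gene diversity index
#'
#' Biallelic expected heterozygosity `1 - (p^2 + q^2)` averaged over markers
#' with at least one call. The index lies in \[0, 0.5\] per marker and is 0
#' when every marker is monomorphic in the group.
#'
#' @param g a [genotype_matrix()].
#' @param group accession IDs (or index) forming the group; default all.
#' @return the mean index, with the across-marker standard deviation as
#'   attribute `"sd"`.
#' @export
nei_index <- function(g, group = NULL) {
  v <- .marker_diversity(g, group, .nei_h)
  structure(unname(v["mean"]), sd = unname(v["sd"]))
}

#' Shannon's diversity index
#'
#' `-(p ln p + q ln q)` averaged over markers, with `0 * log(0)` taken as 0;
#' maximum `ln 2` per biallelic marker.
#'
#' @inheritParams nei_index
#' @return the mean index, with attribute `"sd"` as in [nei_index()].
#' @export
shannon_index <- function(g, group = NULL) {
  v <- .marker_diversity(g, group, .shannon_h)
  structure(unname(v["mean"]), sd = unname(v["sd"]))
}

#' Per-group diversity summary
#'
#' One row per group: accession count, Nei and Shannon indices (mean and SD
#' across markers), and — when metadata are supplied — the percentage of the
#' group's accessions from each region.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [group_assignment()].
#' @param info optional [accession_info()] metadata for region percentages.
#' @return `data.frame`, one row per group.
#' @export
diversity_summary <- function(g, groups, info = NULL) {
  lab <- .aligned_groups(g, groups)
  out <- lapply(sort(unique(lab)), function(k) {
    idx <- which(lab == k)
    nei <- nei_index(g, idx)
    sha <- shannon_index(g, idx)
    row <- data.frame(group = k, n = length(idx),
                      nei = as.numeric(nei), nei_sd = attr(nei, "sd"),
                      shannon = as.numeric(sha), shannon_sd = attr(sha, "sd"),
                      stringsAsFactors = FALSE)
    if (!is.null(info)) {
      reg <- info$region[match(rownames(g$calls)[idx], info$accession_id)]
      reg[is.na(reg)] <- "unknown"
      for (r in c("north", "central", "south", "unknown"))
        row[[paste0("pct_", r)]] <- 100 * mean(reg == r)
    }
    row
  })
  do.call(rbind, out)
}

#' Gene differentiation and gene flow
#'
#' Nei's coefficient of gene differentiation over two or more populations:
#' `H_S` is the size-weighted mean within-group gene diversity, `H_T` the
#' gene diversity at the pooled allele frequencies (both averaged over
#' markers), `G_ST = (H_T - H_S) / H_T`, and gene flow
#' `N_m = (1 - G_ST) / (4 G_ST)` — reported as `Inf` when `G_ST = 0`
#' (no differentiation).
#'
#' @param g a [genotype_matrix()].
#' @param groups a [group_assignment()] with at least two groups.
#' @return list of class `gene_flow_stats`: `h_t`, `h_s`, `g_st`, `n_m`.
#' @export
gst_and_nm <- function(g, groups) {
  lab <- .aligned_groups(g, groups)
  ks <- sort(unique(lab))
  if (length(ks) < 2) stop("G_ST is undefined for a single group")
  # per-marker pooled and within-group frequencies
  f_tot <- allele_frequencies(g)
  ok <- !is.na(f_tot$p_alt)
  ht_m <- .nei_h(f_tot$p_alt[ok])
  hs_m <- rep(0, sum(ok))
  wsum <- rep(0, sum(ok))
  for (k in ks) {
    idx <- which(lab == k)
    fk <- allele_frequencies(g, idx)
    pk <- fk$p_alt[ok]
    w <- length(idx)
    contrib <- ifelse(is.na(pk), 0, .nei_h(pk))
    hs_m <- hs_m + w * ifelse(is.na(pk), 0, contrib)
    wsum <- wsum + w * !is.na(pk)
  }
  hs_m <- ifelse(wsum > 0, hs_m / wsum, NA)
  keep <- !is.na(hs_m)
  h_t <- mean(ht_m[keep]); h_s <- mean(hs_m[keep])
  g_st <- if (h_t > 0) (h_t - h_s) / h_t else 0
  g_st <- min(max(g_st, 0), 1)
  n_m <- if (g_st == 0) Inf else (1 - g_st) / (4 * g_st)
  structure(list(h_t = h_t, h_s = h_s, g_st = g_st, n_m = n_m),
            class = "gene_flow_stats")
}

#' @export
print.gene_flow_stats <- function(x, ...) {
  cat(sprintf("H_T = %.4f  H_S = %.4f  G_ST = %.4f  N_m = %s\n",
              x$h_t, x$h_s, x$g_st,
              if (is.infinite(x$n_m)) "Inf (no differentiation)"
              else sprintf("%.3f", x$n_m)))
  invisible(x)
}

# Weir & Cockerham (1984) variance components for one pair/set of populations.
# calls: accessions x markers; lab: population label per accession.
.wc_theta <- function(calls, lab) {
  pops <- unique(lab)
  r <- length(pops)
  m <- ncol(calls)
  n_i <- p_i <- h_i <- matrix(0, r, m)
  for (i in seq_len(r)) {
    x <- calls[lab == pops[i], , drop = FALSE]
    n_i[i, ] <- colSums(!is.na(x))
    p_i[i, ] <- ifelse(n_i[i, ] > 0, colSums(x, na.rm = TRUE) / (2 * n_i[i, ]), 0)
    h_i[i, ] <- ifelse(n_i[i, ] > 0, colMeans(x == 1L, na.rm = TRUE), 0)
  }
  use <- colSums(n_i > 0) == r & colSums(n_i) > r  # every pop called, df > 0
  n_i <- n_i[, use, drop = FALSE]; p_i <- p_i[, use, drop = FALSE]
  h_i <- h_i[, use, drop = FALSE]
  nbar <- colMeans(n_i)
  nsum <- colSums(n_i)
  nc <- (nsum - colSums(n_i^2) / nsum) / (r - 1)
  pbar <- colSums(n_i * p_i) / nsum
  s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / nsum
  ok <- nbar > 1 & nc > 0
  nbar <- nbar[ok]; nc <- nc[ok]; pbar <- pbar[ok]; s2 <- s2[ok]; hbar <- hbar[ok]
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- sum(a + b + cc)
  if (denom <= 0) return(NA_real_)
  sum(a) / denom
}

# Nei pairwise differentiation: multilocus G_ST between two populations
.nei_pair_fst <- function(calls, lab) {
  pops <- unique(lab)
  p1 <- {x <- calls[lab == pops[1], , drop = FALSE]
         n <- colSums(!is.na(x)); ifelse(n > 0, colSums(x, na.rm = TRUE) / (2 * n), NA)}
  p2 <- {x <- calls[lab == pops[2], , drop = FALSE]
         n <- colSums(!is.na(x)); ifelse(n > 0, colSums(x, na.rm = TRUE) / (2 * n), NA)}
  ok <- !is.na(p1) & !is.na(p2)
  pbar <- (p1[ok] + p2[ok]) / 2
  h_t <- mean(.nei_h(pbar))
  h_s <- mean((.nei_h(p1[ok]) + .nei_h(p2[ok])) / 2)
  if (h_t <= 0) return(0)
  (h_t - h_s) / h_t
}

#' Pairwise F_ST between groups
#'
#' Multilocus pairwise differentiation for every pair of groups, by the
#' Weir–Cockerham (1984) theta estimator (default; ratio of summed variance
#' components, may be slightly negative for undifferentiated pairs — the
#' reported value is clamped at 0 with the raw estimates kept in attribute
#' `"raw"`) or by Nei's G_ST.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [group_assignment()].
#' @param estimator `"weir_cockerham"` or `"nei"`.
#' @return symmetric group x group matrix with zero diagonal.
#' @export
pairwise_fst <- function(g, groups, estimator = c("weir_cockerham", "nei")) {
  estimator <- match.arg(estimator)
  lab <- .aligned_groups(g, groups)
  ks <- sort(unique(lab))
  out <- raw <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  for (i in seq_along(ks)) for (j in seq_len(i - 1)) {
    sel <- lab %in% c(ks[i], ks[j])
    est <- if (estimator == "weir_cockerham")
      .wc_theta(g$calls[sel, , drop = FALSE], lab[sel])
    else .nei_pair_fst(g$calls[sel, , drop = FALSE], lab[sel])
    raw[i, j] <- raw[j, i] <- est
    out[i, j] <- out[j, i] <- min(max(est, 0), 1)
  }
  attr(out, "raw") <- raw
  attr(out, "estimator") <- estimator
  out
}

#' Multilocus Weir-Cockerham F_ST over all groups
#'
#' @inheritParams pairwise_fst
#' @return single multilocus theta estimate.
#' @export
wc_fst <- function(g, groups) {
  lab <- .aligned_groups(g, groups)
  if (length(unique(lab)) < 2) stop("need at least two groups")
  .wc_theta(g$calls, lab)
}

#' Simple-matching genotype distance
#'
#' `d(x, y) = 1 - M/N` where `M` counts markers at which the two accessions
#' carry the same genotype call (heterozygotes match only heterozygotes) and
#' `N` counts markers where both calls are present. Pairs with `N = 0` are
#' flagged missing (`NA`). The squared-Euclidean transform used by the
#' classification procedure is available as a view via
#' [as_squared_euclidean()], never applied silently.
#'
#' @param g a [genotype_matrix()].
#' @return object of class `pair_distance`: list with symmetric matrices `d`
#'   (distances, zero diagonal) and `n_pairs` (non-missing pair counts).
#' @export
simple_matching_distance <- function(g) {
  calls <- g$calls
  pres <- !is.na(calls)
  storage.mode(pres) <- "double"
  n_pairs <- tcrossprod(pres)
  m <- matrix(0, nrow(calls), nrow(calls))
  for (v in 0:2) {
    iv <- !is.na(calls) & calls == v
    storage.mode(iv) <- "double"
    m <- m + tcrossprod(iv)
  }
  d <- 1 - m / n_pairs
  d[n_pairs == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- dimnames(n_pairs) <- list(rownames(calls), rownames(calls))
  structure(list(d = d, n_pairs = n_pairs), class = "pair_distance")
}

#' Squared-Euclidean view of a simple-matching distance
#'
#' Under 0/1 recoding of per-marker matches the squared Euclidean distance is
#' `2 * N * d`, with `N` the per-pair count of non-missing comparisons.
#'
#' @param d a `pair_distance` from [simple_matching_distance()].
#' @return matrix of squared-Euclidean distances.
#' @export
as_squared_euclidean <- function(d) {
  stopifnot(inherits(d, "pair_distance"))
  2 * d$n_pairs * d$d
}

#' @export
print.pair_distance <- function(x, ...) {
  cat("pair_distance over", nrow(x$d), "accessions; mean d =",
      sprintf("%.4f", mean(x$d[upper.tri(x$d)], na.rm = TRUE)), "\n")
  invisible(x)
}

#' Complete-linkage classification
#'
#' Agglomerative clustering where the distance between two groups is the
#' maximum distance over all cross-group pairs. Merge heights are
#' non-decreasing; the result is deterministic for tie-free distances.
#'
#' @param d a `pair_distance` or a symmetric distance matrix.
#' @param k number of groups, or `NULL` to cut at `h`.
#' @param h cut height when `k` is `NULL`.
#' @return a [group_assignment()] with provenance `"genetic"`, carrying the
#'   `hclust` tree as attribute `"tree"`.
#' @export
complete_linkage_cluster <- function(d, k = NULL, h = NULL) {
  m <- if (inherits(d, "pair_distance")) d$d else as.matrix(d)
  if (anyNA(m)) stop("distance matrix has flagged-missing pairs; cannot cluster")
  tree <- stats::hclust(stats::as.dist(m), method = "complete")
  lab <- if (!is.null(k)) stats::cutree(tree, k = k)
         else if (!is.null(h)) stats::cutree(tree, h = h)
         else stop("supply k or h")
  ga <- group_assignment(rownames(m), as.character(lab), "genetic")
  attr(ga, "tree") <- tree
  ga
}

#' Select markers as equally spaced as possible along chromosomes
#'
#' Reproduces the four-step map-thinning procedure used to pick a small
#' marker panel for diversity statistics: (1) give each chromosome a quota
#' proportional to its share of mapped markers (largest-remainder rounding so
#' the quotas sum exactly to `total`); (2) divide the span between the first
#' and last marker of the chromosome by the quota; (3) lay a grid of quota
#' points starting at the first marker with that step; (4) take the mapped
#' marker nearest to each grid point, without replacement, ties going to the
#' lower position.
#'
#' @param markers `data.frame` with columns `marker_id`, `chrom`, `pos`
#'   (e.g. the `markers` element of a [genotype_matrix()]); rows with unknown
#'   chromosome or position are ignored.
#' @param total number of markers to select.
#' @return character vector of selected marker IDs.
#' @export
select_spaced_markers <- function(markers, total) {
  mk <- markers[!is.na(markers$chrom) & !is.na(markers$pos), , drop = FALSE]
  if (nrow(mk) < total) stop("total exceeds the number of mapped markers")
  counts <- table(mk$chrom)
  quota <- largest_remainder(total * as.numeric(counts) / nrow(mk),
                             total, cap = as.numeric(counts))
  names(quota) <- names(counts)
  out <- character(0)
  for (ch in names(counts)) {
    q <- quota[[ch]]
    if (q == 0) next
    sub <- mk[mk$chrom == ch, , drop = FALSE]
    ord <- order(sub$pos, sub$marker_id)
    sub <- sub[ord, , drop = FALSE]
    span <- max(sub$pos) - min(sub$pos)
    grid <- min(sub$pos) + (seq_len(q) - 1) * (span / q)
    taken <- rep(FALSE, nrow(sub))
    for (gp in grid) {
      dist <- abs(sub$pos - gp)
      dist[taken] <- Inf
      # nearest unused marker; ties broken toward the lower position (rows
      # are position-sorted so which.min takes the first = lowest)
      sel <- which.min(dist)
      taken[sel] <- TRUE
    }
    out <- c(out, sub$marker_id[taken])
  }
  out
}
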