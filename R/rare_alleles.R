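#' Identify rare alleles in a population
#'
#' An allele is rare when its frequency in the reference population lies
#' strictly inside `(0, threshold)`: frequency 0 is a lost allele, and the
#' threshold itself is excluded. With the conventional threshold of 0.05 a
#' biallelic marker can contribute at most one rare allele.
#'
#' @param g a [genotype_matrix()].
#' @param population accession IDs (or index) defining the reference
#'   population; default all.
#' @param threshold upper (open) frequency bound, default 0.05.
#' @return `data.frame` of class `rare_allele_set` with columns `marker_id`,
#'   `allele` (`"ref"` or `"alt"`) and `freq` (the allele's frequency in the
#'   reference population).
#' @export
define_rare_alleles <- function(g, population = NULL, threshold = 0.05) {
  f <- allele_frequencies(g, population)
  p <- f$p_alt
  alt_rare <- !is.na(p) & p > 0 & p < threshold
  ref_rare <- !is.na(p) & (1 - p) > 0 & (1 - p) < threshold
  out <- rbind(
    data.frame(marker_id = f$marker_id[alt_rare],
               allele = rep("alt", sum(alt_rare)),
               freq = p[alt_rare], stringsAsFactors = FALSE),
    data.frame(marker_id = f$marker_id[ref_rare],
               allele = rep("ref", sum(ref_rare)),
               freq = 1 - p[ref_rare], stringsAsFactors = FALSE))
  out <- out[order(match(out$marker_id, f$marker_id)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rare_allele_set", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

# for each (marker_id, allele) pair of `set`, is the allele carried by any
# accession in `rows`? (alt allele: dosage >= 1; ref allele: dosage <= 1)
.carried_in <- function(calls, rows, set) {
  if (nrow(set) == 0) return(logical(0))
  sub <- calls[rows, match(set$marker_id, colnames(calls)), drop = FALSE]
  alt_any <- colSums(sub >= 1L, na.rm = TRUE) > 0
  ref_any <- colSums(sub <= 1L, na.rm = TRUE) > 0
  ifelse(set$allele == "alt", alt_any, ref_any)
}

#' Per-group rare-allele report
#'
#' For each group: `nra` (rare-allele count), `nac` (accession count), `raf`
#' (mean frequency of the group's rare alleles), `napa = nra/nac` (rare
#' alleles per accession, 2 decimals), `nura` (rare alleles unique to the
#' group) and `pura = 100 * nura/nra`. Under `scope = "per_group_population"`
#' each group is its own reference population (rarity judged at within-group
#' frequencies); under `"complete_set"` rarity is judged once in the complete
#' population and `nra` counts the complete-set rare alleles carried by at
#' least one member of the group.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [group_assignment()].
#' @param scope reference-population convention, see Details.
#' @param threshold rare-frequency bound, default 0.05.
#' @return `data.frame`, one row per group, plus the complete-set rare count
#'   as attribute `"complete_nra"`.
#' @export
rare_alleles_per_group <- function(g, groups,
                                   scope = c("per_group_population",
                                             "complete_set"),
                                   threshold = 0.05) {
  scope <- match.arg(scope)
  lab <- .aligned_groups(g, groups)
  ks <- sort(unique(lab))
  complete <- define_rare_alleles(g, threshold = threshold)
  sets <- list()
  for (k in ks) {
    idx <- which(lab == k)
    if (scope == "per_group_population") {
      sets[[k]] <- define_rare_alleles(g, idx, threshold)
    } else {
      sets[[k]] <- complete[.carried_in(g$calls, idx, complete), , drop = FALSE]
    }
  }
  uq <- unique_rare_alleles(g, groups, sets)
  out <- do.call(rbind, lapply(ks, function(k) {
    idx <- which(lab == k)
    nra <- nrow(sets[[k]])
    data.frame(group = k, nra = nra, nac = length(idx),
               raf = if (nra > 0) mean(sets[[k]]$freq) else NA_real_,
               napa = round(nra / length(idx), 2),
               nura = uq$nura[uq$group == k],
               pura = uq$pura[uq$group == k],
               stringsAsFactors = FALSE)
  }))
  attr(out, "complete_nra") <- nrow(complete)
  attr(out, "scope") <- scope
  attr(out, "sets") <- sets
  out
}

#' Unique rare alleles per group
#'
#' An allele is unique to group `k` when it is rare in `k`'s reference
#' population and (a) is not in any other group's rare set and (b) is carried
#' by no accession outside `k`. Clause (b) makes the count invariant to group
#' sizes: duplicating a group's accessions changes neither `nura` nor `pura`.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [group_assignment()].
#' @param sets optional named list of per-group [define_rare_alleles()]
#'   results; computed per-group-population when omitted.
#' @param threshold rare-frequency bound when `sets` is computed here.
#' @return `data.frame` with columns `group`, `nra`, `nura`, `pura`.
#' @export
unique_rare_alleles <- function(g, groups, sets = NULL, threshold = 0.05) {
  lab <- .aligned_groups(g, groups)
  ks <- sort(unique(lab))
  if (is.null(sets)) {
    sets <- lapply(ks, function(k)
      define_rare_alleles(g, which(lab == k), threshold))
    names(sets) <- ks
  }
  key <- function(s) if (nrow(s)) paste(s$marker_id, s$allele) else character(0)
  keys <- lapply(sets, key)
  out <- do.call(rbind, lapply(ks, function(k) {
    mine <- keys[[k]]
    others <- unlist(keys[setdiff(ks, k)], use.names = FALSE)
    cand <- sets[[k]][mine %in% setdiff(mine, others), , drop = FALSE]
    outside <- which(lab != k)
    nura <- sum(!.carried_in(g$calls, outside, cand))
    nra <- length(mine)
    data.frame(group = k, nra = nra, nura = nura,
               pura = if (nra > 0) 100 * nura / nra else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Geographic k-means clustering of collection sites
#'
#' k-means (Euclidean distance, least-squares criterion) on standardized
#' latitude, longitude and altitude; accessions missing any coordinate are
#' left out. Multiple restarts, best within-cluster sum of squares kept;
#' deterministic given the seed.
#'
#' @param info an [accession_info()] table.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart number of random restarts (default 10).
#' @return list of class `geo_clusters`: `assignment` (a
#'   [group_assignment()], provenance `"geographic"`), `centers` (cluster
#'   means on the original coordinate scale) and `inertia` (total
#'   within-cluster sum of squares on the standardized scale).
#' @export
geo_kmeans <- function(info, k, seed = 1L, nstart = 10) {
  ok <- !is.na(info$latitude) & !is.na(info$longitude) & !is.na(info$altitude)
  if (sum(ok) < k) stop("fewer accessions with coordinates than clusters")
  x <- as.matrix(info[ok, c("latitude", "longitude", "altitude")])
  xs <- .safe_scale(x)
  set.seed(seed)
  if (k == nrow(xs)) {  # every site its own cluster, zero inertia
    km <- list(cluster = seq_len(k), tot.withinss = 0)
  } else {
    km <- stats::kmeans(xs, centers = k, nstart = nstart, iter.max = 100)
  }
  centers <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(x[km$cluster == cl, , drop = FALSE])))
  structure(list(
    assignment = group_assignment(info$accession_id[ok],
                                  paste0("geo", km$cluster), "geographic"),
    centers = as.data.frame(centers), inertia = km$tot.withinss),
    class = "geo_clusters")
}

#' Cross-classification of geographic clusters and genetic groups
#'
#' Contingency table of accessions carrying both a geographic cluster label
#' and a genetic group label; row/column sums equal the cluster and group
#' sizes among those accessions.
#'
#' @param geo a `geo_clusters` object (or [group_assignment()]).
#' @param genetic a [group_assignment()].
#' @return `table` (geo clusters x genetic groups).
#' @export
cross_classify <- function(geo, genetic) {
  ga <- if (inherits(geo, "geo_clusters")) geo$assignment else geo
  common <- intersect(ga$accession_id, genetic$accession_id)
  table(geo = ga$group[match(common, ga$accession_id)],
        genetic = genetic$group[match(common, genetic$accession_id)])
}

#' Scan for alleles fixed within geographic clusters
#'
#' Within a cluster, a marker is reported as fixed when its call rate among
#' cluster members is at least `min_callrate` (default 60\%), it does not
#' segregate within the cluster (within-cluster MAF equal to 0 under the
#' default `"strict"` rule, or below the rare threshold under `"rare"`), and
#' it does segregate (MAF > 0) in the complete set. The scan emits marker
#' IDs and positions for external genome mapping.
#'
#' @param g a [genotype_matrix()].
#' @param clusters a `geo_clusters` object or [group_assignment()].
#' @param min_callrate minimum within-cluster call rate gate, default 0.6.
#' @param rule `"strict"` (MAF = 0) or `"rare"` (MAF < `threshold`).
#' @param threshold bound used by the `"rare"` rule, default 0.05.
#' @return named list (one element per cluster) of `data.frame`s with
#'   `marker_id`, `chrom`, `pos`, `fixed_allele` (`"ref"` or `"alt"`).
#' @export
fixed_allele_scan <- function(g, clusters, min_callrate = 0.6,
                              rule = c("strict", "rare"), threshold = 0.05) {
  rule <- match.arg(rule)
  ga <- if (inherits(clusters, "geo_clusters")) clusters$assignment else clusters
  f_all <- allele_frequencies(g)
  segregating <- !is.na(f_all$maf) & f_all$maf > 0
  out <- list()
  for (k in sort(unique(ga$group))) {
    ids <- ga$accession_id[ga$group == k]
    ids <- intersect(ids, rownames(g$calls))
    sub <- g$calls[ids, , drop = FALSE]
    callrate <- colMeans(!is.na(sub))
    fk <- allele_frequencies(g, ids)
    fixed <- if (rule == "strict") !is.na(fk$maf) & fk$maf == 0
             else !is.na(fk$maf) & fk$maf < threshold
    hit <- which(callrate >= min_callrate & fixed & segregating)
    out[[k]] <- data.frame(
      marker_id = f_all$marker_id[hit],
      chrom = g$markers$chrom[hit], pos = g$markers$pos[hit],
      fixed_allele = ifelse(fk$p_alt[hit] >= 0.5, "alt", "ref"),
      stringsAsFactors = FALSE)
  }
  out
}
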