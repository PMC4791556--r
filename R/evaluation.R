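#' Compare a core set with the complete set
#'
#' Computes the summary fields used to judge core representativeness:
#' lost-allele counts (markers with MAF = 0) in each set, rare-allele counts
#' and percentages over the total allele count (2 x markers), recovery of
#' the complete set's rare alleles in the core (an allele is recovered when
#' its core frequency is above 0 — the only definition under which recovery
#' and loss percentages sum to 100), the number of complete-set rare alleles
#' whose core frequency reaches 0.05, Shannon and Nei indices per set,
#' accession counts and region percentages.
#'
#' @param g a [genotype_matrix()] of the complete set.
#' @param core a `core_set` or character vector of core accession IDs.
#' @param info optional [accession_info()] for region percentages.
#' @param threshold rare-allele bound, default 0.05.
#' @return list of class `core_comparison`, printable as a two-column table.
#' @export
compare_core_complete <- function(g, core, info = NULL, threshold = 0.05) {
  ids <- if (inherits(core, "core_set")) core$accession_ids else core
  stopifnot(all(ids %in% rownames(g$calls)))
  gc <- subset_accessions(g, ids)
  m <- ncol(g$calls)
  f_all <- allele_frequencies(g)
  f_core <- allele_frequencies(gc)
  rare_all <- define_rare_alleles(g, threshold = threshold)
  rare_core <- define_rare_alleles(gc, threshold = threshold)

  core_freq_of <- function(set) {
    j <- match(set$marker_id, f_core$marker_id)
    p <- f_core$p_alt[j]
    ifelse(set$allele == "alt", p, 1 - p)
  }
  pcf <- core_freq_of(rare_all)
  recovered <- !is.na(pcf) & pcf > 0
  promoted <- !is.na(pcf) & pcf >= threshold
  # no rare alleles to lose: recovery is vacuously complete
  recovery_pct <- if (nrow(rare_all) == 0) 100
                  else 100 * sum(recovered) / nrow(rare_all)

  region_pct <- function(set_ids) {
    if (is.null(info)) return(NULL)
    reg <- info$region[match(set_ids, info$accession_id)]
    reg[is.na(reg)] <- "unknown"
    vapply(c("north", "central", "south", "unknown"),
           function(r) 100 * mean(reg == r), numeric(1))
  }
  structure(list(
    n_markers = m,
    lost_alleles = c(complete = sum(f_all$maf == 0, na.rm = TRUE),
                     core = sum(f_core$maf == 0, na.rm = TRUE)),
    n_rare = c(complete = nrow(rare_all), core = nrow(rare_core)),
    pct_rare = c(complete = 100 * nrow(rare_all) / (2 * m),
                 core = 100 * nrow(rare_core) / (2 * m)),
    rare_cs_recovery_pct = recovery_pct,
    rare_cs_loss_pct = 100 - recovery_pct,
    rare_cs_promoted = sum(promoted),
    shannon = c(complete = as.numeric(shannon_index(g)),
                core = as.numeric(shannon_index(gc))),
    nei = c(complete = as.numeric(nei_index(g)),
            core = as.numeric(nei_index(gc))),
    n_accessions = c(complete = nrow(g$calls), core = nrow(gc$calls)),
    region_pct = list(complete = region_pct(rownames(g$calls)),
                      core = region_pct(ids))),
    class = "core_comparison")
}

#' @export
print.core_comparison <- function(x, ...) {
  fmt <- function(v) if (is.numeric(v)) sprintf("%.2f", v) else v
  cat("                         complete      core\n")
  cat(sprintf("lost alleles [MAF=0]   %8d  %8d\n",
              x$lost_alleles["complete"], x$lost_alleles["core"]))
  cat(sprintf("rare alleles           %8d  %8d\n",
              x$n_rare["complete"], x$n_rare["core"]))
  cat(sprintf("%% rare alleles         %8.2f  %8.2f\n",
              x$pct_rare["complete"], x$pct_rare["core"]))
  cat(sprintf("%% rare-CS recovery       100.00  %8.2f\n",
              x$rare_cs_recovery_pct))
  cat(sprintf("rare-CS freq >= 0.05          -  %8d\n", x$rare_cs_promoted))
  cat(sprintf("Shannon index          %8.2f  %8.2f\n",
              x$shannon["complete"], x$shannon["core"]))
  cat(sprintf("Nei index              %8.2f  %8.2f\n",
              x$nei["complete"], x$nei["core"]))
  cat(sprintf("accessions             %8d  %8d\n",
              x$n_accessions["complete"], x$n_accessions["core"]))
  invisible(x)
}

#' Per-trait mean and variance ratios, complete over core
#'
#' Missing-aware ratios of the complete-set trait mean (and variance) to the
#' core-set value; all ratios are exactly 1 when the core equals the
#' complete set.
#'
#' @param pheno a [phenotype_table()] of the complete set.
#' @param core a `core_set` or character vector of core accession IDs.
#' @return `data.frame` with columns `trait`, `mean_ratio`, `var_ratio`.
#' @export
phenotype_ratio_report <- function(pheno, core) {
  ids <- if (inherits(core, "core_set")) core$accession_ids else core
  idx <- match(ids, pheno$accession_ids)
  if (anyNA(idx)) stop("core accessions missing from the phenotype table")
  out <- do.call(rbind, lapply(names(pheno$traits), function(tr) {
    x <- as.numeric(pheno$traits[[tr]])
    xc <- x[idx]
    data.frame(trait = tr,
               mean_ratio = mean(x, na.rm = TRUE) / mean(xc, na.rm = TRUE),
               var_ratio = stats::var(x, na.rm = TRUE) /
                 stats::var(xc, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Metric (classical) MDS via eigendecomposition of the doubly-centered
#' squared-distance matrix; coordinates are centered and Kruskal-type stress
#' `sqrt(sum (d - dhat)^2 / sum d^2)` is reported. Used to display the
#' positions of core accessions inside the complete collection.
#'
#' @param d a `pair_distance` or symmetric distance matrix.
#' @param dims embedding dimension, default 2.
#' @return list of class `mds_map`: `coords` (rows named by accession),
#'   `stress`, `eig`.
#' @export
mds_coordinates <- function(d, dims = 2) {
  m <- if (inherits(d, "pair_distance")) d$d else as.matrix(d)
  if (anyNA(m)) stop("distance matrix has flagged-missing pairs")
  fit <- stats::cmdscale(stats::as.dist(m), k = dims, eig = TRUE)
  coords <- sweep(fit$points, 2, colMeans(fit$points))
  dhat <- as.matrix(stats::dist(coords))
  up <- upper.tri(m)
  stress <- sqrt(sum((m[up] - dhat[up])^2) / sum(m[up]^2))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  structure(list(coords = coords, stress = stress, eig = fit$eig),
            class = "mds_map")
}

#' @export
print.mds_map <- function(x, ...) {
  cat("mds_map:", nrow(x$coords), "points in", ncol(x$coords),
      sprintf("dimensions, stress %.4f\n", x$stress))
  invisible(x)
}
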