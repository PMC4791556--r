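#' Principal-component reduction of the marker matrix
#'
#' Missing calls are mean-imputed per marker, columns are centered, and the
#' decomposition is taken through the eigenvectors of the accession-side Gram
#' matrix (equivalent to a thin SVD, and cheap when accessions are far fewer
#' than markers). Components are ordered by variance explained; each score
#' column's sign is fixed so its largest-magnitude entry is positive, making
#' the result reproducible up to that convention.
#'
#' @param g a [genotype_matrix()] or plain numeric matrix.
#' @param n_components number of components to keep, or `NULL` to use
#'   `variance_target`.
#' @param variance_target when `n_components` is `NULL`: keep the smallest
#'   number of components whose cumulative variance fraction reaches this
#'   value.
#' @return list of class `pca_reduction`: `scores` (accessions x components),
#'   `variance` (per-component variance), `variance_explained` (fractions),
#'   `cum_variance_explained`.
#' @export
pca_reduce <- function(g, n_components = NULL, variance_target = NULL) {
  x <- if (inherits(g, "genotype_matrix")) {
    calls <- g$calls
    storage.mode(calls) <- "double"
    mu <- colMeans(calls, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(calls))
    if (length(idx)) calls[idx] <- mu[(idx - 1) %/% nrow(calls) + 1]
    calls
  } else as.matrix(g)
  xc <- sweep(x, 2, colMeans(x))
  gram <- tcrossprod(xc)
  e <- eigen(gram, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  pos <- lam > max(lam) * 1e-12
  rank <- sum(pos)
  varex <- lam / sum(lam)
  k <- if (!is.null(n_components)) min(n_components, rank)
       else if (!is.null(variance_target))
         which(cumsum(varex) >= variance_target - 1e-12)[1]
       else rank
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, variance = lam[seq_len(k)] / (nrow(x) - 1),
                 variance_explained = varex[seq_len(k)],
                 cum_variance_explained = cumsum(varex)[seq_len(k)],
                 total_rank = rank),
            class = "pca_reduction")
}

# standardize a phenotype table to a numeric z-scored matrix
.pheno_matrix <- function(pheno) {
  x <- as.matrix(as.data.frame(lapply(pheno$traits, as.numeric)))
  rownames(x) <- pheno$accession_ids
  # column-mean imputation keeps the MFA defined under scattered missingness
  for (j in seq_len(ncol(x))) {
    mj <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- mj
  }
  .safe_scale(x)
}

# cumulative block contributions (%) over the first n_axes of the MFA of
# [Z1, w * Z2]; blocks already MFA-normalized
.mfa_contrib <- function(z1, z2, w, n_axes) {
  z <- cbind(z1, w * z2)
  sv <- svd(z, nu = n_axes, nv = min(ncol(z), max(n_axes, 2)))
  lam <- sv$d^2
  k <- min(n_axes, length(lam))
  v <- sv$v
  b1 <- seq_len(ncol(z1))
  ctr1 <- vapply(seq_len(k), function(s) sum(v[b1, s]^2), numeric(1))
  num <- sum(lam[seq_len(k)] * ctr1)
  den <- sum(lam[seq_len(k)])
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  list(geno_pct = 100 * num / den,
       per_axis_geno_pct = 100 * ctr1,
       eigenvalues = lam[seq_len(k)],
       variance_explained = lam[seq_len(k)] / sum(lam),
       scores = scores)
}

#' Two-block multiple factor analysis with a block-contribution constraint
#'
#' Multiple factor analysis of a genotype block (typically PCA scores of the
#' marker matrix) and a phenotype block: each block is column-standardized
#' (ordinal traits as numeric level codes) and divided by the square root of
#' its first PCA eigenvalue so neither block dominates a priori, then the
#' phenotype block is rescaled by a scalar weight `w` found by bisection so
#' that the cumulative genotype:phenotype contributions to the variance
#' explained by the first `n_axes` axes hit `target_ratio` within `tol`
#' percentage points. The contribution of a block to an axis is the summed
#' squared loading of its columns; the cumulative figure weights axes by
#' their eigenvalues.
#'
#' @param geno_scores numeric matrix (accessions x genotype variables), e.g.
#'   `pca_reduce(g)$scores`.
#' @param pheno a [phenotype_table()] (or numeric matrix) aligned to the same
#'   accessions.
#' @param n_axes number of leading axes the constraint applies to, default 6.
#' @param target_ratio genotype:phenotype percentages, default `c(75, 25)`.
#' @param tol tolerance in percentage points, default 1.
#' @param max_iter bisection iterations cap.
#' @return list of class `hmfa_result`: `scores` (accessions x `n_axes`),
#'   `variance_explained`, `block_contrib` (per-axis genotype %),
#'   `cum_contrib` (cumulative genotype/phenotype %), `weight` (the fitted
#'   `w`).
#' @export
hmfa_two_block <- function(geno_scores, pheno, n_axes = 6,
                           target_ratio = c(75, 25), tol = 1,
                           max_iter = 60) {
  stopifnot(length(target_ratio) == 2, all(target_ratio > 0))
  target <- 100 * target_ratio[1] / sum(target_ratio)
  z1 <- .safe_scale(as.matrix(geno_scores))
  z2 <- if (inherits(pheno, "phenotype_table")) .pheno_matrix(pheno)
        else .safe_scale(as.matrix(pheno))
  if (nrow(z1) != nrow(z2)) stop("blocks must cover the same accessions")
  if (all(abs(z2) < 1e-12))
    stop("phenotype block has zero variance; contributions are 100:0 and the ",
         "requested ratio is unattainable")
  # MFA normalization: divide each block by sqrt of its first eigenvalue
  lead_eig <- function(z) svd(z, nu = 0, nv = 0)$d[1]^2
  z1 <- z1 / sqrt(lead_eig(z1))
  z2 <- z2 / sqrt(lead_eig(z2))
  fct <- function(logw) .mfa_contrib(z1, z2, 10^logw, n_axes)$geno_pct
  lo <- -6; hi <- 6
  g_lo <- fct(lo); g_hi <- fct(hi)   # geno share decreases in w
  if (target > g_lo + tol || target < g_hi - tol)
    stop(sprintf(paste0("target genotype contribution %.1f%% unattainable; ",
                        "achievable range [%.1f%%, %.1f%%] for w in ",
                        "[1e-6, 1e6]"), target, g_hi, g_lo))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g_mid <- fct(mid)
    if (abs(g_mid - target) <= tol * 0.25) break
    if (g_mid > target) lo <- mid else hi <- mid
  }
  w <- 10^mid
  fit <- .mfa_contrib(z1, z2, w, n_axes)
  if (abs(fit$geno_pct - target) > tol)
    stop("bisection failed to reach the target contribution ratio")
  scores <- fit$scores
  rownames(scores) <- rownames(z1)
  colnames(scores) <- paste0("PA", seq_len(ncol(scores)))
  structure(list(scores = scores,
                 variance_explained = fit$variance_explained,
                 eigenvalues = fit$eigenvalues,
                 block_contrib = data.frame(
                   axis = seq_along(fit$per_axis_geno_pct),
                   geno_pct = fit$per_axis_geno_pct,
                   pheno_pct = 100 - fit$per_axis_geno_pct),
                 cum_contrib = c(geno = fit$geno_pct,
                                 pheno = 100 - fit$geno_pct),
                 weight = w, n_axes = n_axes),
            class = "hmfa_result")
}

#' @export
print.hmfa_result <- function(x, ...) {
  cat(sprintf(paste0("hmfa_result: %d axes, cumulative contributions ",
                     "%.1f:%.1f (geno:pheno), w = %.4g\n"),
              x$n_axes, x$cum_contrib["geno"], x$cum_contrib["pheno"],
              x$weight))
  invisible(x)
}

# one EM run for a Gaussian mixture with shared full (or per-group diagonal)
# covariance, initialized from hard labels
.em_gmm <- function(x, init, covariance = "shared", max_iter = 200,
                    tol = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  G <- length(unique(init))
  resp <- matrix(0, n, G)
  resp[cbind(seq_len(n), match(init, sort(unique(init))))] <- 1
  ll_old <- -Inf
  ll_trace <- numeric(0)
  ridge_used <- FALSE
  for (iter in seq_len(max_iter)) {
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-8)
    pi_k <- nk / n
    mu <- crossprod(resp, x) / nk
    if (covariance == "shared") {
      sigma <- matrix(0, d, d)
      for (k in seq_len(G)) {
        xc <- sweep(x, 2, mu[k, ])
        sigma <- sigma + crossprod(xc * resp[, k], xc)
      }
      sigma <- sigma / n
      ch <- tryCatch(chol(sigma), error = function(e) NULL)
      if (is.null(ch)) {
        ridge_used <- TRUE
        sigma <- sigma + diag(1e-6 * mean(diag(sigma)) + 1e-12, d)
        ch <- chol(sigma)
      }
      logd <- vapply(seq_len(G), function(k) .dmvnorm_log(x, mu[k, ], ch),
                     numeric(n))
    } else {  # per-group diagonal
      logd <- vapply(seq_len(G), function(k) {
        xc <- sweep(x, 2, mu[k, ])
        v <- colSums(xc^2 * resp[, k]) / nk[k]
        v <- pmax(v, 1e-10)
        -0.5 * rowSums(sweep(xc^2, 2, v, "/")) - 0.5 * sum(log(v)) -
          0.5 * d * log(2 * pi)
      }, numeric(n))
    }
    logw <- sweep(logd, 2, log(pi_k), "+")
    mx <- apply(logw, 1, max)
    lse <- mx + log(rowSums(exp(logw - mx)))
    ll <- sum(lse)
    resp <- exp(logw - lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
    ll_old <- ll
  }
  if (ridge_used)
    warning("degenerate covariance; ridge regularization applied")
  list(means = mu, sigma = if (covariance == "shared") sigma else NULL,
       weights = pi_k, resp = resp, loglik = ll, ll_trace = ll_trace,
       assignment = max.col(resp, ties.method = "first"))
}

#' Ward-initialized Gaussian-mixture clustering (Ward-MLM)
#'
#' Two-stage grouping of accessions on factor-analysis axes. Stage 1: Ward
#' agglomeration on Euclidean distances gives hard groups for each candidate
#' number of groups `G`. Stage 2: those groups initialize EM for a Gaussian
#' mixture (shared full covariance by default, per-group diagonal available).
#' The number of groups is selected over `g_range` by BIC (default) or by a
#' log-likelihood plateau rule (smallest `G` whose gain over `G - 1` falls
#' below 1\%) matching a raw maximum-likelihood reading. Deterministic: the
#' Ward initialization fixes the EM start.
#'
#' @param scores numeric matrix (accessions x axes), e.g.
#'   `hmfa_two_block(...)$scores`.
#' @param g_range candidate numbers of groups, e.g. `1:25`.
#' @param seed integer seed (kept for interface stability; the procedure is
#'   deterministic).
#' @param criterion `"bic"` or `"loglik"`.
#' @param covariance `"shared"` (full, pooled) or `"diagonal"` (per-group).
#' @return list of class `mixture_fit`: `G`, `assignment` (a
#'   [group_assignment()] with provenance `"mixture"`), `means`, `sigma`,
#'   `weights`, `resp`, `loglik`, `model_scores` (per-candidate BIC and
#'   log-likelihood).
#' @export
ward_mlm_cluster <- function(scores, g_range, seed = 1L,
                             criterion = c("bic", "loglik"),
                             covariance = c("shared", "diagonal")) {
  criterion <- match.arg(criterion)
  covariance <- match.arg(covariance)
  x <- as.matrix(scores)
  n <- nrow(x); d <- ncol(x)
  g_range <- sort(unique(as.integer(g_range)))
  stopifnot(all(g_range >= 1), max(g_range) <= n)
  set.seed(seed)
  tree <- stats::hclust(stats::dist(x), method = "ward.D2")
  fits <- list()
  tab <- data.frame(G = g_range, loglik = NA_real_, bic = NA_real_)
  for (i in seq_along(g_range)) {
    G <- g_range[i]
    init <- stats::cutree(tree, k = G)
    fit <- .em_gmm(x, init, covariance)
    npar <- G * d + (G - 1) +
      if (covariance == "shared") d * (d + 1) / 2 else G * d
    tab$loglik[i] <- fit$loglik
    tab$bic[i] <- -2 * fit$loglik + npar * log(n)
    fits[[i]] <- fit
  }
  best <- if (criterion == "bic") which.min(tab$bic)
  else {
    # smallest G whose relative log-likelihood gain is below 1%
    sel <- length(g_range)
    for (i in seq_along(g_range)[-1]) {
      gain <- (tab$loglik[i] - tab$loglik[i - 1]) / abs(tab$loglik[i - 1])
      if (is.finite(gain) && gain < 0.01) { sel <- i - 1; break }
    }
    sel
  }
  fit <- fits[[best]]
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("acc%0*d", nchar(n), seq_len(n))
  structure(list(G = g_range[best],
                 assignment = group_assignment(
                   ids, paste0("M", fit$assignment), "mixture"),
                 means = fit$means, sigma = fit$sigma, weights = fit$weights,
                 resp = fit$resp, loglik = fit$loglik,
                 ll_trace = fit$ll_trace, model_scores = tab,
                 criterion = criterion),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit: G =", x$G, "groups selected by", x$criterion,
      sprintf("(loglik %.2f)\n", x$loglik))
  invisible(x)
}

#' Gower's mixed-variable distance
#'
#' Per-variable similarity: exact match for categorical variables (genotype
#' calls are three-state categories), `1 - |x_i - x_j| / range` for
#' continuous and ordinal (level-coded) variables. The distance is one minus
#' the weighted mean similarity over the variables observed in both
#' accessions; all distances lie in \[0, 1\].
#'
#' @param geno optional [genotype_matrix()] (markers enter as categorical
#'   variables).
#' @param pheno optional [phenotype_table()] (or numeric matrix treated as
#'   continuous).
#' @param weights optional named numeric weights per variable; default
#'   uniform. Two shortcuts: a single number per block via
#'   `block_weights = c(geno, pheno)`.
#' @param block_weights optional length-2 numeric: total weight given to the
#'   genotype and phenotype blocks (spread uniformly inside each block).
#' @return a `pair_distance` (symmetric matrix `d`, plus `n_pairs` — here the
#'   summed weight of variables observed in both members of each pair).
#' @export
gower_distance <- function(geno = NULL, pheno = NULL, weights = NULL,
                           block_weights = NULL) {
  vars <- list(); kinds <- character(0); wts <- numeric(0)
  n <- NULL; ids <- NULL
  if (!is.null(geno)) {
    stopifnot(inherits(geno, "genotype_matrix"))
    n <- nrow(geno$calls); ids <- rownames(geno$calls)
    gw <- if (!is.null(block_weights)) block_weights[1] / ncol(geno$calls)
          else 1
    for (j in seq_len(ncol(geno$calls))) {
      vars[[length(vars) + 1]] <- geno$calls[, j]
      kinds <- c(kinds, "categorical"); wts <- c(wts, gw)
    }
  }
  if (!is.null(pheno)) {
    tr <- if (inherits(pheno, "phenotype_table")) pheno$traits
          else as.data.frame(pheno)
    # ordinal traits enter as level codes, range-normalized like continuous
    kind <- rep("continuous", ncol(tr))
    pid <- if (inherits(pheno, "phenotype_table")) pheno$accession_ids
           else rownames(tr)
    if (is.null(n)) { n <- nrow(tr); ids <- pid }
    else if (nrow(tr) != n) stop("genotype and phenotype cover different accessions")
    pw <- if (!is.null(block_weights)) block_weights[2] / ncol(tr) else 1
    for (j in seq_len(ncol(tr))) {
      vars[[length(vars) + 1]] <- as.numeric(tr[[j]])
      kinds <- c(kinds, kind[j]); wts <- c(wts, pw)
    }
  }
  if (length(vars) == 0) stop("supply at least one of geno, pheno")
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(vars))
    wts <- as.numeric(weights)
  }
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (v in seq_along(vars)) {
    x <- vars[[v]]
    obs <- !is.na(x)
    o <- outer(obs, obs, "&")
    if (kinds[v] == "categorical") {
      xs <- x; xs[!obs] <- -1
      s <- outer(xs, xs, "==") * 1
    } else {
      rng <- diff(range(x, na.rm = TRUE))
      s <- if (rng == 0) matrix(1, n, n)
           else 1 - abs(outer(x, x, "-")) / rng
      s[!o] <- 0
    }
    s[!o] <- 0
    num <- num + wts[v] * s * o
    den <- den + wts[v] * o
  }
  d <- 1 - num / den
  d[den == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, n_pairs = den), class = "pair_distance")
}

#' Range-normalized distance on factor axes
#'
#' The selection-stage stand-in for a full mixed-variable Gower distance at
#' collection scale: each factor axis is a continuous Gower variable
#' (`1 - |x_i - x_j| / range`), weighted by the variance it explains.
#'
#' @param scores accessions x axes matrix (e.g. from [hmfa_two_block()]).
#' @param axis_weights per-axis weights; default the axis variances.
#' @return a `pair_distance`.
#' @export
axis_gower_distance <- function(scores, axis_weights = NULL) {
  x <- as.matrix(scores)
  if (is.null(axis_weights)) axis_weights <- apply(x, 2, stats::var)
  stopifnot(length(axis_weights) == ncol(x), all(axis_weights >= 0))
  n <- nrow(x)
  num <- matrix(0, n, n)
  for (j in seq_len(ncol(x))) {
    rng <- diff(range(x[, j]))
    s <- if (rng == 0) matrix(1, n, n) else 1 - abs(outer(x[, j], x[, j], "-")) / rng
    num <- num + axis_weights[j] * s
  }
  d <- 1 - num / sum(axis_weights)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  structure(list(d = d, n_pairs = matrix(sum(axis_weights), n, n)),
            class = "pair_distance")
}

#' D-method allocation of core quotas
#'
#' Allocates the core size over groups proportionally to group diversity
#' `D_k`, the mean within-group pairwise distance (0 for singletons). Quotas
#' are rounded by largest remainder so they sum exactly to `core_size`,
#' clamped at group size (excess redistributed), and every non-empty group
#' receives at least `min_quota` when feasible. When all `D_k` are equal
#' (including all zero) quotas are equal up to remainder.
#'
#' @param groups a [group_assignment()] (e.g. `ward_mlm_cluster()$assignment`).
#' @param d a `pair_distance` (or distance matrix) over all accessions.
#' @param core_size total number of accessions to allocate.
#' @param min_quota minimum per non-empty group when feasible, default 1.
#' @return `data.frame` of class `allocation_plan`: `group`, `size`,
#'   `diversity`, `quota`.
#' @export
d_method_allocation <- function(groups, d, core_size, min_quota = 1) {
  m <- if (inherits(d, "pair_distance")) d$d else as.matrix(d)
  ids <- groups$accession_id
  stopifnot(all(ids %in% rownames(m)))
  ks <- sort(unique(groups$group))
  sizes <- vapply(ks, function(k) sum(groups$group == k), integer(1))
  if (core_size > sum(sizes)) stop("core_size exceeds the population")
  div <- vapply(ks, function(k) {
    idx <- ids[groups$group == k]
    if (length(idx) < 2) return(0)
    sub <- m[idx, idx]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }, numeric(1))
  share <- if (sum(div) > 0) div / sum(div) else rep(1 / length(ks), length(ks))
  quota <- largest_remainder(core_size * share, core_size, cap = sizes)
  # minimum-quota rule: raise zero quotas of non-empty groups, taking from
  # the largest quotas (ties toward the lower index)
  if (min_quota > 0 && core_size >= min_quota * length(ks)) {
    while (any(quota < pmin(min_quota, sizes))) {
      i <- which(quota < pmin(min_quota, sizes))[1]
      donor <- which.max(quota - pmin(min_quota, sizes))
      if (quota[donor] <= min_quota) break
      quota[donor] <- quota[donor] - 1L
      quota[i] <- quota[i] + 1L
    }
  }
  out <- data.frame(group = ks, size = sizes, diversity = div, quota = quota,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(sum(out$quota) == core_size, all(out$quota <= out$size))
  class(out) <- c("allocation_plan", "data.frame")
  out
}

#' Stratified search for a Gower-maximal core set
#'
#' Draws `n_candidates` stratified random candidate sets — each samples the
#' group's quota uniformly without replacement within that group — scores
#' every candidate by its mean pairwise distance, and returns the argmax
#' (ties broken toward the lowest candidate index). Reproducible from the
#' seed.
#'
#' @param plan an [d_method_allocation()] plan.
#' @param groups the [group_assignment()] the plan was built from.
#' @param d a `pair_distance` (or matrix) over all accessions.
#' @param n_candidates number of candidates, default 1000.
#' @param seed integer seed.
#' @return list of class `core_set`: `accession_ids`, `mean_gower`
#'   (winning score), `candidate_index`, `plan`, `seed`, `scores` (all
#'   candidate scores).
#' @export
stratified_core_search <- function(plan, groups, d, n_candidates = 1000,
                                   seed = 1L) {
  m <- if (inherits(d, "pair_distance")) d$d else as.matrix(d)
  set.seed(seed)
  ids_by_group <- split(groups$accession_id, groups$group)
  best <- NULL; best_score <- -Inf; best_i <- NA_integer_
  scores <- numeric(n_candidates)
  for (i in seq_len(n_candidates)) {
    sel <- unlist(lapply(seq_len(nrow(plan)), function(r) {
      pool <- ids_by_group[[plan$group[r]]]
      if (plan$quota[r] == 0) return(character(0))
      pool[sample.int(length(pool), plan$quota[r])]
    }), use.names = FALSE)
    sub <- m[sel, sel]
    sc <- mean(sub[upper.tri(sub)], na.rm = TRUE)
    scores[i] <- sc
    if (sc > best_score) { best <- sel; best_score <- sc; best_i <- i }
  }
  structure(list(accession_ids = best, mean_gower = best_score,
                 candidate_index = best_i, plan = plan, seed = seed,
                 scores = scores),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("core_set:", length(x$accession_ids), "accessions, mean distance",
      sprintf("%.4f", x$mean_gower),
      sprintf("(candidate %d of %d, seed %d)\n", x$candidate_index,
              length(x$scores), x$seed))
  invisible(x)
}

#' Monte-Carlo curve of genetic variance against core size
#'
#' For each sampling level (5\% to 100\% in steps of 5\% by default) draws
#' `n_reps` subsamples without replacement, estimates each marker's allele
#' frequency per subsample, and summarizes the across-replicate variance of
#' those frequencies: the differentiation statistic
#' `f_ST = var(p) / (pbar * qbar)` per marker, and the genetic variance `s2`
#' (mean over markers of the chosen statistic — `"var_p"` by default, i.e.
#' `f_ST * pbar * qbar`). At the 100\% level every replicate is the full set,
#' so `var(p) = 0` and `s2 = 0`; under the default statistic `s2` decreases
#' with the sampling level, as sampling theory dictates for hypergeometric
#' draws.
#'
#' @param g a [genotype_matrix()].
#' @param levels sampling fractions, default `seq(0.05, 1, 0.05)`.
#' @param n_reps replicates per level, default 1000.
#' @param statistic `"var_p"` (default), `"fst"` or `"het_var"`
#'   (across-marker variance of subsample expected heterozygosity).
#' @param seed integer seed.
#' @return `data.frame` of class `core_size_curve`: `level`, `n_sub`, `s2`;
#'   the level maximizing `s2` is attribute `"argmax_level"`.
#' @export
simulate_core_size <- function(g, levels = seq(0.05, 1, 0.05), n_reps = 1000,
                               statistic = c("var_p", "fst", "het_var"),
                               seed = 1L) {
  statistic <- match.arg(statistic)
  set.seed(seed)
  calls <- g$calls
  storage.mode(calls) <- "double"
  pres <- !is.na(calls)
  storage.mode(pres) <- "double"
  calls0 <- calls; calls0[is.na(calls0)] <- 0
  n <- nrow(calls)
  out <- data.frame(level = levels, n_sub = pmax(2L, round(levels * n)),
                    s2 = NA_real_)
  for (i in seq_along(levels)) {
    ns <- out$n_sub[i]
    pm <- matrix(NA_real_, n_reps, ncol(calls))
    for (rep in seq_len(n_reps)) {
      rows <- sample.int(n, ns)
      called <- colSums(pres[rows, , drop = FALSE])
      pm[rep, ] <- ifelse(called > 0,
                          colSums(calls0[rows, , drop = FALSE]) / (2 * called),
                          NA)
    }
    vp <- apply(pm, 2, stats::var, na.rm = TRUE)
    pbar <- colMeans(pm, na.rm = TRUE)
    out$s2[i] <- switch(statistic,
      var_p = mean(vp, na.rm = TRUE),
      fst = {
        denom <- pbar * (1 - pbar)
        mean(ifelse(denom > 0, vp / denom, 0), na.rm = TRUE)
      },
      het_var = {
        het <- 2 * pm * (1 - pm)
        mean(apply(het, 2, stats::var, na.rm = TRUE), na.rm = TRUE)
      })
  }
  structure(out, argmax_level = out$level[which.max(out$s2)],
            statistic = statistic, n_reps = n_reps,
            class = c("core_size_curve", "data.frame"))
}

#' End-to-end core reference set construction
#'
#' The full selection pipeline: principal-component reduction of the marker
#' matrix, two-block factor analysis with the genotype:phenotype
#' contribution constraint, Ward-initialized mixture grouping on the leading
#' axes, D-method allocation of the core size proportional to group
#' diversity, and stratified sampling maximizing the mean pairwise
#' (axis-Gower) distance. Identical seed and inputs give an identical core.
#'
#' @param g a [genotype_matrix()].
#' @param pheno a [phenotype_table()] aligned to `g`.
#' @param core_fraction fraction of accessions to select (default 0.1418, the
#'   published core fraction); ignored when `core_size` is given.
#' @param core_size absolute core size, optional.
#' @param n_pcs number of genotype principal components fed to the factor
#'   analysis.
#' @param n_axes factor axes used downstream, default 6.
#' @param target_ratio genotype:phenotype contribution target, default 75:25.
#' @param g_range candidate group numbers for the mixture stage.
#' @param criterion mixture model-selection criterion, `"bic"` or `"loglik"`.
#' @param n_candidates stratified candidates scored, default 1000.
#' @param seed integer seed driving every stochastic step.
#' @return a `core_set` whose provenance fields (`plan`, `hmfa`, `mixture`)
#'   record the intermediate results.
#' @export
build_core_set <- function(g, pheno, core_fraction = 0.1418, core_size = NULL,
                           n_pcs = 100, n_axes = 6, target_ratio = c(75, 25),
                           g_range = 2:25, criterion = "bic",
                           n_candidates = 1000, seed = 1L) {
  n <- nrow(g$calls)
  if (is.null(core_size)) core_size <- max(1L, round(core_fraction * n))
  pca <- pca_reduce(g, n_components = n_pcs)
  hm <- hmfa_two_block(pca$scores, pheno, n_axes = n_axes,
                       target_ratio = target_ratio)
  mix <- ward_mlm_cluster(hm$scores, g_range = g_range, seed = seed,
                          criterion = criterion)
  d <- axis_gower_distance(hm$scores, axis_weights = hm$eigenvalues)
  plan <- d_method_allocation(mix$assignment, d, core_size)
  core <- stratified_core_search(plan, mix$assignment, d,
                                 n_candidates = n_candidates, seed = seed)
  core$hmfa <- hm
  core$mixture <- mix
  core$pca <- pca
  core
}
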