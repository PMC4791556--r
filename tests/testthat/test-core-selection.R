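test_that("PCA reduction preserves geometry and hits variance targets", {
  g <- rand_geno(30, 80, miss = 0.2, seed = 2)
  full <- pca_reduce(g)                       # full rank
  expect_equal(sum(full$variance_explained), 1, tolerance = 1e-8)
  # rotation invariance: distances on full-rank scores equal distances on
  # the mean-imputed matrix
  calls <- g$calls; storage.mode(calls) <- "double"
  mu <- colMeans(calls, na.rm = TRUE)
  for (j in seq_len(ncol(calls))) calls[is.na(calls[, j]), j] <- mu[j]
  expect_equal(unname(as.matrix(dist(full$scores))),
               unname(as.matrix(dist(calls))), tolerance = 1e-8)

  # variance target: smallest k whose cumulative eigenvalue share >= target
  x <- matrix(rnorm(50 * 20), 50, 20) %*% diag(seq(5, 0.5, length.out = 20))
  red <- pca_reduce(x, variance_target = 0.84)
  ev <- eigen(cov(x), symmetric = TRUE)$values  # independent eigen-oracle
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.84)[1]
  expect_equal(ncol(red$scores), k_oracle)
  expect_gte(red$cum_variance_explained[ncol(red$scores)], 0.84)
})

test_that("the block-contribution weight search hits the target ratio", {
  set.seed(11)
  z1 <- matrix(rnorm(200 * 50), 200)
  z2 <- matrix(rnorm(200 * 10), 200)
  hm <- hmfa_two_block(z1, z2, n_axes = 6, target_ratio = c(75, 25), tol = 1)
  expect_lt(abs(hm$cum_contrib["geno"] - 75), 1)
  expect_equal(sum(hm$block_contrib$geno_pct[1] +
                   hm$block_contrib$pheno_pct[1]), 100)

  # grid-search oracle: no weight on a fine grid does materially better
  grid <- 10^seq(log10(hm$weight) - 1, log10(hm$weight) + 1, length.out = 81)
  z1n <- creolecore:::.safe_scale(z1); z2n <- creolecore:::.safe_scale(z2)
  z1n <- z1n / svd(z1n, nu = 0, nv = 0)$d[1]
  z2n <- z2n / svd(z2n, nu = 0, nv = 0)$d[1]
  dev <- sapply(grid, function(w)
    abs(creolecore:::.mfa_contrib(z1n, z2n, w, 6)$geno_pct - 75))
  expect_lte(abs(hm$cum_contrib["geno"] - 75), min(dev) + 1)

  # identical blocks at w = 1 split contributions 50:50
  hm2 <- hmfa_two_block(z1, z1, n_axes = 6, target_ratio = c(50, 50), tol = 1)
  expect_equal(unname(hm2$weight), 1, tolerance = 1e-6)
  expect_equal(unname(hm2$cum_contrib["geno"]), 50, tolerance = 1e-6)

  # zero-variance phenotype block cannot reach 75:25
  expect_error(hmfa_two_block(z1, matrix(1, 200, 4)), "zero variance")
})

test_that("block contributions respond monotonically to the phenotype weight", {
  set.seed(29)
  z1 <- creolecore:::.safe_scale(matrix(rnorm(100 * 20), 100))
  z2 <- creolecore:::.safe_scale(matrix(rnorm(100 * 6), 100))
  z1 <- z1 / svd(z1, nu = 0, nv = 0)$d[1]
  z2 <- z2 / svd(z2, nu = 0, nv = 0)$d[1]
  geno <- sapply(10^seq(-2, 2, length.out = 15), function(w)
    creolecore:::.mfa_contrib(z1, z2, w, 6)$geno_pct)
  expect_true(all(diff(geno) < 0))
})

test_that("Ward-MLM selects the planted number of groups and recovers them", {
  pg <- planted_gaussians(101)
  fit <- ward_mlm_cluster(pg$x, 1:6, seed = 101)
  expect_equal(fit$G, 3)
  expect_gte(ari(fit$assignment$group, pg$truth), 0.95)
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  # model-selection sanity: a single Gaussian yields G = 1
  ok <- sum(sapply(1:10, function(s) {
    set.seed(s); x <- matrix(rnorm(200 * 3), ncol = 3)
    ward_mlm_cluster(x, 1:5, seed = s)$G == 1
  }))
  expect_gte(ok, 8)
})

test_that("Gower distance matches hand computation, brute force, and daisy", {
  # 2 continuous + 2 categorical, similarities (0, 0, 1, 0) -> d = 0.75
  pheno <- data.frame(c1 = c(0, 10), c2 = c(0, 5))
  geno <- genotype_matrix(rbind(a = c(0L, 0L), b = c(0L, 2L)))
  rownames(pheno) <- c("a", "b")
  d <- gower_distance(geno, pheno)
  expect_equal(d$d["a", "b"], 0.75)

  ident <- gower_distance(geno = NULL, pheno = rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(unname(ident$d[1, 2]), 0)

  # random mixed data: brute-force per-variable loop
  set.seed(33)
  n <- 15
  gm <- rand_geno(n, 8, miss = 0.15, seed = 33)
  ph <- data.frame(t1 = rnorm(n), t2 = runif(n))
  ph$t1[3] <- NA
  rownames(ph) <- rownames(gm$calls)
  got <- gower_distance(gm, ph)$d
  exp_d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- w <- 0
    for (v in 1:8) {
      xi <- gm$calls[i, v]; xj <- gm$calls[j, v]
      if (!is.na(xi) && !is.na(xj)) { s <- s + (xi == xj); w <- w + 1 }
    }
    for (tr in 1:2) {
      xi <- ph[i, tr]; xj <- ph[j, tr]
      rng <- diff(range(ph[, tr], na.rm = TRUE))
      if (!is.na(xi) && !is.na(xj)) { s <- s + 1 - abs(xi - xj) / rng; w <- w + 1 }
    }
    exp_d[i, j] <- 1 - s / w
  }
  diag(exp_d) <- 0
  expect_equal(unname(got), exp_d, tolerance = 1e-12)

  # independent implementation: cluster::daisy on the same mixed frame
  skip_if_not_installed("cluster")
  df <- data.frame(lapply(as.data.frame(gm$calls), factor), ph)
  expect_equal(unname(got), unname(as.matrix(cluster::daisy(df, metric = "gower"))),
               tolerance = 1e-8)
})

test_that("D-method quotas are diversity-proportional and conserve the core size", {
  # D = {0.2, 0.1}, core 30 -> quotas {20, 10}
  ids <- paste0("a", 1:80)
  ga <- group_assignment(ids, rep(c("g1", "g2"), each = 40))
  d <- matrix(0.1, 80, 80, dimnames = list(ids, ids))
  d[1:40, 1:40] <- 0.2
  diag(d) <- 0
  plan <- d_method_allocation(ga, d, 30)
  expect_equal(plan$quota, c(20L, 10L))
  expect_equal(plan$diversity, c(0.2, 0.1))

  # equal diversity -> equal quotas up to remainder
  d2 <- matrix(0.3, 80, 80, dimnames = list(ids, ids)); diag(d2) <- 0
  ga3 <- group_assignment(ids, rep(c("g1", "g2", "g3"), c(30, 30, 20)))
  plan2 <- d_method_allocation(ga3, d2, 20)
  expect_lte(diff(range(plan2$quota)), 1)
  expect_equal(sum(plan2$quota), 20)

  # random instances against the independent apportionment oracle
  set.seed(55)
  for (rep in 1:5) {
    nk <- sample(3:6, 1)
    sizes <- sample(5:25, nk, replace = TRUE)
    ids <- paste0("x", seq_len(sum(sizes)))
    ga <- group_assignment(ids, rep(paste0("g", 1:nk), sizes))
    dd <- matrix(runif(sum(sizes)^2, 0.05, 0.6), sum(sizes))
    dd <- (dd + t(dd)) / 2; diag(dd) <- 0
    dimnames(dd) <- list(ids, ids)
    core <- sample(nk:sum(sizes %/% 2), 1)
    plan <- d_method_allocation(ga, dd, core, min_quota = 0)
    expect_equal(sum(plan$quota), core)
    expect_true(all(plan$quota <= plan$size))
    oracle <- bf_apportion(core * plan$diversity / sum(plan$diversity),
                           core, cap = plan$size)
    expect_equal(plan$quota, oracle)
  }
})

test_that("stratified search returns the Gower-argmax candidate reproducibly", {
  set.seed(66)
  sim <- simulate_population(simulation_config(
    n_accessions = 120, n_markers = 400, n_groups = 3,
    group_sizes = c(50, 40, 30), target_fst = 0.15, seed = 66))
  d <- simple_matching_distance(sim$genotypes)
  plan <- d_method_allocation(sim$groups, d, 24)
  cs <- stratified_core_search(plan, sim$groups, d, n_candidates = 40, seed = 9)
  expect_equal(length(cs$accession_ids), 24)
  expect_equal(cs$mean_gower, max(cs$scores))
  expect_equal(cs$candidate_index, which.max(cs$scores))
  # reproducible from the seed
  cs2 <- stratified_core_search(plan, sim$groups, d, n_candidates = 40, seed = 9)
  expect_identical(cs$accession_ids, cs2$accession_ids)

  # quotas equal to group sizes select the complete set
  plan_all <- d_method_allocation(sim$groups, d, 120)
  cs_all <- stratified_core_search(plan_all, sim$groups, d, 1, seed = 1)
  expect_setequal(cs_all$accession_ids, accessions(sim$genotypes))
  expect_equal(cs_all$mean_gower,
               mean(d$d[upper.tri(d$d)], na.rm = TRUE), tolerance = 1e-12)

  # beats the median of 1000 unstratified random subsets of the same size
  set.seed(77)
  rnd <- replicate(1000, {
    idx <- sample(rownames(d$d), 24)
    sub <- d$d[idx, idx]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  })
  expect_gte(cs$mean_gower, median(rnd))
})

test_that("the genetic-variance curve vanishes at full sampling and decreases", {
  g <- rand_geno(60, 150, miss = 0, seed = 10)
  curve <- simulate_core_size(g, n_reps = 200, seed = 5)
  expect_equal(nrow(curve), 20)
  expect_equal(curve$s2[curve$level == 1], 0)
  expect_true(all(diff(curve$s2) < 0))

  mono <- genotype_matrix(matrix(2L, 40, 25))
  cm <- simulate_core_size(mono, levels = c(0.25, 0.5, 1), n_reps = 50,
                           seed = 2)
  expect_equal(cm$s2, c(0, 0, 0))
})

test_that("the end-to-end pipeline is reproducible from its seed", {
  sim <- simulate_population(simulation_config(
    n_accessions = 150, n_markers = 600, n_groups = 4,
    group_sizes = c(50, 40, 35, 25), target_fst = 0.2, seed = 14))
  a <- build_core_set(sim$genotypes, sim$phenotypes, core_fraction = 0.15,
                      n_pcs = 20, g_range = 3:5, n_candidates = 30, seed = 5)
  b <- build_core_set(sim$genotypes, sim$phenotypes, core_fraction = 0.15,
                      n_pcs = 20, g_range = 3:5, n_candidates = 30, seed = 5)
  expect_identical(a$accession_ids, b$accession_ids)
  expect_equal(a$mean_gower, b$mean_gower)
  expect_equal(length(a$accession_ids), round(0.15 * 150))
})
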