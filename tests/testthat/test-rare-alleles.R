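test_that("rare alleles follow the strict open-interval rule", {
  # frequencies {0.01, 0.06, 0}: only the 0.01 allele is rare
  calls <- cbind(c(1L, rep(0L, 49)),               # p_alt = 0.01
                 c(rep(1L, 6), rep(0L, 44)),       # p_alt = 0.06
                 rep(0L, 50))                      # p_alt = 0
  g <- genotype_matrix(calls)
  rs <- define_rare_alleles(g)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$marker_id, "mk1")
  expect_equal(rs$freq, 0.01)

  # p exactly at the threshold is not rare
  g05 <- genotype_matrix(matrix(c(rep(1L, 5), rep(0L, 45)), ncol = 1))
  expect_equal(nrow(define_rare_alleles(g05)), 0)

  # brute-force scan agreement, including rare reference alleles (p > 0.95)
  gr <- rand_geno(80, 60, miss = 0.1, seed = 23)
  gr$calls[, 1] <- c(1L, rep(2L, 79))              # ref allele freq 1/160
  expect_setequal(paste(define_rare_alleles(gr)$marker_id,
                        define_rare_alleles(gr)$allele),
                  bf_rare_keys(gr$calls))
})

test_that("per-group reports compute napa under the group reference population", {
  # one group of 40 with planted in-group rare alleles, one background group
  set.seed(4)
  nA <- 40; nB <- 25; m <- 60
  calls <- matrix(sample(0:2, (nA + nB) * m, TRUE), nA + nB, m)
  for (j in 1:7) {                       # 7 alleles rare within group A
    calls[seq_len(nA), j] <- 0L
    calls[j, j] <- 1L                    # single carrier in A: freq 1/80
  }
  g <- genotype_matrix(calls)
  ga <- group_assignment(accessions(g), rep(c("A", "B"), c(nA, nB)))
  rep_tab <- rare_alleles_per_group(g, ga)
  a <- rep_tab[rep_tab$group == "A", ]
  expect_gte(a$nra, 7)
  expect_equal(a$napa, round(a$nra / nA, 2))
  expect_true(all(attr(rep_tab, "sets")$A$freq > 0 &
                  attr(rep_tab, "sets")$A$freq < 0.05))

  # a single-accession group cannot hold rare alleles: napa = 0
  g1 <- genotype_matrix(matrix(sample(0:2, 30, TRUE), 3, 10))
  ga1 <- group_assignment(rownames(g1$calls), c("solo", "rest", "rest"))
  r1 <- rare_alleles_per_group(g1, ga1)
  expect_equal(r1$napa[r1$group == "solo"], 0)
})

test_that("uniqueness requires rarity in one group and absence elsewhere", {
  # marker 1: allele rare in A only and carried only in A -> unique to A
  # marker 2: allele rare in both A and B -> unique in neither
  nA <- 30; nB <- 30
  calls <- matrix(0L, nA + nB, 3)
  calls[1, 1] <- 1L                          # A-private, freq 1/60 in A
  calls[2, 2] <- 1L; calls[nA + 1, 2] <- 1L  # rare in A and in B
  calls[, 3] <- rep(c(0L, 2L), nA)           # common everywhere
  g <- genotype_matrix(calls)
  ga <- group_assignment(accessions(g), rep(c("A", "B"), c(nA, nB)))
  u <- unique_rare_alleles(g, ga)
  expect_equal(u$nura[u$group == "A"], 1)
  expect_equal(u$nura[u$group == "B"], 0)
})

test_that("pura is invariant to duplicating a group's accessions", {
  set.seed(12)
  sim <- simulate_population(simulation_config(
    n_accessions = 90, n_markers = 300, n_groups = 3,
    group_sizes = c(30, 30, 30), target_fst = 0.15, seed = 12))
  g <- inject_rare_alleles(sim$genotypes, sim$groups, c(G2 = 8), seed = 2)
  base <- unique_rare_alleles(g, sim$groups)

  # duplicate every accession of G2 (fresh IDs, same calls)
  dup_rows <- which(sim$groups$group == "G2")
  calls2 <- rbind(g$calls, g$calls[dup_rows, , drop = FALSE])
  rownames(calls2) <- c(rownames(g$calls), paste0("dup", seq_along(dup_rows)))
  g2 <- genotype_matrix(calls2)
  ga2 <- group_assignment(rownames(calls2),
                          c(sim$groups$group, rep("G2", length(dup_rows))))
  dup <- unique_rare_alleles(g2, ga2)
  expect_equal(dup$nura[dup$group == "G2"], base$nura[base$group == "G2"])
  expect_equal(dup$pura[dup$group == "G2"], base$pura[base$group == "G2"])
})

test_that("complete-set scope restricts groups to complete-set rare alleles", {
  gr <- rand_geno(60, 100, miss = 0.1, seed = 3)
  ga <- group_assignment(rownames(gr$calls), rep(c("a", "b", "c"), each = 20))
  rep_cs <- rare_alleles_per_group(gr, ga, scope = "complete_set")
  sets <- attr(rep_cs, "sets")
  complete_keys <- paste(define_rare_alleles(gr)$marker_id,
                         define_rare_alleles(gr)$allele)
  union_keys <- unique(unlist(lapply(sets, function(s)
    paste(s$marker_id, s$allele))))
  expect_true(all(union_keys %in% complete_keys))
  expect_lte(length(union_keys), attr(rep_cs, "complete_nra"))
})

test_that("geographic k-means recovers planted site clouds and its limits", {
  set.seed(6)
  info <- accession_info(data.frame(
    accession_id = paste0("a", 1:40),
    region = "unknown", state = NA,
    latitude = c(rnorm(20, 18, 0.1), rnorm(20, 28, 0.1)),
    longitude = c(rnorm(20, -97, 0.1), rnorm(20, -106, 0.1)),
    altitude = c(rnorm(20, 2200, 20), rnorm(20, 1500, 20))))
  gk <- geo_kmeans(info, k = 2, seed = 1)
  expect_equal(length(unique(gk$assignment$group[1:20])), 1)
  expect_equal(length(unique(gk$assignment$group[21:40])), 1)
  expect_false(gk$assignment$group[1] == gk$assignment$group[21])

  g1 <- geo_kmeans(info, k = 1, seed = 1)
  expect_equal(unname(unlist(g1$centers)),
               unname(colMeans(info[, c("latitude", "longitude", "altitude")])),
               tolerance = 1e-9)
  gn <- geo_kmeans(info, k = 40, seed = 1)
  expect_lt(gn$inertia, 1e-9)
})

test_that("cross-classification conserves totals and diagonalizes identity", {
  ids <- paste0("a", 1:30)
  lab <- sample(c("x", "y", "z"), 30, TRUE)
  ga <- group_assignment(ids, lab)
  gb <- group_assignment(ids, lab, "geographic")
  tab <- cross_classify(gb, ga)
  expect_equal(sum(tab), 30)
  expect_equal(sum(diag(tab[sort(unique(lab)), sort(unique(lab))])), 30)

  gc <- group_assignment(ids, sample(c("p", "q"), 30, TRUE), "geographic")
  tab2 <- cross_classify(gc, ga)
  expect_equal(sum(tab2), 30)
  expect_equal(unname(rowSums(tab2)), unname(table(gc$group)), ignore_attr = TRUE)
})

test_that("fixed-allele scan honors the call-rate gate and planted truth", {
  set.seed(44)
  n <- 60; m <- 80
  calls <- matrix(sample(0:2, n * m, TRUE), n, m)
  clust <- rep(c("c1", "c2"), each = 30)
  # plant 12 markers fixed (all ref) in c1 but segregating overall
  for (j in 1:12) calls[1:30, j] <- 0L
  # marker 13: fixed in c1 but with poor call rate there -> must be excluded
  calls[1:30, 13] <- 0L
  calls[1:18, 13] <- NA
  g <- genotype_matrix(calls)
  ga <- group_assignment(accessions(g), clust, "geographic")
  out <- fixed_allele_scan(g, ga, min_callrate = 0.6)
  expect_true(all(paste0("mk", sprintf("%02d", 1:12)) %in% out$c1$marker_id))
  expect_false("mk13" %in% out$c1$marker_id)

  # panmictic population, random clusters: spurious fixation is rare.
  # rare_fraction = 0 so every marker segregates at appreciable frequency —
  # an allele at frequency 0.005 is absent from half the collection by
  # sampling alone, which is real (not spurious) cluster monomorphism
  sim <- simulate_population(simulation_config(
    n_accessions = 200, n_markers = 1000, n_groups = 2,
    group_sizes = c(100, 100), target_fst = 0, rare_fraction = 0, seed = 19))
  rnd <- group_assignment(accessions(sim$genotypes),
                          sample(c("r1", "r2"), 200, TRUE), "geographic")
  spur <- fixed_allele_scan(sim$genotypes, rnd)
  expect_lt((nrow(spur$r1) + nrow(spur$r2)) / 2000, 0.01)
})
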