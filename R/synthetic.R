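#' Default trait specifications
#'
#' Twenty-three agronomic and grain-quality traits (4 ordinal, 19 continuous)
#' with the published collection-level means and variances: crop duration and
#' biomass/height scores, phenology and yield under heat, drought and
#' irrigation, and SeedCount/NIRS grain-quality measures. These are the
#' defaults the population simulator draws from.
#'
#' @return `data.frame` with columns `name`, `kind`, `mean`, `variance`,
#'   `n_levels` (`NA` for continuous traits).
#' @export
default_trait_specs <- function() {
  data.frame(
    name = c("duration", "biomass_heading", "biomass_maturity",
             "plant_height_drought", "days_heading_heat", "days_maturity_heat",
             "plant_height_heat", "days_heading_drought",
             "days_maturity_drought", "grain_yield_drought",
             "days_heading_irrigated", "plant_height_irrigated",
             "thousand_kernel_weight", "test_weight", "grain_length",
             "grain_width", "screen3", "screen2", "screen1", "yellow_berry",
             "grain_hardness", "grain_protein", "whole_meal"),
    kind = c(rep("ordinal", 4), rep("continuous", 19)),
    mean = c(2, 2.2, 2.4, 2.9, 63.2, 82.6, 55.4, 86.9, 122.8, 202.3, 99.3,
             146.8, 40.9, 76.2, 6.8, 3.1, 49.5, 22.3, 13.8, 6.9, 59.3, 16.1,
             18.5),
    variance = c(0.1, 1.2, 1.1, 0.1, 50.4, 30.1, 30.7, 96.5, 51.4, 6103.7,
                 135.4, 227.8, 30.5, 8, 0.21, 0.04, 697.6, 158.3, 109.1, 53.8,
                 19.9, 1.8, 14.4),
    n_levels = c(3, 5, 5, 5, rep(NA, 19)),
    stringsAsFactors = FALSE)
}

# default per-group region layout mirroring the published 15-group geography
.default_regions <- function(n_groups) {
  base <- c("central", "central", "north", "central", "north", "north",
            "south", "south", "central", "central", "north", "central",
            "central", "north", "central")
  rep(base, length.out = n_groups)
}

.region_centers <- list(
  north   = c(lat = 28.5, lon = -106.0, alt = 1600),
  central = c(lat = 19.5, lon =  -99.0, alt = 2300),
  south   = c(lat = 17.0, lon =  -96.5, alt = 1600))

#' Simulation configuration
#'
#' Encodes the empirical regime of the landrace collection the package was
#' built around: ~8k accessions x ~20k biallelic GBS SNPs, 15
#' drift-differentiated groups with pairwise F_ST spanning roughly
#' 0.04–0.28, ~40\% of markers at the rare edge of the frequency spectrum,
#' per-marker missingness up to 50\%, heterozygosity capped at 30.5\%
#' (largely inbred lines), 23 mixed traits with published means/variances,
#' and region-structured collection sites. All defaults can be scaled down
#' for fast fixtures.
#'
#' @param n_accessions,n_markers problem size; defaults are the collection
#'   scale (7,987 accessions, 20,526 SNPs).
#' @param n_groups number of latent groups (default 15).
#' @param group_sizes integer sizes summing to `n_accessions`; default the
#'   published 15-group sizes (rescaled when `n_accessions` differs).
#' @param target_fst per-group Balding–Nichols drift parameter; scalar or
#'   length-`n_groups` vector (default evenly spaced on \[0.04, 0.28\]).
#' @param rare_fraction fraction of markers whose ancestral frequency is
#'   seeded at the rare edge (< 0.05 or > 0.95); default 0.404.
#' @param missing_rate `c(min, max)` of the per-marker uniform missingness
#'   distribution; default `c(0, 0.5)`.
#' @param het_max maximum per-marker heterozygote fraction (default 0.305),
#'   enforced through an inbreeding coefficient `1 - 2 * het_max`.
#' @param trait_specs trait specification table as in
#'   [default_trait_specs()].
#' @param group_var_share fraction of each trait's variance placed between
#'   groups (default 0.3).
#' @param geo_centers `data.frame` with per-group `lat`, `lon`, `alt`
#'   centers; default region-based layout.
#' @param geo_jitter `c(degrees, meters)` jitter SDs for coordinates and
#'   altitude.
#' @param seed integer seed; every random draw of the simulator flows from
#'   it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_accessions = 7987, n_markers = 20526,
                              n_groups = 15, group_sizes = NULL,
                              target_fst = NULL, rare_fraction = 0.404,
                              missing_rate = c(0, 0.5), het_max = 0.305,
                              trait_specs = default_trait_specs(),
                              group_var_share = 0.3, geo_centers = NULL,
                              geo_jitter = c(0.8, 150), seed = 1L) {
  stopifnot(n_accessions >= 1, n_markers >= 1, n_groups >= 1,
            rare_fraction >= 0, rare_fraction <= 1,
            missing_rate[1] >= 0, missing_rate[2] <= 1,
            missing_rate[1] <= missing_rate[2],
            het_max >= 0, het_max <= 0.5)
  if (is.null(group_sizes)) {
    ref <- c(1227, 495, 829, 1445, 83, 454, 372, 195, 1147, 290, 640, 324,
             287, 160, 39)
    share <- rep(ref, length.out = n_groups)
    group_sizes <- largest_remainder(n_accessions * share / sum(share),
                                     n_accessions)
  }
  if (any(group_sizes < 1)) stop("infeasible config: empty group")
  if (sum(group_sizes) != n_accessions)
    stop("group_sizes must sum to n_accessions")
  if (length(group_sizes) != n_groups)
    stop("group_sizes must have n_groups entries")
  if (is.null(target_fst))
    target_fst <- seq(0.04, 0.28, length.out = n_groups)
  if (length(target_fst) == 1) target_fst <- rep(target_fst, n_groups)
  stopifnot(all(target_fst >= 0), all(target_fst < 1))
  if (is.null(geo_centers)) {
    reg <- .default_regions(n_groups)
    geo_centers <- do.call(rbind, lapply(reg, function(r)
      as.data.frame(as.list(.region_centers[[r]]))))
    geo_centers$region <- reg
  }
  structure(list(n_accessions = n_accessions, n_markers = n_markers,
                 n_groups = n_groups, group_sizes = as.integer(group_sizes),
                 target_fst = target_fst, rare_fraction = rare_fraction,
                 missing_rate = missing_rate, het_max = het_max,
                 trait_specs = trait_specs, group_var_share = group_var_share,
                 geo_centers = geo_centers, geo_jitter = geo_jitter,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a structured landrace population
#'
#' Group allele frequencies follow a Balding–Nichols model: for ancestral
#' frequency `p` and group drift parameter `F`, the group frequency is
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)`, so the expected differentiation among
#' groups matches `F`. A configured fraction of ancestral frequencies is
#' seeded near 0 (or 1) to create rare alleles. Genotypes are drawn with an
#' inbreeding coefficient `1 - 2 * het_max`, capping heterozygosity;
#' per-marker missingness is uniform on the configured interval. Traits get
#' a group-mean shift carrying `group_var_share` of their variance; ordinal
#' traits are discretized latent normals. Collection sites are jittered
#' around the group's geographic center. Fully reproducible from the seed.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `genotypes` ([genotype_matrix()]),
#'   `phenotypes` ([phenotype_table()]), `info` ([accession_info()]),
#'   `groups` ([group_assignment()] — the planted truth) and `config`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accessions; m <- cfg$n_markers; K <- cfg$n_groups
  acc <- sprintf("ACC%0*d", nchar(n), seq_len(n))
  lab <- rep(seq_len(K), cfg$group_sizes)

  # ancestral frequencies with a seeded rare edge
  is_rare <- stats::runif(m) < cfg$rare_fraction
  p0 <- stats::runif(m, 0.05, 0.95)
  edge <- stats::runif(sum(is_rare), 0.002, 0.049)
  flip <- stats::runif(sum(is_rare)) < 0.5
  p0[is_rare] <- ifelse(flip, 1 - edge, edge)

  # Balding–Nichols group frequencies
  pk <- matrix(0, K, m)
  for (k in seq_len(K)) {
    Fk <- cfg$target_fst[k]
    if (Fk <= 0) pk[k, ] <- p0
    else {
      s <- (1 - Fk) / Fk
      pk[k, ] <- stats::rbeta(m, p0 * s, (1 - p0) * s)
    }
  }

  # genotypes with inbreeding (het cap)
  f_is <- max(0, 1 - 2 * cfg$het_max)
  calls <- matrix(0L, n, m)
  for (k in seq_len(K)) {
    rows <- which(lab == k)
    p <- pk[k, ]
    pq <- p * (1 - p)
    p2 <- rep(p^2 + f_is * pq, each = length(rows))
    p1 <- rep(2 * pq * (1 - f_is), each = length(rows))
    u <- stats::runif(length(rows) * m)
    calls[rows, ] <- ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
  }

  # per-marker missingness
  r <- stats::runif(m, cfg$missing_rate[1], cfg$missing_rate[2])
  mask <- stats::runif(n * m) < rep(r, each = n)
  calls[mask] <- NA_integer_
  rownames(calls) <- acc
  colnames(calls) <- sprintf("SNP%0*d", nchar(m), seq_len(m))
  chrom <- sort(rep_len(paste0("chr", 1:21), m))
  markers <- data.frame(marker_id = colnames(calls), chrom = chrom,
                        pos = as.numeric(stats::ave(seq_len(m), chrom,
                                                    FUN = seq_along)),
                        stringsAsFactors = FALSE)
  geno <- genotype_matrix(calls, markers)

  # traits: group shift + residual noise; ordinal = discretized latent
  ts <- cfg$trait_specs
  traits <- as.data.frame(matrix(NA_real_, n, nrow(ts)))
  names(traits) <- ts$name
  lv <- list()
  for (j in seq_len(nrow(ts))) {
    vb <- cfg$group_var_share * ts$variance[j]
    delta <- stats::rnorm(K, 0, sqrt(vb))
    x <- ts$mean[j] + delta[lab] +
      stats::rnorm(n, 0, sqrt((1 - cfg$group_var_share) * ts$variance[j]))
    if (ts$kind[j] == "ordinal") {
      x <- pmin(pmax(round(x), 1), ts$n_levels[j])
      lv[[ts$name[j]]] <- seq_len(ts$n_levels[j])
    }
    traits[[j]] <- x
  }
  kind <- stats::setNames(ts$kind, ts$name)
  pheno <- phenotype_table(traits, acc, kind, lv)

  # geography
  gc <- cfg$geo_centers
  lat <- gc$lat[lab] + stats::rnorm(n, 0, cfg$geo_jitter[1])
  lon <- gc$lon[lab] + stats::rnorm(n, 0, cfg$geo_jitter[1])
  alt <- gc$alt[lab] + stats::rnorm(n, 0, cfg$geo_jitter[2])
  region <- if ("region" %in% names(gc)) gc$region[lab]
            else ifelse(lat > 24, "north", ifelse(lat < 18.5, "south", "central"))
  info <- accession_info(data.frame(accession_id = acc, region = region,
                                    state = NA_character_, latitude = lat,
                                    longitude = lon, altitude = alt,
                                    stringsAsFactors = FALSE))
  groups <- group_assignment(acc, paste0("G", lab), "genetic")
  list(genotypes = geno, phenotypes = pheno, info = info, groups = groups,
       config = cfg)
}

#' Plant group-private rare alleles
#'
#' Overwrites designated markers so that their minor allele is carried only
#' by members of one designated group, at a whole-population frequency
#' strictly inside (0, 0.05). Carriers are drawn as a random fraction
#' (`carrier_range`) of the group's members, capped so the allele is rare
#' (frequency below the 0.05 bound) both in the whole population and within
#' its own group — planted alleles must register under the per-group
#' reference-population convention of the rare-allele scans. The existing
#' missingness pattern is kept except at carrier cells. Used to create
#' ground truth for the rare-allele and core-retention analyses.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [group_assignment()].
#' @param spec named integer vector: number of private rare alleles to plant
#'   per group.
#' @param carrier_range range of the within-group carrier fraction
#'   (heterozygous carriers among group members), default `c(0.02, 0.09)` —
#'   under half the rare bound, so within-group frequencies stay rare.
#' @param seed integer seed.
#' @return the modified `genotype_matrix`, with attribute `"planted"` — a
#'   `data.frame` of (marker_id, group) pairs.
#' @export
inject_rare_alleles <- function(g, groups, spec, carrier_range = c(0.02, 0.09),
                                seed = 1L) {
  stopifnot(all(spec >= 0))
  if (sum(spec) == 0) return(g)
  lab <- .aligned_groups(g, groups)
  if (sum(spec) > ncol(g$calls))
    stop("infeasible spec: more alleles requested than markers available")
  if (!all(names(spec) %in% lab))
    stop("infeasible spec: unknown or empty group ",
         paste(setdiff(names(spec), lab), collapse = ", "))
  set.seed(seed)
  calls <- g$calls
  pool <- sample(ncol(calls))
  used <- 0
  planted <- list()
  for (k in names(spec)) {
    ck <- spec[[k]]
    if (ck == 0) next
    rows_in <- which(lab == k)
    cols <- pool[used + seq_len(ck)]
    used <- used + ck
    for (j in cols) {
      x <- calls[, j]
      x[!is.na(x)] <- 0L
      n_called <- sum(!is.na(x))
      # heterozygous carriers inside the group, capped so the allele stays
      # rare globally and within the group's own called members
      frac <- stats::runif(1, carrier_range[1], carrier_range[2])
      b <- sum(!is.na(x[rows_in]))  # called group members (pre-forcing)
      cap <- min(floor(0.05 * 2 * n_called) - 1L,
                 max(1L, floor(0.05 * 2 * b) - 1L))
      n_car <- max(1L, min(round(frac * length(rows_in)), length(rows_in), cap))
      car <- sample(rows_in, n_car)
      x[car] <- 1L
      calls[, j] <- x
      stopifnot(n_car / (2 * sum(!is.na(x))) < 0.05, n_car >= 1)
    }
    planted[[k]] <- data.frame(marker_id = colnames(calls)[cols], group = k,
                               stringsAsFactors = FALSE)
  }
  out <- structure(list(calls = calls, markers = g$markers),
                   class = "genotype_matrix")
  attr(out, "planted") <- do.call(rbind, c(planted, make.row.names = FALSE))
  out
}
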