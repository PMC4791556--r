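# IUPAC single-letter diploid codes used by the HapMap dialect
.iupac_het <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

.het_code <- function(a, b) {
  ab <- paste0(pmin(a, b), pmax(a, b))
  out <- unname(.iupac_het[ab])
  out[is.na(out)] <- "N"
  out
}

#' Read a genotype matrix
#'
#' Supported dialects:
#' \describe{
#'   \item{`csv_matrix`}{CSV/TSV with a header row of marker IDs, first column
#'     accession ID, cells 0/1/2 or NA (empty, `NA`, `.` all map to missing).}
#'   \item{`hapmap`}{HapMap-style table with columns `rs`, `alleles` (e.g.
#'     `A/G`), `chrom`, `pos`, then one column per accession holding IUPAC
#'     single-letter codes; heterozygote ambiguity codes map to dosage 1,
#'     `N` (or `-`) to missing.}
#'   \item{`vcf`}{VCF v4.x, GT field only, biallelic records; parsed with
#'     \pkg{vcfR}. Multi-allelic records are dropped with a warning (or
#'     rejected when `multiallelic = "error"`).}
#' }
#' Any unknown or ambiguous call becomes missing; the result is validated
#' before it is returned.
#'
#' @param path path to the file.
#' @param dialect one of `"csv_matrix"`, `"hapmap"`, `"vcf"`.
#' @param multiallelic how to treat multi-allelic VCF records: `"drop"`
#'   (default) or `"error"`.
#' @return a validated [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("csv_matrix", "hapmap", "vcf"),
                           multiallelic = c("drop", "error")) {
  dialect <- match.arg(dialect)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         csv_matrix = .read_csv_matrix(path),
         hapmap     = .read_hapmap(path),
         vcf        = .read_vcf(path, multiallelic))
}

.read_csv_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", "", "."),
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2)
    stop("malformed header in ", path, " (line 1): need accession column plus markers")
  acc <- dt[[1]]
  calls <- as.matrix(dt[, -1, drop = FALSE])
  suppressWarnings(storage.mode(calls) <- "integer")
  rownames(calls) <- acc
  genotype_matrix(calls)
}

.read_hapmap <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  need <- c("rs", "alleles", "chrom", "pos")
  if (!all(need %in% names(dt)[1:4]))
    stop("malformed header in ", path,
         " (line 1): expected columns rs, alleles, chrom, pos")
  acc <- names(dt)[-(1:4)]
  if (length(acc) == 0) stop("no accession columns in ", path)
  al <- strsplit(dt$alleles, "/", fixed = TRUE)
  ref <- vapply(al, `[`, "", 1)
  alt <- vapply(al, function(x) if (length(x) > 1) x[2] else NA_character_, "")
  het <- .het_code(ref, alt)
  raw <- t(as.matrix(dt[, acc, drop = FALSE]))  # accessions x markers
  calls <- matrix(NA_integer_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    calls[, j] <- ifelse(raw[, j] == ref[j], 0L,
                  ifelse(raw[, j] == alt[j], 2L,
                  ifelse(raw[, j] == het[j], 1L, NA_integer_)))
  }
  rownames(calls) <- acc
  colnames(calls) <- dt$rs
  markers <- data.frame(marker_id = dt$rs, chrom = dt$chrom,
                        pos = as.numeric(dt$pos), ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, markers)
}

.read_vcf <- function(path, multiallelic) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for the vcf dialect")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multi-allelic record(s) in ", path)
    warning("dropping ", sum(multi), " multi-allelic record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")      # markers x samples
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dose <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    ifelse(x %in% c("0/0"), 0L,
    ifelse(x %in% c("0/1", "1/0"), 1L,
    ifelse(x %in% c("1/1"), 2L, NA_integer_)))
  }
  calls <- t(apply(gt, 1, dose))
  rownames(calls) <- NULL
  calls <- t(calls)  # accessions x markers after transpose of markers x samples
  rownames(calls) <- colnames(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  colnames(calls) <- ids
  markers <- data.frame(marker_id = ids, chrom = fix$CHROM,
                        pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, markers)
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()] for the same three dialects. For `hapmap`
#' and `vcf`, reference/alternate allele letters are taken from the marker
#' table when present (columns `ref`, `alt`) and default to A/G otherwise;
#' unknown chromosomes/positions are written as `0`.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @param dialect one of `"csv_matrix"`, `"hapmap"`, `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("csv_matrix", "hapmap", "vcf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(g, "genotype_matrix"))
  switch(dialect,
         csv_matrix = .write_csv_matrix(g, path),
         hapmap     = .write_hapmap(g, path),
         vcf        = .write_vcf(g, path))
  invisible(path)
}

.write_csv_matrix <- function(g, path) {
  df <- data.frame(accession = rownames(g$calls), g$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
}

.marker_alleles <- function(g) {
  m <- g$markers
  ref <- if ("ref" %in% names(m)) m$ref else rep("A", nrow(m))
  alt <- if ("alt" %in% names(m)) m$alt else rep("G", nrow(m))
  ref[is.na(ref)] <- "A"; alt[is.na(alt)] <- "G"
  list(ref = ref, alt = alt)
}

.write_hapmap <- function(g, path) {
  m <- g$markers
  a <- .marker_alleles(g)
  het <- .het_code(a$ref, a$alt)
  code <- t(vapply(seq_len(ncol(g$calls)), function(j) {
    x <- g$calls[, j]
    out <- rep("N", length(x))
    out[!is.na(x) & x == 0L] <- a$ref[j]
    out[!is.na(x) & x == 1L] <- het[j]
    out[!is.na(x) & x == 2L] <- a$alt[j]
    out
  }, character(nrow(g$calls))))
  chrom <- ifelse(is.na(m$chrom), "0", m$chrom)
  pos <- ifelse(is.na(m$pos), 0, m$pos)
  df <- data.frame(rs = m$marker_id, alleles = paste0(a$ref, "/", a$alt),
                   chrom = chrom, pos = pos, code,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:4)] <- rownames(g$calls)
  data.table::fwrite(df, path, sep = "\t")
}

.write_vcf <- function(g, path) {
  m <- g$markers
  a <- .marker_alleles(g)
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(ncol(g$calls)), function(j) {
    x <- g$calls[, j]
    gt <- ifelse(is.na(x), "./.", gt_str[as.character(x)])
    paste(c(ifelse(is.na(m$chrom[j]), "0", m$chrom[j]),
            ifelse(is.na(m$pos[j]), 0, format(m$pos[j], scientific = FALSE)),
            m$marker_id[j], a$ref[j], a$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g$calls)), collapse = "\t"))
  writeLines(c(header, body), path)
}

#' Construct a phenotype table
#'
#' @param traits `data.frame` of trait columns (numeric), row-aligned to
#'   `accession_ids`. Ordinal traits are stored as numeric level codes.
#' @param accession_ids character vector of accession IDs.
#' @param trait_kind named character vector, one entry per trait column,
#'   each `"ordinal"` or `"continuous"`.
#' @param levels named list giving, for each ordinal trait, its finite set of
#'   admissible level codes.
#' @return an object of class `phenotype_table`.
#' @export
phenotype_table <- function(traits, accession_ids, trait_kind, levels = list()) {
  traits <- as.data.frame(traits)
  stopifnot(length(accession_ids) == nrow(traits),
            !anyDuplicated(accession_ids))
  if (!setequal(names(trait_kind), names(traits)) ||
      length(trait_kind) != ncol(traits))
    stop("trait_kind must name every trait column exactly once")
  if (!all(trait_kind %in% c("ordinal", "continuous")))
    stop("trait_kind values must be 'ordinal' or 'continuous'")
  trait_kind <- trait_kind[names(traits)]
  for (tr in names(traits)[trait_kind == "ordinal"]) {
    lv <- levels[[tr]]
    if (is.null(lv)) {
      lv <- sort(unique(traits[[tr]][!is.na(traits[[tr]])]))
      levels[[tr]] <- lv
    }
    bad <- !is.na(traits[[tr]]) & !(traits[[tr]] %in% lv)
    if (any(bad))
      stop("ordinal trait '", tr, "' has out-of-level value at row ",
           which(bad)[1])
  }
  structure(list(accession_ids = as.character(accession_ids),
                 traits = traits, trait_kind = trait_kind, levels = levels),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table: ", length(x$accession_ids), " accessions x ",
      ncol(x$traits), " traits (", sum(x$trait_kind == "ordinal"),
      " ordinal, ", sum(x$trait_kind == "continuous"), " continuous)\n",
      sep = "")
  invisible(x)
}

#' Read a phenotype table from CSV
#'
#' The CSV must have a header, an accession-ID column (first by default), and
#' one column per trait. The schema declares the kind of every trait column;
#' ordinal values are checked against their declared level set and a violation
#' reports the offending row and column. Empty cells are missing values; the
#' row is retained.
#'
#' @param path CSV path.
#' @param schema named character vector mapping every trait column to
#'   `"ordinal"` or `"continuous"`.
#' @param levels named list of admissible level codes per ordinal trait
#'   (defaults to the observed values).
#' @param id_col name or index of the accession-ID column.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, schema, levels = list(), id_col = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  idn <- if (is.numeric(id_col)) names(dt)[id_col] else id_col
  acc <- as.character(dt[[idn]])
  traits <- dt[, setdiff(names(dt), idn), drop = FALSE]
  if (!setequal(names(schema), names(traits)))
    stop("schema/column mismatch: schema names ",
         paste(setdiff(names(schema), names(traits)), collapse = ","),
         " vs file columns ",
         paste(setdiff(names(traits), names(schema)), collapse = ","))
  for (tr in names(traits)[schema[names(traits)] == "ordinal"]) {
    lv <- levels[[tr]]
    if (!is.null(lv)) {
      bad <- !is.na(traits[[tr]]) & !(traits[[tr]] %in% lv)
      if (any(bad))
        stop("out-of-level ordinal value in column '", tr, "', row ",
             which(bad)[1])
    }
  }
  phenotype_table(traits, acc, schema[names(traits)], levels)
}

#' Write a phenotype table to CSV
#' @param p a `phenotype_table`.
#' @param path output path.
#' @export
write_phenotypes <- function(p, path) {
  df <- data.frame(accession = p$accession_ids, p$traits,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read accession metadata (collection-site variables)
#'
#' Expects a CSV with columns `accession_id`, `region`, `state`, `latitude`,
#' `longitude`, `altitude` (missing columns are filled with `NA`). Regions
#' are validated against north/central/south/unknown; coordinates are range
#' checked.
#'
#' @param path CSV path.
#' @return `data.frame` of class `accession_info`.
#' @export
read_accession_info <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  accession_info(dt)
}

#' @rdname read_accession_info
#' @param df data.frame with at least an `accession_id` column.
#' @export
accession_info <- function(df) {
  need <- c("accession_id", "region", "state", "latitude", "longitude",
            "altitude")
  for (cl in setdiff(need, names(df))) df[[cl]] <- NA
  df <- df[, need]
  df$accession_id <- as.character(df$accession_id)
  df$region <- as.character(df$region)
  df$region[is.na(df$region)] <- "unknown"
  if (!all(df$region %in% c("north", "central", "south", "unknown")))
    stop("region must be north, central, south or unknown")
  ok_lat <- is.na(df$latitude) | (df$latitude >= -90 & df$latitude <= 90)
  ok_lon <- is.na(df$longitude) | (df$longitude >= -180 & df$longitude <= 180)
  if (!all(ok_lat)) stop("latitude out of [-90, 90] at row ", which(!ok_lat)[1])
  if (!all(ok_lon)) stop("longitude out of [-180, 180] at row ", which(!ok_lon)[1])
  if (anyDuplicated(df$accession_id)) stop("duplicate accession IDs in metadata")
  class(df) <- c("accession_info", "data.frame")
  df
}

#' Construct a group assignment
#'
#' Maps every accession to exactly one group label, with a provenance tag
#' recording how the partition was obtained.
#'
#' @param accession_ids character vector.
#' @param groups vector of group labels, same length.
#' @param provenance `"genetic"`, `"geographic"` or `"mixture"`.
#' @return object of class `group_assignment`: a data.frame with columns
#'   `accession_id` and `group`.
#' @export
group_assignment <- function(accession_ids, groups,
                             provenance = c("genetic", "geographic", "mixture")) {
  provenance <- match.arg(provenance)
  stopifnot(length(accession_ids) == length(groups))
  if (anyDuplicated(accession_ids))
    stop("every accession must be labeled exactly once")
  df <- data.frame(accession_id = as.character(accession_ids),
                   group = as.character(groups), stringsAsFactors = FALSE)
  structure(df, provenance = provenance,
            class = c("group_assignment", "data.frame"))
}

# group labels aligned to the rows of a genotype matrix
.aligned_groups <- function(g, groups) {
  stopifnot(inherits(groups, "group_assignment"))
  idx <- match(rownames(g$calls), groups$accession_id)
  if (anyNA(idx)) stop("group assignment missing for some accessions")
  groups$group[idx]
}
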