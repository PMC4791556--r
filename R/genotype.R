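#' Construct a genotype matrix
#'
#' The central data container: an accessions x markers grid of biallelic SNP
#' calls coded as alternate-allele dosage (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing). Missingness is
#' a first-class state, never conflated with dosage 0.
#'
#' @param calls integer matrix (accessions x markers) with values 0/1/2/`NA`.
#'   Row names are accession IDs, column names marker IDs; if absent they are
#'   generated.
#' @param markers optional `data.frame` with one row per marker and columns
#'   `marker_id`, `chrom`, `pos` (map position, cM or bp — one unit per map;
#'   `NA` when unknown). Extra columns (e.g. `ref`, `alt` allele letters from a
#'   HapMap or VCF source) are carried along.
#' @return an object of class `genotype_matrix` with elements `calls` and
#'   `markers`.
#' @export
genotype_matrix <- function(calls, markers = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("acc%0*d", nchar(nrow(calls)), seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("mk%0*d", nchar(ncol(calls)), seq_len(ncol(calls)))
  if (is.null(markers)) {
    markers <- data.frame(marker_id = colnames(calls),
                          chrom = NA_character_, pos = NA_real_,
                          stringsAsFactors = FALSE)
  }
  rownames(markers) <- NULL
  g <- structure(list(calls = calls, markers = markers),
                 class = "genotype_matrix")
  validate_genotype_matrix(g)
}

#' @rdname genotype_matrix
#' @param g object to validate.
#' @export
validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  if (anyDuplicated(rownames(calls)))
    stop("duplicate accession IDs: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker IDs: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  bad <- !(is.na(calls) | calls == 0L | calls == 1L | calls == 2L)
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA; found ",
         paste(unique(calls[bad]), collapse = ", "))
  if (nrow(g$markers) != ncol(calls))
    stop("marker table has ", nrow(g$markers), " rows but calls has ",
         ncol(calls), " columns")
  if (!identical(as.character(g$markers$marker_id), colnames(calls)))
    stop("marker_id column does not match calls column names")
  if (any(!is.na(g$markers$pos) & g$markers$pos < 0))
    stop("marker positions must be non-negative")
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  calls <- x$calls
  miss <- mean(is.na(calls))
  cat("genotype_matrix: ", nrow(calls), " accessions x ", ncol(calls),
      " markers (", sprintf("%.1f", 100 * miss), "% missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Accession IDs of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return character vector of accession IDs.
#' @export
accessions <- function(g) rownames(g$calls)

#' Restrict a genotype matrix to a subset of accessions
#'
#' @param g a `genotype_matrix`.
#' @param ids accession IDs (or logical/integer row index) to keep, in the
#'   order given.
#' @return a `genotype_matrix` over the selected accessions.
#' @export
subset_accessions <- function(g, ids) {
  calls <- g$calls[ids, , drop = FALSE]
  structure(list(calls = calls, markers = g$markers), class = "genotype_matrix")
}

#' Filter markers by missingness and polymorphism
#'
#' Retains markers whose missing fraction is strictly below
#' `max_missing_fraction` (a threshold of 1 keeps everything, making the
#' filter the identity), optionally dropping markers that are monomorphic
#' (minor allele frequency 0) among the non-missing calls. Accession order is
#' never changed.
#'
#' @param g a `genotype_matrix`.
#' @param max_missing_fraction numeric in \[0, 1\]; a marker is kept when its
#'   missing fraction is < this value.
#' @param drop_monomorphic drop markers with MAF = 0 (including markers with
#'   no calls at all)?
#' @return a filtered `genotype_matrix`; a warning (not an error) if nothing
#'   survives.
#' @export
filter_markers <- function(g, max_missing_fraction = 0.5,
                           drop_monomorphic = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  miss <- colMeans(is.na(g$calls))
  keep <- if (max_missing_fraction >= 1) rep(TRUE, ncol(g$calls))
          else miss < max_missing_fraction
  if (drop_monomorphic) {
    f <- allele_frequencies(g)
    keep <- keep & !is.na(f$maf) & f$maf > 0
  }
  if (!any(keep)) warning("no markers retained by filter_markers()")
  mk <- g$markers[keep, , drop = FALSE]
  rownames(mk) <- NULL
  structure(list(calls = g$calls[, keep, drop = FALSE], markers = mk),
            class = "genotype_matrix")
}
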