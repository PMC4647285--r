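#' Construct a genotype dataset
#'
#' The central container of the package: a samples x markers matrix of
#' diploid biallelic SNP calls together with sample and marker metadata.
#' Genotypes are stored as copies of each marker's *counted* allele
#' (`allele1`): 2 = homozygous counted allele, 1 = heterozygous,
#' 0 = homozygous other allele, `NA` = missing. Nucleotide letters are kept
#' in the marker table so that letter-based formats (ped/map, HapMap) can be
#' written back without loss.
#'
#' @param geno integer matrix, samples in rows and markers in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param samples data frame with columns `id`, `population` and optionally
#'   `project` and `flagged_misidentified`.
#' @param markers data frame with columns `id`, `chromosome`, `position`,
#'   `allele1` (counted allele), `allele2` (other allele, `NA` when never
#'   observed) and optionally `synonyms` (semicolon-separated alternate ids).
#' @return An object of class `genotype_dataset`.
#' @examples
#' geno <- matrix(c(2L, 1L, 0L, NA), nrow = 2)
#' samples <- data.frame(id = c("s1", "s2"), population = "POP1")
#' markers <- data.frame(id = c("m1", "m2"), chromosome = "1",
#'                       position = c(100L, 200L),
#'                       allele1 = c("A", "G"), allele2 = c("C", "T"))
#' d <- genotype_dataset(geno, samples, markers)
#' d
#' @export
genotype_dataset <- function(geno, samples, markers) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (is.null(samples$project)) samples$project <- "default"
  if (is.null(samples$flagged_misidentified)) samples$flagged_misidentified <- FALSE
  if (is.null(markers$synonyms)) markers$synonyms <- ""
  markers$synonyms[is.na(markers$synonyms)] <- ""
  markers$chromosome <- as.character(markers$chromosome)
  markers$position <- as.integer(markers$position)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  obj <- structure(
    list(geno = geno, samples = samples, markers = markers),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(obj)
  rownames(obj$geno) <- samples$id
  colnames(obj$geno) <- markers$id
  obj
}

#' Validate the internal consistency of a genotype dataset
#'
#' Checks dimensions, identifier uniqueness, genotype coding bounds,
#' coordinate validity and that synonym ids never collide with primary ids.
#'
#' @param x a `genotype_dataset`.
#' @return `x`, invisibly; stops with a message on the first violation.
#' @export
validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (nrow(x$geno) != nrow(x$samples))
    stop("genotype matrix has ", nrow(x$geno), " rows but ", nrow(x$samples),
         " samples are declared")
  if (ncol(x$geno) != nrow(x$markers))
    stop("genotype matrix has ", ncol(x$geno), " columns but ",
         nrow(x$markers), " markers are declared")
  if (anyDuplicated(x$samples$id))
    stop("duplicated sample ids: ",
         paste(unique(x$samples$id[duplicated(x$samples$id)]), collapse = ", "))
  if (anyDuplicated(x$markers$id))
    stop("duplicated marker ids: ",
         paste(unique(x$markers$id[duplicated(x$markers$id)]), collapse = ", "))
  if (any(!is.na(x$samples$population) & x$samples$population == ""))
    stop("sample population labels must be non-empty")
  bad <- x$geno[!is.na(x$geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotypes must be coded 0/1/2 copies of the counted allele or NA")
  if (nrow(x$markers) && any(!is.na(x$markers$position) & x$markers$position < 1L))
    stop("marker positions must be >= 1 (1-based coordinates)")
  syn <- unlist(strsplit(x$markers$synonyms[x$markers$synonyms != ""], ";",
                         fixed = TRUE))
  if (length(syn) && any(syn %in% x$markers$id))
    stop("synonym ids overlap primary marker ids: ",
         paste(intersect(syn, x$markers$id), collapse = ", "))
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x", nrow(x$markers),
      "markers\n")
  cat("  populations:", paste(unique(x$samples$population), collapse = ", "),
      "\n")
  miss <- if (length(x$geno)) mean(is.na(x$geno)) else 0
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples in a dataset
#' @param x a `genotype_dataset`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' Number of markers in a dataset
#' @param x a `genotype_dataset`.
#' @return integer count.
#' @export
n_markers <- function(x) nrow(x$markers)

#' Per-sample call rates
#'
#' Fraction of non-missing calls for each individual over all current
#' markers.
#'
#' @param x a `genotype_dataset`.
#' @return named numeric vector, one entry per sample.
#' @export
sample_call_rates <- function(x) {
  if (n_markers(x) == 0L)
    return(stats::setNames(rep(1, n_samples(x)), x$samples$id))
  stats::setNames(rowMeans(!is.na(x$geno)), x$samples$id)
}

#' Per-marker call rates
#'
#' Fraction of non-missing calls for each marker over all current samples.
#'
#' @param x a `genotype_dataset`.
#' @return named numeric vector, one entry per marker.
#' @export
marker_call_rates <- function(x) {
  if (n_samples(x) == 0L)
    return(stats::setNames(rep(1, n_markers(x)), x$markers$id))
  stats::setNames(colMeans(!is.na(x$geno)), x$markers$id)
}

#' Classify chromosome labels into genomic location classes
#'
#' Maps chromosome labels to the three location classes used for marker
#' selection: purely numeric labels are autosomal, `X`/`Y` are sex
#' chromosomes and `MT` (or `M`) is mitochondrial.
#'
#' @param chromosome character vector of chromosome labels.
#' @return character vector with values `"autosomal"`, `"sex"`,
#'   `"mitochondrial"` or `"other"`.
#' @export
chromosome_class <- function(chromosome) {
  chromosome <- toupper(as.character(chromosome))
  out <- rep("other", length(chromosome))
  out[grepl("^[0-9]+$", chromosome)] <- "autosomal"
  out[chromosome %in% c("X", "Y")] <- "sex"
  out[chromosome %in% c("MT", "M")] <- "mitochondrial"
  out
}

#' Subset a genotype dataset
#'
#' Order-preserving selection of samples and markers. Samples can be
#' selected by population, project, misidentification flag or an arbitrary
#' predicate; markers by chromosome location class or an arbitrary
#' predicate. An empty selection yields an empty (but valid) dataset.
#'
#' @param x a `genotype_dataset`.
#' @param populations optional character vector; keep samples from these
#'   populations only.
#' @param projects optional character vector; keep samples from these
#'   genotyping projects only.
#' @param drop_flagged drop samples flagged as possibly misidentified
#'   (default `FALSE`).
#' @param location_classes optional character vector among `"autosomal"`,
#'   `"sex"`, `"mitochondrial"`, `"other"`; keep markers in these classes.
#' @param sample_predicate optional function taking the sample data frame
#'   and returning a logical vector.
#' @param marker_predicate optional function taking the marker data frame
#'   and returning a logical vector.
#' @return a `genotype_dataset` restricted to the selection.
#' @export
subset_dataset <- function(x, populations = NULL, projects = NULL,
                           drop_flagged = FALSE, location_classes = NULL,
                           sample_predicate = NULL, marker_predicate = NULL) {
  keep_s <- rep(TRUE, n_samples(x))
  if (!is.null(populations)) keep_s <- keep_s & x$samples$population %in% populations
  if (!is.null(projects)) keep_s <- keep_s & x$samples$project %in% projects
  if (drop_flagged) keep_s <- keep_s & !x$samples$flagged_misidentified
  if (!is.null(sample_predicate)) keep_s <- keep_s & sample_predicate(x$samples)
  keep_m <- rep(TRUE, n_markers(x))
  if (!is.null(location_classes))
    keep_m <- keep_m & chromosome_class(x$markers$chromosome) %in% location_classes
  if (!is.null(marker_predicate)) keep_m <- keep_m & marker_predicate(x$markers)
  genotype_dataset(
    x$geno[keep_s, keep_m, drop = FALSE],
    x$samples[keep_s, , drop = FALSE],
    x$markers[keep_m, , drop = FALSE]
  )
}

#' Keep selected markers by index or id
#' @param x a `genotype_dataset`.
#' @param idx integer indices or character marker ids to keep, in order.
#' @return a `genotype_dataset`.
#' @keywords internal
keep_markers <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, x$markers$id)
  genotype_dataset(x$geno[, idx, drop = FALSE],
                   x$samples,
                   x$markers[idx, , drop = FALSE])
}

#' Keep selected samples by index or id
#' @param x a `genotype_dataset`.
#' @param idx integer indices or character sample ids to keep, in order.
#' @return a `genotype_dataset`.
#' @keywords internal
keep_samples <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, x$samples$id)
  genotype_dataset(x$geno[idx, , drop = FALSE],
                   x$samples[idx, , drop = FALSE],
                   x$markers)
}

split_synonyms <- function(s) {
  if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
}

join_synonyms <- function(v) paste(unique(v[v != ""]), collapse = ";")
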