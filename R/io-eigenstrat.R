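#' Write a genotype dataset in EIGENSTRAT format
#'
#' Produces the three-file EIGENSTRAT representation: a geno file with one
#' line per marker made of one digit per individual (2 = homozygous for the
#' counted allele, 1 = heterozygous, 0 = homozygous other allele,
#' 9 = missing), a snp file (id, chromosome, genetic distance, position,
#' counted allele, other allele) and an ind file (id, sex, population).
#' Unknown allele letters are written as `0` in the snp file.
#'
#' @param x a `genotype_dataset`.
#' @param geno_path,snp_path,ind_path output file paths.
#' @return invisibly, a list with the three paths.
#' @seealso [read_eigenstrat()]
#' @export
write_eigenstrat <- function(x, geno_path, snp_path, ind_path) {
  g <- x$geno
  defined <- !is.na(x$markers$allele1)
  has_calls <- if (n_samples(x)) colSums(!is.na(g)) > 0L else
    rep(FALSE, n_markers(x))
  if (any(has_calls & !defined))
    stop("marker ", x$markers$id[which(has_calls & !defined)[1]],
         " has non-missing calls but undefined alleles; cannot encode")
  codes <- g
  codes[is.na(codes)] <- 9L
  lines <- apply(codes, 2, paste, collapse = "")
  if (n_markers(x) == 0L) lines <- character(0)
  writeLines(lines, geno_path)

  a1 <- x$markers$allele1; a2 <- x$markers$allele2
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  snp <- data.frame(x$markers$id, x$markers$chromosome, 0.0,
                    x$markers$position, a1, a2)
  utils::write.table(snp, snp_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  ind <- data.frame(x$samples$id, "U", x$samples$population)
  utils::write.table(ind, ind_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(list(geno = geno_path, snp = snp_path, ind = ind_path))
}

#' Read an EIGENSTRAT geno/snp/ind file triple
#'
#' @param geno_path,snp_path,ind_path input file paths, as produced by
#'   [write_eigenstrat()] (snp file with or without the two allele columns).
#' @return a [genotype_dataset()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path) {
  snp_lines <- readLines(snp_path)
  snp_lines <- snp_lines[nzchar(trimws(snp_lines))]
  snp_fields <- strsplit(trimws(snp_lines), "[ \t]+")
  nf <- lengths(snp_fields)
  if (any(nf < 4L))
    stop("snp line ", which(nf < 4L)[1], " has fewer than 4 fields")
  get_allele <- function(f, k) {
    if (length(f) >= k && f[k] != "0") f[k] else NA_character_
  }
  markers <- data.frame(
    id = vapply(snp_fields, `[[`, "", 1L),
    chromosome = vapply(snp_fields, `[[`, "", 2L),
    position = as.integer(vapply(snp_fields, `[[`, "", 4L)),
    allele1 = vapply(snp_fields, get_allele, "", 5L),
    allele2 = vapply(snp_fields, get_allele, "", 6L),
    stringsAsFactors = FALSE
  )
  ind_lines <- readLines(ind_path)
  ind_lines <- ind_lines[nzchar(trimws(ind_lines))]
  ind_fields <- strsplit(trimws(ind_lines), "[ \t]+")
  samples <- data.frame(
    id = vapply(ind_fields, `[[`, "", 1L),
    population = vapply(ind_fields, function(f)
      if (length(f) >= 3L) f[3] else "default", ""),
    stringsAsFactors = FALSE
  )
  geno_lines <- readLines(geno_path)
  geno_lines <- geno_lines[nzchar(geno_lines)]
  if (length(geno_lines) != nrow(markers))
    stop("geno file has ", length(geno_lines), " lines but snp file lists ",
         nrow(markers), " markers")
  n <- nrow(samples)
  geno <- matrix(NA_integer_, n, nrow(markers))
  for (j in seq_along(geno_lines)) {
    digits <- utf8ToInt(geno_lines[j]) - utf8ToInt("0")
    if (length(digits) != n)
      stop("geno line ", j, " has ", length(digits),
           " genotypes but ind file lists ", n, " individuals")
    digits[digits == 9L] <- NA_integer_
    if (any(!is.na(digits) & (digits < 0L | digits > 2L)))
      stop("geno line ", j, " contains digits outside {0,1,2,9}")
    geno[, j] <- digits
  }
  genotype_dataset(geno, samples, markers)
}
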