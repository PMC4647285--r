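#' Read a PLINK text ped/map file pair
#'
#' Parses whitespace-delimited ped/map files with nucleotide-letter alleles
#' (`A`, `C`, `G`, `T`; `0` = missing). The ped family column becomes the
#' sample's population label. The counted allele of each marker is the first
#' non-missing allele letter encountered in file order, which makes the
#' 0/1/2 coding deterministic and independent of allele frequency.
#'
#' @param ped_path path to the ped file (6 leading columns - family,
#'   individual, father, mother, sex, phenotype - then two allele columns
#'   per marker).
#' @param map_path path to the map file (chromosome, marker id, genetic
#'   distance, physical position).
#' @return a [genotype_dataset()].
#' @seealso [write_ped_map()]
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf < 4L))
    stop("map line ", which(nf < 4L)[1], " has ", nf[nf < 4L][1],
         " fields; expected at least 4")
  map <- do.call(rbind, lapply(map_fields, function(f) f[1:4]))
  markers <- data.frame(
    id = map[, 2], chromosome = map[, 1],
    position = as.integer(map[, 4]),
    allele1 = NA_character_, allele2 = NA_character_,
    stringsAsFactors = FALSE
  )
  m <- nrow(markers)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * m
  nf <- lengths(ped_fields)
  if (any(nf != expected)) {
    i <- which(nf != expected)[1]
    stop("ped line ", i, " has ", nf[i], " fields; expected ", expected,
         " (6 + 2 x ", m, " markers)")
  }
  n <- length(ped_fields)
  samples <- data.frame(
    id = vapply(ped_fields, `[[`, "", 2L),
    population = vapply(ped_fields, `[[`, "", 1L),
    stringsAsFactors = FALSE
  )

  # alleles as an n x 2m character matrix; "0" = missing
  al <- do.call(rbind, lapply(ped_fields, function(f) f[-(1:6)]))
  al[al == "0"] <- NA_character_
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    j <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype for sample ", samples$id[j[1]],
         " at marker ", markers$id[j[2]])
  }

  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(rbind(a1[, j], a2[, j]))   # file order: sample-major, allele pair
    obs <- obs[!is.na(obs)]
    alleles <- unique(obs)
    if (length(alleles) > 2L)
      stop("marker ", markers$id[j], " has ", length(alleles),
           " distinct alleles (", paste(alleles, collapse = ","),
           "); biallelic data required")
    if (length(alleles) >= 1L) markers$allele1[j] <- alleles[1]
    if (length(alleles) == 2L) markers$allele2[j] <- alleles[2]
    geno[, j] <- (a1[, j] == markers$allele1[j]) + (a2[, j] == markers$allele1[j])
  }
  genotype_dataset(geno, samples, markers)
}

#' Write a genotype dataset as PLINK text ped/map files
#'
#' The population label is written in the family column; father, mother,
#' sex and phenotype are written as `0 0 0 -9`. Missing calls become
#' `0 0`.
#'
#' @param x a `genotype_dataset`.
#' @param ped_path,map_path output file paths.
#' @return invisibly, a list with the two paths.
#' @export
write_ped_map <- function(x, ped_path, map_path) {
  map <- data.frame(x$markers$chromosome, x$markers$id, 0,
                    x$markers$position)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  letters2 <- genotype_letters(x, sep = " ", missing = "0 0")
  lead <- cbind(x$samples$population, x$samples$id, "0", "0", "0", "-9")
  lines <- apply(cbind(lead, letters2), 1, paste, collapse = " ")
  if (n_samples(x) == 0L) lines <- character(0)
  writeLines(lines, ped_path)
  invisible(list(ped = ped_path, map = map_path))
}

#' Render genotype calls as allele-letter strings
#'
#' @param x a `genotype_dataset`.
#' @param sep separator between the two allele letters.
#' @param missing string used for missing calls.
#' @return character matrix, samples x markers.
#' @keywords internal
genotype_letters <- function(x, sep = " ", missing = "0 0") {
  n <- n_samples(x); m <- n_markers(x)
  out <- matrix(missing, n, m)
  for (j in seq_len(m)) {
    a1 <- x$markers$allele1[j]; a2 <- x$markers$allele2[j]
    g <- x$geno[, j]
    needs2 <- any(!is.na(g) & g < 2L)
    if ((any(!is.na(g)) && is.na(a1)) || (needs2 && is.na(a2)))
      stop("marker ", x$markers$id[j],
           " has non-missing calls but undefined alleles; cannot encode")
    out[!is.na(g) & g == 2L, j] <- paste(a1, a1, sep = sep)
    out[!is.na(g) & g == 1L, j] <- paste(a1, a2, sep = sep)
    out[!is.na(g) & g == 0L, j] <- paste(a2, a2, sep = sep)
  }
  out
}
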