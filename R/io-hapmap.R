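#' Write a genotype dataset in HapMap format
#'
#' Tab-delimited export with the standard eleven metadata columns
#' (rs#, alleles, chrom, pos, strand, assembly#, center, protLSID,
#' assayLSID, panelLSID, QCcode) followed by one column per sample holding
#' the two allele letters concatenated (`NN` = missing). Export only; the
#' package does not read HapMap files back.
#'
#' @param x a `genotype_dataset`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_hapmap <- function(x, path) {
  header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
              x$samples$id)
  a1 <- x$markers$allele1; a2 <- x$markers$allele2
  allele_col <- ifelse(is.na(a1), "NA",
                       ifelse(is.na(a2), a1, paste0(a1, "/", a2)))
  calls <- t(genotype_letters(x, sep = "", missing = "NN"))
  meta <- cbind(x$markers$id, allele_col, x$markers$chromosome,
                x$markers$position, "+", "NA", "NA", "NA", "NA", "NA", "NA")
  body <- apply(cbind(meta, calls), 1, paste, collapse = "\t")
  if (n_markers(x) == 0L) body <- character(0)
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}
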