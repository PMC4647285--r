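#' Collapse markers duplicated at the same chromosome position
#'
#' Genotyping chips sometimes carry the same physical SNP under different
#' identifiers. Markers sharing a (chromosome, position) pair are compared
#' individual by individual after reconciling their counted-allele
#' orientation: if all non-missing genotypes agree, one marker is kept (the
#' first in dataset order) and the other ids are recorded as its synonyms.
#' Groups with any discordant non-missing genotype, or with incompatible
#' allele pairs, are never merged - every member is dropped and the group is
#' reported as discordant.
#'
#' @param x a `genotype_dataset` whose markers carry chromosome and
#'   position.
#' @return a list with `dataset` (curated `genotype_dataset`) and `report`
#'   (data frame with one row per duplicate group: `chromosome`,
#'   `position`, `members`, `kept`, `status`).
#' @export
deduplicate_by_position <- function(x) {
  key <- paste(x$markers$chromosome, x$markers$position, sep = ":")
  groups <- split(seq_len(n_markers(x)), key)
  dup_groups <- groups[lengths(groups) > 1L]
  drop <- integer(0)
  report <- list()
  markers <- x$markers
  for (g in dup_groups) {
    g <- sort(g)
    first <- g[1]
    concordant <- TRUE
    for (other in g[-1]) {
      flip <- reconcile_orientation(
        markers$allele1[first], markers$allele2[first],
        markers$allele1[other], markers$allele2[other],
        allow_strand_flip = FALSE
      )
      if (is.na(flip)) { concordant <- FALSE; break }
      g1 <- x$geno[, first]
      g2 <- if (flip) 2L - x$geno[, other] else x$geno[, other]
      both <- !is.na(g1) & !is.na(g2)
      if (any(g1[both] != g2[both])) { concordant <- FALSE; break }
    }
    if (concordant) {
      syn <- c(split_synonyms(markers$synonyms[first]),
               markers$id[g[-1]],
               unlist(lapply(markers$synonyms[g[-1]], split_synonyms)))
      markers$synonyms[first] <- join_synonyms(syn)
      drop <- c(drop, g[-1])
      status <- "merged"
      kept <- markers$id[first]
    } else {
      drop <- c(drop, g)
      status <- "discordant"
      kept <- NA_character_
    }
    report[[length(report) + 1L]] <- data.frame(
      chromosome = markers$chromosome[first],
      position = markers$position[first],
      members = paste(markers$id[g], collapse = ";"),
      kept = kept, status = status, stringsAsFactors = FALSE
    )
  }
  keep <- setdiff(seq_len(n_markers(x)), drop)
  out <- genotype_dataset(x$geno[, keep, drop = FALSE], x$samples,
                          markers[keep, , drop = FALSE])
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(chromosome = character(0), position = integer(0),
               members = character(0), kept = character(0),
               status = character(0), stringsAsFactors = FALSE)
  list(dataset = out, report = report)
}

#' Decide whether two allele codings refer to the same SNP
#'
#' Returns `FALSE` when the second coding already counts the same allele as
#' the first, `TRUE` when its counted allele is the first coding's other
#' allele (genotypes must be complemented as `2 - g`), and `NA` when the
#' codings cannot be reconciled. With `allow_strand_flip`, reverse-strand
#' letter pairs are also accepted unless the pair is strand-ambiguous
#' (A/T or C/G), where a flip cannot be distinguished from an allele swap.
#'
#' @param ref1,ref2 reference counted and other allele letters.
#' @param oth1,oth2 the other coding's counted and other allele letters.
#' @param allow_strand_flip also try complementary-strand letters.
#' @return `TRUE`, `FALSE` or `NA` (irreconcilable).
#' @keywords internal
reconcile_orientation <- function(ref1, ref2, oth1, oth2,
                                  allow_strand_flip = TRUE) {
  ref <- c(ref1, ref2); oth <- c(oth1, oth2)
  ref_set <- ref[!is.na(ref)]; oth_set <- oth[!is.na(oth)]
  if (!length(oth_set) || !length(ref_set)) return(FALSE)
  if (all(oth_set %in% ref_set)) {
    if (!is.na(oth1) && !is.na(ref1) && oth1 == ref1) return(FALSE)
    if (!is.na(oth1) && !is.na(ref2) && oth1 == ref2) return(TRUE)
    return(NA)
  }
  if (allow_strand_flip) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ambiguous <- function(s) length(s) == 2L && setequal(s, comp[s])
    if (ambiguous(ref_set) || ambiguous(oth_set)) return(NA)
    flipped <- unname(comp[oth_set])
    if (all(!is.na(flipped)) && all(flipped %in% ref_set)) {
      f1 <- unname(comp[oth1])
      if (!is.na(f1) && !is.na(ref1) && f1 == ref1) return(FALSE)
      if (!is.na(f1) && !is.na(ref2) && f1 == ref2) return(TRUE)
    }
  }
  NA
}

#' Merge a user dataset with a reference dataset on shared markers
#'
#' Restricts both datasets to the markers they share - matched by primary
#' id or recorded synonym on either side - and stacks reference and user
#' individuals over that common marker set. User genotypes are recoded to
#' the reference's counted allele, complementing copy numbers (`2 - g`)
#' where the counted alleles are swapped and flipping strand where the
#' letter pairs are reverse complements. Markers whose allele pairs cannot
#' be reconciled, including strand-ambiguous A/T and C/G pairs whose
#' letters do not match the reference directly, are dropped and reported.
#'
#' @param user a `genotype_dataset` of query individuals.
#' @param reference a `genotype_dataset` of reference individuals.
#' @return a list with `dataset` (merged `genotype_dataset`, reference
#'   samples first, markers in reference order with reference metadata) and
#'   `dropped` (data frame of shared-but-irreconcilable markers with a
#'   `reason` column).
#' @export
merge_on_shared_markers <- function(user, reference) {
  ref_names <- c(reference$markers$id,
                 unlist(lapply(reference$markers$synonyms, split_synonyms)))
  ref_index <- c(seq_len(n_markers(reference)),
                 rep(seq_len(n_markers(reference)),
                     vapply(reference$markers$synonyms,
                            function(s) length(split_synonyms(s)), 0L)))
  lookup <- stats::setNames(ref_index, ref_names)

  match_ref <- function(j) {
    names_j <- c(user$markers$id[j], split_synonyms(user$markers$synonyms[j]))
    hit <- lookup[names_j]
    hit <- hit[!is.na(hit)]
    if (length(hit)) unname(hit[1]) else NA_integer_
  }
  ref_of <- vapply(seq_len(n_markers(user)), match_ref, 0L)
  shared <- which(!is.na(ref_of))
  if (!length(shared))
    stop("no markers shared between the user and reference datasets")

  keep_u <- integer(0); keep_r <- integer(0); flips <- logical(0)
  dropped <- list()
  for (j in shared) {
    r <- ref_of[j]
    flip <- reconcile_orientation(
      reference$markers$allele1[r], reference$markers$allele2[r],
      user$markers$allele1[j], user$markers$allele2[j],
      allow_strand_flip = TRUE
    )
    if (is.na(flip)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        user_id = user$markers$id[j], reference_id = reference$markers$id[r],
        reason = "irreconcilable_alleles", stringsAsFactors = FALSE)
    } else {
      keep_u <- c(keep_u, j); keep_r <- c(keep_r, r)
      flips <- c(flips, flip)
    }
  }
  if (!length(keep_r))
    stop("all shared markers had irreconcilable allele codings")
  ord <- order(keep_r)
  keep_u <- keep_u[ord]; keep_r <- keep_r[ord]; flips <- flips[ord]

  ug <- user$geno[, keep_u, drop = FALSE]
  if (any(flips))
    ug[, flips] <- 2L - ug[, flips, drop = FALSE]
  if (any(user$samples$id %in% reference$samples$id))
    stop("sample ids present in both datasets: ",
         paste(intersect(user$samples$id, reference$samples$id),
               collapse = ", "))
  geno <- rbind(reference$geno[, keep_r, drop = FALSE], ug)
  samples <- rbind(
    reference$samples[, c("id", "population", "project",
                          "flagged_misidentified")],
    user$samples[, c("id", "population", "project", "flagged_misidentified")]
  )
  merged <- genotype_dataset(geno, samples,
                             reference$markers[keep_r, , drop = FALSE])
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(user_id = character(0), reference_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(dataset = merged, dropped = dropped)
}
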