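#' Allele sharing distance between two individuals
#'
#' For each locus genotyped in both individuals the proportion of alleles
#' alike in state is the size of the multiset intersection of the two
#' diploid allele pairs divided by 2: identical homozygotes score 1,
#' heterozygote versus heterozygote scores 1 (both allele types shared at a
#' biallelic locus), homozygote versus heterozygote scores 0.5, and
#' opposite homozygotes score 0. On the 0/1/2 counted-allele coding this is
#' `1 - |g1 - g2| / 2`. The distance is one minus the mean proportion over
#' the loci genotyped in both (pairwise-complete).
#'
#' @param g1,g2 numeric vectors of 0/1/2 copy numbers over the same marker
#'   set, `NA` = missing.
#' @return distance in `[0, 1]`.
#' @examples
#' asd_pair(c(2, 1, 0), c(1, 1, 2))  # per-locus alike 0.5, 1, 0 -> ASD 0.5
#' @export
asd_pair <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  both <- !is.na(g1) & !is.na(g2)
  if (!any(both))
    stop("no locus genotyped in both individuals: distance undefined")
  mean(abs(g1[both] - g2[both])) / 2
}

#' Allele sharing distances between query and reference individuals
#'
#' Computes the full queries x reference-individuals distance matrix on a
#' merged dataset, excluding per pair the loci missing in either member,
#' and records the per-pair overlap (number of loci genotyped in both) so
#' that callers can enforce a stricter overlap floor. Pairs below
#' `min_overlap` genotyped loci get an `NA` distance.
#'
#' @param x a `genotype_dataset` containing both query and reference
#'   individuals over a shared marker set (e.g. from
#'   [merge_on_shared_markers()]).
#' @param query_ids,reference_ids character vectors of sample ids.
#' @param min_overlap minimum number of jointly genotyped loci required to
#'   report a distance (default 1).
#' @return an object of class `asd_matrix`: list with `asd` (queries x
#'   references matrix in `[0, 1]`), `overlap` (integer matrix),
#'   `query_ids`, `reference_ids` and `reference_populations`.
#' @export
asd_query_vs_reference <- function(x, query_ids, reference_ids,
                                   min_overlap = 1L) {
  qi <- match(query_ids, x$samples$id)
  ri <- match(reference_ids, x$samples$id)
  if (anyNA(qi)) stop("unknown query ids: ",
                      paste(query_ids[is.na(qi)], collapse = ", "))
  if (anyNA(ri)) stop("unknown reference ids: ",
                      paste(reference_ids[is.na(ri)], collapse = ", "))
  Q <- x$geno[qi, , drop = FALSE]
  R <- x$geno[ri, , drop = FALSE]
  nq <- length(qi); nr <- length(ri)
  asd <- matrix(NA_real_, nq, nr, dimnames = list(query_ids, reference_ids))
  overlap <- matrix(0L, nq, nr, dimnames = dimnames(asd))
  Rna <- is.na(R)
  for (i in seq_len(nq)) {
    qv <- Q[i, ]
    d <- abs(sweep(R, 2, qv, "-"))
    ok <- !Rna & rep(!is.na(qv), each = nr)
    cnt <- rowSums(ok)
    s <- rowSums(d * ok, na.rm = TRUE)
    overlap[i, ] <- cnt
    asd[i, ] <- ifelse(cnt >= max(1L, min_overlap), s / (2 * cnt), NA_real_)
  }
  structure(list(asd = asd, overlap = overlap,
                 query_ids = query_ids, reference_ids = reference_ids,
                 reference_populations =
                   x$samples$population[ri]),
            class = "asd_matrix")
}

#' Per-population summary of allele sharing distances
#'
#' For each query, reference populations are ranked by ascending mean
#' distance to the query's reference individuals (ties broken by population
#' label order) and the closest `top_n` are reported with their mean,
#' minimum and maximum distance and the number of reference individuals.
#'
#' @param asd an `asd_matrix` from [asd_query_vs_reference()].
#' @param top_n how many closest populations to report per query
#'   (conventionally 5 or 10).
#' @return data frame with columns `query`, `rank`, `population`,
#'   `mean_asd`, `min_asd`, `max_asd`, `n_reference`.
#' @export
population_asd_summary <- function(asd, top_n = 5L) {
  stopifnot(inherits(asd, "asd_matrix"), top_n >= 1L)
  pops <- asd$reference_populations
  rows <- lapply(seq_along(asd$query_ids), function(i) {
    d <- asd$asd[i, ]
    by_pop <- split(d, pops)
    stats <- data.frame(
      population = names(by_pop),
      mean_asd = vapply(by_pop, function(v) mean(v, na.rm = TRUE), 0),
      min_asd = vapply(by_pop, function(v) suppressWarnings(min(v, na.rm = TRUE)), 0),
      max_asd = vapply(by_pop, function(v) suppressWarnings(max(v, na.rm = TRUE)), 0),
      n_reference = vapply(by_pop, function(v) sum(!is.na(v)), 0L),
      stringsAsFactors = FALSE
    )
    stats <- stats[order(stats$mean_asd, stats$population), , drop = FALSE]
    stats <- utils::head(stats, top_n)
    cbind(query = asd$query_ids[i],
          rank = seq_len(nrow(stats)), stats,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the full ASD matrix in long format (asd_results.tsv)
#'
#' @param asd an `asd_matrix`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_asd_results <- function(asd, path) {
  long <- data.frame(
    query = rep(asd$query_ids, times = length(asd$reference_ids)),
    reference = rep(asd$reference_ids, each = length(asd$query_ids)),
    population = rep(asd$reference_populations,
                     each = length(asd$query_ids)),
    asd = as.vector(asd$asd),
    n_overlap = as.vector(asd$overlap),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Write the top-N population summary (asd_summary.tsv)
#'
#' @param summary data frame from [population_asd_summary()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_asd_summary <- function(summary, path) {
  utils::write.table(summary, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
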