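#' Quality-filtering configuration
#'
#' Bundles the thresholds of the filtering cascade. Call-rate comparisons
#' keep an individual or marker when its rate is greater than or equal to
#' the threshold; the Hardy-Weinberg and minor-allele-frequency filters
#' remove strictly below their thresholds (a marker with p exactly at the
#' threshold, or MAF exactly at the floor, is kept).
#'
#' @param min_individual_call_rate keep individuals with call rate at or
#'   above this fraction (default 0.95).
#' @param min_marker_call_rate keep markers with call rate at or above this
#'   fraction (default 0.75).
#' @param reverse_call_rate_order apply the marker call-rate filter before
#'   the individual filter (default `FALSE`: individuals first).
#' @param hwe_p_threshold remove markers with exact Hardy-Weinberg p-value
#'   strictly below this (default 0.001).
#' @param hwe_per_population test Hardy-Weinberg within each population
#'   separately instead of pooling all selected individuals (default
#'   `FALSE`; pooling can inflate rejections for structured data through
#'   the Wahlund effect).
#' @param min_maf remove markers with minor allele frequency strictly below
#'   this fraction, computed over all selected individuals pooled across
#'   populations (default 0.01).
#' @param filter_call_rate,filter_hwe,filter_maf enable flags for the three
#'   stages.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_individual_call_rate = 0.95,
                      min_marker_call_rate = 0.75,
                      reverse_call_rate_order = FALSE,
                      hwe_p_threshold = 0.001,
                      hwe_per_population = FALSE,
                      min_maf = 0.01,
                      filter_call_rate = TRUE,
                      filter_hwe = TRUE,
                      filter_maf = TRUE) {
  stopifnot(
    min_individual_call_rate >= 0, min_individual_call_rate <= 1,
    min_marker_call_rate >= 0, min_marker_call_rate <= 1,
    hwe_p_threshold >= 0, hwe_p_threshold <= 1,
    min_maf >= 0, min_maf <= 1
  )
  structure(list(
    min_individual_call_rate = min_individual_call_rate,
    min_marker_call_rate = min_marker_call_rate,
    reverse_call_rate_order = reverse_call_rate_order,
    hwe_p_threshold = hwe_p_threshold,
    hwe_per_population = hwe_per_population,
    min_maf = min_maf,
    filter_call_rate = filter_call_rate,
    filter_hwe = filter_hwe,
    filter_maf = filter_maf
  ), class = "qc_config")
}

new_selection_summary <- function() {
  data.frame(stage = character(0),
             n_samples_before = integer(0), n_markers_before = integer(0),
             n_samples_after = integer(0), n_markers_after = integer(0),
             removed = character(0), note = character(0),
             stringsAsFactors = FALSE)
}

add_stage <- function(summary, stage, before, after, removed_ids,
                      note = "") {
  rbind(summary, data.frame(
    stage = stage,
    n_samples_before = n_samples(before),
    n_markers_before = n_markers(before),
    n_samples_after = n_samples(after),
    n_markers_after = n_markers(after),
    removed = paste(removed_ids, collapse = ";"),
    note = note, stringsAsFactors = FALSE))
}

#' Individual and marker call-rate filter
#'
#' Two-stage filter on genotyping call rates. In the default order,
#' individuals are filtered first (call rate computed over all current
#' markers), then markers (call rate computed over the surviving
#' individuals only); `reverse_call_rate_order` swaps the two stages. The
#' second stage is always evaluated on the first stage's survivors, so the
#' order matters whenever missingness is concentrated.
#'
#' @param x a `genotype_dataset`.
#' @param config a [qc_config()].
#' @return a list with `dataset` and `summary` (stage-by-stage data frame).
#'   Removing every sample or marker records a warning note in the summary
#'   and returns the empty dataset rather than failing.
#' @export
call_rate_filter <- function(x, config = qc_config()) {
  summary <- new_selection_summary()
  ind_stage <- function(d) {
    rates <- sample_call_rates(d)
    keep <- rates >= config$min_individual_call_rate
    list(dataset = keep_samples(d, which(keep)),
         removed = d$samples$id[!keep])
  }
  mark_stage <- function(d) {
    rates <- marker_call_rates(d)
    keep <- rates >= config$min_marker_call_rate
    list(dataset = keep_markers(d, which(keep)),
         removed = d$markers$id[!keep])
  }
  stages <- if (config$reverse_call_rate_order)
    list(marker_call_rate = mark_stage, individual_call_rate = ind_stage)
  else
    list(individual_call_rate = ind_stage, marker_call_rate = mark_stage)
  cur <- x
  for (nm in names(stages)) {
    res <- stages[[nm]](cur)
    note <- if (n_samples(res$dataset) == 0L || n_markers(res$dataset) == 0L)
      "warning: selection emptied" else ""
    summary <- add_stage(summary, nm, cur, res$dataset, res$removed, note)
    cur <- res$dataset
  }
  list(dataset = cur, summary = summary)
}

#' Exact test for Hardy-Weinberg equilibrium at a biallelic locus
#'
#' Conditional exact test on the genotype counts given the allele counts:
#' every heterozygote count compatible with the observed allele counts is
#' enumerated (they share the parity of the minor allele count), each is
#' given its probability under random mating, and the two-sided p-value is
#' the total probability of configurations no more probable than the one
#' observed. Probabilities are built with the standard stable recurrence
#' over neighbouring heterozygote counts.
#'
#' @param n_hom_counted count of homozygotes for the counted allele.
#' @param n_het count of heterozygotes.
#' @param n_hom_other count of homozygotes for the other allele.
#' @return exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(10, 0, 10)   # strong heterozygote deficit
#' hwe_exact_test(0, 0, 25)    # monomorphic: p = 1
#' @export
hwe_exact_test <- function(n_hom_counted, n_het, n_hom_other) {
  stopifnot(n_hom_counted >= 0, n_het >= 0, n_hom_other >= 0)
  n <- n_hom_counted + n_het + n_hom_other
  if (n == 0L) stop("no genotyped individuals: p-value undefined")
  n_a <- 2L * n_hom_counted + n_het
  rare <- min(n_a, 2L * n - n_a)
  if (rare == 0L) return(1)

  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- numeric(length(hets))
  # unnormalized probabilities via the ratio
  # P(h+2)/P(h) = 4 hom_rare(h) hom_common(h) / ((h+1)(h+2))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1L]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    logp[i] <- logp[i - 1L] + log(4 * hom_r * hom_c) -
      log((h + 1) * (h + 2))
  }
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("observed heterozygote count is not attainable ",
                       "given the allele counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

marker_genotype_counts <- function(geno) {
  g <- geno
  cbind(n2 = colSums(g == 2L, na.rm = TRUE),
        n1 = colSums(g == 1L, na.rm = TRUE),
        n0 = colSums(g == 0L, na.rm = TRUE))
}

#' Hardy-Weinberg equilibrium filter
#'
#' Removes markers whose exact Hardy-Weinberg test p-value falls strictly
#' below the threshold. By default genotype counts are pooled over all
#' currently selected individuals; with `hwe_per_population` the test runs
#' within each population and a marker is removed if it is rejected in any
#' population. Markers with no genotyped individuals are left untouched by
#' this filter (the call-rate filter is the place to drop them).
#'
#' @param x a `genotype_dataset`.
#' @param config a [qc_config()].
#' @return a list with `dataset` and `summary`.
#' @export
hwe_filter <- function(x, config = qc_config()) {
  p <- hwe_marker_pvalues(x, per_population = config$hwe_per_population)
  keep <- is.na(p) | p >= config$hwe_p_threshold
  out <- keep_markers(x, which(keep))
  summary <- add_stage(new_selection_summary(), "hwe", x, out,
                       x$markers$id[!keep])
  list(dataset = out, summary = summary)
}

#' Exact Hardy-Weinberg p-values for every marker
#'
#' @param x a `genotype_dataset`.
#' @param per_population when `TRUE`, return the minimum p-value across
#'   populations with at least one genotyped individual at the marker.
#' @return numeric vector of p-values, `NA` for markers with no genotyped
#'   individuals.
#' @export
hwe_marker_pvalues <- function(x, per_population = FALSE) {
  pvals_of <- function(geno) {
    cnt <- marker_genotype_counts(geno)
    vapply(seq_len(nrow(cnt)), function(j) {
      if (sum(cnt[j, ]) == 0L) return(NA_real_)
      hwe_exact_test(cnt[j, "n2"], cnt[j, "n1"], cnt[j, "n0"])
    }, 0)
  }
  if (!per_population) return(pvals_of(x$geno))
  per_pop <- lapply(split(seq_len(n_samples(x)), x$samples$population),
                    function(idx) pvals_of(x$geno[idx, , drop = FALSE]))
  mat <- do.call(cbind, per_pop)
  apply(mat, 1, function(p) if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE))
}

#' Minor-allele-frequency filter
#'
#' The minor allele frequency of each marker is the lesser of the counted
#' allele frequency and its complement, computed over all non-missing calls
#' pooled across populations. Markers strictly below the floor are removed;
#' markers with no genotyped individuals count as MAF 0 and are removed
#' whenever the floor is positive.
#'
#' @param x a `genotype_dataset`.
#' @param config a [qc_config()].
#' @return a list with `dataset` and `summary`.
#' @export
maf_filter <- function(x, config = qc_config()) {
  maf <- marker_maf(x)
  keep <- maf >= config$min_maf
  out <- keep_markers(x, which(keep))
  summary <- add_stage(new_selection_summary(), "maf", x, out,
                       x$markers$id[!keep])
  list(dataset = out, summary = summary)
}

#' Minor allele frequencies over the whole dataset
#' @param x a `genotype_dataset`.
#' @return numeric vector, one MAF per marker (0 for ungenotyped markers).
#' @export
marker_maf <- function(x) {
  freq <- colMeans(x$geno, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  pmin(freq, 1 - freq)
}

#' Run the full quality-filtering cascade
#'
#' Applies, in order, the call-rate filters (individuals and markers, order
#' configurable), the exact Hardy-Weinberg filter and the minor-allele-
#' frequency filter, each optional. The returned summary mirrors the
#' selection report users download (`selection.txt`): one row per stage
#' with before/after counts and the removed identifiers.
#'
#' @param x a `genotype_dataset`.
#' @param config a [qc_config()].
#' @return a list with `dataset` and `summary`.
#' @seealso [write_selection_summary()]
#' @export
run_qc <- function(x, config = qc_config()) {
  summary <- new_selection_summary()
  cur <- x
  if (config$filter_call_rate) {
    res <- call_rate_filter(cur, config)
    summary <- rbind(summary, res$summary)
    cur <- res$dataset
  }
  if (config$filter_hwe) {
    res <- hwe_filter(cur, config)
    summary <- rbind(summary, res$summary)
    cur <- res$dataset
  }
  if (config$filter_maf) {
    res <- maf_filter(cur, config)
    summary <- rbind(summary, res$summary)
    cur <- res$dataset
  }
  list(dataset = cur, summary = summary)
}

#' Write a selection summary as a selection.txt-style TSV
#'
#' @param summary the `summary` data frame from [run_qc()] or an individual
#'   filter.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_selection_summary <- function(summary, path) {
  utils::write.table(summary, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
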