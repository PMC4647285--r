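#' Threshold-based population assignment from ancestry proportions
#'
#' A query is assigned to the population with its highest estimated
#' ancestry proportion if and only if that maximum strictly exceeds the
#' threshold `t`; otherwise it is left unassigned. At low thresholds
#' several populations may clear `t`, in which case the one with the
#' highest ancestry wins; exact argmax ties are broken by population label
#' order and flagged.
#'
#' @param q queries x K matrix of ancestry proportions (rows on the
#'   simplex) with population column names, e.g. `result$q` from
#'   [supervised_em()].
#' @param t ancestry threshold in `[0, 1]`; a maximum exactly equal to `t`
#'   leaves the query unassigned.
#' @return data frame with columns `query`, `assigned` (population label or
#'   `NA` when unassigned), `ancestry` (the supporting maximum), `tied`
#'   and `threshold`.
#' @export
assign_populations <- function(q, t) {
  stopifnot(t >= 0, t <= 1, !is.null(colnames(q)))
  pops <- colnames(q)
  ord <- order(pops)
  qo <- q[, ord, drop = FALSE]
  top <- apply(qo, 1, which.max)  # first (label-order) argmax on ties
  best <- qo[cbind(seq_len(nrow(qo)), top)]
  tied <- apply(qo, 1, function(r) sum(r == max(r)) > 1L)
  assigned <- ifelse(best > t, pops[ord][top], NA_character_)
  ids <- rownames(q)
  if (is.null(ids)) ids <- paste0("query", seq_len(nrow(q)))
  data.frame(query = ids, assigned = assigned, ancestry = best,
             tied = tied, threshold = t, stringsAsFactors = FALSE)
}

#' Assignment and misassignment rates against known origins
#'
#' The assignment rate is the fraction of all queries assigned to some
#' population; the misassignment rate is the fraction of *assigned*
#' queries whose assigned population differs from their population of
#' origin. With zero assigned queries the misassignment rate is undefined
#' and reported as `NA`, never as 0.
#'
#' @param outcomes data frame from [assign_populations()].
#' @param truth character vector of true population labels, one per query.
#' @return a list with `assignment_rate`, `misassignment_rate`,
#'   `n_assigned` and `n_misassigned`.
#' @export
assignment_rates <- function(outcomes, truth) {
  stopifnot(length(truth) == nrow(outcomes))
  assigned <- !is.na(outcomes$assigned)
  n_assigned <- sum(assigned)
  n_mis <- sum(assigned & outcomes$assigned != truth)
  list(
    assignment_rate = n_assigned / nrow(outcomes),
    misassignment_rate = if (n_assigned > 0) n_mis / n_assigned else NA_real_,
    n_assigned = n_assigned,
    n_misassigned = n_mis
  )
}

#' Assignment/misassignment rates over a grid of ancestry thresholds
#'
#' @param q queries x K ancestry matrix (see [assign_populations()]).
#' @param truth character vector of true population labels.
#' @param thresholds ordered numeric grid in `[0, 1]` (default 101 points,
#'   0.00 to 1.00).
#' @return data frame of class `rate_curve` with columns `threshold`,
#'   `assignment_rate`, `misassignment_rate` (`NA` where no query is
#'   assigned) and `n_assigned`. The assignment rate is non-increasing in
#'   the threshold.
#' @export
rate_curve <- function(q, truth, thresholds = seq(0, 1, by = 0.01)) {
  rows <- lapply(thresholds, function(t) {
    r <- assignment_rates(assign_populations(q, t), truth)
    data.frame(threshold = t, assignment_rate = r$assignment_rate,
               misassignment_rate = r$misassignment_rate,
               n_assigned = r$n_assigned)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_curve", "data.frame")
  out
}

#' Write a rate curve as TSV
#' @param curve a `rate_curve` data frame.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_rate_curve <- function(curve, path) {
  utils::write.table(curve, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Self-assignment evaluation over SNP subset sizes and EM tolerances
#'
#' Evaluation protocol for the assignment pipeline: every individual of a
#' labelled dataset is treated as a query against a reference panel built
#' from that same dataset (self-assignment; the evaluated individual stays
#' inside its population's frequency estimate unless `leave_one_out`).
#' For each requested SNP subset size, markers are sampled uniformly
#' without replacement under the seed; for each EM tolerance, ancestry
#' proportions are estimated and the assignment/misassignment rate curve
#' computed over the threshold grid.
#'
#' @param x a `genotype_dataset` with population labels.
#' @param snp_sizes integer vector of marker subset sizes (each at most the
#'   marker count; the full count means no subsampling).
#' @param epsilons numeric vector of EM stopping tolerances.
#' @param thresholds ancestry threshold grid (default 101 points 0-1).
#' @param min_individuals reference-population size floor passed to
#'   [build_reference_panel()] (default 15).
#' @param leave_one_out re-estimate the panel frequencies without the
#'   evaluated individual before scoring it (default `FALSE`, matching the
#'   plain self-assignment protocol).
#' @param seed integer seed controlling marker subsampling.
#' @return a list of `rate_curve` data frames keyed
#'   `"size<NN>_eps<EE>"`, each carrying attributes `snp_size` and
#'   `epsilon`.
#' @export
self_assignment_experiment <- function(x, snp_sizes, epsilons,
                                       thresholds = seq(0, 1, by = 0.01),
                                       min_individuals = 15L,
                                       leave_one_out = FALSE,
                                       seed = 1L) {
  stopifnot(all(snp_sizes >= 1L), all(snp_sizes <= n_markers(x)))
  curves <- list()
  for (size in snp_sizes) {
    set.seed(seed + size)
    idx <- if (size == n_markers(x)) seq_len(n_markers(x)) else
      sort(sample.int(n_markers(x), size))
    sub <- keep_markers(x, idx)
    panel <- build_reference_panel(sub, min_individuals = min_individuals)
    in_panel <- sub$samples$population %in% panel$populations
    queries <- sub$samples$id[in_panel]
    truth <- sub$samples$population[in_panel]
    g <- align_to_panel(sub, panel, queries)
    for (eps in epsilons) {
      qmat <- if (leave_one_out) {
        loo_ancestry(sub, panel, queries, em_config(epsilon = eps))
      } else {
        supervised_em(g, panel, em_config(epsilon = eps))$q
      }
      curve <- rate_curve(qmat, truth, thresholds)
      attr(curve, "snp_size") <- size
      attr(curve, "epsilon") <- eps
      curves[[sprintf("size%d_eps%g", size, eps)]] <- curve
    }
  }
  curves
}

loo_ancestry <- function(x, panel, queries, config) {
  out <- matrix(NA_real_, length(queries), length(panel$populations),
                dimnames = list(queries, panel$populations))
  for (i in seq_along(queries)) {
    id <- queries[i]
    rest <- keep_samples(x, setdiff(x$samples$id, id))
    p <- build_reference_panel(rest, min_individuals = 1L)
    p <- p[c("populations", "marker_ids", "f", "y", "n")]
    # keep the panel's population set even if leaving one out drops a pop
    keep <- match(panel$populations, p$populations)
    if (anyNA(keep)) stop("leave-one-out removed population: ", id)
    p$f <- p$f[keep, , drop = FALSE]
    p$populations <- panel$populations
    class(p) <- "reference_panel"
    g <- align_to_panel(x, p, id)
    out[i, ] <- supervised_em(g, p, config)$q
  }
  out
}
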