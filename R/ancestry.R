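#' Build a reference panel of Laplace-smoothed allele frequencies
#'
#' For each population with at least `min_individuals` samples, the counted
#' allele frequency at each marker is estimated as `(y + 1) / (n + 2)`,
#' where `y` is the counted-allele copy count and `n` the total number of
#' allele copies among genotyped individuals (twice the genotyped
#' diploids). The add-one smoothing keeps every frequency strictly inside
#' (0, 1), so the ancestry likelihood below is always finite. Populations
#' below the size floor are excluded and reported.
#'
#' @param x a `genotype_dataset` with population labels.
#' @param min_individuals minimum population size to qualify as a reference
#'   population (default 15).
#' @return an object of class `reference_panel`: list with `populations`
#'   (K labels), `marker_ids`, `f` (K x markers frequency matrix), `y` and
#'   `n` (count matrices), `sizes` (individuals per population) and
#'   `excluded` (populations under the floor).
#' @export
build_reference_panel <- function(x, min_individuals = 15L) {
  tab <- table(x$samples$population)
  qualifying <- sort(names(tab)[tab >= min_individuals])
  excluded <- sort(names(tab)[tab < min_individuals])
  if (!length(qualifying))
    stop("no population has at least ", min_individuals, " individuals")
  K <- length(qualifying); M <- n_markers(x)
  y <- matrix(0, K, M, dimnames = list(qualifying, x$markers$id))
  n <- matrix(0, K, M, dimnames = dimnames(y))
  for (k in seq_len(K)) {
    idx <- which(x$samples$population == qualifying[k])
    g <- x$geno[idx, , drop = FALSE]
    y[k, ] <- colSums(g, na.rm = TRUE)
    n[k, ] <- 2 * colSums(!is.na(g))
  }
  structure(list(
    populations = qualifying, marker_ids = x$markers$id,
    f = (y + 1) / (n + 2), y = y, n = n,
    sizes = as.integer(tab[qualifying]),
    excluded = excluded
  ), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", length(x$populations), "populations x",
      length(x$marker_ids), "markers\n")
  if (length(x$excluded))
    cat("  excluded (below size floor):", paste(x$excluded, collapse = ", "),
        "\n")
  invisible(x)
}

#' Configuration for the supervised-clustering EM algorithm
#'
#' @param epsilon stopping tolerance: the algorithm stops once the increase
#'   in a query's log-likelihood between successive iterations falls below
#'   `epsilon`. Looser values (the conventional presets are 0.01, 0.1 and
#'   1) terminate faster at some cost in accuracy.
#' @param max_iterations safety cap on EM iterations (default 10000); a
#'   query hitting the cap is flagged as not converged.
#' @param init `"uniform"` (deterministic, each ancestry 1/K) or
#'   `"random"` (Dirichlet(1) draw, controlled by `seed`).
#' @param seed integer seed used only for random initialization.
#' @return an object of class `em_config`.
#' @export
em_config <- function(epsilon = 0.1, max_iterations = 10000L,
                      init = c("uniform", "random"), seed = NULL) {
  stopifnot(epsilon > 0, max_iterations >= 1L)
  structure(list(epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 init = match.arg(init), seed = seed),
            class = "em_config")
}

#' Log-likelihood of a query genotype vector given ancestry proportions
#'
#' Under the fixed-frequency admixture model, each allele copy of
#' individual j at locus m is drawn from population k with probability
#' `q_k` and is then the counted allele with probability `f_km`. The
#' log-likelihood over the non-missing loci is
#' `sum_m g_m log(sum_k q_k f_km) + (2 - g_m) log(sum_k q_k (1 - f_km))`.
#' An all-missing query has log-likelihood 0 (empty sum).
#'
#' @param g numeric vector of 0/1/2 copy numbers aligned to the panel's
#'   markers, `NA` = missing.
#' @param q ancestry proportions on the K-simplex.
#' @param panel a [build_reference_panel()] result.
#' @return finite log-likelihood value.
#' @export
ancestry_loglikelihood <- function(g, q, panel) {
  stopifnot(length(q) == length(panel$populations),
            length(g) == length(panel$marker_ids),
            abs(sum(q) - 1) < 1e-6, all(q >= 0))
  ok <- !is.na(g)
  if (!any(ok)) return(0)
  a <- as.vector(q %*% panel$f[, ok, drop = FALSE])
  b <- as.vector(q %*% (1 - panel$f[, ok, drop = FALSE]))
  sum(g[ok] * log(a) + (2 - g[ok]) * log(b))
}

#' Estimate ancestry proportions by supervised clustering
#'
#' Fixed-frequency EM for the admixture model: reference allele frequencies
#' are held at their Laplace-smoothed panel values and only the ancestry
#' proportions `q` of each query are optimized. Starting from the
#' configured initialization, each iteration applies the update
#' `q'_k = (1 / 2M') * sum_m [ g_m q_k f_km / sum_l q_l f_lm
#'   + (2 - g_m) q_k (1 - f_km) / sum_l q_l (1 - f_lm) ]`
#' over the `M'` non-missing loci, which never decreases the
#' log-likelihood. A query stops (and its estimate is frozen) once its
#' log-likelihood gain over one iteration drops below `epsilon`; queries
#' are otherwise independent given the fixed frequencies.
#'
#' @param g numeric vector (one query) or matrix (queries x markers) of
#'   0/1/2 copy numbers aligned to `panel$marker_ids`, `NA` = missing.
#' @param panel a [build_reference_panel()] result.
#' @param config an [em_config()].
#' @return an object of class `ancestry_proportions`: list with `q`
#'   (queries x K matrix, rows on the simplex), `loglik`, `iterations`,
#'   `converged` and `populations`.
#' @export
supervised_em <- function(g, panel, config = em_config()) {
  if (is.vector(g)) g <- matrix(g, nrow = 1)
  M <- length(panel$marker_ids)
  stopifnot(ncol(g) == M)
  K <- length(panel$populations)
  nq <- nrow(g)
  ids <- rownames(g)
  if (is.null(ids)) ids <- paste0("query", seq_len(nq))

  W <- !is.na(g)
  Mp <- rowSums(W)
  if (any(Mp == 0L))
    stop("query with no genotyped locus shared with the panel: ",
         paste(ids[Mp == 0L], collapse = ", "))
  Gm <- ifelse(W, g, 0)
  H <- ifelse(W, 2 - g, 0)
  F <- panel$f
  Fc <- 1 - F

  Q <- if (config$init == "uniform") {
    matrix(1 / K, nq, K)
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    r <- matrix(stats::rexp(nq * K), nq, K)
    r / rowSums(r)
  }
  dimnames(Q) <- list(ids, panel$populations)

  iterations <- integer(nq)
  converged <- rep(FALSE, nq)
  loglik <- rep(NA_real_, nq)

  loglik_rows <- function(Qa, rows) {
    A <- Qa %*% F
    B <- Qa %*% Fc
    rowSums(Gm[rows, , drop = FALSE] * log(A) +
              H[rows, , drop = FALSE] * log(B))
  }

  if (K == 1L) {
    Q[] <- 1
    return(structure(list(q = Q, loglik = loglik_rows(Q, seq_len(nq)),
                          iterations = iterations, converged = !logical(nq),
                          populations = panel$populations),
                     class = "ancestry_proportions"))
  }

  active <- seq_len(nq)
  ll_old <- loglik_rows(Q[active, , drop = FALSE], active)
  iter <- 0L
  while (length(active) && iter < config$max_iterations) {
    iter <- iter + 1L
    Qa <- Q[active, , drop = FALSE]
    A <- Qa %*% F
    B <- Qa %*% Fc
    U <- (Gm[active, , drop = FALSE] / A) %*% t(F)
    V <- (H[active, , drop = FALSE] / B) %*% t(Fc)
    Qn <- Qa * (U + V) / (2 * Mp[active])
    Qn <- Qn / rowSums(Qn)
    ll_new <- rowSums(Gm[active, , drop = FALSE] * log(Qn %*% F) +
                        H[active, , drop = FALSE] * log(Qn %*% Fc))
    Q[active, ] <- Qn
    iterations[active] <- iter
    done <- (ll_new - ll_old) < config$epsilon
    loglik[active] <- ll_new
    converged[active[done]] <- TRUE
    ll_old <- ll_new[!done]
    active <- active[!done]
  }
  structure(list(q = Q, loglik = loglik, iterations = iterations,
                 converged = converged, populations = panel$populations),
            class = "ancestry_proportions")
}

#' @export
print.ancestry_proportions <- function(x, ...) {
  cat("ancestry_proportions:", nrow(x$q), "queries x",
      length(x$populations), "reference populations\n")
  cat("  converged:", sum(x$converged), "/", length(x$converged), "\n")
  invisible(x)
}

#' Tabulate supervised-clustering results
#'
#' Produces the two tables users download: the complete results (one row
#' per query with all ancestry proportions, final log-likelihood,
#' iteration count and convergence flag) and a summary naming each query's
#' top population by estimated ancestry. Population columns keep the
#' panel's order across queries.
#'
#' @param result an `ancestry_proportions` object from [supervised_em()].
#' @param truth optional character vector of true population labels (one
#'   per query); when supplied the summary gains a `correct` column.
#' @return a list with data frames `results` and `summary`.
#' @export
ancestry_report <- function(result, truth = NULL) {
  qmat <- result$q
  results <- data.frame(query = rownames(qmat), qmat,
                        loglik = result$loglik,
                        iterations = result$iterations,
                        converged = result$converged,
                        stringsAsFactors = FALSE, check.names = FALSE)
  top_idx <- apply(qmat, 1, which.max)
  summary <- data.frame(
    query = rownames(qmat),
    top_population = result$populations[top_idx],
    ancestry = qmat[cbind(seq_len(nrow(qmat)), top_idx)],
    stringsAsFactors = FALSE
  )
  if (!is.null(truth)) {
    stopifnot(length(truth) == nrow(qmat))
    summary$truth <- truth
    summary$correct <- summary$top_population == truth
  }
  rownames(results) <- rownames(summary) <- NULL
  list(results = results, summary = summary)
}

#' Write ancestry tables (ancestry_results.tsv / ancestry_summary.tsv)
#'
#' @param report a list from [ancestry_report()].
#' @param results_path,summary_path output file paths.
#' @return invisibly, a list with the two paths.
#' @export
write_ancestry_report <- function(report, results_path, summary_path) {
  utils::write.table(report$results, results_path, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  utils::write.table(report$summary, summary_path, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(list(results = results_path, summary = summary_path))
}

#' Align a dataset's genotypes to a panel's marker order
#'
#' @param x a `genotype_dataset`.
#' @param panel a `reference_panel`.
#' @param sample_ids samples to extract (default all).
#' @return numeric matrix, samples x panel markers, `NA` where the dataset
#'   lacks a panel marker.
#' @export
align_to_panel <- function(x, panel, sample_ids = x$samples$id) {
  si <- match(sample_ids, x$samples$id)
  if (anyNA(si)) stop("unknown sample ids: ",
                      paste(sample_ids[is.na(si)], collapse = ", "))
  mi <- match(panel$marker_ids, x$markers$id)
  out <- matrix(NA_real_, length(si), length(panel$marker_ids),
                dimnames = list(sample_ids, panel$marker_ids))
  ok <- !is.na(mi)
  out[, ok] <- x$geno[si, mi[ok], drop = FALSE]
  out
}
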