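#' Principal component analysis of a genotype matrix
#'
#' Genotypes are coded 0/1/2 copies of the counted allele; monomorphic and
#' fully missing markers are dropped, remaining missing calls are imputed
#' with the marker mean, each marker is mean-centered and - when
#' `normalize` - divided by `sqrt(p(1-p))` with `p` the counted-allele
#' frequency estimated from the analysis sample itself (the usual
#' normalization for genotype PCA, which upweights rare variants). Sample
#' coordinates are the projections on the leading eigenvectors of the
#' sample covariance matrix.
#'
#' @param x a `genotype_dataset` with at least 2 samples and 2 polymorphic
#'   markers.
#' @param n_components number of components to compute (default 10);
#'   truncated with a warning when the data support fewer.
#' @param normalize divide centered genotypes by `sqrt(p(1-p))` (default
#'   `TRUE`).
#' @return an object of class `pca_result`: list with `coordinates`
#'   (samples x components), `eigenvalues` (non-increasing),
#'   `variance_fraction`, `markers_used` (ids) and `samples` (the sample
#'   table, for labelled output).
#' @export
run_pca <- function(x, n_components = 10L, normalize = TRUE) {
  if (n_samples(x) < 2L) stop("PCA needs at least 2 samples")
  g <- x$geno
  p_hat <- colMeans(g, na.rm = TRUE) / 2
  n_obs <- colSums(!is.na(g))
  poly <- n_obs > 0L & p_hat > 0 & p_hat < 1
  if (sum(poly) < 2L) stop("PCA needs at least 2 polymorphic markers")
  g <- g[, poly, drop = FALSE]
  p_hat <- p_hat[poly]

  X <- g
  mu <- 2 * p_hat
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, mu)
  if (normalize) X <- sweep(X, 2, sqrt(p_hat * (1 - p_hat)), "/")

  n <- nrow(X)
  max_k <- min(n - 1L, ncol(X))
  k <- min(n_components, max_k)
  if (k < n_components)
    warning("requested ", n_components, " components but the data support ",
            k, "; truncating")
  sv <- svd(X, nu = max_k, nv = 0)
  eig <- sv$d[seq_len(max_k)]^2 / (n - 1)
  coords <- sv$u %*% diag(sv$d[seq_len(max_k)], max_k, max_k)
  coords <- coords[, seq_len(k), drop = FALSE]
  dimnames(coords) <- list(x$samples$id, paste0("PC", seq_len(k)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig[seq_len(k)],
    variance_fraction = eig[seq_len(k)] / sum(eig),
    markers_used = x$markers$id[poly],
    samples = x$samples
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$coordinates), "samples,",
      length(x$eigenvalues), "components,",
      length(x$markers_used), "markers\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' Write PCA results in smartpca-style output files
#'
#' The evec file holds a header line with the eigenvalues (prefixed
#' `#eigvals:`) followed by one line per sample: id, the coordinates on
#' each computed component, and the population label. The eval file holds
#' one eigenvalue per line.
#'
#' @param result a [run_pca()] result.
#' @param evec_path,eval_path output file paths (conventionally
#'   `output.pca.evec` and `output.eval`).
#' @return invisibly, a list with the two paths.
#' @export
write_pca_outputs <- function(result, evec_path, eval_path) {
  header <- paste(c("#eigvals:",
                    sprintf("%.6f", result$eigenvalues)), collapse = " ")
  body <- paste(
    result$samples$id,
    apply(result$coordinates, 1,
          function(r) paste(sprintf("%.6f", r), collapse = " ")),
    result$samples$population
  )
  writeLines(c(header, body), evec_path)
  writeLines(sprintf("%.6f", result$eigenvalues), eval_path)
  invisible(list(evec = evec_path, eval = eval_path))
}

#' Read a smartpca-style evec file
#'
#' @param evec_path path to a file written by [write_pca_outputs()].
#' @return a list with `eigenvalues`, `coordinates` (matrix with sample id
#'   rownames) and `populations`.
#' @export
read_pca_evec <- function(evec_path) {
  lines <- readLines(evec_path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  eig <- as.numeric(header[-1])
  fields <- strsplit(trimws(lines[-1]), "[ \t]+")
  ids <- vapply(fields, `[[`, "", 1L)
  pops <- vapply(fields, function(f) f[length(f)], "")
  coords <- do.call(rbind, lapply(fields, function(f)
    as.numeric(f[2:(length(f) - 1L)])))
  rownames(coords) <- ids
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  list(eigenvalues = eig, coordinates = coords, populations = pops)
}
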