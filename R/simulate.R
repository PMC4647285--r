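#' Simulate differentiated reference populations (Balding-Nichols model)
#'
#' Generates a synthetic panel of diverged populations genotyped at
#' unlinked biallelic SNPs. Per marker, an ancestral counted-allele
#' frequency `p` is drawn uniformly from `ancestral_range`; each
#' population's frequency is then drawn from the Balding-Nichols Beta
#' distribution with shape parameters `p(1-F)/F` and `(1-p)(1-F)/F`, whose
#' mean is `p` and whose variance `F p(1-p)` is controlled by the
#' differentiation parameter `F` (an FST analog). Genotypes are two
#' independent allele copies per individual. Markers sit on a single
#' synthetic autosome at consecutive positions with random distinct
#' nucleotide letters; no linkage disequilibrium is simulated.
#'
#' @param n_populations number of populations (labels `POP01`, ...).
#' @param n_per_population diploid individuals per population.
#' @param n_markers number of SNPs.
#' @param fst differentiation parameter `F` in (0, 1).
#' @param ancestral_range range of the uniform ancestral frequency draw
#'   (default `c(0.05, 0.95)`).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a list with `dataset` (a `genotype_dataset`), `freq` (true
#'   K x markers population frequency matrix) and `ancestral` (the
#'   ancestral frequencies).
#' @export
simulate_reference <- function(n_populations = 10L, n_per_population = 20L,
                               n_markers = 10000L, fst = 0.1,
                               ancestral_range = c(0.05, 0.95),
                               seed = 1L) {
  stopifnot(n_populations >= 1L, n_per_population >= 1L, n_markers >= 1L,
            fst > 0, fst < 1)
  set.seed(seed)
  K <- n_populations; M <- n_markers
  p_anc <- stats::runif(M, ancestral_range[1], ancestral_range[2])
  pops <- sprintf("POP%02d", seq_len(K))
  freq <- matrix(0, K, M, dimnames = list(pops, NULL))
  for (k in seq_len(K)) {
    f <- stats::rbeta(M, p_anc * (1 - fst) / fst,
                      (1 - p_anc) * (1 - fst) / fst)
    freq[k, ] <- pmin(pmax(f, 1e-9), 1 - 1e-9)
  }
  markers <- simulated_marker_table(M)
  colnames(freq) <- markers$id

  n <- K * n_per_population
  geno <- matrix(NA_integer_, n, M)
  samples <- data.frame(
    id = sprintf("%s_ind%03d", rep(pops, each = n_per_population),
                 rep(seq_len(n_per_population), K)),
    population = rep(pops, each = n_per_population),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(K)) {
    rows <- which(samples$population == pops[k])
    geno[rows, ] <- matrix(
      stats::rbinom(length(rows) * M, 2L, rep(freq[k, ], each = length(rows))),
      length(rows), M)
  }
  list(dataset = genotype_dataset(geno, samples, markers),
       freq = freq, ancestral = p_anc)
}

simulated_marker_table <- function(M) {
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, M, replace = TRUE)
  shift <- sample(1:3, M, replace = TRUE)
  a2 <- bases[(match(a1, bases) + shift - 1L) %% 4L + 1L]
  data.frame(
    id = sprintf("snp%06d", seq_len(M)),
    chromosome = "1",
    position = seq_len(M),
    allele1 = a1, allele2 = a2,
    stringsAsFactors = FALSE
  )
}

#' Simulate admixed individuals with known ancestry proportions
#'
#' Each of the individual's two allele copies at each locus is drawn by
#' first sampling a source population from the design proportions `q_star`
#' and then sampling the counted allele with that population's frequency -
#' the generative counterpart of the fixed-frequency admixture likelihood,
#' so the designed `q_star` is the quantity the supervised-clustering
#' estimator should recover.
#'
#' @param freq K x markers population frequency matrix (e.g. `freq` from
#'   [simulate_reference()]).
#' @param q_star ancestry design vector on the K-simplex.
#' @param n_individuals number of admixed individuals to draw.
#' @param markers marker table matching `freq`'s columns (use the reference
#'   dataset's `$markers` so the two datasets share marker metadata).
#' @param population population label for the new samples (default
#'   `"ADMIXED"`).
#' @param id_prefix prefix for sample ids.
#' @param seed integer seed.
#' @return a `genotype_dataset` of the admixed individuals.
#' @export
simulate_admixed <- function(freq, q_star, n_individuals, markers,
                             population = "ADMIXED",
                             id_prefix = population, seed = 1L) {
  K <- nrow(freq); M <- ncol(freq)
  stopifnot(length(q_star) == K, abs(sum(q_star) - 1) < 1e-9,
            all(q_star >= 0), nrow(markers) == M, n_individuals >= 1L)
  set.seed(seed)
  n <- n_individuals
  geno <- matrix(0L, n, M)
  for (copy in 1:2) {
    src <- matrix(sample.int(K, n * M, replace = TRUE, prob = q_star), n, M)
    f <- matrix(freq[cbind(as.vector(src), rep(seq_len(M), each = n))], n, M)
    geno <- geno + (matrix(stats::runif(n * M), n, M) < f)
  }
  samples <- data.frame(
    id = sprintf("%s_ind%03d", id_prefix, seq_len(n)),
    population = population, stringsAsFactors = FALSE
  )
  genotype_dataset(geno, samples, markers)
}

#' Set genotype calls to missing at random
#'
#' Each call is independently set missing with the given probability;
#' useful for exercising the call-rate filters.
#'
#' @param x a `genotype_dataset`.
#' @param rate missing probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a `genotype_dataset` with injected missingness.
#' @export
inject_missingness <- function(x, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(x)
  set.seed(seed)
  g <- x$geno
  g[matrix(stats::runif(length(g)) < rate, nrow(g), ncol(g))] <- NA_integer_
  genotype_dataset(g, x$samples, x$markers)
}

#' Simulate a full assignment study: reference panel plus admixed queries
#'
#' Convenience wrapper producing a reference dataset and, optionally,
#' admixed query individuals from an admixture design, with the true
#' ancestry of every query recorded.
#'
#' @param n_populations,n_per_population,n_markers,fst,ancestral_range,seed
#'   passed to [simulate_reference()].
#' @param admixture optional design: a list of `list(q = <simplex vector>,
#'   n = <count>)` entries, one per admixed group.
#' @param missing_rate fraction of calls set missing in both datasets
#'   (default 0).
#' @return a list with `reference` (dataset), `freq`, `queries` (dataset or
#'   `NULL`) and `truth_q` (queries x K matrix of designed ancestries).
#' @export
simulate_study <- function(n_populations = 10L, n_per_population = 20L,
                           n_markers = 10000L, fst = 0.1,
                           ancestral_range = c(0.05, 0.95),
                           admixture = NULL, missing_rate = 0,
                           seed = 1L) {
  ref <- simulate_reference(n_populations, n_per_population, n_markers,
                            fst, ancestral_range, seed = seed)
  queries <- NULL; truth_q <- NULL
  if (!is.null(admixture)) {
    parts <- list()
    for (i in seq_along(admixture)) {
      d <- admixture[[i]]
      parts[[i]] <- simulate_admixed(
        ref$freq, d$q, d$n, ref$dataset$markers,
        population = sprintf("ADMIX%02d", i),
        seed = seed + 1000L + i)
    }
    geno <- do.call(rbind, lapply(parts, `[[`, "geno"))
    samples <- do.call(rbind, lapply(parts, `[[`, "samples"))
    queries <- genotype_dataset(geno, samples, ref$dataset$markers)
    truth_q <- do.call(rbind, lapply(seq_along(admixture), function(i)
      matrix(admixture[[i]]$q, admixture[[i]]$n, n_populations,
             byrow = TRUE)))
    dimnames(truth_q) <- list(queries$samples$id,
                              rownames(ref$freq))
  }
  reference <- ref$dataset
  if (missing_rate > 0) {
    reference <- inject_missingness(reference, missing_rate,
                                    seed = seed + 500L)
    if (!is.null(queries))
      queries <- inject_missingness(queries, missing_rate,
                                    seed = seed + 501L)
  }
  list(reference = reference, freq = ref$freq, queries = queries,
       truth_q = truth_q)
}
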