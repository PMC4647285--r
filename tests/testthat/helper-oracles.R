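# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different computational routes than the package.

# Exact HWE p-value by direct enumeration of the conditional distribution of
# the heterozygote count given the allele counts, with explicit factorial
# arithmetic (the package uses the stable neighbour-ratio recurrence).
hwe_enumeration_oracle <- function(naa, nab, nbb) {
  N <- naa + nab + nbb
  nA <- 2 * naa + nab
  nB <- 2 * N - nA
  hets <- seq.int(nA %% 2, min(nA, nB), by = 2)
  prob <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- N - h - a
    exp(lfactorial(N) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
          h * log(2) +
          lfactorial(nA) + lfactorial(nB) - lfactorial(2 * N))
  }, 0)
  obs <- match(nab, hets)
  list(p = sum(prob[prob <= prob[obs] * (1 + 1e-12)]), total = sum(prob))
}

# Per-locus alike-in-state proportion from explicit allele-letter pairs via
# multiset intersection (the package works on 0/1/2 dosages).
ibs_share_oracle <- function(pair1, pair2) {
  shared <- 0L
  remaining <- pair2
  for (a in pair1) {
    hit <- match(a, remaining)
    if (!is.na(hit)) { shared <- shared + 1L; remaining <- remaining[-hit] }
  }
  shared / 2
}

asd_letter_oracle <- function(gen1, gen2) {
  per_locus <- mapply(ibs_share_oracle, gen1, gen2)
  1 - mean(per_locus)
}

dosage_to_pairs <- function(g, a1 = "A", a2 = "B") {
  lapply(g, function(v) switch(as.character(v),
                               "2" = c(a1, a1), "1" = c(a1, a2),
                               "0" = c(a2, a2)))
}

# Admixture log-likelihood written directly from the model definition,
# locus by locus (used for the grid-search oracle).
loglik_direct <- function(g, q, f) {
  ll <- 0
  for (m in seq_along(g)) {
    if (is.na(g[m])) next
    pa <- sum(q * f[, m])
    ll <- ll + g[m] * log(pa) + (2 - g[m]) * log(1 - pa)
  }
  ll
}

# 1-D grid search maximizer of the K=2 likelihood (direct evaluation of
# the per-locus mixture probabilities over the whole grid).
grid_search_q1 <- function(g, f, step = 1e-3) {
  grid <- seq(0, 1, by = step)
  ok <- !is.na(g)
  pa <- outer(grid, f[1, ok]) + outer(1 - grid, f[2, ok])
  ll <- as.vector(pa %^log% g[ok])
  grid[which.max(ll)]
}

# helper operator: row-wise sum of g*log(pa) + (2-g)*log(1-pa)
`%^log%` <- function(pa, g) {
  log(pa) %*% g + log(1 - pa) %*% (2 - g)
}

# Small dataset from a dosage matrix; alleles A (counted) / C per marker.
make_dataset <- function(geno, populations = rep("POP1", nrow(geno)),
                         ids = sprintf("s%d", seq_len(nrow(geno))),
                         chromosome = "1") {
  m <- ncol(geno)
  genotype_dataset(
    geno,
    data.frame(id = ids, population = populations,
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("m%d", seq_len(m)), chromosome = chromosome,
               position = seq_len(m) * 100L,
               allele1 = "A", allele2 = "C", stringsAsFactors = FALSE)
  )
}

# The 4 x 4 missingness fixture used by the call-rate order tests:
# MISSING at (s2,m1),(s2,m2),(s4,m1),(s4,m2),(s4,m3).
call_rate_fixture <- function() {
  geno <- matrix(1L, 4, 4)
  geno[2, 1] <- NA; geno[2, 2] <- NA
  geno[4, 1] <- NA; geno[4, 2] <- NA; geno[4, 3] <- NA
  geno[1, ] <- c(2L, 0L, 1L, 2L)
  geno[3, ] <- c(0L, 2L, 1L, 0L)
  make_dataset(geno)
}

fresh_dir <- function(prefix = "fixture") {
  d <- tempfile(prefix)
  dir.create(d)
  d
}

write_fixture_ped_map <- function(dir = fresh_dir()) {
  ped <- c(
    "FAM1 A 0 0 1 -9 A A A G C C",
    "FAM2 B 0 0 2 -9 A G 0 0 C T"
  )
  map <- c("1\tm1\t0\t100", "1\tm2\t0\t200", "2\tm3\t0\t300")
  ped_path <- file.path(dir, "fixture.ped")
  map_path <- file.path(dir, "fixture.map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  list(ped = ped_path, map = map_path, dir = dir)
}
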