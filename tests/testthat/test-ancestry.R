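test_that("Laplace smoothing gives strictly interior frequencies", {
  # population fixed for the other allele: y = 0 among n = 30 copies
  d <- make_dataset(matrix(0L, 15, 1), populations = rep("P1", 15))
  panel <- build_reference_panel(d, min_individuals = 15)
  expect_equal(unname(panel$f[1, 1]), 1 / 32)

  # y = 3 counted copies among n = 10 -> f = 4/12
  d2 <- make_dataset(matrix(c(2L, 1L, 0L, 0L, 0L), 5, 1),
                     populations = rep("P1", 5))
  panel2 <- build_reference_panel(d2, min_individuals = 5)
  expect_equal(unname(panel2$f[1, 1]), 4 / 12)

  # all calls missing in a forced tiny population -> symmetric f = 1/2
  d3 <- make_dataset(matrix(NA_integer_, 2, 1), populations = rep("P1", 2))
  panel3 <- build_reference_panel(d3, min_individuals = 1)
  expect_equal(unname(panel3$f[1, 1]), 0.5)

  expect_true(all(panel$f > 0 & panel$f < 1))
})

test_that("populations below the reference size floor are excluded", {
  d <- make_dataset(matrix(1L, 20, 2),
                    populations = rep(c("BIG", "SMALL"), c(16, 4)))
  panel <- build_reference_panel(d, min_individuals = 15)
  expect_equal(panel$populations, "BIG")
  expect_equal(panel$excluded, "SMALL")
  expect_error(build_reference_panel(d, min_individuals = 50),
               "no population")
})

test_that("ancestry log-likelihood matches a hand-expanded sum", {
  panel <- structure(list(
    populations = c("P1", "P2"), marker_ids = paste0("m", 1:3),
    f = rbind(c(0.2, 0.5, 0.8), c(0.6, 0.3, 0.1))),
    class = "reference_panel")
  q <- c(0.25, 0.75)
  g <- c(2, 1, NA)
  a1 <- 0.25 * 0.2 + 0.75 * 0.6   # locus 1 counted-allele prob
  a2 <- 0.25 * 0.5 + 0.75 * 0.3
  by_hand <- 2 * log(a1) + (1 * log(a2) + 1 * log(1 - a2))
  expect_equal(ancestry_loglikelihood(g, q, panel), by_hand)

  # K = 1 collapses to the binomial log-likelihood under f
  panel1 <- structure(list(populations = "P1", marker_ids = paste0("m", 1:3),
                           f = rbind(c(0.2, 0.5, 0.8))),
                      class = "reference_panel")
  g1 <- c(2, 0, 1)
  expect_equal(ancestry_loglikelihood(g1, 1, panel1),
               sum(dbinom(g1, 2, panel1$f[1, ], log = TRUE)) -
                 sum(log(choose(2, g1))))
  # all loci missing -> empty sum
  expect_equal(ancestry_loglikelihood(rep(NA, 3), q, panel), 0)
})

test_that("supervised EM handles the degenerate cases exactly", {
  # K = 1: q = 1 immediately
  d <- make_dataset(matrix(1L, 16, 4), populations = rep("P1", 16))
  panel <- build_reference_panel(d, min_individuals = 15)
  res <- supervised_em(c(2, 1, 0, 1), panel)
  expect_equal(unname(res$q[1, ]), 1)
  expect_true(res$converged)

  # identical population frequencies: flat likelihood, first check stops at
  # the uniform point
  panel2 <- structure(list(populations = c("P1", "P2"),
                           marker_ids = paste0("m", 1:4),
                           f = rbind(c(.3, .6, .2, .8), c(.3, .6, .2, .8))),
                      class = "reference_panel")
  res2 <- supervised_em(c(2, 1, 0, 1), panel2, em_config(epsilon = 1e-8))
  expect_equal(unname(res2$q[1, ]), c(0.5, 0.5))
  expect_true(res2$converged)
  expect_equal(res2$iterations, 1L)

  # a query sharing no genotyped locus with the panel is an error
  expect_error(supervised_em(rep(NA_real_, 4), panel2), "no genotyped locus")
})

test_that("EM drives a pure-source query to its population (grid-search oracle)", {
  f <- rbind(rep(0.9, 100), rep(0.1, 100))
  panel <- structure(list(populations = c("P1", "P2"),
                          marker_ids = paste0("m", 1:100), f = f),
                     class = "reference_panel")
  g <- rep(2, 100)
  res <- supervised_em(g, panel, em_config(epsilon = 1e-6))
  expect_gte(res$q[1, "P1"], 0.99)
  q1_grid <- grid_search_q1(g, f, step = 1e-3)
  expect_equal(unname(res$q[1, "P1"]), q1_grid, tolerance = 2e-3)
})

test_that("K=2 EM at tight epsilon matches grid search on random instances", {
  set.seed(31)
  for (rep in 1:5) {
    M <- 150
    f <- rbind(runif(M, 0.05, 0.95), runif(M, 0.05, 0.95))
    q_true <- runif(1)
    g <- rbinom(M, 2, q_true * f[1, ] + (1 - q_true) * f[2, ])
    g[sample(M, 10)] <- NA
    panel <- structure(list(populations = c("P1", "P2"),
                            marker_ids = paste0("m", seq_len(M)), f = f),
                       class = "reference_panel")
    res <- supervised_em(g, panel, em_config(epsilon = 1e-8,
                                             max_iterations = 50000))
    q1_grid <- grid_search_q1(g, f, step = 1e-4)
    expect_equal(unname(res$q[1, 1]), q1_grid, tolerance = 1e-3)
  }
})

test_that("EM log-likelihood is non-decreasing and q stays on the simplex", {
  set.seed(32)
  K <- 3; M <- 60
  f <- matrix(runif(K * M, 0.05, 0.95), K, M)
  panel <- structure(list(populations = paste0("P", 1:K),
                          marker_ids = paste0("m", seq_len(M)), f = f),
                     class = "reference_panel")
  for (rep in 1:10) {
    g <- sample(c(0:2, NA), M, replace = TRUE, prob = c(.3, .3, .3, .1))
    lls <- vapply(1:20, function(k) {
      r <- supervised_em(g, panel, em_config(epsilon = 1e-12,
                                             max_iterations = k))
      expect_equal(sum(r$q), 1, tolerance = 1e-9)
      r$loglik
    }, 0)
    expect_true(all(diff(lls) >= -1e-9))
  }
})

test_that("designed ancestries are recovered on simulated admixture", {
  sim <- simulate_study(
    n_populations = 3, n_per_population = 20, n_markers = 4000, fst = 0.1,
    admixture = list(list(q = c(0.6, 0.3, 0.1), n = 8),
                     list(q = c(1, 0, 0), n = 4)),
    seed = 33)
  panel <- build_reference_panel(sim$reference, min_individuals = 15)
  g <- align_to_panel(sim$queries, panel)
  res <- supervised_em(g, panel, em_config(epsilon = 1e-4))
  err <- mean(abs(res$q - sim$truth_q))
  expect_lt(err, 0.05)

  # a looser stopping criterion cannot beat a tighter one on the same data
  res_loose <- supervised_em(g, panel, em_config(epsilon = 1))
  res_tight <- supervised_em(g, panel, em_config(epsilon = 0.01))
  expect_lte(mean(abs(res_tight$q - sim$truth_q)),
             mean(abs(res_loose$q - sim$truth_q)))
})

test_that("ancestry report tables are stable and round-trip through TSV", {
  qmat <- rbind(q1 = c(0.7, 0.3), q2 = c(0.2, 0.8))
  colnames(qmat) <- c("PA", "PB")
  res <- structure(list(q = qmat, loglik = c(-10.5, -12.25),
                        iterations = c(3L, 4L),
                        converged = c(TRUE, TRUE),
                        populations = c("PA", "PB")),
                   class = "ancestry_proportions")
  rep1 <- ancestry_report(res, truth = c("PA", "PA"))
  expect_equal(rep1$summary$top_population, c("PA", "PB"))
  expect_equal(rep1$summary$ancestry, c(0.7, 0.8))
  expect_equal(rep1$summary$correct, c(TRUE, FALSE))
  expect_equal(names(rep1$results)[2:3], c("PA", "PB"))

  dir <- fresh_dir()
  write_ancestry_report(rep1, file.path(dir, "ancestry_results.tsv"),
                        file.path(dir, "ancestry_summary.tsv"))
  back <- read.delim(file.path(dir, "ancestry_results.tsv"),
                     check.names = FALSE)
  expect_equal(as.matrix(back[, c("PA", "PB")]),
               unname(qmat), ignore_attr = TRUE, tolerance = 1e-6)
})
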