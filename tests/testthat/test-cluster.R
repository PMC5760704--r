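fit_two_cluster_sim <- function(seed, n_iter = 1500, burn_in = 500) {
  cfg <- simulation_config(purity = 1, mean_depth = 100,
                           n_clonal_mutations = 100, subclone_ccfs = 0.4,
                           subclone_mutation_counts = 100, driver_spec = NULL,
                           seed = seed)
  tum <- simulate_tumor(cfg)
  fit <- ccf_cluster(tum$mutations, tum$segments, purity = 1,
                     n_iter = n_iter, burn_in = burn_in, seed = seed)
  list(tum = tum, fit = fit)
}

test_that("a single mutation yields a single fully-occupied cluster", {
  mut <- make_mutation_table(0.5, depth = 100)
  fit <- ccf_cluster(mut, NULL, purity = 1, n_iter = 200, burn_in = 50, seed = 1)
  expect_identical(nrow(fit$clusters), 1L)
  expect_identical(fit$clusters$n, 1L)
  keep <- seq.int(fit$trace$burn_in + 1L, fit$trace$n_iter)
  occupied <- apply(fit$trace$z[keep, , drop = FALSE], 1,
                    function(z) length(unique(z)))
  expect_true(all(occupied == 1))
})

test_that("identical seed and inputs reproduce the trace exactly", {
  mut <- make_mutation_table(c(0.5, 0.48, 0.2, 0.22, 0.19), depth = 80)
  f1 <- ccf_cluster(mut, NULL, 1, n_iter = 150, burn_in = 50, seed = 42)
  f2 <- ccf_cluster(mut, NULL, 1, n_iter = 150, burn_in = 50, seed = 42)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$clusters, f2$clusters)
})

test_that("two simulated clusters at CCF 1.0 and 0.4 are recovered", {
  r <- fit_two_cluster_sim(seed = 101)
  cl <- r$fit$clusters
  big2 <- cl[order(-cl$n), ][1:2, ]
  means <- sort(big2$mean_ccf, decreasing = TRUE)
  expect_lt(abs(means[1] - 1.0), 0.05)
  expect_lt(abs(means[2] - 0.4), 0.05)
  expect_true(all(abs(big2$n - 100) <= 10))
  # >= 90% of mutations MAP-assigned to their true cluster
  truth <- r$tum$truth$mutations$clone
  hi <- big2$cluster[which.max(big2$mean_ccf)]
  lo <- big2$cluster[which.min(big2$mean_ccf)]
  asg <- r$fit$assignments$cluster
  acc <- mean((truth == "clonal" & asg == hi) |
              (truth == "subclone1" & asg == lo))
  expect_gte(acc, 0.9)
  expect_identical(r$fit$n_clusters, 2L)
})

test_that("a 50/50 posterior split is resolved to the higher-CCF cluster", {
  # constructed symmetric trace: two stable components; mutation 5 alternates
  Tn <- 40L; n <- 5L
  z <- matrix(rep(c(1L, 1L, 2L, 2L, 1L), each = Tn), Tn, n)
  z[, 5] <- rep(c(1L, 2L), Tn / 2)
  loc <- matrix(rep(c(1.0, 0.4, rep(0.7, 8)), each = Tn), Tn, 10)
  trace <- list(z = z, loc = loc, alpha = rep(1, Tn), burn_in = 0L,
                n_iter = Tn, K = 10L)
  s <- assign_clusters(trace)
  amb <- s$assignments[5, ]
  expect_equal(amb$prob, 0.5)
  hi <- s$clusters$cluster[which.max(s$clusters$mean_ccf)]
  expect_identical(amb$cluster, hi)
})

test_that("low-CCF clusters dissolve into the smallest surviving cluster", {
  cl <- make_clusters(c(1.0, 0.4, 0.05), n = c(50, 30, 7))
  asg <- make_assignments(cl)
  f <- filter_low_ccf_clusters(cl, asg, threshold = 0.10)
  expect_identical(f$clusters$mean_ccf, c(1.0, 0.4))
  expect_equal(f$clusters$n[2], 37)          # members moved to 0.4 cluster
  expect_true(all(f$assignments$cluster != 3))

  cl2 <- make_clusters(c(1.0, 0.08, 0.05), n = c(50, 4, 3))
  f2 <- filter_low_ccf_clusters(cl2, make_assignments(cl2), threshold = 0.10)
  expect_identical(f2$clusters$mean_ccf, 1.0)
  expect_equal(f2$clusters$n, 57)

  cl3 <- make_clusters(1.0)
  f3 <- filter_low_ccf_clusters(cl3, make_assignments(cl3))
  expect_identical(f3$clusters, cl3)

  # the top cluster is never dissolved even when below threshold
  cl4 <- make_clusters(c(0.08, 0.05), n = c(5, 4))
  f4 <- filter_low_ccf_clusters(cl4, make_assignments(cl4), threshold = 0.10)
  expect_identical(nrow(f4$clusters), 1L)
  expect_identical(f4$clusters$mean_ccf, 0.08)
})

test_that("cluster sizes are conserved through filtering", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    ccf <- sort(runif(k, 0.02, 1.1), decreasing = TRUE)
    ns <- sample(2:60, k, replace = TRUE)
    cl <- make_clusters(ccf, n = ns)
    asg <- make_assignments(cl)
    f <- filter_low_ccf_clusters(cl, asg)
    expect_identical(sum(f$clusters$n), sum(ns))
    expect_identical(nrow(f$assignments), sum(ns))
    expect_true(all(f$assignments$cluster %in% f$clusters$cluster))
  }
})

test_that("discrete-cluster counting applies the upward borderline rule", {
  expect_identical(count_discrete_clusters(make_clusters(1.0, n = 40)), 1L)
  cl <- make_clusters(c(1.0, 0.4), n = c(40, 30))
  expect_identical(count_discrete_clusters(cl), 2L)
  # singleton cluster: not discrete unless borderline-occupied
  cl$n[2] <- 1L
  cl$occupancy <- c(1, 0.9)
  expect_identical(count_discrete_clusters(cl), 1L)
  cl$occupancy <- c(1, 0.5)
  expect_identical(count_discrete_clusters(cl), 2L)
})

test_that("single-clone simulations mostly report exactly one cluster", {
  ks <- vapply(1:20, function(s) {
    cfg <- simulation_config(purity = 1, mean_depth = 100,
                             n_clonal_mutations = 60,
                             driver_spec = data.frame(gene = "GNAQ", clone = 0),
                             seed = s)
    tum <- simulate_tumor(cfg)
    fit <- ccf_cluster(tum$mutations, tum$segments, 1,
                       n_iter = 800, burn_in = 300, seed = s)
    top <- fit$clusters$mean_ccf[which.max(fit$clusters$n)]
    expect_lt(abs(top - 1), 0.05)     # clonal location recovered
    fit$n_clusters
  }, integer(1))
  expect_gte(mean(ks == 1L), 0.9)
})

test_that("degenerate inputs are rejected", {
  mut <- make_mutation_table(c(0.5, 0.2))
  mut$ref_count <- c(0L, 0L); mut$alt_count <- c(0L, 0L)
  expect_error(ccf_cluster(mut, NULL, 1, seed = 1), "depth|unobservable")
})
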