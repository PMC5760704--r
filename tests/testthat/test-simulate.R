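test_that("neutral tail sampling matches the 1/f^2 law", {
  expect_length(sample_neutral_tail(0, 0.05, 0.5, seed = 1), 0)
  expect_error(sample_neutral_tail(10, 0.5, 0.1), "window")
  # inverse CDF endpoints: u = 0 -> fmax, u = 1 -> fmin
  inv <- function(u, fmin, fmax) 1 / (u * (1 / fmin - 1 / fmax) + 1 / fmax)
  expect_equal(inv(0, 0.05, 0.5), 0.5)
  expect_equal(inv(1, 0.05, 0.5), 0.05)
  f <- sample_neutral_tail(50, 0.05, 0.5, seed = 3)
  expect_true(all(f >= 0.05 & f <= 0.5))

  # mean count over 1000 seeds within 3 SE of mu/beta * (1/fmin - 1/fmax) = 180
  counts <- vapply(1:1000, function(s)
    length(sample_neutral_tail(10, 0.05, 0.5, seed = s)), numeric(1))
  se <- sqrt(180 / 1000)
  expect_lt(abs(mean(counts) - 180), 3 * se)
})

test_that("empirical M(f) of a large tail matches mu/beta*(1/f - 1/fmax)", {
  mob <- 20000; fmin <- 0.05; fmax <- 0.5
  f <- sample_neutral_tail(mob, fmin, fmax, seed = 1)
  expect_gt(length(f), 1e4)
  theo <- function(x) mob * (1 / x - 1 / fmax)
  for (x in c(fmin, (fmin + fmax) / 2, 0.9 * fmax)) {
    emp <- sum(f >= x)
    expect_lt(abs(emp - theo(x)) / theo(x), 0.02)
  }
  # full-distribution shape check against the analytic CDF
  cdf <- function(x) (1 / fmin - 1 / x) / (1 / fmin - 1 / fmax)
  ks <- suppressWarnings(stats::ks.test(f, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("read simulation is binomial at Poisson depth conditioned >= 1", {
  r0 <- simulate_reads(rep(0, 200), 50, seed = 1)
  expect_true(all(r0$alt_count == 0))
  r1 <- simulate_reads(rep(1, 200), 50, seed = 1)
  expect_true(all(r1$ref_count == 0))
  rlow <- simulate_reads(rep(0.5, 500), 0.5, seed = 2)
  expect_true(all(rlow$ref_count + rlow$alt_count >= 1))
  r <- simulate_reads(rep(0.5, 2000), 100, seed = 3)
  vaf <- r$alt_count / (r$alt_count + r$ref_count)
  se <- sqrt(0.25 / 100) / sqrt(2000)
  expect_lt(abs(mean(vaf) - 0.5), 3 * se)
})

test_that("a pure diploid single-clone tumor has true VAF 0.5 everywhere", {
  cfg <- simulation_config(purity = 1, mean_depth = 80, n_clonal_mutations = 30,
                           driver_spec = data.frame(gene = "GNAQ", clone = 0),
                           seed = 5)
  tum <- simulate_tumor(cfg)
  expect_true(all(tum$truth$mutations$true_vaf == 0.5))
  expect_true(all(tum$truth$mutations$true_ccf == 1))
})

test_that("clonal BAP1 on LOH3 attains the purity-adjusted hemizygous VAF", {
  p <- 0.8
  cfg <- simulation_config(purity = p, mean_depth = 100, n_clonal_mutations = 5,
    cna_spec = data.frame(label = "LOH3", major_cn = 1, minor_cn = 0, clone = 0),
    driver_spec = data.frame(gene = c("GNAQ", "BAP1"), clone = c(0, 0)),
    seed = 6)
  tum <- simulate_tumor(cfg)
  tm <- tum$truth$mutations
  expect_equal(tm$true_vaf[tm$label == "BAP1"], p / (p * 1 + (1 - p) * 2))
  expect_equal(tm$true_vaf[tm$label == "GNAQ"], p / 2)    # diploid locus
  expect_true(all(tm$true_ccf[tm$label != ""] == 1))
  # LOH3 segment carries the clone's CCF as clonal fraction
  seg <- tum$segments
  expect_equal(seg$clonal_fraction[seg$label == "LOH3"], 1)
})

test_that("simulation is byte-reproducible and records ambiguous truth", {
  cfg <- simulation_config(purity = 0.9, mean_depth = 60, n_clonal_mutations = 20,
    subclone_ccfs = c(0.6, 0.3), subclone_mutation_counts = c(10, 10),
    neutral_mu_over_beta = 5, seed = 9)
  t1 <- simulate_tumor(cfg); t2 <- simulate_tumor(cfg)
  expect_identical(t1$mutations, t2$mutations)
  expect_identical(t1$segments, t2$segments)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tumor(t1, d1); write_tumor(t2, d2)
  for (f in c("mutations.tsv", "segments.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # each emitted mutation appears exactly once in the truth record
  expect_identical(nrow(t1$truth$mutations), nrow(t1$mutations))
  expect_false(anyDuplicated(t1$truth$mutations[c("chrom", "pos")]) > 0)
  # 0.3 fits under both the MRCA and the 0.6 subclone: both recorded
  expect_identical(t1$truth$ambiguous_parents[[2]], c(1L, 2L))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(subclone_ccfs = c(0.3, 0.6),
                                 subclone_mutation_counts = c(5, 5)),
               "descending")
  expect_error(simulation_config(subclone_ccfs = c(0.7, 0.6),
                                 subclone_mutation_counts = c(5, 5)),
               "pigeonhole")
  expect_error(simulation_config(driver_spec = data.frame(gene = "BAP1", clone = 2)),
               "nonexistent clone")
  expect_error(simulation_config(driver_spec = data.frame(gene = "NOTAGENE", clone = 0)),
               "unknown driver")
  expect_error(simulation_config(neutral_fmin = 0.4, neutral_fmax = 0.3))
})
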