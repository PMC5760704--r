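test_that("tree construction follows the pigeonhole principle", {
  # single cluster: normal -> MRCA, no subclones
  t1 <- build_clone_tree(make_clusters(1.0))
  expect_identical(nrow(t1$nodes), 1L)
  expect_identical(t1$nodes$parent, 0L)
  expect_equal(t1$nodes$ccf, 1)

  # 0.7 + 0.5 cannot be siblings -> unique chain
  t2 <- build_clone_tree(make_clusters(c(1.0, 0.7, 0.5)))
  expect_identical(t2$nodes$parent, c(0L, 1L, 2L))
  expect_length(t2$ambiguous_parents, 0)

  # 0.3 fits under both the MRCA and the 0.6 node -> ambiguous, drawn shallow
  t3 <- build_clone_tree(make_clusters(c(1.0, 0.6, 0.3)))
  expect_identical(t3$nodes$parent, c(0L, 1L, 1L))
  expect_identical(t3$ambiguous_parents[["3"]], c(1L, 2L))
})

test_that("every emitted tree satisfies the pigeonhole invariant", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(1:5, 1)
    ccf <- c(1, sort(runif(k - 1, 0.05, 0.95), decreasing = TRUE))
    tr <- build_clone_tree(make_clusters(ccf, n = sample(5:50, k, replace = TRUE)))
    for (j in seq_len(nrow(tr$nodes))) {
      kids <- which(tr$nodes$parent == j)
      expect_lte(sum(tr$nodes$ccf[kids]), tr$nodes$ccf[j] + tr$tolerance + 1e-9)
    }
  }
})

test_that("placements match exhaustive enumeration of valid topologies", {
  set.seed(33)
  for (i in 1:150) {
    k <- sample(2:4, 1)
    ccf <- c(1, sort(round(runif(k - 1, 0.05, 0.99), 3), decreasing = TRUE))
    tr <- build_clone_tree(make_clusters(ccf))
    oracle <- oracle_parent_sets(ccf, tolerance = tr$tolerance)
    for (node in seq.int(2, k)) {
      want <- oracle[[node - 1]]
      amb <- tr$ambiguous_parents[[as.character(node)]]
      got <- if (!is.null(amb)) amb else tr$nodes$parent[node]
      expect_identical(as.integer(got), as.integer(want))
      # the drawn parent is one of the enumerated valid placements
      expect_true(tr$nodes$parent[node] %in% want)
    }
  }
})

test_that("CNAs attach to the node whose CCF interval holds their fraction", {
  cl <- make_clusters(c(1.0, 0.5), n = c(60, 30))
  cna <- data.frame(label = c("LOH3", "8q+"), clonal_fraction = c(1.0, 0.5))
  tr <- build_clone_tree(cl, cna = cna)
  expect_match(tr$nodes$labels[1], "LOH3")
  expect_match(tr$nodes$labels[2], "8q\\+")
})

test_that("aberration classification reproduces the MRCA/subclone semantics", {
  # clonal Gq + LOH3, subclonal BAP1: the canonical class 2 pattern
  cl <- make_clusters(c(1.0, 0.6), n = c(80, 25))
  cna <- data.frame(label = "LOH3", clonal_fraction = 1.0)
  asg <- data.frame(mutation = 1:2, cluster = c(1L, 2L), prob = 1)
  mut <- make_mutation_table(c(0.5, 0.3))
  mut$label <- c("GNAQ", "BAP1")
  tr <- build_clone_tree(cl, cna = cna, assignments = asg, mutations = mut)
  calls <- classify_aberrations(tr, c("GNAQ", "BAP1", "LOH3", "SF3B1"))
  expect_identical(calls$status[calls$label == "GNAQ"], "MRCA")
  expect_identical(calls$status[calls$label == "LOH3"], "MRCA")
  expect_identical(calls$status[calls$label == "BAP1"], "subclone")
  expect_identical(calls$status[calls$label == "SF3B1"], "absent")

  # MRCA call requires clonal compatibility: CI containing 1 and mean >= 0.9
  cl_low <- make_clusters(c(0.8, 0.4))      # top cluster not clonal
  tr_low <- build_clone_tree(cl_low, cna = data.frame(label = "6p+",
                                                      clonal_fraction = 0.8))
  calls_low <- classify_aberrations(tr_low, "6p+")
  expect_identical(calls_low$status, "subclone")
})

test_that("classification from simulator truth reproduces the truth table", {
  cfg <- simulation_config(purity = 0.9, mean_depth = 100,
    n_clonal_mutations = 30, subclone_ccfs = 0.5, subclone_mutation_counts = 15,
    cna_spec = data.frame(label = c("LOH3", "6p+"), major_cn = c(1, 2),
                          minor_cn = c(0, 1), clone = c(0, 1)),
    driver_spec = data.frame(gene = c("GNAQ", "BAP1", "SF3B1"),
                             clone = c(0, 0, 1)),
    seed = 31)
  tum <- simulate_tumor(cfg)
  # exact clusters straight from truth, bypassing the sampler
  topo <- tum$truth$tree
  truth_mut <- tum$truth$mutations
  cl <- data.frame(cluster = seq_len(nrow(topo)), mean_ccf = topo$ccf,
                   ccf_lo = topo$ccf, ccf_hi = topo$ccf,
                   n = as.integer(table(factor(truth_mut$clone,
                                               levels = topo$clone))),
                   n_lo = 0, n_hi = 0, occupancy = 1)
  asg <- data.frame(mutation = seq_len(nrow(truth_mut)),
                    cluster = match(truth_mut$clone, topo$clone), prob = 1)
  asg <- asg[!is.na(asg$cluster), ]
  tr <- build_clone_tree(cl, cna = cna_calls(tum$segments),
                         assignments = asg, mutations = truth_mut)
  calls <- classify_aberrations(tr, c("GNAQ", "BAP1", "SF3B1", "LOH3", "6p+"))
  expect_identical(calls$status[calls$label %in% c("GNAQ", "BAP1", "LOH3")],
                   rep("MRCA", 3))
  expect_identical(calls$status[calls$label %in% c("SF3B1", "6p+")],
                   rep("subclone", 2))
})

test_that("the life-history SVG is well-formed and metrically faithful", {
  skip_if_not_installed("xml2")
  path <- withr::local_tempfile(fileext = ".svg")

  # single clone: exactly two node discs (normal + MRCA)
  t1 <- build_clone_tree(make_clusters(1.0, n = 40))
  write_life_history_svg(t1, path)
  doc <- xml2::read_xml(path)
  circles <- xml2::xml_find_all(doc, ".//*[local-name()='circle']")
  expect_length(circles, 2)

  # branch counts 100 and 50 render at 2:1 Euclidean length
  t2 <- build_clone_tree(make_clusters(c(1.0, 0.5), n = c(100, 50)))
  write_life_history_svg(t2, path)
  doc <- xml2::read_xml(path)
  lines <- xml2::xml_find_all(doc, ".//*[local-name()='line']")
  len <- function(ln) {
    a <- as.numeric(xml2::xml_attrs(ln)[c("x1", "y1", "x2", "y2")])
    sqrt((a[3] - a[1])^2 + (a[4] - a[2])^2)
  }
  counts <- as.integer(xml2::xml_attr(lines, "data-count"))
  lens <- vapply(lines, len, numeric(1))
  expect_equal(lens[counts == 100] / lens[counts == 50], 2, tolerance = 0.01)
  # disc area tracks the cell fraction: r ~ sqrt(ccf)
  discs <- xml2::xml_find_all(doc, ".//*[local-name()='circle']")
  rr <- as.numeric(xml2::xml_attr(discs, "r"))
  kinds <- xml2::xml_attr(discs, "data-kind")
  expect_equal(rr[kinds == "subclone"] / rr[kinds == "mrca"], sqrt(0.5),
               tolerance = 0.01)

  # ambiguous node: dashed alternative drawn under each extra parent
  t3 <- build_clone_tree(make_clusters(c(1.0, 0.6, 0.3)))
  write_life_history_svg(t3, path)
  doc <- xml2::read_xml(path)
  amb <- xml2::xml_find_all(doc, ".//*[@data-ambiguous='true']")
  expect_gte(length(amb), 2)    # one extra branch + one ghost disc
  txt <- xml2::xml_text(xml2::xml_find_all(doc, ".//*[local-name()='text']"))
  expect_true(any(grepl("alternative placement", txt)))
})

test_that("tree JSON serialization round-trips node structure", {
  tr <- build_clone_tree(make_clusters(c(1.0, 0.6, 0.3)))
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tr, path, seed = 7)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$nodes$parent, tr$nodes$parent)
  expect_equal(doc$ambiguous_parents[["3"]], c(1L, 2L))
  expect_equal(doc$seed, 7)
})
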