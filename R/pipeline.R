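#' Load a pipeline run configuration from YAML
#'
#' The YAML mirrors [run_sample()]'s arguments: `mutations`, `segments`,
#' `purity`, `outdir`, `seed`, and optional `neutrality` (fmin, fmax,
#' clonal_cutoff, min_mutations, r2_threshold), `clustering` (n_iter,
#' burn_in, K, low_ccf_threshold), `tolerance`, `sex`. All analysis cutoffs
#' are surfaced so they can be retuned per data set.
#'
#' @param path YAML file path.
#' @return Named list suitable for `do.call(run_sample, ...)`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("mutations", "segments")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured ", f, " file does not exist: ", cfg[[f]])
  }
  cfg
}

#' Run the full clonality and neutrality pipeline on one sample
#'
#' Orchestrates: read inputs, CCF annotation, Dirichlet-process clustering,
#' pigeonhole clone-tree construction with MRCA/subclone classification of
#' aberrations, the neutral-evolution test, and a one-row per-sample summary.
#' Outputs written to `outdir`: `ccf.tsv`, `clusters.tsv`, `assignments.tsv`,
#' `tree.json`, `tree.svg`, `neutrality.tsv`, `summary.tsv`. Every TSV header
#' records the seed; two runs with identical config and seed are
#' byte-identical.
#'
#' @param mutations Mutation table path or data frame.
#' @param segments Segment table path, data frame, or `NULL` (diploid assumed).
#' @param purity Tumor purity in (0, 1].
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @param seed Integer seed for the Gibbs sampler.
#' @param neutrality Named list of [test_neutrality()] overrides.
#' @param clustering Named list of [ccf_cluster()] overrides.
#' @param tolerance Pigeonhole tolerance for [build_clone_tree()].
#' @param sex Passed to [annotate_ccf()].
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with `ccf`, `fit`, `tree`, `aberrations`,
#'   `neutrality`, `summary`.
#' @export
run_sample <- function(mutations, segments = NULL, purity, outdir = NULL,
                       seed = 1L, neutrality = list(), clustering = list(),
                       tolerance = 0.05, sex = c("female", "male"),
                       verbose = TRUE) {
  sex <- match.arg(sex)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) say("[umclone] %-12s %.1fs", what,
                              proc.time()[["elapsed"]] - t0)
  if (is.character(mutations)) mutations <- read_mutations(mutations)
  if (is.character(segments)) segments <- read_segments(segments)
  stopifnot(purity > 0, purity <= 1)
  sample_name <- if ("sample" %in% names(mutations)) mutations$sample[1] else "sample"
  stage("read")

  ccf <- annotate_ccf(mutations, segments, purity, sex)
  stage("ccf")

  fit <- do.call(ccf_cluster, c(list(mutations = ccf, purity = purity,
                                     seed = seed), clustering))
  stage("cluster")

  cna <- if (!is.null(segments)) cna_calls(segments) else NULL
  tree <- build_clone_tree(fit$clusters, cna = cna,
                           assignments = fit$assignments, mutations = ccf,
                           tolerance = tolerance)
  all_labels <- unique(c(ccf$label[!is.na(ccf$label) & ccf$label != ""],
                         if (!is.null(cna)) cna$label))
  aberr <- classify_aberrations(tree, all_labels)
  stage("tree")

  neut <- do.call(test_neutrality, c(list(vafs = ccf$vaf), neutrality))
  stage("neutrality")

  summary_row <- data.frame(
    sample = sample_name,
    n_mutations = nrow(ccf),
    n_clusters = fit$n_clusters,
    mrca_aberrations = paste(aberr$label[aberr$status == "MRCA"], collapse = ","),
    subclonal_aberrations = paste(aberr$label[aberr$status == "subclone"],
                                  collapse = ","),
    n_window = neut$n_window,
    evaluable = neut$evaluable,
    slope_mu_over_beta = neut$slope_mu_over_beta,
    r_squared = neut$r_squared,
    neutral = neut$neutral,
    stringsAsFactors = FALSE)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_tsv_seeded(ccf, file.path(outdir, "ccf.tsv"), seed)
    write_tsv_seeded(fit$clusters, file.path(outdir, "clusters.tsv"), seed)
    write_tsv_seeded(fit$assignments, file.path(outdir, "assignments.tsv"), seed)
    write_tree_json(tree, file.path(outdir, "tree.json"), seed)
    write_life_history_svg(tree, file.path(outdir, "tree.svg"), seed)
    write_tsv_seeded(data.frame(f = neut$mf$f, M = neut$mf$M),
                     file.path(outdir, "mf.tsv"), seed)
    write_tsv_seeded(data.frame(sample = sample_name, n_window = neut$n_window,
                                slope_mu_over_beta = neut$slope_mu_over_beta,
                                r_squared = neut$r_squared,
                                evaluable = neut$evaluable,
                                neutral = neut$neutral),
                     file.path(outdir, "neutrality.tsv"), seed)
    write_tsv_seeded(summary_row, file.path(outdir, "summary.tsv"), seed)
    write_tsv_seeded(aberr, file.path(outdir, "aberrations.tsv"), seed)
    stage("write")
  }
  invisible(list(ccf = ccf, fit = fit, tree = tree, aberrations = aberr,
                 neutrality = neut, summary = summary_row))
}
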