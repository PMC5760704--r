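# Canonical loci (hg19-like coordinates) used to place driver mutations and
# arm-level copy-number aberrations on a simplified 22+X chromosome genome.
.driver_loci <- data.frame(
  gene  = c("GNAQ", "GNA11", "CYSLTR2", "PLCB4", "BAP1", "SF3B1", "EIF1AX",
            "RBM10", "SRSF2", "SF3A1", "SRSF7"),
  chrom = c("9", "19", "13", "20", "3", "2", "X", "X", "17", "22", "2"),
  pos   = c(80409488L, 3118942L, 49281206L, 9049700L, 52437514L, 198267483L,
            20142636L, 47028416L, 74732959L, 30731907L, 38975866L),
  stringsAsFactors = FALSE
)

.cna_catalog <- data.frame(
  label = c("LOH3", "6p+", "8q+"),
  chrom = c("3", "6", "8"),
  start = c(0L, 0L, 45600000L),
  end   = c(198022430L, 61000000L, 146364022L),
  stringsAsFactors = FALSE
)

.chrom_sizes <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560
)

#' Configuration for a synthetic tumor
#'
#' Defines the clonal architecture of one simulated tumor: a clonal cluster at
#' CCF 1 carrying the initiating Gq and prognostic BSE driver mutations, up to
#' a few subclonal clusters obeying the pigeonhole constraint, canonical
#' copy-number aberrations (LOH3, 6p+, 8q+) assigned to clones, and a neutral
#' subclonal mutation tail with cumulative distribution
#' \eqn{M(f) = (\mu/\beta)(1/f - 1/f_{max})}.
#'
#' @param purity Tumor purity in (0, 1].
#' @param mean_depth Mean sequencing depth (Poisson, conditioned >= 1 read).
#' @param n_clonal_mutations Passenger mutations in the clonal (CCF = 1)
#'   cluster, drivers excluded.
#' @param subclone_ccfs Numeric vector of subclone CCFs in (0, 1), sorted
#'   descending. May be empty.
#' @param subclone_mutation_counts Mutations per subclone cluster (same length
#'   as `subclone_ccfs`).
#' @param subclone_parents Integer vector of parent clone indices (0 = the
#'   MRCA clone); defaults to all subclones being children of the MRCA.
#' @param neutral_mu_over_beta Mutation rate per effective division
#'   \eqn{\mu/\beta \ge 0} of the neutral tail; 0 disables the tail.
#' @param neutral_fmin,neutral_fmax VAF window of the simulated neutral tail,
#'   0 < fmin < fmax <= 0.5 (0.5 is the diploid heterozygous ceiling).
#' @param cna_spec Data frame with columns `label`, `major_cn`, `minor_cn`,
#'   `clone` (0 = clonal). Labels in the canonical catalog (LOH3, 6p+, 8q+)
#'   get their genomic coordinates filled in; other labels need `chrom`,
#'   `start`, `end` columns.
#' @param driver_spec Data frame with columns `gene`, `clone`. Genes must be
#'   in the built-in locus table (Gq: GNAQ, GNA11, CYSLTR2, PLCB4; BSE: BAP1,
#'   SF3B1, EIF1AX; alternative spliceosome: RBM10, SRSF2, SF3A1, SRSF7).
#' @param sample Sample name written to the mutation table.
#' @param seed Integer seed; the simulation is byte-reproducible given it.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(purity = 0.9, mean_depth = 100,
                              n_clonal_mutations = 50,
                              subclone_ccfs = numeric(0),
                              subclone_mutation_counts = integer(0),
                              subclone_parents = NULL,
                              neutral_mu_over_beta = 0,
                              neutral_fmin = 0.05, neutral_fmax = 0.5,
                              cna_spec = NULL,
                              driver_spec = data.frame(gene = "GNAQ", clone = 0),
                              sample = "SIM", seed = 1L) {
  stopifnot(purity > 0, purity <= 1, mean_depth > 0, n_clonal_mutations >= 0)
  if (length(subclone_ccfs)) {
    stopifnot(all(subclone_ccfs > 0), all(subclone_ccfs < 1))
    if (any(diff(subclone_ccfs) > 0))
      stop("subclone_ccfs must be sorted descending")
    stopifnot(length(subclone_mutation_counts) == length(subclone_ccfs))
  }
  if (is.null(subclone_parents)) subclone_parents <- rep(0L, length(subclone_ccfs))
  stopifnot(length(subclone_parents) == length(subclone_ccfs))
  if (any(subclone_parents < 0 | subclone_parents >= seq_along(subclone_ccfs) + 0))
    stop("subclone parent indices must reference an earlier clone (0 = MRCA)")
  # pigeonhole validity of the configured truth
  ccf_all <- c(1, subclone_ccfs)
  for (j in seq_along(ccf_all) - 1L) {
    kids <- which(subclone_parents == j)
    if (length(kids) && sum(subclone_ccfs[kids]) > ccf_all[j + 1L] + 1e-9)
      stop("subclone CCFs violate the pigeonhole constraint under clone ", j)
    if (length(kids) && any(subclone_ccfs[kids] > ccf_all[j + 1L] + 1e-9))
      stop("child subclone CCF exceeds its parent's CCF")
  }
  if (neutral_mu_over_beta < 0) stop("neutral_mu_over_beta must be >= 0")
  stopifnot(neutral_fmin > 0, neutral_fmin < neutral_fmax, neutral_fmax <= 0.5)
  if (!is.null(cna_spec)) {
    cna_spec <- as.data.frame(cna_spec)
    stopifnot(all(c("label", "major_cn", "minor_cn", "clone") %in% names(cna_spec)))
    need <- !(cna_spec$label %in% .cna_catalog$label)
    if (any(need) && !all(c("chrom", "start", "end") %in% names(cna_spec)))
      stop("non-canonical CNA labels need chrom/start/end columns")
    if (any(cna_spec$clone > length(subclone_ccfs)))
      stop("cna_spec references a nonexistent clone")
  }
  if (!is.null(driver_spec)) {
    driver_spec <- as.data.frame(driver_spec)
    stopifnot(all(c("gene", "clone") %in% names(driver_spec)))
    if (!all(driver_spec$gene %in% .driver_loci$gene))
      stop("unknown driver gene(s): ",
           paste(setdiff(driver_spec$gene, .driver_loci$gene), collapse = ", "))
    if (any(driver_spec$clone > length(subclone_ccfs)))
      stop("driver_spec references a nonexistent clone")
  }
  structure(list(
    purity = purity, mean_depth = mean_depth,
    n_clonal_mutations = as.integer(n_clonal_mutations),
    subclone_ccfs = as.numeric(subclone_ccfs),
    subclone_mutation_counts = as.integer(subclone_mutation_counts),
    subclone_parents = as.integer(subclone_parents),
    neutral_mu_over_beta = neutral_mu_over_beta,
    neutral_fmin = neutral_fmin, neutral_fmax = neutral_fmax,
    cna_spec = cna_spec, driver_spec = driver_spec,
    sample = sample, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw true VAFs of a neutral mutation tail
#'
#' Under neutral growth the cumulative number of subclonal mutations with
#' frequency at least f is \eqn{M(f) = (\mu/\beta)(1/f - 1/f_{max})}, i.e. the
#' VAF density is proportional to \eqn{1/f^2}. The number of tail mutations is
#' Poisson with mean \eqn{(\mu/\beta)(1/f_{min} - 1/f_{max})} and each VAF is
#' drawn by inverting the CDF:
#' \eqn{f = 1 / (u (1/f_{min} - 1/f_{max}) + 1/f_{max})}, u ~ Uniform(0,1).
#'
#' @param mu_over_beta Mutation rate per effective division, >= 0.
#' @param fmin,fmax VAF window, 0 < fmin < fmax.
#' @param seed Optional integer seed.
#' @return Numeric vector of true VAFs (possibly empty).
#' @export
sample_neutral_tail <- function(mu_over_beta, fmin, fmax, seed = NULL) {
  if (fmin >= fmax || fmin <= 0) stop("invalid VAF window: need 0 < fmin < fmax")
  if (mu_over_beta < 0) stop("mu_over_beta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (mu_over_beta == 0) return(numeric(0))
  n <- stats::rpois(1, mu_over_beta * (1 / fmin - 1 / fmax))
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  1 / (u * (1 / fmin - 1 / fmax) + 1 / fmax)
}

#' Simulate read counts at a site
#'
#' Depth is Poisson(`mean_depth`) conditioned on at least one read (zero-depth
#' sites are unobservable); the alternate count is Binomial(depth, `true_vaf`).
#'
#' @param true_vaf True allele fraction(s) in \[0, 1\].
#' @param mean_depth Mean depth, > 0.
#' @param seed Optional integer seed.
#' @return Data frame with columns `ref_count`, `alt_count`.
#' @export
simulate_reads <- function(true_vaf, mean_depth, seed = NULL) {
  stopifnot(all(true_vaf >= 0), all(true_vaf <= 1), mean_depth > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_vaf)
  depth <- stats::qpois(stats::runif(n, stats::dpois(0, mean_depth), 1), mean_depth)
  alt <- stats::rbinom(n, depth, true_vaf)
  data.frame(ref_count = depth - alt, alt_count = alt)
}

.random_sites <- function(n, chroms, seed_offset = NULL) {
  ch <- sample(chroms, n, replace = TRUE)
  pos <- floor(stats::runif(n) * (.chrom_sizes[ch] - 1)) + 1
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(chrom = ch, pos = as.integer(pos), ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic tumor sample
#'
#' Emits a somatic mutation table (with binomially sampled read counts), a
#' BED-like copy-number segment table, the purity, and a ground-truth record of
#' every assignment. Driver mutations are placed at their canonical loci in
#' their configured clone; each mutation's expected VAF is computed through the
#' forward model [expected_vaf()] using the copy-number segment covering its
#' position, so e.g. a clonal BAP1 mutation on an LOH3 chromosome attains the
#' elevated VAF that the loss of the wild-type allele implies. Neutral-tail
#' mutations are placed on CNA-free chromosomes, since the tail is defined in
#' VAF space for the diploid heterozygous state.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `"um_tumor"` with elements `mutations`, `segments`,
#'   `purity`, and `truth` (per-mutation `clone`, `true_ccf`, `true_vaf`,
#'   `neutral_tail`; clone tree topology; pigeonhole-ambiguous parent sets
#'   computed from the true CCFs).
#' @export
simulate_tumor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- length(config$subclone_ccfs)
  clone_ccf <- c(1, config$subclone_ccfs)   # index i -> clone i-1

  # --- segments ---------------------------------------------------------------
  cna <- config$cna_spec
  seg <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    major_cn = integer(0), minor_cn = integer(0),
                    clonal_fraction = numeric(0), label = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(cna) && nrow(cna)) {
    for (i in seq_len(nrow(cna))) {
      hit <- match(cna$label[i], .cna_catalog$label)
      if (!is.na(hit)) {
        row <- data.frame(chrom = .cna_catalog$chrom[hit],
                          start = .cna_catalog$start[hit],
                          end = .cna_catalog$end[hit])
      } else {
        row <- data.frame(chrom = as.character(cna$chrom[i]),
                          start = cna$start[i], end = cna$end[i])
      }
      seg <- rbind(seg, cbind(row, data.frame(
        major_cn = cna$major_cn[i], minor_cn = cna$minor_cn[i],
        clonal_fraction = clone_ccf[cna$clone[i] + 1L],
        label = cna$label[i], stringsAsFactors = FALSE)))
    }
  }
  cna_chroms <- unique(seg$chrom)
  diploid <- setdiff(names(.chrom_sizes), c(cna_chroms, "X"))
  bg <- data.frame(chrom = diploid, start = 0L,
                   end = as.integer(.chrom_sizes[diploid]),
                   major_cn = 1L, minor_cn = 1L, clonal_fraction = 1,
                   label = "", stringsAsFactors = FALSE)
  # diploid filler for the uncovered remainder of CNA chromosomes
  for (ch in cna_chroms) {
    covered <- seg[seg$chrom == ch, , drop = FALSE]
    covered <- covered[order(covered$start), , drop = FALSE]
    bounds <- c(0, as.vector(t(covered[, c("start", "end")])), .chrom_sizes[[ch]])
    gaps <- matrix(bounds, ncol = 2, byrow = TRUE)
    gaps <- gaps[gaps[, 1] < gaps[, 2], , drop = FALSE]
    if (nrow(gaps))
      bg <- rbind(bg, data.frame(chrom = ch, start = gaps[, 1], end = gaps[, 2],
                                 major_cn = 1L, minor_cn = 1L,
                                 clonal_fraction = 1, label = "",
                                 stringsAsFactors = FALSE))
  }
  segments <- rbind(seg, bg)
  segments <- segments[order(match(segments$chrom, names(.chrom_sizes)),
                             segments$start), , drop = FALSE]
  rownames(segments) <- NULL

  # --- mutations --------------------------------------------------------------
  drv <- config$driver_spec
  muts <- list(); clone_of <- integer(0); labels <- character(0)
  if (!is.null(drv) && nrow(drv)) {
    loci <- .driver_loci[match(drv$gene, .driver_loci$gene), ]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(drv), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    muts[[1]] <- data.frame(chrom = loci$chrom, pos = loci$pos, ref = ref,
                            alt = unname(alt), stringsAsFactors = FALSE)
    clone_of <- c(clone_of, drv$clone)
    labels <- c(labels, drv$gene)
  }
  n_per_clone <- c(config$n_clonal_mutations, config$subclone_mutation_counts)
  for (j in seq_along(n_per_clone)) {
    nj <- n_per_clone[j]
    if (nj > 0) {
      muts[[length(muts) + 1L]] <- .random_sites(nj, setdiff(names(.chrom_sizes), "X"))
      clone_of <- c(clone_of, rep(j - 1L, nj))
      labels <- c(labels, rep("", nj))
    }
  }
  tail_vaf <- numeric(0)
  if (config$neutral_mu_over_beta > 0) {
    tail_vaf <- sample_neutral_tail(config$neutral_mu_over_beta,
                                    config$neutral_fmin, config$neutral_fmax)
    if (length(tail_vaf)) {
      muts[[length(muts) + 1L]] <- .random_sites(length(tail_vaf), diploid)
      clone_of <- c(clone_of, rep(NA_integer_, length(tail_vaf)))
      labels <- c(labels, rep("", length(tail_vaf)))
    }
  }
  mut <- do.call(rbind, muts)
  n <- nrow(mut)

  # --- true VAFs through the forward model ------------------------------------
  idx <- match_segment(mut$chrom, mut$pos, segments)
  major <- ifelse(is.na(idx), 1L, segments$major_cn[idx])
  minor <- ifelse(is.na(idx), 1L, segments$minor_cn[idx])
  cfrac <- ifelse(is.na(idx), 1, segments$clonal_fraction[idx])
  total_eff <- pmax(cfrac * (major + minor) + (1 - cfrac) * 2, 1)
  is_tail <- is.na(clone_of)
  true_ccf <- ifelse(is_tail, NA_real_, clone_ccf[clone_of + 1L])
  true_vaf <- numeric(n)
  # clustered mutations: multiplicity 1 on one retained copy
  cl <- !is_tail
  true_vaf[cl] <- expected_vaf(true_ccf[cl], config$purity, total_eff[cl], 2, 1)
  if (any(is_tail)) {
    # tail VAFs are defined for the pure diploid het state; attenuate by purity
    true_vaf[is_tail] <- tail_vaf * config$purity
    true_ccf[is_tail] <- ccf_from_vaf(true_vaf[is_tail], config$purity, 2, 2, 1)
  }
  reads <- simulate_reads(true_vaf, config$mean_depth)

  mutations <- data.frame(sample = config$sample, mut,
                          ref_count = reads$ref_count,
                          alt_count = reads$alt_count,
                          label = labels, stringsAsFactors = FALSE)
  ord <- order(match(mutations$chrom, names(.chrom_sizes)), mutations$pos)
  mutations <- mutations[ord, , drop = FALSE]
  rownames(mutations) <- NULL

  clone_names <- c("clonal", if (S) paste0("subclone", seq_len(S)))
  truth_mut <- data.frame(
    chrom = mut$chrom[ord], pos = mut$pos[ord],
    clone = ifelse(is_tail[ord], "tail", clone_names[clone_of[ord] + 1L]),
    true_ccf = true_ccf[ord], true_vaf = true_vaf[ord],
    neutral_tail = is_tail[ord], label = labels[ord],
    stringsAsFactors = FALSE)
  topo <- data.frame(clone = c("clonal", if (S) paste0("subclone", seq_len(S))),
                     ccf = clone_ccf,
                     parent = c("normal",
                                if (S) clone_names[config$subclone_parents + 1L]),
                     stringsAsFactors = FALSE)
  amb <- if (S) pigeonhole_parent_sets(clone_ccf) else list()

  structure(list(mutations = mutations, segments = segments,
                 purity = config$purity,
                 truth = list(mutations = truth_mut, tree = topo,
                              ambiguous_parents = amb,
                              seed = config$seed),
                 config = config),
            class = "um_tumor")
}

#' @export
print.um_tumor <- function(x, ...) {
  cat("Synthetic tumor sample '", x$config$sample, "'\n", sep = "")
  cat("  purity:", x$purity, " mean depth:", x$config$mean_depth, "\n")
  cat("  mutations:", nrow(x$mutations),
      "(", sum(x$truth$mutations$neutral_tail), "neutral tail )\n")
  cat("  clones:", nrow(x$truth$tree), " segments:", nrow(x$segments), "\n")
  invisible(x)
}

#' Write the three synthetic-tumor artifacts to a directory
#'
#' `mutations.tsv` and `segments.tsv` follow the pipeline input contracts;
#' `truth.json` records every ground-truth assignment. Files are
#' byte-reproducible for a fixed config.
#'
#' @param tumor A `"um_tumor"` object from [simulate_tumor()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_tumor <- function(tumor, dir) {
  stopifnot(inherits(tumor, "um_tumor"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pm <- file.path(dir, "mutations.tsv")
  ps <- file.path(dir, "segments.tsv")
  pt <- file.path(dir, "truth.json")
  write_tsv_seeded(tumor$mutations, pm, tumor$truth$seed)
  write_tsv_seeded(tumor$segments, ps, tumor$truth$seed)
  jsonlite::write_json(tumor$truth, pt, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(mutations = pm, segments = ps, truth = pt))
}
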