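#' Expected variant allele frequency for a mutation at a given cancer cell fraction
#'
#' Forward model linking the cancer cell fraction (CCF) of a mutation to the
#' allele fraction expected in reads, given tumor purity and local copy number:
#' \deqn{E[VAF] = \frac{m \rho \cdot CCF}{\rho n_t + (1-\rho) n_n}}
#' where \eqn{m} is the number of mutant copies per tumor cell, \eqn{\rho} the
#' purity, \eqn{n_t} the tumor total copy number at the locus and \eqn{n_n} the
#' normal-cell copy number (2 on autosomes).
#'
#' @param ccf Cancer cell fraction, the fraction of tumor cells carrying the
#'   mutation. Values above 1 are admitted (super-clonal states are possible in
#'   the clustering prior) and propagate linearly.
#' @param purity Tumor purity \eqn{\rho} in (0, 1].
#' @param tumor_total_cn Total tumor copy number \eqn{n_t \ge 1} at the locus
#'   (may be non-integer for subclonal segments, see [annotate_ccf()]).
#' @param normal_cn Normal-cell copy number (2 for autosomes, 1 for male X/Y).
#' @param multiplicity Mutant copies per tumor cell, integer \eqn{\ge 1}.
#' @return Expected VAF (numeric, vectorised over its arguments).
#' @seealso [ccf_from_vaf()] for the inverse, [annotate_ccf()] for table-level use.
#' @examples
#' expected_vaf(1, 1, 2, 2, 1)    # pure diploid het: 0.5
#' expected_vaf(1, 1, 1, 2, 1)    # pure LOH: 1.0
#' expected_vaf(0.5, 0.8, 2, 2, 1) # 0.2
#' @export
expected_vaf <- function(ccf, purity, tumor_total_cn = 2, normal_cn = 2,
                         multiplicity = 1L) {
  stopifnot(all(purity > 0), all(purity <= 1), all(tumor_total_cn >= 1),
            all(multiplicity >= 1))
  multiplicity * purity * ccf / (purity * tumor_total_cn + (1 - purity) * normal_cn)
}

#' Cancer cell fraction from an observed variant allele frequency
#'
#' Exact algebraic inverse of [expected_vaf()]. The result is not clipped:
#' values above 1 are reported raw so that super-clonal inconsistencies remain
#' visible downstream.
#'
#' @inheritParams expected_vaf
#' @param vaf Observed allele fraction in \[0, 1\].
#' @return CCF estimate (may exceed 1).
#' @examples
#' ccf_from_vaf(0.2, 0.8, 2, 2, 1)  # 0.5
#' ccf_from_vaf(0.6, 1.0, 2, 2, 1)  # 1.2, super-clonal
#' @export
ccf_from_vaf <- function(vaf, purity, tumor_total_cn = 2, normal_cn = 2,
                         multiplicity = 1L) {
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  stopifnot(all(purity > 0), all(purity <= 1), all(tumor_total_cn >= 1))
  vaf * (purity * tumor_total_cn + (1 - purity) * normal_cn) / (multiplicity * purity)
}

#' Estimate mutant-allele multiplicity from the observed VAF
#'
#' The number of mutant copies per tumor cell is estimated as the rounded
#' solution of the forward model at CCF = 1, clamped to \[1, major_cn\]:
#' \eqn{m = clamp(round(vaf (\rho n_t + (1-\rho) n_n) / \rho), 1, major\_cn)}.
#'
#' @inheritParams ccf_from_vaf
#' @param major_cn Major (larger) allele-specific copy number of the covering
#'   segment; the multiplicity cannot exceed it.
#' @return Integer multiplicity.
#' @examples
#' estimate_multiplicity(0.5, 1, tumor_total_cn = 2, major_cn = 1)  # 1
#' estimate_multiplicity(0.9, 1, tumor_total_cn = 2, major_cn = 2)  # 2
#' @export
estimate_multiplicity <- function(vaf, purity, tumor_total_cn = 2, normal_cn = 2,
                                  major_cn = 1L) {
  stopifnot(all(major_cn >= 1))
  m <- round(vaf * (purity * tumor_total_cn + (1 - purity) * normal_cn) / purity)
  as.integer(pmin(pmax(m, 1L), major_cn))
}

#' Normal-cell copy number for a chromosome
#'
#' 2 for autosomes; 1 for X and Y in males. Sex defaults to female so X is
#' diploid unless stated otherwise.
#'
#' @param chrom Chromosome names (with or without a "chr" prefix).
#' @param sex `"female"` or `"male"`.
#' @return Integer vector of germline copy numbers.
#' @export
normal_copy_number <- function(chrom, sex = c("female", "male")) {
  sex <- match.arg(sex)
  ch <- sub("^chr", "", as.character(chrom))
  n <- rep(2L, length(ch))
  if (sex == "male") n[ch %in% c("X", "Y")] <- 1L
  n
}

# Wilson 95% score interval on a binomial proportion; no continuity correction.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lo = pmax(0, centre - half), hi = pmin(1, centre + half))
}

match_segment <- function(chrom, pos, segments) {
  # segments use BED convention (0-based half-open); pos is 1-based
  idx <- rep(NA_integer_, length(pos))
  for (i in seq_along(pos)) {
    hit <- which(segments$chrom == chrom[i] &
                 segments$start < pos[i] & pos[i] <= segments$end)
    if (length(hit)) idx[i] <- hit[1]
  }
  idx
}

#' Annotate a mutation table with purity/copy-number-adjusted CCFs
#'
#' For each mutation: locate the covering copy-number segment, form the
#' effective tumor total copy number (for subclonal segments the
#' clonal-fraction-weighted average of the aberrant and diploid state),
#' estimate the mutant multiplicity, and convert the observed VAF and its
#' Wilson 95% CI to the CCF scale through [ccf_from_vaf()].
#'
#' Mutations with no covering segment are assumed diploid (total copy number
#' 2, multiplicity 1) and a warning is raised.
#'
#' @param mutations Data frame with at least `chrom`, `pos`, `ref_count`,
#'   `alt_count` (the mutation-table contract of [read_mutations()]).
#' @param segments Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `major_cn`, `minor_cn`, `clonal_fraction`, or `NULL` to
#'   assume a diploid genome.
#' @param purity Tumor purity in (0, 1].
#' @param sex `"female"` or `"male"`; controls the germline copy number of X/Y.
#' @return The input data frame with columns `depth`, `vaf`, `major_cn`,
#'   `minor_cn`, `total_cn` (effective), `normal_cn`, `multiplicity`, `ccf`,
#'   `ccf_lo`, `ccf_hi` appended.
#' @export
annotate_ccf <- function(mutations, segments = NULL, purity = 1,
                         sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(is.data.frame(mutations), nrow(mutations) >= 1)
  depth <- mutations$ref_count + mutations$alt_count
  if (any(depth <= 0)) stop("mutations with zero total depth are unobservable")
  vaf <- mutations$alt_count / depth
  ncn <- normal_copy_number(mutations$chrom, sex)

  major <- rep(1L, nrow(mutations)); minor <- rep(1L, nrow(mutations))
  cfrac <- rep(1, nrow(mutations))
  if (!is.null(segments) && nrow(segments)) {
    idx <- match_segment(mutations$chrom, mutations$pos, segments)
    if (anyNA(idx)) {
      warning(sum(is.na(idx)),
              " mutation(s) not covered by any segment; assuming diploid")
    }
    ok <- !is.na(idx)
    major[ok] <- segments$major_cn[idx[ok]]
    minor[ok] <- segments$minor_cn[idx[ok]]
    cfrac[ok] <- segments$clonal_fraction[idx[ok]]
  }
  # subclonal segments: clonal-fraction-weighted average total copy number
  total_eff <- cfrac * (major + minor) + (1 - cfrac) * ncn
  total_eff <- pmax(total_eff, 1)
  m <- estimate_multiplicity(vaf, purity, total_eff, ncn, pmax(major, 1L))
  ci <- wilson_ci(mutations$alt_count, depth)
  out <- mutations
  out$depth <- depth
  out$vaf <- vaf
  out$major_cn <- major
  out$minor_cn <- minor
  out$total_cn <- total_eff
  out$normal_cn <- ncn
  out$multiplicity <- m
  out$ccf <- ccf_from_vaf(vaf, purity, total_eff, ncn, m)
  out$ccf_lo <- ccf_from_vaf(ci[, "lo"], purity, total_eff, ncn, m)
  out$ccf_hi <- ccf_from_vaf(ci[, "hi"], purity, total_eff, ncn, m)
  out
}
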