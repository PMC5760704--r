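# Truncated stick-breaking DP mixture over CCF, binomial read-count emission.
# Cluster locations live on a discrete grid over (0, ccf_max]; the binomial
# log-likelihood of every mutation at every grid point is precomputed once,
# which makes both the location full-conditional and the assignment step
# table lookups.
dp_gibbs <- function(alt, depth, q, n_iter, burn_in, K = 10L,
                     ccf_max = 1.25, grid_step = 0.005,
                     alpha_shape = 1, alpha_rate = 1) {
  n <- length(alt)
  stopifnot(n >= 1, length(depth) == n, length(q) == n, n_iter > burn_in)
  if (all(depth == 0)) stop("all mutations have zero depth")
  grid <- seq(grid_step, ccf_max, by = grid_step)
  G <- length(grid)
  P <- pmin(pmax(outer(q, grid), 1e-9), 1 - 1e-9)
  L <- matrix(stats::dbinom(rep(alt, G), rep(depth, G), as.vector(P), log = TRUE),
              n, G)

  # init: spread occupied locations over the naive CCF range
  naive <- pmin(pmax((alt / pmax(depth, 1)) / pmax(q, 1e-9), grid_step), ccf_max)
  gidx <- pmax(1L, pmin(G, as.integer(round(
    stats::quantile(naive, probs = seq(0, 1, length.out = K)) / grid_step))))
  z <- max.col(L[, gidx, drop = FALSE], ties.method = "first")
  alpha <- 1

  Z <- matrix(0L, n_iter, n)
  LOC <- matrix(NA_real_, n_iter, K)
  ALPHA <- numeric(n_iter)
  eps <- 1e-12
  for (it in seq_len(n_iter)) {
    nk <- tabulate(z, K)
    # stick-breaking weights
    tailcount <- rev(cumsum(rev(nk)))           # n_{>=k}
    v <- numeric(K)
    for (k in seq_len(K - 1L)) {
      v[k] <- stats::rbeta(1, 1 + nk[k], alpha + tailcount[k + 1L])
      v[k] <- min(max(v[k], eps), 1 - eps)
    }
    v[K] <- 1
    logw <- log(v) + c(0, cumsum(log(1 - v[-K])))
    # concentration parameter, Gamma(1,1) prior
    alpha <- stats::rgamma(1, alpha_shape + K - 1,
                           alpha_rate - sum(log(1 - v[seq_len(K - 1L)])))
    # cluster locations: exact full conditional on the grid
    S <- rowsum(L, z)
    occ <- as.integer(rownames(S))
    for (k in seq_len(K)) {
      row <- match(k, occ)
      if (!is.na(row)) {
        lp <- S[row, ]
        w <- exp(lp - max(lp))
        gidx[k] <- sample.int(G, 1L, prob = w)
      } else {
        gidx[k] <- sample.int(G, 1L)            # draw from the uniform base measure
      }
    }
    # assignments: Gumbel-max categorical sampling
    logpost <- sweep(L[, gidx, drop = FALSE], 2, logw, "+")
    gum <- -log(-log(matrix(stats::runif(n * K), n, K)))
    z <- max.col(logpost + gum, ties.method = "first")

    Z[it, ] <- z
    LOC[it, ] <- grid[gidx]
    ALPHA[it] <- alpha
  }
  list(z = Z, loc = LOC, alpha = ALPHA, burn_in = burn_in, n_iter = n_iter,
       K = K, grid = grid)
}

#' Summarise a posterior trace into mutation clusters
#'
#' Label switching and transient single-member clusters make raw trace labels
#' meaningless, so clusters are identified from the posterior pairwise
#' co-assignment matrix (average-linkage clustering, cut at co-assignment
#' probability 0.5). Each resulting cluster is anchored, in every retained
#' iteration, at the raw mixture component holding the plurality of its
#' members; the cluster's CCF is the posterior mean of that anchored location
#' (2.5/97.5 percentile interval) and its mutation count carries the interval
#' of the anchored per-iteration occupancy counts. Finally every mutation is
#' assigned to its maximum-posterior-probability cluster, with ties going to
#' the higher-CCF cluster.
#'
#' @param trace A posterior trace as stored in a fitted [ccf_cluster()] object.
#' @return List with `clusters` (data frame: `cluster`, `mean_ccf`, `ccf_lo`,
#'   `ccf_hi`, `n`, `n_lo`, `n_hi`, `occupancy` — the fraction of retained
#'   iterations in which the cluster is distinct from all higher-CCF
#'   clusters) and `assignments` (data frame: `mutation`, `cluster`, `prob`).
#' @export
assign_clusters <- function(trace) {
  keep <- seq.int(trace$burn_in + 1L, trace$n_iter)
  stopifnot(length(keep) > 0)
  Tn <- length(keep)
  n <- ncol(trace$z)
  K <- trace$K
  Z <- trace$z[keep, , drop = FALSE]
  Lc <- trace$loc[keep, , drop = FALSE]

  # posterior pairwise co-assignment
  if (n == 1L) {
    part <- 1L
  } else {
    C <- matrix(0, n, n)
    I <- matrix(0, n, K)
    for (t in seq_len(Tn)) {
      I[] <- 0
      I[cbind(seq_len(n), Z[t, ])] <- 1
      C <- C + tcrossprod(I)
    }
    C <- C / Tn
    hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
    part <- stats::cutree(hc, h = 0.5)
  }
  P <- max(part)

  # per-iteration anchor: raw component holding the plurality of each part
  anchor <- function(part, P) {
    reps <- matrix(0L, Tn, P)
    for (t in seq_len(Tn)) {
      zt <- Z[t, ]
      for (j in seq_len(P))
        reps[t, j] <- which.max(tabulate(zt[part == j], K))
    }
    reps
  }
  reps <- anchor(part, P)
  # parts whose anchors coincide in most iterations sit in the same mixture
  # component and are one cluster; merge greedily until stable
  repeat {
    if (P <= 1L) break
    agree <- matrix(0, P, P)
    for (a in seq_len(P - 1L)) for (b in seq.int(a + 1L, P))
      agree[a, b] <- mean(reps[, a] == reps[, b])
    best <- arrayInd(which.max(agree), dim(agree))
    if (agree[best[1], best[2]] <= 0.5) break
    part[part == best[2]] <- best[1]
    part <- match(part, sort(unique(part)))
    P <- max(part)
    reps <- anchor(part, P)
  }
  # a lone mutation is an uncertain assignment, not a cluster: fold singleton
  # parts into the multi-member part they co-assign with most
  sizes <- tabulate(part, P)
  if (any(sizes >= 2L) && any(sizes == 1L)) {
    hosts <- which(sizes >= 2L)
    for (j in which(sizes == 1L)) {
      i <- which(part == j)
      aff <- vapply(hosts, function(h) mean(C[i, part == h]), numeric(1))
      part[i] <- hosts[which.max(aff)]
    }
    part <- match(part, sort(unique(part)))
    P <- max(part)
    reps <- anchor(part, P)
  }
  loc_j <- vapply(seq_len(P), function(j) Lc[cbind(seq_len(Tn), reps[, j])],
                  numeric(Tn))
  loc_j <- matrix(loc_j, nrow = Tn)
  # order clusters by descending CCF
  ord <- order(-colMeans(loc_j))
  reps <- reps[, ord, drop = FALSE]
  loc_j <- loc_j[, ord, drop = FALSE]
  part <- match(part, ord)

  # maximum-posterior-probability reassignment against the anchored clusters
  Pm <- vapply(seq_len(P), function(j) colMeans(Z == reps[, j]), numeric(n))
  Pm <- matrix(Pm, nrow = n)
  map <- max.col(Pm, ties.method = "first")   # ties -> higher-CCF cluster
  present <- sort(unique(map))

  cnt_j <- vapply(seq_len(P), function(j) rowSums(Z == reps[, j]), numeric(Tn))
  cnt_j <- matrix(cnt_j, nrow = Tn)
  # occupancy: distinct from every higher-CCF cluster's anchor
  occup <- vapply(seq_len(P), function(j) {
    if (j == 1) return(1)
    mean(rowSums(reps[, seq_len(j - 1L), drop = FALSE] == reps[, j]) == 0)
  }, numeric(1))

  clus <- do.call(rbind, lapply(present, function(j) {
    data.frame(cluster = j,
               mean_ccf = mean(loc_j[, j]),
               ccf_lo = stats::quantile(loc_j[, j], 0.025, names = FALSE),
               ccf_hi = stats::quantile(loc_j[, j], 0.975, names = FALSE),
               n = sum(map == j),
               n_lo = stats::quantile(cnt_j[, j], 0.025, names = FALSE),
               n_hi = stats::quantile(cnt_j[, j], 0.975, names = FALSE),
               occupancy = occup[j])
  }))
  rownames(clus) <- NULL
  assignments <- data.frame(mutation = seq_len(n), cluster = map,
                            prob = Pm[cbind(seq_len(n), map)])
  list(clusters = clus, assignments = assignments)
}

#' Dissolve low-CCF mutation clusters
#'
#' Clusters located below `threshold` on the adjusted allele-fraction (CCF)
#' scale are excluded as independent subclones, because their mutations may be
#' spread across multiple clones rather than forming one; their members are
#' reassigned to the surviving cluster with the smallest mean CCF. The
#' top (highest-CCF) cluster is never dissolved.
#'
#' @param clusters Cluster data frame as produced by [assign_clusters()].
#' @param assignments Matching assignment data frame.
#' @param threshold CCF below which a cluster is dissolved (default 0.10).
#' @return List with updated `clusters` and `assignments`.
#' @export
filter_low_ccf_clusters <- function(clusters, assignments, threshold = 0.10) {
  stopifnot(nrow(clusters) >= 1)
  top <- clusters$cluster[which.max(clusters$mean_ccf)]
  drop <- clusters$cluster[clusters$mean_ccf < threshold & clusters$cluster != top]
  if (!length(drop)) return(list(clusters = clusters, assignments = assignments))
  keep <- clusters[!(clusters$cluster %in% drop), , drop = FALSE]
  sink <- keep$cluster[which.min(keep$mean_ccf)]
  moved <- assignments$cluster %in% drop
  assignments$cluster[moved] <- sink
  n_moved <- sum(moved)
  i <- which(keep$cluster == sink)
  keep$n[i] <- keep$n[i] + n_moved
  keep$n_lo[i] <- keep$n_lo[i] + n_moved
  keep$n_hi[i] <- keep$n_hi[i] + n_moved
  rownames(keep) <- NULL
  list(clusters = keep, assignments = assignments)
}

#' Count discrete mutation clusters
#'
#' A cluster counts as discrete when it holds at least two mutations.
#' Borderline clusters — occupied in 40–60% of retained iterations — are
#' resolved upward and counted regardless, the deterministic analogue of
#' taking the higher of two reviewers' counts.
#'
#' @param clusters Filtered cluster data frame (with an `occupancy` column).
#' @return Integer number of discrete clusters.
#' @export
count_discrete_clusters <- function(clusters) {
  occ <- if ("occupancy" %in% names(clusters)) clusters$occupancy else 1
  sum(clusters$n >= 2 | (occ >= 0.4 & occ <= 0.6))
}

#' Fit a Dirichlet-process mixture to mutation CCFs
#'
#' Clusters somatic mutations by cancer cell fraction with a truncated
#' stick-breaking Dirichlet-process mixture sampled by Gibbs. The emission is
#' binomial on the alt read count with success probability
#' [expected_vaf()](cluster CCF, purity, local copy number, multiplicity); the
#' base measure on cluster CCF is Uniform(0, `ccf_max`) with `ccf_max` 1.25 so
#' that a genuinely clonal cluster is not squeezed below 1 by sampling noise;
#' the concentration parameter has a Gamma(1, 1) prior and is resampled every
#' sweep. After summarisation, clusters below `low_ccf_threshold` are
#' dissolved via [filter_low_ccf_clusters()].
#'
#' @param mutations Mutation data frame ([read_mutations()] contract); if not
#'   yet annotated it is passed through [annotate_ccf()] first.
#' @param segments Optional copy-number segment data frame.
#' @param purity Tumor purity in (0, 1].
#' @param n_iter,burn_in Total and discarded Gibbs sweeps.
#' @param K Truncation level of the stick-breaking representation.
#' @param ccf_max,grid_step Support and resolution of the location grid.
#' @param low_ccf_threshold Cluster-dissolution threshold on the CCF scale.
#' @param seed Integer seed; the trace is reproducible given it.
#' @param sex Passed to [annotate_ccf()].
#' @return An object of class `"ccf_dp"`: list with `clusters`, `assignments`
#'   (both post-filtering), `clusters_raw`, `n_clusters` (discrete-cluster
#'   count), `trace`, `data` (annotated mutations), `purity`, `seed`.
#' @examples
#' cfg <- simulation_config(purity = 1, n_clonal_mutations = 40, seed = 7)
#' tum <- simulate_tumor(cfg)
#' fit <- ccf_cluster(tum$mutations, tum$segments, tum$purity,
#'                    n_iter = 300, burn_in = 100, seed = 7)
#' fit$clusters
#' @export
ccf_cluster <- function(mutations, segments = NULL, purity = 1,
                        n_iter = 1500L, burn_in = 500L, K = 10L,
                        ccf_max = 1.25, grid_step = 0.005,
                        low_ccf_threshold = 0.10, seed = NULL,
                        sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (!all(c("multiplicity", "total_cn", "normal_cn") %in% names(mutations)))
    mutations <- annotate_ccf(mutations, segments, purity, sex)
  if (!is.null(seed)) set.seed(seed)
  q <- with(mutations, multiplicity * purity /
              (purity * total_cn + (1 - purity) * normal_cn))
  trace <- dp_gibbs(mutations$alt_count, mutations$depth, q,
                    n_iter = n_iter, burn_in = burn_in, K = K,
                    ccf_max = ccf_max, grid_step = grid_step)
  summ <- assign_clusters(trace)
  filt <- filter_low_ccf_clusters(summ$clusters, summ$assignments,
                                  low_ccf_threshold)
  structure(list(clusters = filt$clusters, assignments = filt$assignments,
                 clusters_raw = summ$clusters,
                 n_clusters = count_discrete_clusters(filt$clusters),
                 trace = trace, data = mutations, purity = purity,
                 low_ccf_threshold = low_ccf_threshold, seed = seed,
                 call = match.call()),
            class = "ccf_dp")
}

#' @export
print.ccf_dp <- function(x, ...) {
  cat("Dirichlet-process CCF clustering\n")
  cat("  mutations:", nrow(x$data), "  purity:", x$purity, "\n")
  cat("  discrete clusters:", x$n_clusters, "\n")
  print(format(x$clusters, digits = 3), ...)
  invisible(x)
}

#' @export
summary.ccf_dp <- function(object, ...) {
  keep <- seq.int(object$trace$burn_in + 1L, object$trace$n_iter)
  cat("Truncated DP mixture (K =", object$trace$K, "),",
      object$trace$n_iter, "sweeps,", object$trace$burn_in, "burn-in\n")
  cat("posterior mean concentration alpha:",
      format(mean(object$trace$alpha[keep]), digits = 3), "\n\n")
  print(format(object$clusters, digits = 3))
  invisible(object)
}

#' @export
coef.ccf_dp <- function(object, ...) {
  stats::setNames(object$clusters$mean_ccf, paste0("cluster", object$clusters$cluster))
}

#' @export
plot.ccf_dp <- function(x, breaks = 40, ...) {
  graphics::hist(x$data$ccf, breaks = breaks, col = "grey85", border = "white",
                 main = "CCF distribution and posterior clusters",
                 xlab = "cancer cell fraction", ...)
  graphics::abline(v = x$clusters$mean_ccf, col = "firebrick", lwd = 2)
  graphics::rug(x$clusters$ccf_lo, col = "firebrick")
  graphics::rug(x$clusters$ccf_hi, col = "firebrick")
  invisible(x)
}
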