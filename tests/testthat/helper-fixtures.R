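# Shared fixture builders; everything is generated in code.

# cluster table in the shape assign_clusters() returns
make_clusters <- function(ccf, n = 50, width = 0.03, occupancy = 1) {
  data.frame(cluster = seq_along(ccf), mean_ccf = ccf,
             ccf_lo = ccf - width, ccf_hi = ccf + width,
             n = rep_len(n, length(ccf)),
             n_lo = rep_len(pmax(n - 5, 0), length(ccf)),
             n_hi = rep_len(n + 5, length(ccf)),
             occupancy = rep_len(occupancy, length(ccf)))
}

make_assignments <- function(clusters) {
  data.frame(mutation = seq_len(sum(clusters$n)),
             cluster = rep(clusters$cluster, clusters$n),
             prob = 1)
}

# mutation table with exact counts at given VAFs and depth
make_mutation_table <- function(vafs, depth = 100, sample = "S1") {
  n <- length(vafs)
  alt <- round(vafs * depth)
  data.frame(sample = sample, chrom = rep("1", n), pos = seq_len(n) * 1000L,
             ref = "A", alt = "T",
             ref_count = depth - alt, alt_count = alt, label = "",
             stringsAsFactors = FALSE)
}

# independent brute-force oracle: enumerate every parent vector over clusters
# ordered by descending CCF (node 1 = MRCA) by recursive descent and keep the
# pigeonhole-valid ones; returns per-node valid parent sets
oracle_parent_sets <- function(ccf, tolerance = 0.05) {
  K <- length(ccf)
  sets <- rep(list(integer(0)), K - 1)
  par <- integer(K)
  recurse <- function(i) {
    if (i > K) {
      for (j in 2:K) sets[[j - 1]] <<- union(sets[[j - 1]], par[j])
      return(invisible())
    }
    for (p in seq_len(i - 1)) {
      par[i] <<- p
      # check partial validity: sums at node p among placed nodes
      ok <- TRUE
      for (q in seq_len(i)) {
        kids <- which(par[seq.int(2, i)] == q) + 1L
        if (length(kids) && sum(ccf[kids]) > ccf[q] + tolerance + 1e-9) ok <- FALSE
        if (length(kids) && any(ccf[kids] > ccf[q] + tolerance + 1e-9)) ok <- FALSE
      }
      if (ok) recurse(i + 1L)
    }
  }
  if (K >= 2) recurse(2L)
  lapply(sets, sort)
}
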