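# Enumerate all parent assignments for clusters ordered by descending CCF
# (node 1 = MRCA; node i may attach to any node j < i) and keep those
# satisfying the pigeonhole constraint: at every node the children's CCFs sum
# to at most the parent's CCF plus the tolerance.
enumerate_topologies <- function(ccf, tolerance = 0.05) {
  K <- length(ccf)
  if (K <= 1) return(matrix(integer(0), 1, 0))
  choices <- lapply(seq.int(2L, K), function(i) seq_len(i - 1L))
  combos <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  ok <- apply(combos, 1L, function(par) {
    for (j in seq_len(K)) {
      kids <- which(par == j) + 1L
      if (length(kids)) {
        if (sum(ccf[kids]) > ccf[j] + tolerance + 1e-9) return(FALSE)
        if (any(ccf[kids] > ccf[j] + tolerance + 1e-9)) return(FALSE)
      }
    }
    TRUE
  })
  combos[ok, , drop = FALSE]
}

# Per-cluster sets of pigeonhole-valid parents across all valid topologies.
# ccf[1] is the MRCA; returns a list indexed by node 2..K.
pigeonhole_parent_sets <- function(ccf, tolerance = 0.05) {
  K <- length(ccf)
  if (K <= 1) return(list())
  valid <- enumerate_topologies(ccf, tolerance)
  lapply(seq_len(K - 1L), function(i) sort(unique(valid[, i])))
}

#' Build a life-history clone tree by the pigeonhole principle
#'
#' The highest-CCF cluster becomes the most recent common ancestor (MRCA),
#' child of the normal-cell root, with its CCF fixed at 1 by construction
#' (every aberration it carries is in 100% of tumor cells). Remaining clusters
#' are attached, in descending CCF order, wherever the pigeonhole constraint
#' holds: at each node the CCFs of its children may not sum to more than the
#' node's own CCF plus `tolerance`. All valid topologies are enumerated; when
#' a cluster admits several parents across them, the drawn tree uses the
#' highest-CCF (shallowest) valid parent and the full set is recorded in
#' `ambiguous_parents`, mirroring the convention of mapping rare unplaceable
#' aberrations to all possible nodes. If no fully consistent topology exists,
#' clusters are attached greedily and unplaceable ones go to the MRCA with an
#' inconsistency flag.
#'
#' Copy-number aberrations are attached to the node whose cluster CCF interval
#' contains their clonal fraction (nearest mean CCF as fallback); driver
#' mutation labels follow their mutation's cluster assignment when
#' `assignments` and annotated `mutations` are supplied.
#'
#' @param clusters Cluster data frame from [ccf_cluster()] / [assign_clusters()]
#'   (columns `cluster`, `mean_ccf`, `ccf_lo`, `ccf_hi`, `n`).
#' @param cna Optional data frame of copy-number aberrations with columns
#'   `label` and `clonal_fraction` (e.g. [cna_calls()] output).
#' @param assignments,mutations Optional assignment table and mutation table
#'   (with a `label` column) used to place driver labels on branches.
#' @param tolerance Slack on pigeonhole sums (CCF units).
#' @return Object of class `"clone_tree"`: list with `nodes` (data frame:
#'   `node`, `cluster`, `ccf`, `parent`, `branch_count`, `labels`),
#'   `ambiguous_parents` (named list), `inconsistent` flag, `tolerance`.
#' @export
build_clone_tree <- function(clusters, cna = NULL, assignments = NULL,
                             mutations = NULL, tolerance = 0.05) {
  stopifnot(nrow(clusters) >= 1)
  ord <- order(-clusters$mean_ccf, -clusters$n)
  cl <- clusters[ord, , drop = FALSE]
  K <- nrow(cl)
  ccf <- cl$mean_ccf
  ccf[1] <- 1                      # MRCA is clonal by construction

  parent <- integer(K); parent[1] <- 0L   # 0 = normal root
  ambiguous <- list()
  inconsistent <- FALSE
  enumerated <- K <= 9                    # (K-1)! topologies; greedy beyond that
  if (K > 1) {
    if (enumerated) {
      valid <- enumerate_topologies(ccf, tolerance)
    } else {
      valid <- matrix(integer(0), 0, K - 1)
    }
    if (nrow(valid)) {
      # lexicographically-first valid topology: each cluster prefers the
      # highest-CCF parent, decided in attachment order
      pick <- valid
      for (i in seq_len(K - 1L)) {
        best <- min(pick[, i])
        pick <- pick[pick[, i] == best, , drop = FALSE]
        parent[i + 1L] <- best
      }
      for (i in seq_len(K - 1L)) {
        ps <- sort(unique(valid[, i]))
        if (length(ps) > 1) ambiguous[[as.character(i + 1L)]] <- ps
      }
    } else {
      # greedy fallback; unplaceable clusters hang off the MRCA
      for (i in seq.int(2L, K)) {
        placed <- FALSE
        for (j in seq_len(i - 1L)) {
          kids <- which(parent[seq_len(i - 1L)] == j)
          if (ccf[i] <= ccf[j] + tolerance + 1e-9 &&
              sum(ccf[kids]) + ccf[i] <= ccf[j] + tolerance + 1e-9) {
            parent[i] <- j; placed <- TRUE; break
          }
        }
        if (!placed) { parent[i] <- 1L; inconsistent <- TRUE }
      }
    }
  }

  labels <- rep("", K)
  if (!is.null(assignments) && !is.null(mutations) &&
      "label" %in% names(mutations)) {
    lab <- mutations$label
    has <- which(!is.na(lab) & lab != "")
    for (i in has) {
      clid <- assignments$cluster[assignments$mutation == i]
      node <- match(clid, cl$cluster)
      if (!is.na(node))
        labels[node] <- if (labels[node] == "") lab[i]
                        else paste(labels[node], lab[i], sep = ",")
    }
  }
  if (!is.null(cna) && nrow(cna)) {
    for (i in seq_len(nrow(cna))) {
      cf <- cna$clonal_fraction[i]
      inside <- which(cl$ccf_lo - 1e-9 <= cf & cf <= cl$ccf_hi + 1e-9)
      node <- if (length(inside)) {
        inside[which.min(abs(cl$mean_ccf[inside] - cf))]
      } else {
        which.min(abs(ccf - cf))
      }
      labels[node] <- if (labels[node] == "") cna$label[i]
                      else paste(labels[node], cna$label[i], sep = ",")
    }
  }

  nodes <- data.frame(node = seq_len(K), cluster = cl$cluster, ccf = ccf,
                      ccf_lo = cl$ccf_lo, ccf_hi = cl$ccf_hi,
                      mean_ccf_raw = cl$mean_ccf,
                      parent = parent, branch_count = cl$n,
                      labels = labels, stringsAsFactors = FALSE)
  # pigeonhole invariant must hold on the emitted tree (fallback excepted)
  if (!inconsistent) {
    for (j in seq_len(K)) {
      kids <- which(nodes$parent == j)
      stopifnot(sum(nodes$ccf[kids]) <= nodes$ccf[j] + tolerance + 1e-9)
    }
  }
  structure(list(nodes = nodes, ambiguous_parents = ambiguous,
                 inconsistent = inconsistent, enumerated = enumerated,
                 tolerance = tolerance),
            class = "clone_tree")
}

#' Classify aberrations as ancestral (MRCA) or subclonal
#'
#' An aberration sitting on the MRCA node is called `MRCA` — present in 100%
#' of tumor cells, hence arising before the most recent common ancestor —
#' provided the underlying cluster is compatible with clonality (its 95% CCF
#' interval contains 1 and its mean CCF is at least 0.9); on any lower node,
#' or on an MRCA whose cluster fails that check, it is `subclone`; labels not
#' found anywhere are `absent`.
#'
#' @param tree A `"clone_tree"` object.
#' @param labels Character vector of driver / CNA labels to look up.
#' @return Data frame with `label`, `status` (`MRCA`/`subclone`/`absent`),
#'   `ccf`, `ccf_lo`, `ccf_hi` of the supporting node.
#' @export
classify_aberrations <- function(tree, labels) {
  nodes <- tree$nodes
  node_labels <- strsplit(nodes$labels, ",", fixed = TRUE)
  mrca_clonal <- nodes$ccf_lo[1] - 1e-9 <= 1 && 1 <= nodes$ccf_hi[1] + 1e-9 &&
                 nodes$mean_ccf_raw[1] >= 0.9
  out <- lapply(labels, function(lb) {
    hit <- which(vapply(node_labels, function(v) lb %in% v, logical(1)))
    if (!length(hit))
      return(data.frame(label = lb, status = "absent", ccf = NA_real_,
                        ccf_lo = NA_real_, ccf_hi = NA_real_))
    h <- hit[1]
    status <- if (h == 1L && mrca_clonal) "MRCA" else "subclone"
    data.frame(label = lb, status = status, ccf = nodes$ccf[h],
               ccf_lo = nodes$ccf_lo[h], ccf_hi = nodes$ccf_hi[h])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Derive copy-number aberration calls from a segment table
#'
#' Non-diploid segments become labelled aberrations carrying their clonal
#' fraction. A `label` column is used verbatim when present (arm-level names
#' such as `LOH3`, `6p+`, `8q+` cannot be recovered from coordinates alone);
#' otherwise a generic label is derived: `LOH<chrom>` for 1+0 states,
#' `<chrom>+` for gains, `<chrom>-` for losses, `<chrom>:CN-LOH` for
#' copy-neutral LOH.
#'
#' @param segments Segment data frame.
#' @return Data frame with `label`, `clonal_fraction` (deduplicated).
#' @export
cna_calls <- function(segments) {
  tot <- segments$major_cn + segments$minor_cn
  ab <- which(!(segments$major_cn == 1 & segments$minor_cn == 1))
  if (!length(ab))
    return(data.frame(label = character(0), clonal_fraction = numeric(0)))
  lab <- if ("label" %in% names(segments)) segments$label[ab] else ""
  ch <- sub("^chr", "", segments$chrom[ab])
  generic <- ifelse(segments$minor_cn[ab] == 0 & segments$major_cn[ab] == 1,
                    paste0("LOH", ch),
             ifelse(tot[ab] > 2, paste0(ch, "+"),
             ifelse(tot[ab] < 2, paste0(ch, "-"), paste0(ch, ":CN-LOH"))))
  lab <- ifelse(is.na(lab) | lab == "", generic, lab)
  out <- data.frame(label = lab, clonal_fraction = segments$clonal_fraction[ab],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone life-history tree (normal -> MRCA -> subclones)\n")
  if (x$inconsistent) cat("  ! pigeonhole-inconsistent placement flagged\n")
  n <- x$nodes
  for (i in seq_len(nrow(n))) {
    ind <- paste(rep("  ", tree_depth(x, i)), collapse = "")
    amb <- x$ambiguous_parents[[as.character(n$node[i])]]
    cat(sprintf("%s%s (CCF %.2f, %d mutations)%s%s\n", ind,
                if (i == 1) "MRCA" else paste0("subclone ", n$node[i]),
                n$ccf[i], n$branch_count[i],
                if (n$labels[i] != "") paste0(" [", n$labels[i], "]") else "",
                if (!is.null(amb)) paste0(" {ambiguous parents: ",
                                          paste(amb, collapse = ","), "}") else ""))
  }
  invisible(x)
}

tree_depth <- function(tree, i) {
  d <- 0L
  while (tree$nodes$parent[i] != 0L) { i <- tree$nodes$parent[i]; d <- d + 1L }
  d
}

#' Serialize a clone tree to JSON
#'
#' @param tree A `"clone_tree"` object.
#' @param path Output path.
#' @param seed Optional seed to record in the document.
#' @return Invisibly, `path`.
#' @export
write_tree_json <- function(tree, path, seed = NULL) {
  doc <- list(nodes = tree$nodes,
              ambiguous_parents = tree$ambiguous_parents,
              inconsistent = tree$inconsistent,
              tolerance = tree$tolerance)
  if (!is.null(seed)) doc$seed <- seed
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
plot.clone_tree <- function(x, ...) {
  lay <- svg_layout(x)
  nd <- lay$nodes
  graphics::plot(NA, xlim = range(c(nd$x - 30, nd$x + 30)),
                 ylim = rev(range(c(nd$y - 30, nd$y + 30))),
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Clone life history", ...)
  for (i in seq_len(nrow(nd))) if (nd$parent_row[i] > 0) {
    p <- nd$parent_row[i]
    graphics::segments(nd$x[p], nd$y[p], nd$x[i], nd$y[i],
                       lwd = 1 + 6 * nd$ccf[i], col = "grey55")
  }
  graphics::symbols(nd$x, nd$y, circles = nd$r, inches = FALSE, add = TRUE,
                    bg = ifelse(nd$kind == "normal", "grey90",
                         ifelse(nd$kind == "mrca", "grey40", "steelblue")),
                    fg = "black")
  lab <- nd$label != ""
  graphics::text(nd$x[lab] + nd$r[lab] + 4, nd$y[lab], nd$label[lab], adj = 0, cex = 0.8)
  invisible(x)
}
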