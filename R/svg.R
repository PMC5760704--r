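# Geometry shared by the SVG writer and the base-graphics plot method.
# Branch Euclidean length is exactly proportional to the branch mutation
# count; node disc area is proportional to the clone's cell percentage.
svg_layout <- function(tree, len_per_mutation = NULL, min_len = 0,
                       r_max = 22, x_gap = 90) {
  nd <- tree$nodes
  K <- nrow(nd)
  counts <- pmax(nd$branch_count, 1)
  if (is.null(len_per_mutation)) {
    # deepest root-to-leaf path spans ~360 units
    depth_sum <- vapply(seq_len(K), function(i) {
      s <- counts[i]
      while (nd$parent[i] != 0L) { i <- nd$parent[i]; s <- s + counts[i] }
      s
    }, numeric(1))
    len_per_mutation <- 360 / max(depth_sum)
  }
  # leaf ordering by depth-first walk
  children <- lapply(seq_len(K), function(j) which(nd$parent == j))
  leaves_under <- function(j) {
    if (!length(children[[j]])) return(1L)
    sum(vapply(children[[j]], leaves_under, integer(1)))
  }
  nleaf <- leaves_under(1L)
  xslot <- numeric(K)
  cursor <- 0
  assign_x <- function(j) {
    if (!length(children[[j]])) {
      cursor <<- cursor + 1
      xslot[j] <<- cursor
    } else {
      for (k in children[[j]]) assign_x(k)
      xslot[j] <<- mean(xslot[children[[j]]])
    }
  }
  assign_x(1L)
  width <- max(300, (nleaf + 1) * x_gap)
  x0 <- width / 2

  # rows: 1 = normal root, then the K clone nodes
  x <- numeric(K + 1); y <- numeric(K + 1)
  x[1] <- x0; y[1] <- 50
  # place each node at exact distance len_per_mutation * count from its parent
  place <- function(j) {
    p <- nd$parent[j]
    prow <- if (p == 0L) 1L else p + 1L
    d <- min_len + len_per_mutation * counts[j]
    tx <- (xslot[j] - (nleaf + 1) / 2) * x_gap + x0
    dx <- tx - x[prow]
    if (abs(dx) >= d) dx <- sign(dx) * 0.7 * d
    dy <- sqrt(d^2 - dx^2)
    x[j + 1L] <<- x[prow] + dx
    y[j + 1L] <<- y[prow] + dy
    for (k in children[[j]]) place(k)
  }
  place(1L)
  r <- c(10, r_max * sqrt(pmin(nd$ccf, 1)))
  nodes <- data.frame(
    row = seq_len(K + 1),
    node = c(0L, nd$node),
    x = x, y = y, r = r,
    ccf = c(NA, nd$ccf),
    count = c(NA, counts),
    parent_row = c(0L, ifelse(nd$parent == 0L, 1L, nd$parent + 1L)),
    kind = c("normal", ifelse(seq_len(K) == 1, "mrca", "subclone")),
    label = c("normal", nd$labels),
    stringsAsFactors = FALSE)
  list(nodes = nodes, width = width,
       height = max(y) + 60, len_per_mutation = len_per_mutation,
       min_len = min_len)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Render a clone tree as an editable life-history SVG
#'
#' Draws the life-history plot: the normal precursor cell at the top, the MRCA
#' below it, and subclones beneath. Node disc area is proportional to the
#' percentage of tumor cells in the clone, branch Euclidean length is
#' proportional to the number of mutations on the branch (plus a constant
#' offset for legibility, recorded in the `data-min-len` attribute), and
#' branch stroke width is proportional to the cell percentage. Aberration
#' labels are printed beside their branch. Nodes with ambiguous pigeonhole
#' placement are additionally drawn dashed under each alternative parent.
#' Every branch carries `data-node` and `data-count` attributes so the file
#' is machine-checkable as well as editable.
#'
#' @param tree A `"clone_tree"` object.
#' @param path Output file path.
#' @param seed Optional seed recorded in the document description.
#' @return Invisibly, `path`.
#' @export
write_life_history_svg <- function(tree, path, seed = NULL) {
  lay <- svg_layout(tree)
  nd <- lay$nodes
  fmt <- function(v) formatC(v, format = "f", digits = 2)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d" data-min-len="%s">',
            ceiling(lay$width), ceiling(lay$height),
            ceiling(lay$width), ceiling(lay$height), fmt(lay$min_len)),
    sprintf('<desc>Clone life history%s</desc>',
            if (is.null(seed)) "" else xml_escape(paste0("; seed=", seed)))
  )
  # branches first so discs overlay them
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent_row[i]
    if (p == 0L) next
    w <- 2 + 10 * min(nd$ccf[i], 1)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#9a9a9a" stroke-width="%s" data-node="%d" data-count="%d"/>',
      fmt(nd$x[p]), fmt(nd$y[p]), fmt(nd$x[i]), fmt(nd$y[i]), fmt(w),
      nd$node[i], nd$count[i]))
    if (nd$label[i] != "" && nd$kind[i] != "normal") {
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="11" font-family="sans-serif">%s</text>',
        fmt((nd$x[p] + nd$x[i]) / 2 + 8), fmt((nd$y[p] + nd$y[i]) / 2),
        xml_escape(nd$label[i])))
    }
  }
  # ambiguous alternatives: dashed branch + dashed disc under each extra parent
  for (nm in names(tree$ambiguous_parents)) {
    node <- as.integer(nm)
    row <- which(nd$node == node)
    prim <- nd$parent_row[row]
    for (ap in tree$ambiguous_parents[[nm]]) {
      aprow <- ap + 1L
      if (aprow == prim) next
      d <- lay$min_len + lay$len_per_mutation * nd$count[row]
      ax <- nd$x[aprow] + 0.35 * d
      ay <- nd$y[aprow] + sqrt(d^2 - (0.35 * d)^2)
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#9a9a9a" stroke-width="1.5" stroke-dasharray="5,4" data-node="%d" data-count="%d" data-ambiguous="true"/>',
        fmt(nd$x[aprow]), fmt(nd$y[aprow]), fmt(ax), fmt(ay), node, nd$count[row]))
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#4878a8" stroke-dasharray="4,3" data-node="%d" data-ambiguous="true"/>',
        fmt(ax), fmt(ay), fmt(nd$r[row]), node))
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="10" font-family="sans-serif" fill="#4878a8">alternative placement</text>',
        fmt(ax + nd$r[row] + 4), fmt(ay)))
    }
  }
  fill <- c(normal = "#e0e0e0", mrca = "#5a5a5a", subclone = "#4878a8")
  for (i in seq_len(nrow(nd))) {
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="black" data-node="%d" data-kind="%s"/>',
      fmt(nd$x[i]), fmt(nd$y[i]), fmt(nd$r[i]), fill[[nd$kind[i]]],
      nd$node[i], nd$kind[i]))
  }
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-size="11" font-family="sans-serif" text-anchor="middle">normal</text>',
    fmt(nd$x[1]), fmt(nd$y[1] - nd$r[1] - 6)))
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")   # LF endings for byte reproducibility
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
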