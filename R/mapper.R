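#' Mapper cover and clustering parameters
#'
#' `resolution` is the number of base intervals per lens (the study default,
#' 29 per lens, gives a 29 x 29 product cover); `gain` multiplies each base
#' interval's width about its center, so adjacent intervals overlap by a
#' fraction `(gain - 1) / gain` of their extended width; `equalized` places
#' base boundaries at empirical quantiles so every base interval holds an
#' approximately equal share of patients; `cluster_histogram_bins` controls
#' the first-gap cut of the in-cell single-linkage dendrogram.
#'
#' @param resolution Bins per lens, >= 1. Default 29.
#' @param gain Overlap multiplier, > 1. Default 1.6.
#' @param equalized Quantile-based base intervals? Default TRUE.
#' @param cluster_histogram_bins Histogram bins for the cluster-count
#'   heuristic, >= 2. Default 10.
#' @return An object of class `mapper_config`.
#' @export
mapper_config <- function(resolution = 29, gain = 1.6, equalized = TRUE,
                          cluster_histogram_bins = 10) {
  if (resolution < 1) stop("resolution must be >= 1")
  if (!(gain > 1)) stop("gain must be > 1")
  if (cluster_histogram_bins < 2) stop("cluster_histogram_bins must be >= 2")
  structure(list(resolution = as.integer(resolution), gain = gain,
                 equalized = isTRUE(equalized),
                 cluster_histogram_bins = as.integer(cluster_histogram_bins)),
            class = "mapper_config")
}

# overlap-extended 1-D cover over one lens: base boundaries at quantiles
# (equalized) or equal width, each base interval widened by `gain` about
# its center
cover_intervals_1d <- function(x, resolution, equalized, gain) {
  if (equalized) {
    b <- stats::quantile(x, probs = seq(0, 1, length.out = resolution + 1),
                         names = FALSE, type = 7)
  } else {
    b <- seq(min(x), max(x), length.out = resolution + 1)
  }
  lo_base <- b[-(resolution + 1)]
  hi_base <- b[-1]
  ctr <- (lo_base + hi_base) / 2
  half <- (hi_base - lo_base) * gain / 2
  data.frame(lo = ctr - half, hi = ctr + half)
}

# membership of points in a 1-D interval list: closed-open, the last
# interval closed-closed so the maximum is covered
interval_members_1d <- function(x, iv) {
  res <- nrow(iv)
  lapply(seq_len(res), function(k) {
    if (k < res) {
      which(x >= iv$lo[k] & x < iv$hi[k])
    } else {
      which(x >= iv$lo[k] & x <= iv$hi[k])
    }
  })
}

#' Build the 2-D product cover over the lens space
#'
#' The cover is the cross product of two overlapping 1-D interval covers,
#' one per lens. A patient belongs to cell `(i, j)` when its lens-1 value
#' falls in extended interval `i` and its lens-2 value in extended interval
#' `j`; interval containment is closed-open except the last interval, which
#' is closed at both ends. Because `gain > 1`, every patient falls in at
#' least one interval per lens, so the cells cover the cohort.
#'
#' @param lens `n x 2` lens matrix from [mds_lenses()].
#' @param cfg A [mapper_config()].
#' @return A list of cells (empty cells included), each a list with
#'   `index = c(i, j)`, `interval_1`, `interval_2` (numeric `c(lo, hi)`),
#'   and `members` (integer patient row indices). `n = 0` gives an empty
#'   list.
#' @export
build_cover <- function(lens, cfg) {
  stopifnot(inherits(cfg, "mapper_config"))
  n <- nrow(lens)
  if (n == 0) return(list())
  if (any(!is.finite(lens))) stop("lens values must be finite")
  res <- cfg$resolution
  iv1 <- cover_intervals_1d(lens[, 1], res, cfg$equalized, cfg$gain)
  iv2 <- cover_intervals_1d(lens[, 2], res, cfg$equalized, cfg$gain)
  mem1 <- interval_members_1d(lens[, 1], iv1)
  mem2 <- interval_members_1d(lens[, 2], iv2)
  cells <- vector("list", res * res)
  idx <- 1L
  for (i in seq_len(res)) {
    for (j in seq_len(res)) {
      cells[[idx]] <- list(
        index = c(i, j),
        interval_1 = c(iv1$lo[i], iv1$hi[i]),
        interval_2 = c(iv2$lo[j], iv2$hi[j]),
        members = intersect(mem1[[i]], mem2[[j]])
      )
      idx <- idx + 1L
    }
  }
  cells
}

#' Cluster the patients of one cover cell
#'
#' Single-linkage hierarchical clustering of the cell's members under the
#' global distance matrix restricted to them, cut by the first-gap
#' heuristic: build a histogram of the dendrogram merge heights with
#' `cluster_histogram_bins` bins spanning their range; the cut is placed at
#' the lower edge of the first empty bin. No empty bin (or a singleton or
#' pair cell, or all merge heights equal) means a single cluster.
#'
#' @param members Integer patient indices of the cell.
#' @param d Full patient distance matrix.
#' @param cfg A [mapper_config()].
#' @return A list of integer vectors partitioning `members`.
#' @export
cluster_cell <- function(members, d, cfg) {
  k <- length(members)
  if (k == 0) return(list())
  if (k == 1) return(list(members))
  sub <- d[members, members, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  h <- hc$height
  rng <- range(h)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(list(sort(members)))
  }
  breaks <- seq(rng[1], rng[2], length.out = cfg$cluster_histogram_bins + 1)
  bin <- findInterval(h, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = cfg$cluster_histogram_bins)
  empty <- which(counts == 0)
  if (length(empty) == 0) return(list(sort(members)))
  cut_h <- breaks[empty[1]]
  grp <- stats::cutree(hc, h = cut_h)
  out <- split(members, grp)
  names(out) <- NULL
  lapply(out, sort)
}

#' Assemble the nerve graph of the clustered cover
#'
#' One node per in-cell cluster; an undirected edge joins two nodes exactly
#' when they share at least one patient, weighted by the number of shared
#' patients. Node ids are assigned row-major over cells then cluster index,
#' so the graph is stable for a fixed input order.
#'
#' @param cells Cover from [build_cover()].
#' @param clusters_per_cell List (parallel to `cells`) of cluster lists from
#'   [cluster_cell()].
#' @param patient_ids Character ids of all patients (indexed by the integer
#'   members).
#' @return An object of class `mapper_graph`: a list with `graph` (an
#'   igraph with vertex attributes `cell_i`, `cell_j`, `size` and edge
#'   attribute `weight`), `members` (list of integer patient indices per
#'   node) and `patient_ids`.
#' @export
build_graph <- function(cells, clusters_per_cell, patient_ids) {
  members <- list()
  cell_i <- integer()
  cell_j <- integer()
  for (c_idx in seq_along(cells)) {
    for (cl in clusters_per_cell[[c_idx]]) {
      if (length(cl) == 0) next
      members[[length(members) + 1L]] <- cl
      cell_i <- c(cell_i, cells[[c_idx]]$index[1])
      cell_j <- c(cell_j, cells[[c_idx]]$index[2])
    }
  }
  n_nodes <- length(members)
  n_pat <- length(patient_ids)
  if (n_nodes == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    # sparse node x patient incidence; crossprod counts shared patients
    inc <- Matrix::sparseMatrix(
      i = rep.int(seq_len(n_nodes), lengths(members)),
      j = unlist(members),
      x = 1,
      dims = c(n_nodes, n_pat)
    )
    ov <- Matrix::tcrossprod(inc)
    ov <- methods::as(ov, "TsparseMatrix")
    keep <- ov@i < ov@j  # upper triangle, 0-based indices
    edges <- cbind(ov@i[keep] + 1L, ov@j[keep] + 1L)
    w <- ov@x[keep]
    g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
    if (nrow(edges) > 0) {
      g <- igraph::add_edges(g, t(edges), weight = w)
    }
    igraph::V(g)$name <- as.character(seq_len(n_nodes))
    igraph::V(g)$cell_i <- cell_i
    igraph::V(g)$cell_j <- cell_j
    igraph::V(g)$size <- lengths(members)
  }
  structure(list(graph = g, members = members, patient_ids = patient_ids),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("mapper_graph: %d nodes, %d edges, %d patients covered\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(unique(unlist(x$members)))))
  invisible(x)
}

#' Build the full Mapper network from lens values and distances
#'
#' Convenience wrapper: [build_cover()] then [cluster_cell()] on every
#' non-empty cell, then [build_graph()].
#'
#' @param lens `n x 2` lens matrix.
#' @param d Patient distance matrix.
#' @param cfg A [mapper_config()].
#' @return A `mapper_graph`.
#' @export
build_mapper <- function(lens, d, cfg = mapper_config()) {
  cells <- build_cover(lens, cfg)
  clusters <- lapply(cells, function(cell) cluster_cell(cell$members, d, cfg))
  ids <- rownames(lens)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(lens)))
  build_graph(cells, clusters, ids)
}

#' Export a Mapper network
#'
#' GraphML with the node attributes already on the graph plus any extra
#' per-node attributes supplied (e.g. a mean feature value or a mortality
#' rate), or a plain CSV edge list.
#'
#' @param mg A `mapper_graph`.
#' @param path Output path.
#' @param node_attrs Optional named list of vectors (one value per node) to
#'   attach before writing.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(mg, path, node_attrs = list()) {
  g <- mg$graph
  for (nm in names(node_attrs)) {
    g <- igraph::set_vertex_attr(g, nm, value = node_attrs[[nm]])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(mg, path) {
  e <- igraph::as_edgelist(mg$graph)
  df <- data.frame(from = e[, 1], to = e[, 2],
                   weight = igraph::E(mg$graph)$weight)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-node mean of a patient-level variable
#'
#' @param mg A `mapper_graph`.
#' @param x Numeric vector indexed like the patients.
#' @return Numeric vector, one mean per node.
#' @export
node_means <- function(mg, x) {
  vapply(mg$members, function(m) mean(x[m]), numeric(1))
}
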