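# shared fixtures and independent oracles

# wrap an igraph into the mapper_graph container with singleton node members
as_mapper_graph <- function(g, members = NULL) {
  n <- igraph::vcount(g)
  if (is.null(members)) members <- as.list(seq_len(n))
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(n))
  if (igraph::ecount(g) > 0 && is.null(igraph::E(g)$weight)) {
    igraph::E(g)$weight <- 1
  }
  ids <- as.character(seq_len(max(unlist(members))))
  structure(list(graph = g, members = members, patient_ids = ids),
            class = "mapper_graph")
}

# brute-force nerve: edge iff two clusters from different node indices share
# a patient; returns a sorted edge matrix with weights
brute_force_nerve <- function(members) {
  n <- length(members)
  out <- NULL
  if (n >= 2) {
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        ov <- length(intersect(members[[u]], members[[v]]))
        if (ov > 0) out <- rbind(out, c(u, v, ov))
      }
    }
  }
  if (is.null(out)) matrix(numeric(0), ncol = 3) else out
}

# edge matrix (from, to, weight) of a mapper_graph, sorted
graph_edge_matrix <- function(mg) {
  e <- igraph::as_edgelist(mg$graph, names = FALSE)
  if (nrow(e) == 0) return(matrix(numeric(0), ncol = 3))
  e <- t(apply(e, 1, sort))
  m <- cbind(e, igraph::E(mg$graph)$weight)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# sup-distance between two empirical CDFs by direct enumeration
brute_force_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# small complete preprocessed matrix for distance/lens tests
random_feature_matrix <- function(n, p, seed) {
  set.seed(seed)
  feature_matrix(matrix(rnorm(n * p), n, p))
}

# modularity of a 2-block partition, for the brute-force Louvain check
best_two_block_modularity <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  best_memb <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    q <- igraph::modularity(g, memb)
    if (q > best) {
      best <- q
      best_memb <- memb
    }
  }
  list(modularity = best, membership = best_memb)
}
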