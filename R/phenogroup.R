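#' Drop nodes disconnected from the main network
#'
#' Patients placed only in nodes outside the largest connected component are
#' outliers and are excluded from all downstream analyses. A patient present
#' in both a kept and a removed node is *not* an outlier: membership in the
#' main network suffices.
#'
#' @param mg A `mapper_graph`.
#' @return A list with `graph` (the main-component `mapper_graph`) and
#'   `outlier_patients` (character ids). Ties in component size are broken
#'   toward the component containing the lowest node id.
#' @export
remove_outliers <- function(mg) {
  g <- mg$graph
  if (igraph::vcount(g) == 0) stop("cannot remove outliers from an empty graph")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    # tie: component holding the lowest node id
    first_node <- vapply(best, function(cid) min(which(comp$membership == cid)),
                         integer(1))
    best <- best[which.min(first_node)]
  }
  keep <- which(comp$membership == best)
  kept_pat <- unique(unlist(mg$members[keep]))
  all_pat <- unique(unlist(mg$members))
  outliers <- sort(setdiff(all_pat, kept_pat))
  sub <- igraph::induced_subgraph(g, keep)
  out <- structure(
    list(graph = sub, members = mg$members[keep],
         patient_ids = mg$patient_ids),
    class = "mapper_graph"
  )
  list(graph = out, outlier_patients = mg$patient_ids[outliers])
}

#' Louvain community autogrouping
#'
#' Modularity maximization on the weighted network (edge weight = number of
#' shared patients) by the standard multi-level Louvain iteration. The node
#' visit order is randomized, so `seed` fixes the result.
#'
#' @param mg A connected `mapper_graph`.
#' @param seed Integer seed.
#' @return Integer vector of contiguous group labels (1-based), one per
#'   node, with the achieved modularity as attribute `"modularity"`.
#' @export
louvain_autogroup <- function(mg, seed = 1L) {
  g <- mg$graph
  if (igraph::vcount(g) > 0 && igraph::components(g)$no > 1) {
    stop("louvain_autogroup expects a connected graph; remove outliers first")
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  memb <- as.integer(igraph::membership(cl))
  memb <- match(memb, sort(unique(memb)))
  attr(memb, "modularity") <- igraph::modularity(g, memb,
                                                 weights = igraph::E(g)$weight)
  memb
}

# boundary edges (exactly one endpoint inside), per group, unweighted counts
group_boundary_counts <- function(edge_ends, memb, n_groups) {
  ga <- memb[edge_ends[, 1]]
  gb <- memb[edge_ends[, 2]]
  cross <- ga != gb
  tabulate(c(ga[cross], gb[cross]), nbins = n_groups)
}

#' Merge autogroups down to k phenogroups
#'
#' Iteratively reduces the Louvain autogrouping to `k` groups by the
#' connectivity rule: at each step the group with the most outbound edges
#' relative to its size (number of nodes) is merged into the adjacent group
#' with which it shares the most edges. Edges are counted unweighted. Ties
#' are deterministic: the group to merge is the one with the smaller size,
#' then the lower label; the merge target is the one with the larger size,
#' then the lower label. Each step reduces the group count by exactly one.
#'
#' @param mg A connected `mapper_graph`.
#' @param partition Integer labels from [louvain_autogroup()].
#' @param k Target number of phenogroups, `1 <= k <=` initial group count.
#' @return A list of phenogroups, each a list with `label`, `node_set`
#'   (integer node indices) and `patient_set` (character patient ids, the
#'   union over the group's nodes). Phenogroups may overlap in patients.
#' @export
merge_to_k <- function(mg, partition, k) {
  memb <- as.integer(partition)
  n_groups <- length(unique(memb))
  if (k < 1) stop("k must be >= 1")
  if (n_groups < k) {
    stop(sprintf("partition has %d groups, fewer than k = %d", n_groups, k))
  }
  ee <- igraph::as_edgelist(mg$graph, names = FALSE)
  while (n_groups > k) {
    sizes <- tabulate(memb, nbins = n_groups)
    outbound <- group_boundary_counts(ee, memb, n_groups)
    score <- outbound / sizes
    cand <- which(score == max(score))
    if (length(cand) > 1) cand <- cand[sizes[cand] == min(sizes[cand])]
    sel <- min(cand)

    ga <- memb[ee[, 1]]
    gb <- memb[ee[, 2]]
    inv <- (ga == sel) != (gb == sel)
    other <- ifelse(ga[inv] == sel, gb[inv], ga[inv])
    if (length(other) == 0) stop("selected group has no adjacent group")
    cnt <- tabulate(other, nbins = n_groups)
    tgt <- which(cnt == max(cnt))
    if (length(tgt) > 1) tgt <- tgt[sizes[tgt] == max(sizes[tgt])]
    tgt <- min(tgt)

    memb[memb == sel] <- tgt
    memb <- match(memb, sort(unique(memb)))
    n_groups <- n_groups - 1L
  }
  lapply(seq_len(n_groups), function(lab) {
    nodes <- which(memb == lab)
    list(label = lab,
         node_set = nodes,
         patient_set = mg$patient_ids[sort(unique(unlist(mg$members[nodes])))])
  })
}

#' Patient-level phenogroup assignment
#'
#' A patient's label set contains every phenogroup owning a node the patient
#' belongs to; overlap between phenogroups is preserved, not resolved, so
#' some patients carry two (or more) labels.
#'
#' @param groups Phenogroup list from [merge_to_k()].
#' @return A named list mapping each covered patient id to its sorted
#'   integer label set.
#' @export
assign_patients <- function(groups) {
  out <- list()
  for (g in groups) {
    for (p in g$patient_set) {
      out[[p]] <- c(out[[p]], g$label)
    }
  }
  lapply(out, sort)
}

#' Resolve overlapping assignments to a single label
#'
#' For evaluation (e.g. against latent simulation labels) each multi-label
#' patient is resolved to its first (lowest) label.
#'
#' @param assignment List from [assign_patients()].
#' @return Named integer vector of single labels.
#' @export
primary_labels <- function(assignment) {
  vapply(assignment, function(l) l[[1]], integer(1))
}

#' Are all phenogroup node sets connected?
#'
#' Post-hoc check that every phenogroup induces a connected subgraph of the
#' main network.
#'
#' @param mg The main-component `mapper_graph`.
#' @param groups Phenogroup list.
#' @return Logical vector, one entry per group.
#' @export
phenogroups_connected <- function(mg, groups) {
  vapply(groups, function(g) {
    sub <- igraph::induced_subgraph(mg$graph, g$node_set)
    igraph::vcount(sub) == 0 || igraph::components(sub)$no == 1
  }, logical(1))
}

#' Export phenogroup assignments as CSV
#'
#' Columns `patient_id` and `labels` (semicolon-joined when a patient
#' belongs to more than one phenogroup).
#'
#' @param assignment List from [assign_patients()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignment, path) {
  df <- data.frame(
    patient_id = names(assignment),
    labels = vapply(assignment, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-phenogroup feature summaries and mortality
#'
#' Means of each feature and the crude death rate within every phenogroup's
#' patient set. Mortality is surfaced for inspection only; the merge rule
#' itself never reads outcome data.
#'
#' @param groups Phenogroup list.
#' @param features A `feature_matrix` (pre- or post-imputation).
#' @param survival Survival data frame with `patient_id` and `event`.
#' @return A data frame: one row per (group, feature) plus a `mortality` row
#'   per group.
#' @export
phenogroup_summary <- function(groups, features, survival) {
  rows <- list()
  for (g in groups) {
    idx <- match(g$patient_set, features$patient_ids)
    for (j in seq_len(ncol(features$values))) {
      v <- features$values[idx, j]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g$label, feature = colnames(features$values)[j],
        mean = mean(v, na.rm = TRUE), n = sum(!is.na(v))
      )
    }
    ev <- survival$event[match(g$patient_set, survival$patient_id)]
    rows[[length(rows) + 1L]] <- data.frame(
      group = g$label, feature = ".mortality",
      mean = mean(ev, na.rm = TRUE), n = sum(!is.na(ev))
    )
  }
  do.call(rbind, rows)
}
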