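test_that("outlier removal keeps the largest component only", {
  g <- igraph::make_ring(10)
  mg <- as_mapper_graph(g)
  res <- remove_outliers(mg)
  expect_equal(igraph::vcount(res$graph$graph), 10)
  expect_length(res$outlier_patients, 0)

  # 10-node component plus a 2-node appendage
  g2 <- igraph::disjoint_union(igraph::make_ring(10),
                               igraph::make_full_graph(2))
  mg2 <- as_mapper_graph(g2, members = as.list(1:12))
  res2 <- remove_outliers(mg2)
  expect_equal(igraph::vcount(res2$graph$graph), 10)
  expect_setequal(res2$outlier_patients, c("11", "12"))
})

test_that("a patient shared with the main network is not an outlier", {
  g <- igraph::disjoint_union(igraph::make_ring(4), igraph::make_ring(3))
  members <- list(1:2, 3:4, 5:6, 7:8, c(8L, 9L), 10:11, 12:13)
  mg <- as_mapper_graph(g, members)
  res <- remove_outliers(mg)
  # patient 8 appears in node 4 (kept) and node 5 (removed)
  expect_false("8" %in% res$outlier_patients)
  expect_setequal(res$outlier_patients, as.character(9:13))
})

test_that("louvain recovers two cliques joined by one edge", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  mg <- as_mapper_graph(g)
  part <- louvain_autogroup(mg, seed = 1)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[1:5])), 1)
  expect_equal(length(unique(part[6:10])), 1)
  # equals the brute-force optimum over all 2-block partitions
  oracle <- best_two_block_modularity(g)
  expect_equal(attr(part, "modularity"), oracle$modularity, tolerance = 1e-12)
  # and beats the trivial one-group partition
  expect_gt(attr(part, "modularity"),
            igraph::modularity(g, rep(1, 10)))
})

test_that("a single node forms a single group", {
  mg <- as_mapper_graph(igraph::make_empty_graph(1, directed = FALSE))
  expect_equal(unique(louvain_autogroup(mg, seed = 1)), 1L)
})

test_that("merge_to_k follows the outbound-per-size rule with tie-breaks", {
  # path a - b - c with singleton groups; b has score 2, merges into a
  g <- igraph::make_graph(~ a - b, b - c)
  mg <- as_mapper_graph(g, members = as.list(1:3))
  groups <- merge_to_k(mg, c(1L, 2L, 3L), 2)
  sets <- lapply(groups, `[[`, "node_set")
  expect_equal(sets, list(c(1L, 2L), 3L))
  # k equal to current group count is a no-op
  same <- merge_to_k(mg, c(1L, 2L, 3L), 3)
  expect_equal(lapply(same, `[[`, "node_set"), list(1L, 2L, 3L))
  # k = 1 swallows everything
  all_in <- merge_to_k(mg, c(1L, 2L, 3L), 1)
  expect_equal(all_in[[1]]$node_set, 1:3)
  expect_error(merge_to_k(mg, c(1L, 2L, 3L), 4), "fewer than k")
})

test_that("patient assignment preserves overlap", {
  g <- igraph::make_graph(~ a - b)
  mg <- as_mapper_graph(g, members = list(c(1L, 2L), c(2L, 3L)))
  groups <- merge_to_k(mg, c(1L, 2L), 2)
  asg <- assign_patients(groups)
  expect_equal(asg[["1"]], 1L)
  expect_equal(asg[["2"]], c(1L, 2L))
  expect_equal(asg[["3"]], 2L)
  expect_equal(primary_labels(asg)[["2"]], 1L)
})

test_that("phenogroup counts obey inclusion-exclusion on a synthetic run", {
  co <- generate_cohort(separated_cohort_config(400, seed = 5))
  prep <- preprocess(co$features)
  d <- normalized_correlation_distance(prep$matrix)
  mg <- build_mapper(mds_lenses(d), d, mapper_config(resolution = 4))
  ro <- remove_outliers(mg)
  part <- louvain_autogroup(ro$graph, seed = 5)
  k <- min(5, length(unique(part)))
  groups <- merge_to_k(ro$graph, part, k)
  asg <- assign_patients(groups)
  n_labels <- lengths(asg)
  if (all(n_labels <= 2)) {
    sizes <- vapply(groups, function(g) length(g$patient_set), integer(1))
    expect_equal(sum(sizes) - sum(n_labels == 2), length(asg))
  }
  # every phenogroup induces a connected subgraph
  expect_true(all(phenogroups_connected(ro$graph, groups)))
  # no patient uncovered, none from outside the main component
  expect_setequal(names(asg),
                  setdiff(ro$graph$patient_ids[unique(unlist(mg$members))],
                          ro$outlier_patients))
})

test_that("the phenogrouping chain is deterministic for a fixed seed", {
  run_once <- function() {
    co <- generate_cohort(separated_cohort_config(300, seed = 9))
    prep <- preprocess(co$features)
    d <- normalized_correlation_distance(prep$matrix)
    mg <- build_mapper(mds_lenses(d), d, mapper_config(resolution = 4))
    ro <- remove_outliers(mg)
    part <- louvain_autogroup(ro$graph, seed = 9)
    merge_to_k(ro$graph, part, min(5, length(unique(part))))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(lapply(a, `[[`, "patient_set"),
                   lapply(b, `[[`, "patient_set"))
})
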