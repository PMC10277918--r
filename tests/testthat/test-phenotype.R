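test_that("kNN graph reproduces brute-force neighbors and Jaccard symmetry", {
  cells <- blob_cells()
  g <- build_knn_graph(cells, k = 5, scale = FALSE)
  # oracle: full distance matrix kNN
  nn <- knn_brute(as.matrix(cells), 5)
  el <- igraph::as_edgelist(g)
  oracle_edges <- unique(t(apply(
    cbind(rep(1:40, 5), as.vector(nn)), 1, sort)))
  expect_setequal(paste(el[, 1], el[, 2]),
                  paste(oracle_edges[, 1], oracle_edges[, 2]))
  # no cross-blob edges between well-separated blobs
  expect_false(any((el[, 1] <= 20) != (el[, 2] <= 20)))
  # weights in (0, 1]
  w <- igraph::E(g)$weight
  expect_true(all(w > 0 & w <= 1))
})

test_that("three equidistant cells at k = 2 give a complete graph of weight 1", {
  cells <- tibble::tibble(m1 = c(0, 1, 0.5), m2 = c(0, 0, sqrt(3) / 2))
  g <- build_knn_graph(cells, k = 2, scale = FALSE)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::E(g)$weight, rep(1, 3))
  expect_error(build_knn_graph(cells, k = 3), "smaller")
})

test_that("Louvain recovers planted communities and reports true modularity", {
  # two disjoint 5-cliques
  cl5 <- t(utils::combn(5, 2))
  edges <- rbind(cl5, cl5 + 5L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  part <- louvain_communities(g, seed = 1)
  expect_equal(length(unique(part$cluster)), 2)
  expect_equal(length(unique(part$cluster[1:5])), 1)
  expect_equal(length(unique(part$cluster[6:10])), 1)
  expect_false(part$cluster[1] == part$cluster[6])
  # reported modularity equals the direct formula on the partition
  expect_equal(attr(part, "modularity"),
               modularity_enum(edges, rep(1, nrow(edges)), part$cluster),
               tolerance = 1e-12)
})

test_that("Louvain modularity is maximal over all partitions of two triangles", {
  tri <- rbind(c(1, 2), c(2, 3), c(1, 3))
  edges <- rbind(tri, tri + 3L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  part <- louvain_communities(g, seed = 1)
  q_all <- vapply(all_partitions(6), function(memb)
    modularity_enum(edges, rep(1, 6), memb), numeric(1))
  expect_equal(attr(part, "modularity"), max(q_all), tolerance = 1e-12)
})

test_that("degenerate graphs are handled", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  part <- louvain_communities(g1)
  expect_equal(part$cluster, 1L)
  expect_equal(attr(part, "modularity"), 0)
  expect_error(louvain_communities(igraph::make_empty_graph(0)), "Empty")
  # modularity never below the all-singletons partition
  cells <- blob_cells()
  g <- build_knn_graph(cells, k = 5)
  part <- louvain_communities(g, seed = 2)
  q_single <- igraph::modularity(g, seq_len(40),
                                 weights = igraph::E(g)$weight)
  expect_gte(attr(part, "modularity"), q_single)
})

test_that("clustering is deterministic and subset-safe", {
  cells <- small_cells()
  a <- cluster_cells(cells, k = 15, seed = 42)
  b <- cluster_cells(cells, k = 15, seed = 42)
  expect_identical(a$assignments, b$assignments)
  expect_equal(sum(a$sizes), nrow(cells))
  expect_true(all(diff(a$sizes) <= 0))   # ids ordered by size
  # running on a gated subset touches only subset rows
  sub <- cells[cells$patient_id %in% c("P01", "P02"), ]
  s <- cluster_cells(sub, k = 10, seed = 1)
  expect_setequal(unique(s$assignments$patient_id), c("P01", "P02"))
  expect_equal(nrow(s$assignments), nrow(sub))
})

test_that("MEM scores follow the enrichment formula", {
  # cluster median 8 vs reference 2, equal IQRs -> raw +6
  set.seed(31)
  base <- stats::runif(400)
  d <- tibble::tibble(m1 = c(base + 8, base + 2), m2 = stats::runif(800))
  cl <- rep(1:2, each = 400)
  mem <- mem_scores(d, cl, markers = c("m1", "m2"))
  expect_equal(mem$raw["1", "m1"], 6, tolerance = 0.2)
  expect_gt(mem$scores["1", "m1"], 0)
  expect_lt(mem$scores["2", "m1"], 0)
  # null case: same distribution on m2 -> |raw| small
  expect_lt(abs(mem$raw["1", "m2"]), 0.5)
  # scaled scores bounded by 10
  expect_lte(max(abs(mem$scores)), 10)
  expect_equal(max(abs(mem$scores)), 10)
  expect_error(mem_scores(d, rep(1, 800)), "2 clusters")
})

test_that("meta-clustering merges by hierarchy and conserves cells", {
  profiles <- matrix(c(0, 0, 0.1, 0.1, 5, 5, 5.1, 5.1), ncol = 2,
                     byrow = TRUE)
  mm <- meta_cluster(profiles, n_meta = 2)
  expect_equal(mm$meta_cluster[1], mm$meta_cluster[2])
  expect_equal(mm$meta_cluster[3], mm$meta_cluster[4])
  expect_false(mm$meta_cluster[1] == mm$meta_cluster[3])
  # identity at n_meta = n
  mm2 <- meta_cluster(profiles, n_meta = 4)
  expect_equal(length(unique(mm2$meta_cluster)), 4)
  expect_error(meta_cluster(profiles, n_meta = 5), "exceeds")
  # average-linkage heights match the naive O(n^2) oracle
  set.seed(32)
  X <- matrix(stats::rnorm(15), 5, 3)
  tree <- attr(meta_cluster(X, n_meta = 2), "tree")
  expect_equal(tree$height, avg_linkage_heights(X), tolerance = 1e-10)
  # cell counts conserved under the cluster -> meta map
  cells <- small_cells()
  cl <- cluster_cells(cells, k = 15, seed = 42)
  mem <- mem_scores(cells, cl)
  mm3 <- meta_cluster(mem, n_meta = min(5, length(cl$sizes)))
  assigned <- dplyr::left_join(cl$assignments, mm3, by = "cluster")
  expect_false(any(is.na(assigned$meta_cluster)))
  expect_equal(nrow(assigned), nrow(cells))
})

test_that("tumor groups recover planted composition structure", {
  set.seed(33)
  mk_patient <- function(id, p_high, n = 150) {
    is_a <- stats::runif(n) < p_high
    tibble::tibble(
      patient_id = id,
      m1 = stats::rnorm(n, ifelse(is_a, 5, 0), 0.3),
      m2 = stats::rnorm(n, ifelse(is_a, 0, 5), 0.3)
    )
  }
  cells <- dplyr::bind_rows(
    purrr::map(sprintf("A%d", 1:4), mk_patient, p_high = 0.9),
    purrr::map(sprintf("B%d", 1:4), mk_patient, p_high = 0.1)
  )
  tg <- cluster_tumors(cells, n_groups = 2, markers = c("m1", "m2"),
                       min_cells = 50)
  truth <- ifelse(startsWith(tg$groups$patient_id, "A"), 1, 2)
  expect_equal(adjusted_rand(tg$groups$group, truth), 1)
  # singleton groups at n_groups = n_patients
  tg2 <- cluster_tumors(cells, n_groups = 8, markers = c("m1", "m2"),
                        min_cells = 50)
  expect_equal(sort(tg2$groups$group), 1:8)
  # features invariant to cell-row order
  perm <- cells[sample(nrow(cells)), ]
  tg3 <- cluster_tumors(perm, n_groups = 2, markers = c("m1", "m2"),
                        min_cells = 50)
  expect_equal(dplyr::arrange(tg3$groups, patient_id),
               dplyr::arrange(tg$groups, patient_id))
  # low-count patients are excluded with a warning
  cells_uneven <- dplyr::bind_rows(cells, mk_patient("C1", 0.5, n = 40))
  expect_warning(
    tg4 <- cluster_tumors(cells_uneven, n_groups = 2,
                          markers = c("m1", "m2"), min_cells = 50),
    "excluded")
  expect_false("C1" %in% tg4$groups$patient_id)
})

test_that("abundance comparison reproduces the exact rank test", {
  pats <- sprintf("p%d", 1:6)
  fr <- tibble::tibble(
    patient_id = rep(pats, 2),
    cluster = rep(1:2, each = 6),
    fraction = c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3,
                 0.1, 0.2, 0.3, 0.9, 0.8, 0.7)
  )
  outcome <- tibble::tibble(patient_id = pats, recurrent = rep(c(0, 1), each = 3))
  ab <- compare_abundance(fr, outcome)
  row1 <- ab[ab$cluster == 1, ]
  expect_equal(row1$u, 9)
  expect_equal(row1$p_value, 0.1, tolerance = 1e-12)
  oracle <- mw_enum(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(row1$p_value, oracle$p, tolerance = 1e-12)
  # identical fractions in both groups -> p = 1 everywhere
  fr2 <- fr
  fr2$fraction <- rep(c(0.4, 0.6), each = 6)
  ab2 <- compare_abundance(fr2, outcome)
  expect_true(all(ab2$p_value == 1))
  # fractions must sum to 1 per patient
  fr3 <- fr; fr3$fraction[1] <- 0.5
  expect_error(compare_abundance(fr3, outcome), "sum to 1")
  expect_error(
    compare_abundance(fr, tibble::tibble(patient_id = pats,
                                         recurrent = c(0, 1, 1, 1, 1, 1))),
    "at least 2 patients")
})

test_that("the planted phenotype dominates the abundance screen across seeds", {
  runs <- recovery_runs(50)
  expect_gte(mean(runs$planted_is_smallest), 0.8)
  expect_true(all(runs$planted_direction_ok[runs$planted_p < 0.05]))
})
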