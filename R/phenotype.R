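#' Build a Jaccard-weighted k-nearest-neighbor graph
#'
#' The PhenoGraph construction: each cell is connected to its k nearest
#' neighbors in marker space (Euclidean, on per-marker z-scaled transformed
#' intensities by default), the edge set is symmetrized, and each edge is
#' reweighted by the Jaccard similarity of the two cells' neighborhoods
#' (neighbor sets include the cell itself, so weights lie in (0, 1]).
#'
#' @param cells Cell tibble with transformed marker columns.
#' @param markers Marker columns used for clustering (default: all).
#' @param k Number of nearest neighbors; default 30; must be < n cells.
#' @param scale Z-scale each marker before the kNN search (default `TRUE`).
#' @param weighting `"jaccard"` (default) or `"unweighted"` (all weights 1).
#' @return An [igraph] graph with `weight` edge attribute; vertex order
#'   follows the row order of `cells`.
#' @export
build_knn_graph <- function(cells, markers = marker_columns(cells), k = 30,
                            scale = TRUE, weighting = c("jaccard",
                                                        "unweighted")) {
  weighting <- match.arg(weighting)
  X <- as.matrix(cells[, markers])
  n <- nrow(X)
  if (k >= n) rlang::abort("`k` must be smaller than the number of cells.")
  if (scale) {
    sds <- apply(X, 2, stats::sd)
    X <- base::scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  # ties among equidistant neighbors are broken deterministically inside the
  # search backend; the tie notice is not actionable here
  nn <- suppressWarnings(
    BiocNeighbors::findKNN(X, k = k, get.distance = FALSE)$index)
  # neighbor sets including self
  sets <- cbind(seq_len(n), nn)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L), j = as.vector(sets),
                            x = 1, dims = c(n, n))
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  if (weighting == "jaccard") {
    inter <- Matrix::tcrossprod(A)
    iv <- inter[edges]
    w <- iv / (2 * (k + 1) - iv)
  } else {
    w <- rep(1, nrow(edges))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  g
}

#' Louvain community detection
#'
#' Partitions the graph by Louvain modularity optimization at the given
#' resolution. Cluster ids are contiguous, ordered by decreasing size.
#'
#' @param graph A weighted [igraph] graph (e.g. from [build_knn_graph()]).
#' @param resolution Louvain resolution parameter; default 1.
#' @param seed Integer seed making the partition reproducible.
#' @return A tibble with columns `node` and `cluster`, with attributes
#'   `modularity` (at the given resolution) and `sizes`.
#' @export
louvain_communities <- function(graph, resolution = 1, seed = 1L) {
  n <- igraph::vcount(graph)
  if (n == 0) rlang::abort("Empty graph.")
  if (igraph::ecount(graph) == 0) {
    memb <- seq_len(n)
    mod <- 0
  } else {
    set.seed(seed)
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
    memb <- igraph::membership(cl)
    mod <- igraph::modularity(graph, memb,
                              weights = igraph::E(graph)$weight,
                              resolution = resolution)
  }
  sizes <- table(memb)
  relabel <- match(names(sizes)[order(-as.integer(sizes),
                                      as.integer(names(sizes)))],
                   names(sizes))
  new_id <- match(as.integer(factor(memb, levels = names(sizes))),
                  relabel)
  out <- tibble::tibble(node = seq_len(n), cluster = new_id)
  attr(out, "modularity") <- mod
  attr(out, "sizes") <- as.integer(table(new_id))
  out
}

#' PhenoGraph-style clustering of cells
#'
#' Convenience wrapper: [build_knn_graph()] then [louvain_communities()],
#' plus per-cluster sizes and median marker profiles.
#'
#' @inheritParams build_knn_graph
#' @inheritParams louvain_communities
#' @return An object of class `imc_clusters`: `assignments` (the input key
#'   columns plus `cluster`), `modularity`, `sizes`, `profiles` (tibble of
#'   per-cluster median marker values), `markers`, and `params`.
#' @export
cluster_cells <- function(cells, markers = marker_columns(cells), k = 30,
                          resolution = 1, seed = 1L, scale = TRUE,
                          weighting = "jaccard") {
  g <- build_knn_graph(cells, markers, k = k, scale = scale,
                       weighting = weighting)
  part <- louvain_communities(g, resolution = resolution, seed = seed)
  keys <- intersect(c("image_id", "patient_id", "cell_id"), names(cells))
  assignments <- dplyr::bind_cols(cells[, keys],
                                  tibble::tibble(cluster = part$cluster))
  profiles <- dplyr::bind_cols(cells[, markers],
                               tibble::tibble(cluster = part$cluster)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(markers), stats::median),
                     .groups = "drop")
  structure(
    list(assignments = assignments,
         modularity = attr(part, "modularity"),
         sizes = attr(part, "sizes"),
         profiles = profiles, markers = markers,
         params = list(k = k, resolution = resolution, seed = seed,
                       scale = scale, weighting = weighting)),
    class = "imc_clusters"
  )
}

#' @export
print.imc_clusters <- function(x, ...) {
  cat(sprintf("PhenoGraph clustering: %d cells, %d clusters, modularity %.3f\n",
              nrow(x$assignments), length(x$sizes), x$modularity))
  invisible(x)
}

#' Marker enrichment modeling (MEM) scores
#'
#' For each cluster and marker, a signed enrichment of the cluster against
#' all remaining cells: `|median_pop - median_ref| + IQR_ref/IQR_pop - 1`,
#' carrying the sign of the median difference, then scaled per run so the
#' largest absolute raw score maps to 10. A zero IQR is replaced by the
#' smallest positive IQR observed in the run.
#'
#' @param cells Cell tibble with transformed marker columns.
#' @param clusters Integer cluster id per row, or an `imc_clusters` object.
#' @param markers Marker columns to score.
#' @return An object of class `imc_mem`: `scores` (cluster x marker matrix
#'   in \[-10, 10\]), `raw`, and the `med_pop`, `med_ref`, `iqr_pop`,
#'   `iqr_ref` component matrices.
#' @export
mem_scores <- function(cells, clusters, markers = marker_columns(cells)) {
  if (inherits(clusters, "imc_clusters")) {
    clusters <- clusters$assignments$cluster
  }
  stopifnot(length(clusters) == nrow(cells))
  ids <- sort(unique(clusters))
  if (length(ids) < 2L) rlang::abort("MEM needs at least 2 clusters.")
  if (min(table(clusters)) < 2L) rlang::abort("Every cluster needs >= 2 cells.")
  X <- as.matrix(cells[, markers])
  med_pop <- iqr_pop <- med_ref <- iqr_ref <-
    matrix(NA_real_, length(ids), length(markers),
           dimnames = list(ids, markers))
  for (i in seq_along(ids)) {
    inc <- clusters == ids[i]
    med_pop[i, ] <- apply(X[inc, , drop = FALSE], 2, stats::median)
    iqr_pop[i, ] <- apply(X[inc, , drop = FALSE], 2, stats::IQR)
    med_ref[i, ] <- apply(X[!inc, , drop = FALSE], 2, stats::median)
    iqr_ref[i, ] <- apply(X[!inc, , drop = FALSE], 2, stats::IQR)
  }
  iqrs <- c(iqr_pop, iqr_ref)
  if (any(iqrs == 0)) {
    floor_iqr <- min(iqrs[iqrs > 0])
    if (!is.finite(floor_iqr)) floor_iqr <- 1
    message("Zero IQR replaced by smallest positive IQR (",
            signif(floor_iqr, 3), ").")
    iqr_pop[iqr_pop == 0] <- floor_iqr
    iqr_ref[iqr_ref == 0] <- floor_iqr
  }
  diff_med <- med_pop - med_ref
  raw <- (abs(diff_med) + iqr_ref / iqr_pop - 1) * sign(diff_med)
  mx <- max(abs(raw))
  scores <- if (mx > 0) raw * (10 / mx) else raw
  structure(list(scores = scores, raw = raw, med_pop = med_pop,
                 med_ref = med_ref, iqr_pop = iqr_pop, iqr_ref = iqr_ref),
            class = "imc_mem")
}

#' @export
print.imc_mem <- function(x, ...) {
  cat(sprintf("MEM profile: %d clusters x %d markers (scores in [-10, 10])\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Merge clusters into meta clusters by hierarchical clustering
#'
#' Agglomerates cluster-level profiles (MEM scores or median marker
#' profiles) and cuts the tree at `n_meta` groups, merging clusters with
#' similar expression patterns.
#'
#' @param profiles An `imc_mem` (its scores are used), an `imc_clusters`
#'   (its median profiles are used), or a numeric matrix / tibble with one
#'   row per cluster.
#' @param n_meta Number of meta clusters; must not exceed the number of
#'   clusters.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   "average".
#' @return A tibble `cluster` -> `meta_cluster`, with the `hclust` tree as
#'   attribute `"tree"`.
#' @export
meta_cluster <- function(profiles, n_meta, linkage = "average") {
  if (inherits(profiles, "imc_mem")) {
    M <- profiles$scores
    ids <- as.integer(rownames(M))
  } else if (inherits(profiles, "imc_clusters")) {
    M <- as.matrix(profiles$profiles[, profiles$markers])
    ids <- profiles$profiles$cluster
  } else if (is.matrix(profiles)) {
    M <- profiles
    ids <- seq_len(nrow(M))
  } else {
    M <- as.matrix(dplyr::select(tibble::as_tibble(profiles),
                                 dplyr::where(is.numeric)))
    ids <- seq_len(nrow(M))
  }
  if (nrow(M) < 2L) rlang::abort("Need at least 2 cluster profiles.")
  if (n_meta > nrow(M)) rlang::abort("`n_meta` exceeds the number of clusters.")
  hc <- stats::hclust(stats::dist(M), method = linkage)
  ct <- stats::cutree(hc, k = n_meta)
  out <- tibble::tibble(cluster = ids, meta_cluster = as.integer(ct))
  attr(out, "tree") <- hc
  out
}

#' Hierarchical clustering of tumors into patient groups
#'
#' Builds one feature vector per patient — per-marker medians of single-cell
#' expression, per-meta-cluster cell fractions, or both — scales features,
#' and cuts an agglomerative tree into `n_groups`. Groups are labeled in
#' dendrogram (left-to-right) order. Patients with fewer than `min_cells`
#' cells are excluded with a warning.
#'
#' @param cells Cell tibble with `patient_id` and transformed markers.
#' @param n_groups Number of tumor groups.
#' @param markers Marker columns for the median features.
#' @param features `"marker_medians"` (default), `"meta_fractions"`, or
#'   `"both"`.
#' @param assignments Per-cell cluster/meta-cluster tibble (needs
#'   `patient_id` and `cluster` or `meta_cluster` columns); required for the
#'   fraction features.
#' @param linkage Linkage method; default "average".
#' @param min_cells Minimum cells per patient; default 100.
#' @return An object of class `imc_tumorgroups`: `groups` (tibble
#'   patient_id, group), `features` (the scaled feature matrix), `tree`.
#' @export
cluster_tumors <- function(cells, n_groups,
                           markers = marker_columns(cells),
                           features = c("marker_medians", "meta_fractions",
                                        "both"),
                           assignments = NULL, linkage = "average",
                           min_cells = 100) {
  features <- match.arg(features)
  counts <- table(cells$patient_id)
  keep <- names(counts)[counts >= min_cells]
  if (length(keep) < length(counts)) {
    rlang::warn(paste0(length(counts) - length(keep),
                       " patient(s) excluded with < ", min_cells, " cells."))
  }
  if (length(keep) < 2L) rlang::abort("Need at least 2 patients.")
  cells <- cells[cells$patient_id %in% keep, ]
  feat <- NULL
  if (features %in% c("marker_medians", "both")) {
    med <- cells |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(markers), stats::median),
                       .groups = "drop") |>
      dplyr::arrange(.data$patient_id)
    feat <- as.matrix(med[, markers])
    rownames(feat) <- med$patient_id
  }
  if (features %in% c("meta_fractions", "both")) {
    if (is.null(assignments)) {
      rlang::abort("`assignments` is required for fraction features.")
    }
    cl_col <- if ("meta_cluster" %in% names(assignments)) "meta_cluster"
              else "cluster"
    fr <- assignments |>
      dplyr::filter(.data$patient_id %in% keep) |>
      dplyr::count(.data$patient_id, .data[[cl_col]]) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      tidyr::pivot_wider(id_cols = "patient_id",
                         names_from = dplyr::all_of(cl_col),
                         values_from = "fraction", values_fill = 0,
                         names_prefix = "mc") |>
      dplyr::arrange(.data$patient_id)
    frm <- as.matrix(fr[, -1])
    rownames(frm) <- fr$patient_id
    feat <- if (is.null(feat)) frm else cbind(feat, frm[rownames(feat), ])
  }
  sds <- apply(feat, 2, stats::sd)
  featz <- base::scale(feat, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  hc <- stats::hclust(stats::dist(featz), method = linkage)
  ct <- stats::cutree(hc, k = n_groups)
  # relabel groups in dendrogram (left-to-right) order
  ord <- unique(ct[hc$order])
  grp <- match(ct, ord)
  structure(
    list(groups = tibble::tibble(patient_id = rownames(feat),
                                 group = grp),
         features = featz, tree = hc, n_groups = n_groups),
    class = "imc_tumorgroups"
  )
}

#' @export
print.imc_tumorgroups <- function(x, ...) {
  cat(sprintf("Tumor groups: %d patients in %d groups (%s)\n",
              nrow(x$groups), x$n_groups,
              paste(table(x$groups$group), collapse = "/")))
  invisible(x)
}

#' Per-patient cluster fractions
#'
#' Each patient's cells are tallied per cluster and normalized so fractions
#' sum to 1 over the clusters present in the table; patients without cells
#' in a cluster get an explicit 0.
#'
#' @param assignments Tibble with `patient_id` and a cluster column.
#' @param cluster_col Name of the cluster column (default `"cluster"`).
#' @return A tibble `patient_id`, `cluster`, `fraction` covering the full
#'   patient x cluster grid.
#' @export
cluster_fractions <- function(assignments, cluster_col = "cluster") {
  assignments |>
    dplyr::count(.data$patient_id, cluster = .data[[cluster_col]]) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(.data$patient_id, .data$cluster,
                    fill = list(n = 0L, fraction = 0)) |>
    dplyr::select("patient_id", "cluster", "fraction")
}

#' Differential cluster abundance between outcome groups
#'
#' For each cluster, a two-sided Mann-Whitney U test compares per-patient
#' fractions between non-recurrent and recurrent patients. Raw p-values are
#' reported (the convention for these per-cluster screens); a
#' Benjamini-Hochberg column can be added with `adjust = TRUE`.
#'
#' @param fractions Tibble `patient_id`, `cluster`, `fraction` (see
#'   [cluster_fractions()]); per-patient fractions must sum to 1.
#' @param outcome Tibble with `patient_id` and `recurrent` (0/1).
#' @param adjust Add a BH-adjusted `p_adjusted` column; default `FALSE`.
#' @param alpha Significance level for the `significant` flag; default 0.05.
#' @return An `imc_abundance` tibble: `cluster`, `median_nonrecurrent`,
#'   `median_recurrent`, `u`, `p_value`, `significant` (and `p_adjusted`).
#' @export
compare_abundance <- function(fractions, outcome, adjust = FALSE,
                              alpha = 0.05) {
  sums <- fractions |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-6)) {
    rlang::abort("Per-patient fractions must sum to 1 over clusters.")
  }
  d <- dplyr::inner_join(fractions, outcome[, c("patient_id", "recurrent")],
                         by = "patient_id")
  n_per <- d |> dplyr::distinct(.data$patient_id, .data$recurrent) |>
    dplyr::count(.data$recurrent)
  if (nrow(n_per) < 2L || any(n_per$n < 2L)) {
    rlang::abort("Each outcome group needs at least 2 patients.")
  }
  out <- d |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(g, key) {
      x <- g$fraction[g$recurrent == 0]
      y <- g$fraction[g$recurrent == 1]
      mw <- mann_whitney_u(x, y)
      tibble::tibble(median_nonrecurrent = stats::median(x),
                     median_recurrent = stats::median(y),
                     u = mw$u, p_value = mw$p_value)
    }) |>
    dplyr::ungroup()
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- (if (adjust) out$p_adjusted else out$p_value) < alpha
  class(out) <- c("imc_abundance", class(out))
  attr(out, "alpha") <- alpha
  out
}
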