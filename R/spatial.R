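#' Mask-contact neighbor graph of an image
#'
#' Two cells are neighbors when dilating one cell's pixel set by
#' `expansion_px` reaches the other — equivalently, when the minimum
#' Euclidean distance between their pixel centers is at most `expansion_px`.
#' Only boundary pixels are searched (the minimum inter-cell pixel distance
#' is always attained at boundaries), using a fixed-radius neighbor search.
#'
#' @param mask Integer label matrix (0 = background).
#' @param expansion_px Dilation radius in pixels; default 4; must be >= 1.
#' @return A tibble of unordered neighbor pairs `cell_a < cell_b`.
#' @export
build_neighbor_graph <- function(mask, expansion_px = 4) {
  if (expansion_px < 1) rlang::abort("`expansion_px` must be >= 1.")
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask > 0)) {
    return(tibble::tibble(cell_a = integer(0), cell_b = integer(0)))
  }
  # boundary pixels: any 8-neighbor (or image edge) has a different value
  pad <- matrix(-1L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  boundary <- matrix(FALSE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    boundary <- boundary | (nb != core)
  }
  sel <- which(boundary & mask > 0)
  lab <- mask[sel]
  coords <- cbind(x = (sel - 1L) %/% h, y = (sel - 1L) %% h)
  nb <- BiocNeighbors::findNeighbors(coords, threshold = expansion_px)$index
  pairs <- purrr::map_dfr(seq_along(nb), function(i) {
    j <- nb[[i]]
    j <- j[lab[j] != lab[i]]
    if (length(j) == 0) return(NULL)
    tibble::tibble(cell_a = pmin(lab[i], lab[j]),
                   cell_b = pmax(lab[i], lab[j]))
  })
  if (nrow(pairs) == 0) {
    return(tibble::tibble(cell_a = integer(0), cell_b = integer(0)))
  }
  dplyr::distinct(pairs) |> dplyr::arrange(.data$cell_a, .data$cell_b)
}

#' Neighbor graphs for every image of a cohort
#'
#' @param cohort An `imc_cohort` with rendered masks.
#' @param expansion_px Dilation radius in pixels; default 4.
#' @return A tibble `image_id`, `cell_a`, `cell_b`.
#' @export
neighbor_graphs <- function(cohort, expansion_px = 4) {
  if (is.null(cohort$masks)) {
    rlang::abort("Cohort was simulated with render_images = FALSE.")
  }
  purrr::map_dfr(names(cohort$masks), function(id) {
    dplyr::bind_cols(tibble::tibble(image_id = id),
                     build_neighbor_graph(cohort$masks[[id]], expansion_px))
  })
}

#' Extract the neighbors of a query cell population
#'
#' Returns the union of cells adjacent to any query cell, excluding the
#' query cells themselves by default (the analysis concerns cells directly
#' adjacent to, not including, the query population).
#'
#' @param edges Neighbor pairs: a tibble with `cell_a`, `cell_b` and
#'   optionally `image_id` (required when `query` spans images).
#' @param query Query cells: an integer vector (single image) or a tibble
#'   with `image_id` and `cell_id`.
#' @param include_query Keep query cells that are themselves neighbors of
#'   other query cells; default `FALSE`.
#' @return Neighbor cells in the same form as `query` (vector or tibble).
#' @export
extract_neighbors <- function(edges, query, include_query = FALSE) {
  if (is.data.frame(query)) {
    stopifnot(all(c("image_id", "cell_id") %in% names(query)),
              "image_id" %in% names(edges))
    if (nrow(query) == 0) {
      rlang::warn("Empty query; returning an empty neighbor set.")
      return(query[0, c("image_id", "cell_id")])
    }
    key <- function(img, id) paste(img, id, sep = "\r")
    qk <- key(query$image_id, query$cell_id)
    ak <- key(edges$image_id, edges$cell_a)
    bk <- key(edges$image_id, edges$cell_b)
    hit_a <- ak %in% qk
    hit_b <- bk %in% qk
    nbr <- dplyr::bind_rows(
      tibble::tibble(image_id = edges$image_id[hit_a],
                     cell_id = edges$cell_b[hit_a]),
      tibble::tibble(image_id = edges$image_id[hit_b],
                     cell_id = edges$cell_a[hit_b])
    ) |> dplyr::distinct()
    if (!include_query) {
      nbr <- nbr[!key(nbr$image_id, nbr$cell_id) %in% qk, ]
    }
    dplyr::arrange(nbr, .data$image_id, .data$cell_id)
  } else {
    if (length(query) == 0) {
      rlang::warn("Empty query; returning an empty neighbor set.")
      return(integer(0))
    }
    nbr <- c(edges$cell_b[edges$cell_a %in% query],
             edges$cell_a[edges$cell_b %in% query])
    nbr <- unique(nbr)
    if (!include_query) nbr <- setdiff(nbr, query)
    sort(nbr)
  }
}

#' Cluster and test the neighborhood of a query population
#'
#' Extracts the cells adjacent to a query population, clusters them
#' PhenoGraph-style, computes per-patient cluster fractions, and tests each
#' cluster's abundance between recurrence groups with a two-sided
#' Mann-Whitney U test.
#'
#' @param cells Cell tibble with transformed markers, `image_id`,
#'   `patient_id`, `cell_id`.
#' @param edges Cohort-wide neighbor pairs from [neighbor_graphs()].
#' @param query Tibble with `image_id`, `cell_id` of the query cells (e.g.
#'   gated epithelial or CD8 T cells).
#' @param outcome Tibble with `patient_id`, `recurrent`.
#' @param markers,k,resolution,seed Passed to [cluster_cells()].
#' @param alpha Significance level for flagging clusters; default 0.05.
#' @return An `imc_neighborhood` object: `neighbors` (the extracted cell
#'   rows), `clusters` (`imc_clusters`), `fractions`, and `tests`
#'   (`imc_abundance`).
#' @export
neighborhood_enrichment <- function(cells, edges, query, outcome,
                                    markers = marker_columns(cells), k = 30,
                                    resolution = 1, seed = 1L,
                                    alpha = 0.05) {
  nbr <- extract_neighbors(edges, query)
  sub <- dplyr::inner_join(cells, nbr, by = c("image_id", "cell_id"))
  with_cells <- dplyr::distinct(sub, .data$patient_id) |>
    dplyr::inner_join(outcome, by = "patient_id")
  if (length(unique(with_cells$recurrent)) < 2L ||
      any(table(with_cells$recurrent) < 2L)) {
    rlang::abort("Need >= 2 patients per outcome group with neighbor cells.")
  }
  cl <- cluster_cells(sub, markers = markers, k = k,
                      resolution = resolution, seed = seed)
  fr <- cluster_fractions(cl$assignments)
  tests <- compare_abundance(fr, outcome, alpha = alpha)
  structure(list(neighbors = sub, clusters = cl, fractions = fr,
                 tests = tests, query_n = nrow(query)),
            class = "imc_neighborhood")
}

#' @export
print.imc_neighborhood <- function(x, ...) {
  cat(sprintf(
    "Neighborhood enrichment: %d query cells -> %d neighbors, %d clusters, %d flagged\n",
    x$query_n, nrow(x$neighbors), length(x$clusters$sizes),
    sum(x$tests$significant)))
  invisible(x)
}
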