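#' Quantile-anchored ("range") batch correction
#'
#' For each marker and acquisition batch, fits the affine map sending the
#' batch's (`q_low`, `q_high`) intensity quantiles onto the reference
#' quantiles (pooled over all cells by default, or a named reference batch)
#' and applies it to every cell of that batch. This removes multiplicative
#' and additive per-marker batch effects after trimming extremes — an
#' unanchored range-rescaling correction in the mass-cytometry tradition.
#' Corrected intensities are clipped at 0. A batch whose two anchor
#' quantiles coincide is left unchanged with a warning.
#'
#' @param cells Cell tibble with a `batch` column and raw marker columns.
#' @param markers Marker column names to correct (default: all panel columns
#'   found via [marker_columns()]).
#' @param q_low,q_high Anchor quantiles in (0, 1); defaults 0.01 and 0.99.
#' @param reference `"pooled"` (default) or a batch id.
#' @return The cell tibble with marker columns replaced by corrected values.
#' @export
range_batch_correct <- function(cells, markers = marker_columns(cells),
                                q_low = 0.01, q_high = 0.99,
                                reference = "pooled") {
  stopifnot(q_low < q_high, q_low > 0, q_high < 1)
  if (!"batch" %in% names(cells)) rlang::abort("`cells` needs a `batch` column.")
  batches <- unique(cells$batch)
  if (min(table(cells$batch)) < 2L) {
    rlang::abort("Need at least 2 cells per batch.")
  }
  if (!identical(reference, "pooled") && !reference %in% batches) {
    rlang::abort("`reference` must be \"pooled\" or an existing batch id.")
  }
  for (m in markers) {
    v <- cells[[m]]
    ref_v <- if (identical(reference, "pooled")) v else v[cells$batch == reference]
    ref_q <- stats::quantile(ref_v, c(q_low, q_high), names = FALSE)
    for (b in batches) {
      sel <- cells$batch == b
      bq <- stats::quantile(v[sel], c(q_low, q_high), names = FALSE)
      if (diff(bq) <= 0) {
        rlang::warn(paste0("Degenerate batch ", b, " for marker ", m,
                           ": anchor quantiles coincide; left unchanged."))
        next
      }
      slope <- diff(ref_q) / diff(bq)
      cells[[m]][sel] <- pmax(ref_q[1] + (v[sel] - bq[1]) * slope, 0)
    }
  }
  cells
}

#' Arcsinh-transform marker intensities
#'
#' Applies `asinh(x / cofactor)` to each marker column, the standard
#' variance-stabilizing transform for mass-cytometry counts (cofactor 5).
#' The transform is strictly increasing and invertible.
#'
#' @param cells Cell tibble with raw marker columns.
#' @param markers Marker column names (default: all panel columns).
#' @param cofactor Positive divisor applied before `asinh`; default 5.
#' @return The cell tibble with marker columns transformed in place; the
#'   cofactor is recorded in attribute `"cofactor"`.
#' @examples
#' d <- tibble::tibble(batch = "b1", vimentin = c(0, 5))
#' arcsinh_transform(d, markers = "vimentin")$vimentin # 0, asinh(1)
#' @export
arcsinh_transform <- function(cells, markers = marker_columns(cells),
                              cofactor = 5) {
  if (cofactor <= 0) rlang::abort("`cofactor` must be positive.")
  for (m in markers) {
    if (any(cells[[m]] < 0)) rlang::abort("Intensities must be non-negative.")
    cells[[m]] <- asinh(cells[[m]] / cofactor)
  }
  attr(cells, "cofactor") <- cofactor
  cells
}

#' Marker columns of a cell table
#'
#' All numeric columns that are not structural (ids, coordinates, area,
#' gates, cluster labels).
#'
#' @param cells A cell tibble.
#' @return Character vector of marker column names.
#' @export
marker_columns <- function(cells) {
  structural <- c("cell_id", "image_id", "patient_id", "batch", "x", "y",
                  "area_px", "cluster", "meta_cluster", "phenotype")
  nm <- setdiff(names(cells), structural)
  nm <- nm[!startsWith(nm, "gate_") & !startsWith(nm, "threshold_")]
  nm[vapply(cells[nm], is.numeric, logical(1))]
}
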