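#' Quantify per-cell intensities from an image and label mask
#'
#' For every positive label in the mask, computes the mean intensity of each
#' channel over the cell's pixels, the unweighted pixel centroid (0-based,
#' x = column, y = row) and the pixel area. Labels need not be consecutive;
#' every positive label yields exactly one row.
#'
#' @param image A height x width x channel numeric array (or a matrix for a
#'   single channel).
#' @param mask Integer label matrix of the same height/width; 0 = background.
#' @param panel Character vector of marker names, one per channel.
#' @param image_id,patient_id,batch Identifiers carried into the table.
#' @return A tibble with one row per cell: `cell_id`, `image_id`,
#'   `patient_id`, `batch`, `x`, `y`, `area_px`, then one raw mean-intensity
#'   column per marker.
#' @examples
#' img <- array(7, dim = c(4, 4, 1))
#' msk <- matrix(c(1, 1, 0, 2, rep(0, 12)), 4, 4)
#' quantify_image(img, msk, panel = "vimentin", image_id = "img1")
#' @export
quantify_image <- function(image, mask, panel, image_id,
                           patient_id = NA_character_,
                           batch = NA_character_) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (!identical(dim(image)[1:2], dim(mask))) {
    rlang::abort("`image` and `mask` must share pixel dimensions.")
  }
  if (dim(image)[3] != length(panel)) {
    rlang::abort("`panel` length must equal the channel count.")
  }
  idx <- which(mask > 0)
  if (length(idx) == 0) {
    out <- tibble::tibble(
      cell_id = integer(0), image_id = character(0),
      patient_id = character(0), batch = character(0),
      x = numeric(0), y = numeric(0), area_px = integer(0))
    for (m in panel) out[[m]] <- numeric(0)
    return(out)
  }
  lab <- as.integer(mask[idx])
  labs <- sort(unique(lab))
  f <- match(lab, labs)
  area <- tabulate(f, nbins = length(labs))
  h <- nrow(mask)
  # 0-based pixel coordinates: x = column, y = row
  px_x <- (idx - 1L) %/% h
  px_y <- (idx - 1L) %% h
  cx <- as.vector(rowsum(px_x, f)) / area
  cy <- as.vector(rowsum(px_y, f)) / area
  means <- vapply(seq_along(panel), function(ch) {
    v <- image[idx + (ch - 1L) * length(mask)]
    rowsum(v, f)[, 1] / area
  }, numeric(length(labs)))
  if (is.null(dim(means))) means <- matrix(means, nrow = length(labs))
  colnames(means) <- panel
  dplyr::bind_cols(
    tibble::tibble(cell_id = labs, image_id = image_id,
                   patient_id = patient_id, batch = batch,
                   x = cx, y = cy, area_px = as.integer(area)),
    tibble::as_tibble(means)
  )
}

#' Quantify every image of a simulated cohort
#'
#' Runs [quantify_image()] on each image/mask pair and merges the results
#' into a single cell table with patient and batch annotations from the
#' manifest.
#'
#' @param cohort An `imc_cohort` with rendered images.
#' @return A merged cell tibble (see [quantify_image()]).
#' @export
quantify_cohort <- function(cohort) {
  if (is.null(cohort$images)) {
    rlang::abort("Cohort was simulated with render_images = FALSE.")
  }
  panel <- cohort$panel$marker_name
  tabs <- purrr::map(seq_len(nrow(cohort$images_manifest)), function(r) {
    m <- cohort$images_manifest[r, ]
    quantify_image(cohort$images[[m$image_id]], cohort$masks[[m$image_id]],
                   panel, image_id = m$image_id, patient_id = m$patient_id,
                   batch = m$batch)
  })
  merge_images(tabs)
}

#' Merge per-image cell tables
#'
#' Concatenates cell tables from multiple images (e.g. the two TMA cores of
#' one tumor) while guaranteeing a globally unique (image_id, cell_id) key.
#'
#' @param tables A list of cell tibbles from [quantify_image()].
#' @return One concatenated tibble.
#' @export
merge_images <- function(tables) {
  out <- dplyr::bind_rows(tables)
  if (anyDuplicated(out[, c("image_id", "cell_id")]) > 0L) {
    rlang::abort("Key collision: duplicate (image_id, cell_id) pairs.")
  }
  out
}
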