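#' Default 21-marker IMC panel
#'
#' The clustering panel used throughout: smooth-muscle actin, vimentin,
#' cytokeratin, CD31, CD45, estrogen receptor, CD4, E-cadherin, CD68, p53,
#' CD20, CD8a, VEGF, beta-catenin, podoplanin, Ki-67, collagen type I, CD3,
#' pERK1/2, progesterone receptor and pS6.
#'
#' @return Character vector of 21 marker names.
#' @export
default_panel <- function() {
  c("aSMA", "vimentin", "cytokeratin", "CD31", "CD45", "ER", "CD4",
    "E_cadherin", "CD68", "p53", "CD20", "CD8a", "VEGF", "B_catenin",
    "podoplanin", "Ki67", "collagen_I", "CD3", "pERK", "PR", "pS6")
}

#' Define a synthetic cell phenotype
#'
#' A phenotype is a log-normal intensity profile over the panel plus its
#' expected share of cells per patient and how that share shifts in recurrent
#' patients.
#'
#' @param name Phenotype name.
#' @param lineage One of "epithelial", "stromal", "immune", "endothelial".
#' @param mean_log Named numeric vector (one entry per panel marker) of
#'   log-scale mean intensities.
#' @param sd_log Named positive numeric vector of log-scale SDs, or a single
#'   value recycled over markers.
#' @param baseline_fraction Expected fraction of cells in non-recurrent
#'   patients, in \[0, 1\].
#' @param shift_recurrent Additive change to the fraction in recurrent
#'   patients (fractions are renormalized per group).
#' @return A `phenotype_spec` list.
#' @export
phenotype_spec <- function(name, lineage, mean_log, sd_log = 0.4,
                           baseline_fraction, shift_recurrent = 0) {
  lineage <- match.arg(lineage,
                       c("epithelial", "stromal", "immune", "endothelial"))
  if (length(sd_log) == 1L) {
    sd_log <- stats::setNames(rep(sd_log, length(mean_log)), names(mean_log))
  }
  stopifnot(
    length(mean_log) == length(sd_log),
    !is.null(names(mean_log)),
    all(sd_log > 0),
    baseline_fraction >= 0, baseline_fraction <= 1
  )
  structure(
    list(name = name, lineage = lineage,
         mean_log = mean_log, sd_log = sd_log[names(mean_log)],
         baseline_fraction = baseline_fraction,
         shift_recurrent = shift_recurrent),
    class = "phenotype_spec"
  )
}

#' Log-scale marker profile for a phenotype
#'
#' Builds a named per-marker vector of log-scale mean intensities: "on"
#' markers at `hi_level` (exp(3) ~ 20 counts), intermediate markers at
#' `mid_level`, everything else at background (`lo_level`, exp(-0.7) ~ 0.5
#' counts).
#'
#' @param panel Marker names.
#' @param high,mid Markers expressed at the high / intermediate level.
#' @param hi_level,mid_level,lo_level Log-scale means.
#' @return Named numeric vector over `panel`.
#' @export
marker_profile <- function(panel, high = character(), mid = character(),
                           hi_level = 3, mid_level = 1.5, lo_level = -0.7) {
  mu <- stats::setNames(rep(lo_level, length(panel)), panel)
  mu[high] <- hi_level
  mu[mid] <- mid_level
  mu
}

#' Default synthetic phenotypes
#'
#' Six phenotypes spanning the tissue compartments of an endometrial tumor
#' TMA core: a vimentin-high hormone-receptor-positive epithelial phenotype
#' (depleted in recurrent patients), a vimentin-low epithelial phenotype,
#' aSMA+ stroma, CD8 T cells, macrophages and endothelium. The vimentin-high
#' epithelial fraction drops by 0.15 in recurrent patients, mirroring the
#' prognostic contrast the pipeline is built to detect.
#'
#' @param panel Marker names (default [default_panel()]).
#' @param shift_vim_high Additive fraction shift of the vimentin-high
#'   epithelial phenotype in recurrent patients; default -0.15.
#' @return List of [phenotype_spec()] objects.
#' @export
default_phenotypes <- function(panel = default_panel(),
                               shift_vim_high = -0.15) {
  list(
    phenotype_spec("epithelial_vim_high", "epithelial",
      marker_profile(panel,
        high = c("cytokeratin", "E_cadherin", "vimentin", "ER", "PR",
                 "B_catenin")),
      baseline_fraction = 0.30, shift_recurrent = shift_vim_high),
    phenotype_spec("epithelial_vim_low", "epithelial",
      marker_profile(panel,
        high = c("cytokeratin", "E_cadherin", "p53"),
        mid = c("B_catenin", "pS6")),
      baseline_fraction = 0.25, shift_recurrent = -shift_vim_high * 2 / 3),
    phenotype_spec("stromal", "stromal",
      marker_profile(panel,
        high = c("aSMA", "vimentin", "collagen_I"),
        mid = "podoplanin"),
      baseline_fraction = 0.25, shift_recurrent = -shift_vim_high / 3),
    phenotype_spec("cd8_t", "immune",
      marker_profile(panel, high = c("CD3", "CD8a", "CD45"),
                     mid = "vimentin"),
      baseline_fraction = 0.08),
    phenotype_spec("macrophage", "immune",
      marker_profile(panel, high = c("CD68", "CD45"), mid = "vimentin"),
      baseline_fraction = 0.06),
    phenotype_spec("endothelial", "endothelial",
      marker_profile(panel, high = c("CD31", "VEGF"),
                     mid = c("vimentin", "podoplanin")),
      baseline_fraction = 0.06)
  )
}

#' Configure a synthetic IMC cohort
#'
#' Defaults emulate a two-batch TMA study of 36 stage IB endometrial tumors,
#' 17 of them recurrent, each patient contributing 1-3 ablated cores
#' (multi-channel images) of 2,000-3,300 cells, for roughly 2,000-10,000
#' cells per patient. Acquisition batches alternate per core and the second
#' batch carries a 1.5-fold multiplicative intensity inflation on every
#' marker. Recurrent patients draw exponential event times (faster for
#' patients whose planted vimentin-high epithelial fraction is below the
#' cohort median, hazard ratio 4); non-recurrent patients draw uniform
#' censoring times.
#'
#' @param n_patients,n_recurrent Cohort size and number of recurrent
#'   patients.
#' @param images_per_patient Integer range (min, max) of images per patient.
#' @param cells_per_image Integer range of cells per image.
#' @param image_size_px Image size (width, height) in pixels.
#' @param cell_radius_px Range of cell disk radii in pixels.
#' @param n_batches Number of acquisition batches; images cycle through them.
#' @param batch_scale_factors Per-batch multiplicative intensity factors:
#'   a numeric vector of length `n_batches`, or an `n_batches` x n_markers
#'   matrix for marker-specific factors.
#' @param panel Marker names.
#' @param phenotypes List of [phenotype_spec()]; baseline fractions are
#'   renormalized to sum to 1 per patient group.
#' @param composition_precision Dirichlet precision of patient-to-patient
#'   composition noise around the group mean (larger = less variable).
#' @param contact_fraction Fraction of cells placed in contact (<= 1 px gap)
#'   with an earlier cell, so contact-based neighbor graphs are non-trivial.
#' @param min_gap_px Minimum boundary gap (pixels) between non-contact cells.
#' @param pixel_noise_cv Coefficient of variation of within-cell pixel noise
#'   (0 = uniform disks).
#' @param survival List: `base_event_rate` (events/month for vimentin-high
#'   recurrent patients), `hazard_ratio` (rate multiplier for vimentin-low
#'   recurrent patients), `censor_range_months` (uniform censoring window for
#'   non-recurrent patients), `prognostic_phenotype` (phenotype whose planted
#'   fraction defines vimentin-low status at the cohort median).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 36, n_recurrent = 17,
                          images_per_patient = c(1, 3),
                          cells_per_image = c(2000, 3300),
                          image_size_px = c(800, 800),
                          cell_radius_px = c(2, 4),
                          n_batches = 2,
                          batch_scale_factors = c(1, 1.5),
                          panel = default_panel(),
                          phenotypes = default_phenotypes(panel),
                          composition_precision = 200,
                          contact_fraction = 0.3,
                          min_gap_px = 2,
                          pixel_noise_cv = 0,
                          survival = list(base_event_rate = log(2) / 36,
                                          hazard_ratio = 4,
                                          censor_range_months = c(12, 72),
                                          prognostic_phenotype =
                                            "epithelial_vim_high")) {
  if (is.vector(batch_scale_factors) && !is.matrix(batch_scale_factors)) {
    batch_scale_factors <- matrix(rep(batch_scale_factors, length(panel)),
                                  nrow = n_batches,
                                  dimnames = list(NULL, panel))
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_recurrent = as.integer(n_recurrent),
    images_per_patient = as.integer(images_per_patient),
    cells_per_image = as.integer(cells_per_image),
    image_size_px = as.integer(image_size_px),
    cell_radius_px = as.numeric(cell_radius_px),
    n_batches = as.integer(n_batches),
    batch_scale_factors = batch_scale_factors,
    panel = panel,
    phenotypes = phenotypes,
    composition_precision = composition_precision,
    contact_fraction = contact_fraction,
    min_gap_px = min_gap_px,
    pixel_noise_cv = pixel_noise_cv,
    survival = survival
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_patients >= 1, cfg$n_recurrent >= 0,
    cfg$n_recurrent <= cfg$n_patients,
    length(cfg$images_per_patient) == 2,
    cfg$images_per_patient[1] >= 1,
    diff(cfg$images_per_patient) >= 0,
    length(cfg$cells_per_image) == 2, cfg$cells_per_image[1] >= 0,
    cfg$cell_radius_px[1] >= 1,
    nrow(cfg$batch_scale_factors) == cfg$n_batches,
    all(cfg$batch_scale_factors > 0),
    cfg$composition_precision > 0,
    cfg$contact_fraction >= 0, cfg$contact_fraction <= 1,
    cfg$pixel_noise_cv >= 0
  )
  ph_markers <- lapply(cfg$phenotypes, function(p) names(p$mean_log))
  if (!all(vapply(ph_markers, identical, logical(1), y = cfg$panel))) {
    rlang::abort("Phenotype marker profiles must match the panel exactly.")
  }
  # geometry: reject requested densities beyond random-sequential packing
  rmax <- max(cfg$cell_radius_px)
  need <- cfg$cells_per_image[2] * pi * (rmax + cfg$min_gap_px / 2)^2
  if (need > 0.55 * prod(cfg$image_size_px)) {
    rlang::abort(paste0(
      "Infeasible geometry: ", cfg$cells_per_image[2], " cells of radius <= ",
      rmax, " cannot be packed into ", cfg$image_size_px[1], "x",
      cfg$image_size_px[2], " px without overlap."))
  }
  invisible(cfg)
}

#' Group-level expected phenotype composition
#'
#' Baseline fractions for non-recurrent patients; baseline plus
#' `shift_recurrent` (floored at 0) for recurrent patients. Each vector is
#' renormalized to sum to exactly 1.
#'
#' @param phenotypes List of [phenotype_spec()].
#' @return A tibble with columns `phenotype`, `nonrecurrent`, `recurrent`.
#' @export
group_composition <- function(phenotypes) {
  base <- vapply(phenotypes, `[[`, numeric(1), "baseline_fraction")
  shift <- vapply(phenotypes, `[[`, numeric(1), "shift_recurrent")
  rec <- pmax(base + shift, 0)
  tibble::tibble(
    phenotype = vapply(phenotypes, `[[`, character(1), "name"),
    nonrecurrent = base / sum(base),
    recurrent = rec / sum(rec)
  )
}

# uniform draw from an integer range; safe when lo == hi (unlike sample())
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Place non-overlapping cells in an image as disks
#'
#' Random sequential placement of `n` disk-shaped cells with radii drawn from
#' `radius_range`. A `contact_fraction` of cells is placed deliberately in
#' contact (boundary gap <= 1 px) with a previously placed cell; all other
#' pairs keep a boundary gap of at least `min_gap` px. Disks never overlap,
#' so every label is a connected, pairwise-disjoint pixel set.
#'
#' @param n Number of cells (0 allowed).
#' @param image_size (width, height) in pixels.
#' @param radius_range (min, max) disk radius in pixels.
#' @param contact_fraction Fraction of cells placed in contact.
#' @param min_gap Minimum boundary gap for non-contact placements, pixels.
#' @param max_tries Placement attempts per cell before giving up.
#' @return An integer label matrix (rows = y, cols = x; 0 = background) with
#'   attributes `centers` (n x 2 matrix of 0-based x, y), `radii`, and
#'   `contact_pairs` (2-column matrix of deliberately contacting label
#'   pairs).
#' @export
place_cells <- function(n, image_size, radius_range, contact_fraction = 0.3,
                        min_gap = 2, max_tries = 200) {
  w <- image_size[1]; h <- image_size[2]
  mask <- matrix(0L, nrow = h, ncol = w)
  centers <- matrix(NA_real_, n, 2)
  radii <- numeric(n)
  contact_pairs <- matrix(integer(0), ncol = 2)
  if (n == 0) {
    return(structure(mask, centers = centers, radii = radii,
                     contact_pairs = contact_pairs))
  }
  rmax <- max(radius_range)
  # spatial hash grid: bins of the maximum interaction distance
  s <- 2 * rmax + max(min_gap, 1) + 1
  ngx <- max(1L, ceiling(w / s)); ngy <- max(1L, ceiling(h / s))
  grid <- vector("list", ngx * ngy)
  bin_of <- function(x, y) {
    gx <- min(ngx - 1L, max(0L, floor(x / s)))
    gy <- min(ngy - 1L, max(0L, floor(y / s)))
    as.integer(gx * ngy + gy + 1L)
  }
  neighbours_of <- function(x, y) {
    gx <- min(ngx - 1L, max(0L, floor(x / s)))
    gy <- min(ngy - 1L, max(0L, floor(y / s)))
    idx <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      cx <- gx + dx; cy <- gy + dy
      if (cx >= 0 && cx < ngx && cy >= 0 && cy < ngy) {
        idx <- c(idx, grid[[cx * ngy + cy + 1L]])
      }
    }
    idx
  }
  ok_at <- function(x, y, r, partner = 0L) {
    nb <- neighbours_of(x, y)
    nb <- nb[nb != partner]
    if (length(nb) == 0) return(TRUE)
    d2 <- (centers[nb, 1] - x)^2 + (centers[nb, 2] - y)^2
    all(d2 >= (radii[nb] + r + min_gap)^2)
  }
  want_contact <- stats::runif(n) < contact_fraction
  want_contact[1] <- FALSE
  for (i in seq_len(n)) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      # a contact placement can be geometrically blocked (e.g. every partner
      # already sits in a tight pair); fall back to random placement
      if (want_contact[i] && try > max_tries / 2) want_contact[i] <- FALSE
      if (want_contact[i]) {
        j <- sample.int(i - 1L, 1L)
        gap <- stats::runif(1, 0.2, 1.0)
        theta <- stats::runif(1, 0, 2 * pi)
        d <- radii[j] + r + gap
        x <- centers[j, 1] + d * cos(theta)
        y <- centers[j, 2] + d * sin(theta)
        if (x < r + 1 || x > w - r - 2 || y < r + 1 || y > h - r - 2) next
        if (!ok_at(x, y, r, partner = j)) next
        contact_pairs <- rbind(contact_pairs, c(j, i))
      } else {
        x <- stats::runif(1, r + 1, w - r - 2)
        y <- stats::runif(1, r + 1, h - r - 2)
        if (!ok_at(x, y, r)) next
      }
      centers[i, ] <- c(x, y)
      radii[i] <- r
      grid[[bin_of(x, y)]] <- c(grid[[bin_of(x, y)]], i)
      placed <- TRUE
      break
    }
    if (!placed) {
      rlang::abort(paste0("Infeasible geometry: could not place cell ", i,
                          " of ", n, " after ", max_tries, " attempts."))
    }
  }
  # rasterize: pixel centers within radius; 0-based coordinates
  for (i in seq_len(n)) {
    x <- centers[i, 1]; y <- centers[i, 2]; r <- radii[i]
    xs <- max(0, floor(x - r)):min(w - 1, ceiling(x + r))
    ys <- max(0, floor(y - r)):min(h - 1, ceiling(y + r))
    px <- expand.grid(x = xs, y = ys)
    inside <- (px$x - x)^2 + (px$y - y)^2 <= r^2
    mask[cbind(px$y[inside] + 1L, px$x[inside] + 1L)] <- i
  }
  structure(mask, centers = centers, radii = radii,
            contact_pairs = contact_pairs)
}

#' Simulate a multiplexed imaging cohort with planted structure
#'
#' Generates, per image, a multi-channel intensity image and a matching
#' integer label mask, together with the panel table, per-patient clinical
#' table, per-image manifest, and a ground-truth table recording each cell's
#' planted phenotype and true mean intensities. Cell intensities are drawn
#' log-normally from the cell's phenotype profile and multiplied by the
#' image's batch factor. All tables are generated before any rasterization,
#' so they are identical whether or not images are rendered, and identical
#' config + seed reproduces identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed controlling all randomness.
#' @param render_images If `FALSE`, skip disk placement and rasterization and
#'   return tables only (fast path for composition/survival studies).
#' @return An `imc_cohort` list: `images` (named list of height x width x
#'   channel arrays, or `NULL`), `masks` (named list of label matrices),
#'   `panel` (tibble: channel_index, marker_name), `clinical` (one row per
#'   patient: patient_id, recurrent, time_months, event, n_images),
#'   `images_manifest` (image_id, patient_id, batch, n_cells), `truth`
#'   (per cell: image_id, patient_id, cell_id, phenotype and true mean
#'   intensity per marker), `truth_patients` (patient-level planted
#'   composition and vimentin-low status), `contacts` (planted contact
#'   pairs per image) and `config`.
#' @export
simulate_cohort <- function(config, seed = 1L, render_images = TRUE) {
  validate_cohort_config(config)
  set.seed(seed)
  panel <- config$panel
  K <- length(panel)
  comp <- group_composition(config$phenotypes)
  ph_names <- comp$phenotype
  mu <- do.call(rbind, lapply(config$phenotypes, `[[`, "mean_log"))
  sdl <- do.call(rbind, lapply(config$phenotypes, `[[`, "sd_log"))
  rownames(mu) <- rownames(sdl) <- ph_names

  pid <- sprintf("P%02d", seq_len(config$n_patients))
  recurrent <- rep(0L, config$n_patients)
  recurrent[sample.int(config$n_patients, config$n_recurrent)] <- 1L

  # patient compositions around the group mean
  prec <- config$composition_precision
  comp_pat <- t(vapply(seq_len(config$n_patients), function(i) {
    target <- if (recurrent[i] == 1L) comp$recurrent else comp$nonrecurrent
    rdirichlet1(prec * pmax(target, 1e-6))
  }, numeric(length(ph_names))))
  colnames(comp_pat) <- ph_names

  # image design
  n_img <- sample_range(config$images_per_patient[1],
                        config$images_per_patient[2], config$n_patients)
  manifest <- purrr::map_dfr(seq_len(config$n_patients), function(i) {
    tibble::tibble(
      image_id = sprintf("%s_img%d", pid[i], seq_len(n_img[i])),
      patient_id = pid[i],
      batch = sprintf("batch%d",
                      ((seq_len(n_img[i]) - 1L) %% config$n_batches) + 1L),
      n_cells = sample_range(config$cells_per_image[1],
                             config$cells_per_image[2], n_img[i])
    )
  })

  # per-cell phenotype and true intensities (batch factor applied)
  truth <- purrr::map_dfr(seq_len(nrow(manifest)), function(r) {
    m <- manifest[r, ]
    n <- m$n_cells
    p <- comp_pat[m$patient_id == pid, , drop = TRUE]
    ph <- ph_names[sample.int(length(ph_names), n, replace = TRUE, prob = p)]
    draws <- matrix(
      stats::rlnorm(n * K, meanlog = mu[ph, , drop = FALSE],
                    sdlog = sdl[ph, , drop = FALSE]),
      nrow = n, ncol = K, dimnames = list(NULL, panel)
    )
    b <- as.integer(sub("batch", "", m$batch))
    draws <- sweep(draws, 2, config$batch_scale_factors[b, panel], `*`)
    dplyr::bind_cols(
      tibble::tibble(image_id = m$image_id, patient_id = m$patient_id,
                     batch = m$batch, cell_id = seq_len(n), phenotype = ph),
      tibble::as_tibble(draws)
    )
  })

  # survival: exponential event times for recurrent patients (rate inflated
  # by the hazard ratio when the planted vimentin-high fraction is below the
  # cohort median), uniform censoring for non-recurrent patients
  sv <- config$survival
  prog <- sv$prognostic_phenotype
  if (!prog %in% ph_names) {
    rlang::abort("`survival$prognostic_phenotype` is not a phenotype name.")
  }
  vim_frac <- comp_pat[, prog]
  vim_low <- vim_frac <= stats::median(vim_frac)
  rate <- sv$base_event_rate * ifelse(vim_low, sv$hazard_ratio, 1)
  time_months <- ifelse(
    recurrent == 1L,
    stats::rexp(config$n_patients, rate = rate),
    stats::runif(config$n_patients, sv$censor_range_months[1],
                 sv$censor_range_months[2])
  )
  time_months <- pmax(time_months, 0.1)
  clinical <- tibble::tibble(
    patient_id = pid, recurrent = recurrent,
    time_months = time_months, event = recurrent, n_images = n_img
  )
  truth_patients <- dplyr::bind_cols(
    tibble::tibble(patient_id = pid, recurrent = recurrent,
                   vimentin_high_fraction = vim_frac,
                   vimentin_low = vim_low),
    tibble::as_tibble(comp_pat)
  )

  masks <- NULL; images <- NULL; contacts <- NULL
  if (render_images) {
    masks <- vector("list", nrow(manifest))
    images <- vector("list", nrow(manifest))
    contacts <- vector("list", nrow(manifest))
    names(masks) <- names(images) <- names(contacts) <- manifest$image_id
    w <- config$image_size_px[1]; h <- config$image_size_px[2]
    for (r in seq_len(nrow(manifest))) {
      m <- manifest[r, ]
      mask <- place_cells(m$n_cells, config$image_size_px,
                          config$cell_radius_px,
                          contact_fraction = config$contact_fraction,
                          min_gap = config$min_gap_px)
      img <- array(0, dim = c(h, w, K), dimnames = list(NULL, NULL, panel))
      vals <- as.matrix(truth[truth$image_id == m$image_id, panel])
      idx <- which(mask > 0)
      lab <- mask[idx]
      if (config$pixel_noise_cv > 0) {
        realized <- matrix(0, nrow = m$n_cells, ncol = K,
                           dimnames = list(NULL, panel))
        npx <- tabulate(lab, nbins = m$n_cells)
        for (ch in seq_len(K)) {
          pxv <- vals[lab, ch] *
            pmax(stats::rnorm(length(lab), 1, config$pixel_noise_cv), 0)
          img[idx + (ch - 1L) * (h * w)] <- pxv
          realized[, ch] <- rowsum(pxv, lab)[, 1] / npx
        }
        truth[truth$image_id == m$image_id, panel] <-
          tibble::as_tibble(realized)
      } else {
        for (ch in seq_len(K)) {
          img[idx + (ch - 1L) * (h * w)] <- vals[lab, ch]
        }
      }
      masks[[r]] <- mask
      images[[r]] <- img
      cp <- attr(mask, "contact_pairs")
      contacts[[r]] <- tibble::tibble(
        image_id = m$image_id,
        cell_a = if (nrow(cp)) as.integer(cp[, 1]) else integer(0),
        cell_b = if (nrow(cp)) as.integer(cp[, 2]) else integer(0)
      )
    }
    contacts <- dplyr::bind_rows(contacts)
  }

  structure(
    list(images = images, masks = masks,
         panel = tibble::tibble(channel_index = seq_len(K),
                                marker_name = panel),
         clinical = clinical, images_manifest = manifest,
         truth = truth, truth_patients = truth_patients,
         contacts = contacts, config = config, seed = seed),
    class = "imc_cohort"
  )
}

#' @export
print.imc_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic IMC cohort: %d patients (%d recurrent), %d images, %d cells\n",
    nrow(x$clinical), sum(x$clinical$recurrent), nrow(x$images_manifest),
    nrow(x$truth)))
  cat(sprintf("  panel: %d markers; images %s\n", nrow(x$panel),
              if (is.null(x$images)) "not rendered" else "rendered"))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Images are written as multi-page 32-bit TIFFs (one page per channel, in
#' panel order) normalized by a per-image scale recorded in the manifest CSV;
#' masks as single-channel 16-bit TIFFs (0 = background); panel, clinical,
#' manifest and truth tables as CSV.
#'
#' @param cohort An `imc_cohort` with rendered images.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$images)) {
    rlang::abort("Cohort was simulated with render_images = FALSE.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$images_manifest
  manifest$intensity_scale <- vapply(
    manifest$image_id, function(id) max(cohort$images[[id]], 1e-12),
    numeric(1))
  for (id in manifest$image_id) {
    img <- cohort$images[[id]]
    sc <- manifest$intensity_scale[manifest$image_id == id]
    pages <- lapply(seq_len(dim(img)[3]), function(ch) img[, , ch] / sc)
    tiff::writeTIFF(pages, file.path(dir, paste0(id, ".tiff")),
                    bits.per.sample = 32L, reduce = FALSE)
    tiff::writeTIFF(cohort$masks[[id]] / 65535,
                    file.path(dir, paste0(id, "_mask.tiff")),
                    bits.per.sample = 16L, reduce = FALSE)
  }
  utils::write.csv(cohort$panel, file.path(dir, "panel.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "images.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a multi-channel intensity image written by [write_cohort()]
#'
#' @param path TIFF path.
#' @param scale Intensity scale recorded in the manifest.
#' @return A height x width x channel array.
#' @export
read_image_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (ch in seq_along(pages)) arr[, , ch] <- pages[[ch]] * scale
  arr
}

#' Read a label mask written by [write_cohort()]
#'
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}
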