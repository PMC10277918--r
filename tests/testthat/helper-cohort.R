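# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Two well-separated Gaussian blobs in marker space.
blob_cells <- function(n_per = 20, sep = 30, d = 3, seed = 30) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * d), n_per),
             matrix(stats::rnorm(n_per * d, mean = sep), n_per))
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("m", seq_len(d))
  out
}

# A small rendered cohort exercising every pipeline stage.
small_cohort <- function() {
  cached("small_cohort", function() {
    cfg <- cohort_config(
      n_patients = 8, n_recurrent = 4,
      images_per_patient = c(1, 2), cells_per_image = c(120, 180),
      image_size_px = c(220, 220)
    )
    simulate_cohort(cfg, seed = 101)
  })
}

# Paired-core design at full cohort scale (tables only): every patient
# contributes one image per batch, so the two batches sample the same
# patients and the planted x1.5 factor is the only systematic batch
# difference. Batch medians of bimodal markers are noisy at small n, so the
# correction invariant is checked at the study's cell counts.
paired_truth <- function() {
  cached("paired_truth", function() {
    cfg <- cohort_config(images_per_patient = c(2, 2))
    co <- simulate_cohort(cfg, seed = 202, render_images = FALSE)
    list(cells = co$truth, corrected = range_batch_correct(co$truth),
         markers = co$panel$marker_name)
  })
}

small_cells <- function() {
  cached("small_cells", function() {
    small_cohort() |>
      quantify_cohort() |>
      range_batch_correct() |>
      arcsinh_transform()
  })
}

# Composition/survival recovery across 50 seeds at the cohort's study
# conditions (36 patients / 17 recurrent, -0.15 planted shift, hazard ratio
# 4), on the table-only fast path.
recovery_runs <- function(n_seeds = 50) {
  cached(paste0("recovery_", n_seeds), function() {
    purrr::map_dfr(seq_len(n_seeds), function(s) {
      cfg <- cohort_config(images_per_patient = c(1, 1),
                           cells_per_image = c(500, 800))
      co <- simulate_cohort(cfg, seed = 1000 + s, render_images = FALSE)
      fr <- cluster_fractions(co$truth, cluster_col = "phenotype")
      ab <- compare_abundance(fr, co$clinical)
      planted <- ab[ab$cluster == "epithelial_vim_high", ]
      km <- km_logrank(
        co$clinical,
        groups = ifelse(co$truth_patients$vimentin_low, "low", "high"))
      tibble::tibble(
        seed = 1000 + s,
        planted_p = planted$p_value,
        planted_is_smallest = planted$p_value == min(ab$p_value),
        planted_direction_ok =
          planted$median_nonrecurrent > planted$median_recurrent,
        logrank_p = km$p_value
      )
    })
  })
}
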