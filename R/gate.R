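#' Define a gating rule
#'
#' A cell receives a population label when all required-positive markers
#' exceed their per-image thresholds and no required-negative marker does.
#' Thresholds are resolved per image: automatically by Otsu's method on the
#' transformed values (the reproducible analogue of setting cut-offs by eye
#' per image), by a per-image quantile, or as a fixed value.
#'
#' @param name Population name (used as column `gate_<name>`).
#' @param positive,negative Marker name vectors (disjoint).
#' @param method Threshold policy: `"otsu"`, `"quantile"` or `"fixed"`.
#' @param quantile Quantile probability when `method = "quantile"` (also the
#'   fallback when Otsu is unresolvable on a constant channel).
#' @param value Fixed threshold when `method = "fixed"`.
#' @return A `gating_rule` list.
#' @export
gating_rule <- function(name, positive, negative = character(),
                        method = c("otsu", "quantile", "fixed"),
                        quantile = 0.75, value = NULL) {
  method <- match.arg(method)
  if (length(intersect(positive, negative)) > 0L) {
    rlang::abort("Positive and negative marker sets must be disjoint.")
  }
  if (method == "fixed" && is.null(value)) {
    rlang::abort("`value` is required for a fixed threshold.")
  }
  structure(list(name = name, positive = positive, negative = negative,
                 method = method, quantile = quantile, value = value),
            class = "gating_rule")
}

#' Default gating rules for the major populations
#'
#' Epithelial cells: E-cadherin+ cytokeratin+ aSMA-; non-epithelial cells:
#' aSMA+ E-cadherin- (mutually exclusive with epithelial by construction);
#' CD8 T cells: CD8a+ CD3+; proliferative cells: Ki-67+.
#'
#' @param method Threshold policy passed to every rule.
#' @return List of [gating_rule()] objects.
#' @export
default_gates <- function(method = "otsu") {
  list(
    gating_rule("epithelial", positive = c("E_cadherin", "cytokeratin"),
                negative = "aSMA", method = method),
    gating_rule("nonepithelial", positive = "aSMA",
                negative = "E_cadherin", method = method),
    gating_rule("cd8_t", positive = c("CD8a", "CD3"), method = method),
    gating_rule("proliferative", positive = "Ki67", method = method)
  )
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance over a binned histogram — the automatic
#' analogue of a manual positive/negative intensity cut-off.
#'
#' @param x Numeric vector.
#' @param n_breaks Number of histogram bins.
#' @return Threshold value, or `NA` when `x` is constant.
#' @export
otsu_threshold <- function(x, n_breaks = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = n_breaks + 1L)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / pmax(w1, 1)
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

resolve_threshold <- function(x, rule) {
  switch(rule$method,
    fixed = rule$value,
    quantile = stats::quantile(x, rule$quantile, names = FALSE),
    otsu = {
      t <- otsu_threshold(x)
      if (is.na(t)) {
        rlang::warn("Otsu unresolvable on a constant channel; falling back to quantile.")
        t <- stats::quantile(x, rule$quantile, names = FALSE)
      }
      t
    }
  )
}

#' Apply gating rules to a cell table
#'
#' Thresholds are resolved independently for every image, matching per-image
#' cut-off setting. Adds one logical column `gate_<name>` per rule; labels
#' may overlap across rules (a cell can be both CD8 T and proliferative).
#'
#' @param cells Cell tibble with transformed marker columns and `image_id`.
#' @param rules List of [gating_rule()] objects (default [default_gates()]).
#' @return `cells` with one `gate_<name>` logical column per rule.
#' @export
apply_gates <- function(cells, rules = default_gates()) {
  all_markers <- unique(unlist(lapply(rules, function(r)
    c(r$positive, r$negative))))
  missing <- setdiff(all_markers, names(cells))
  if (length(missing) > 0L) {
    rlang::abort(paste0("Unknown marker(s): ", paste(missing, collapse = ", ")))
  }
  # per image x marker x rule thresholds
  img <- cells$image_id
  for (rule in rules) {
    lab <- rep(TRUE, nrow(cells))
    for (m in c(rule$positive, rule$negative)) {
      pos <- m %in% rule$positive
      th <- rep(NA_real_, nrow(cells))
      for (id in unique(img)) {
        sel <- img == id
        th[sel] <- resolve_threshold(cells[[m]][sel], rule)
      }
      lab <- lab & (if (pos) cells[[m]] > th else cells[[m]] <= th)
    }
    cells[[paste0("gate_", rule$name)]] <- lab
  }
  cells
}

#' Per-patient compartment counts with subtraction arithmetic
#'
#' Counts cells per patient in the epithelial and non-epithelial
#' compartments, and derives, for each immune (and the proliferative)
#' population, the number inside the epithelial compartment as
#' `total - in_nonepithelial`; stromal cells are the non-epithelial cells
#' left after subtracting the immune populations. Derived counts that go
#' negative under threshold noise are floored at 0 with a warning.
#'
#' @param cells Gated cell tibble (output of [apply_gates()]).
#' @param immune_gates Names of immune gate columns (without the `gate_`
#'   prefix); default `"cd8_t"`.
#' @param proliferative_gate Name of the proliferation gate, or `NULL`.
#' @return A tibble with one row per patient: totals, compartment counts,
#'   per-population `<pop>_total`, `<pop>_nonepi`, `<pop>_epi` and `stromal`.
#' @export
compartment_counts <- function(cells, immune_gates = "cd8_t",
                               proliferative_gate = "proliferative") {
  needed <- paste0("gate_", c("epithelial", "nonepithelial", immune_gates,
                              proliferative_gate))
  missing <- setdiff(needed, names(cells))
  if (length(missing) > 0L) {
    rlang::abort(paste0("Missing gate column(s): ",
                        paste(missing, collapse = ", ")))
  }
  pops <- c(immune_gates, proliferative_gate)
  out <- cells |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      epithelial = sum(.data$gate_epithelial),
      nonepithelial = sum(.data$gate_nonepithelial),
      ungated = sum(!.data$gate_epithelial & !.data$gate_nonepithelial),
      dplyr::across(dplyr::all_of(paste0("gate_", pops)),
                    list(total = sum), .names = "{sub('gate_', '', .col)}_total"),
      .groups = "drop"
    )
  for (p in pops) {
    nonepi <- cells |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        v = sum(.data[[paste0("gate_", p)]] & .data$gate_nonepithelial),
        .groups = "drop")
    out[[paste0(p, "_nonepi")]] <- nonepi$v[match(out$patient_id,
                                                  nonepi$patient_id)]
    epi <- out[[paste0(p, "_total")]] - out[[paste0(p, "_nonepi")]]
    if (any(epi < 0)) {
      rlang::warn(paste0("Negative derived count for ", p,
                         " in the epithelial compartment; floored at 0."))
      epi <- pmax(epi, 0)
    }
    out[[paste0(p, "_epi")]] <- epi
  }
  immune_nonepi <- rowSums(as.matrix(
    out[, paste0(immune_gates, "_nonepi"), drop = FALSE]))
  stromal <- out$nonepithelial - immune_nonepi
  if (any(stromal < 0)) {
    rlang::warn("Negative derived stromal count; floored at 0.")
    stromal <- pmax(stromal, 0)
  }
  out$stromal <- stromal
  out
}
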