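#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PhenoGraph clustering
#'
#' @param x An `imc_clusters` object.
#' @param ... Unused.
#' @return One row per cluster with its size and share of cells.
#' @export
tidy.imc_clusters <- function(x, ...) {
  tibble::tibble(
    cluster = seq_along(x$sizes),
    n_cells = x$sizes,
    fraction = x$sizes / sum(x$sizes)
  )
}

#' @rdname tidy.imc_clusters
#' @export
glance.imc_clusters <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$assignments),
                 n_clusters = length(x$sizes),
                 modularity = x$modularity)
}

#' Tidy a Kaplan-Meier comparison
#'
#' @param x An `imc_survfit` object.
#' @param ... Unused.
#' @return One row per step of each group's survival curve: `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
tidy.imc_survfit <- function(x, ...) {
  f <- x$fit
  strata <- rep(sub("^group=", "", names(f$strata)), f$strata)
  tibble::tibble(group = strata, time = f$time, n_risk = f$n.risk,
                 n_event = f$n.event, n_censor = f$n.censor,
                 survival = f$surv)
}

#' @rdname tidy.imc_survfit
#' @export
glance.imc_survfit <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p_value = x$p_value)
}

#' Tidy an abundance comparison
#'
#' @param x An `imc_abundance` tibble.
#' @param ... Unused.
#' @return The underlying per-cluster results tibble.
#' @export
tidy.imc_abundance <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "imc_abundance")
  out
}

#' @rdname tidy.imc_abundance
#' @export
glance.imc_abundance <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x),
                 n_significant = sum(x$significant),
                 min_p = min(x$p_value),
                 alpha = attr(x, "alpha"))
}

#' Tidy a MEM profile
#'
#' @param x An `imc_mem` object.
#' @param ... Unused.
#' @return Long tibble `cluster`, `marker`, `score`, `raw`.
#' @export
tidy.imc_mem <- function(x, ...) {
  tibble::tibble(
    cluster = rep(as.integer(rownames(x$scores)), ncol(x$scores)),
    marker = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores),
    raw = as.vector(x$raw)
  )
}
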