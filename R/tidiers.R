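#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a landscape PCA
#'
#' @param x a [summarize_pca()] result.
#' @param what `"loadings"` (per-unit PC1 loadings, the default) or
#'   `"scores"` (per-window PC1 scores).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.landscape_pca <- function(x, what = c("loadings", "scores"), ...) {
  what <- match.arg(what)
  if (what == "loadings") x$loadings else x$scores
}

#' One-row summary of a landscape PCA
#'
#' @param x a [summarize_pca()] result.
#' @param ... unused.
#' @return tibble with `n_windows`, `n_units`, `pc1_var_explained`,
#'   `n_dropped_windows`.
#' @export
glance.landscape_pca <- function(x, ...) {
  tibble(
    n_windows = nrow(x$scores),
    n_units = nrow(x$loadings),
    pc1_var_explained = x$var_explained[1],
    n_dropped_windows = length(x$dropped_windows)
  )
}

#' Tidy simulator ground truth
#'
#' @param x a `sim_truth` object (the `truth` element of
#'   [simulate_dataset()]).
#' @param ... unused.
#' @return tibble per window: `window`, `lambda`, `admixed`.
#' @export
tidy.sim_truth <- function(x, ...) {
  nw <- length(x$lambda)
  tibble(
    window = seq_len(nw),
    lambda = x$lambda,
    admixed = seq_len(nw) %in% unlist(x$admixed_windows)
  )
}
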