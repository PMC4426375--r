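#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects: `tidy()` returns
#' the per-component table, `glance()` a one-row summary.
#'
#' @param x A `qtl_scan`, `qtl_peaks`, `fdr_result`, `h2_fit` or
#'   `bubble_classifier`.
#' @param ... Unused.
#' @name riailmap-tidiers
NULL

#' @rdname riailmap-tidiers
#' @export
tidy.fdr_result <- function(x, ...) x$curve

#' @rdname riailmap-tidiers
#' @export
glance.fdr_result <- function(x, ...) {
  tibble(threshold = x$threshold, target_fdr = x$target_fdr,
         n_perm = x$n_perm, n_peaks = nrow(x$peaks), seed = x$seed)
}

#' @rdname riailmap-tidiers
#' @export
tidy.h2_fit <- function(x, ...) {
  tibble(component = c("strain", "residual"),
         variance = c(x$sigma2_strain, x$sigma2_resid))
}

#' @rdname riailmap-tidiers
#' @export
glance.h2_fit <- function(x, ...) {
  tibble(H2 = x$H2, sigma2_strain = x$sigma2_strain,
         sigma2_resid = x$sigma2_resid, n_strains = x$n_strains,
         n_obs = x$n_obs, method = x$method, truncated = x$truncated)
}

#' @rdname riailmap-tidiers
#' @export
tidy.bubble_classifier <- function(x, ...) {
  tibble(feature = names(x$weights), weight = unname(x$weights))
}

#' @rdname riailmap-tidiers
#' @export
glance.bubble_classifier <- function(x, ...) {
  tibble(training_accuracy = x$training_accuracy,
         n_support_vectors = nrow(x$svm$SV))
}

#' @rdname riailmap-tidiers
#' @export
glance.qtl_scan <- function(x, ...) {
  x %>%
    group_by(.data$trait) %>%
    summarise(max_lod = max(.data$lod, na.rm = TRUE),
              peak_marker = .data$marker[which.max(.data$lod)],
              n = first(.data$n), .groups = "drop")
}
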