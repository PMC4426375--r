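#' Broad-sense heritability from repeat measures
#'
#' Fits the random-intercept model `y_ij = mu + s_i + e_ij` (strain `i`,
#' replicate `j`) by REML and returns the variance decomposition:
#' `H2 = sigma2_strain / (sigma2_strain + sigma2_resid)`, the fraction of
#' phenotypic variance explained by strain. Unbalanced designs are supported.
#' If REML fails, a one-way ANOVA method-of-moments estimate is used instead
#' and flagged; negative moment estimates are truncated at zero and flagged,
#' keeping `H2` in \[0, 1\].
#'
#' @param data Tibble with columns `strain` and `value` (one row per
#'   replicate measure).
#' @return List of class `h2_fit`: `sigma2_strain`, `sigma2_resid`, `H2`,
#'   `n_strains`, `n_obs`, `method` (`"reml"` or `"mom"`), `truncated`.
#' @examples
#' d <- tibble::tibble(strain = rep(letters[1:10], each = 3),
#'                     value = rep(rnorm(10), each = 3) + rnorm(30, sd = 0.5))
#' estimate_h2(d)$H2
#' @export
estimate_h2 <- function(data) {
  stopifnot(all(c("strain", "value") %in% names(data)))
  d <- filter(data, is.finite(.data$value))
  reps <- table(d$strain)
  if (length(reps) < 10L) abort("need at least 10 strains")
  if (mean(reps >= 2) < 0.5) {
    abort("need at least 2 replicates for at least half the strains")
  }
  if (all(reps < 2)) abort("variance components unidentifiable: all strains singleton")

  fit <- tryCatch(
    lme4::lmer(value ~ 1 + (1 | strain), data = d, REML = TRUE),
    error = function(e) NULL, warning = function(w) NULL
  )
  truncated <- FALSE
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2s <- vc$vcov[vc$grp == "strain"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    method <- "reml"
  } else {
    mom <- h2_mom(d)
    s2s <- mom$s2s; s2e <- mom$s2e
    truncated <- mom$truncated
    method <- "mom"
  }
  if (s2s <= 0) { s2s <- max(s2s, 0); truncated <- TRUE }
  structure(
    list(sigma2_strain = s2s, sigma2_resid = s2e,
         H2 = s2s / (s2s + s2e),
         n_strains = length(reps), n_obs = nrow(d),
         method = method, truncated = truncated),
    class = "h2_fit"
  )
}

# one-way ANOVA method of moments (Sokal-Rohlf); exact REML match when the
# design is balanced and the estimate is interior
h2_mom <- function(d) {
  k <- table(d$strain)
  a <- length(k)
  N <- sum(k)
  grand <- mean(d$value)
  means <- tapply(d$value, d$strain, mean)
  ss_within <- sum((d$value - means[d$strain])^2)
  ss_among <- sum(k * (means - grand)^2)
  ms_within <- ss_within / (N - a)
  ms_among <- ss_among / (a - 1)
  n0 <- (N - sum(k^2) / N) / (a - 1)
  s2s <- (ms_among - ms_within) / n0
  truncated <- s2s < 0
  list(s2s = max(s2s, 0), s2e = ms_within, truncated = truncated)
}

#' Per-trait heritability table
#'
#' Runs [estimate_h2()] for every trait column of a replicate-level table and
#' reports the components plus the mean H2 across traits.
#'
#' @param data Tibble with `strain`, optionally `condition`, and numeric
#'   trait columns (one row per replicate measure).
#' @param traits Trait columns; defaults to all numeric non-id columns.
#' @return Tibble one row per trait (`trait`, `sigma2_strain`,
#'   `sigma2_resid`, `H2`, `method`); failures propagate as `NA` rows. The
#'   across-trait mean H2 is in `attr(, "mean_H2")`.
#' @export
h2_report <- function(data, traits = NULL) {
  if (is.null(traits)) {
    traits <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      c("rep", "col"))
  }
  rows <- purrr::map_dfr(traits, function(tr) {
    fit <- tryCatch(
      estimate_h2(tibble(strain = data$strain, value = data[[tr]])),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      tibble(trait = tr, sigma2_strain = NA_real_, sigma2_resid = NA_real_,
             H2 = NA_real_, method = NA_character_)
    } else {
      tibble(trait = tr, sigma2_strain = fit$sigma2_strain,
             sigma2_resid = fit$sigma2_resid, H2 = fit$H2, method = fit$method)
    }
  })
  attr(rows, "mean_H2") <- if (nrow(rows) > 0) mean(rows$H2, na.rm = TRUE) else NA_real_
  rows
}

#' @export
print.h2_fit <- function(x, ...) {
  cat("Broad-sense heritability (random strain intercept,", x$method, ")\n")
  cat(sprintf("  sigma2_strain = %.4f  sigma2_resid = %.4f  H2 = %.3f\n",
              x$sigma2_strain, x$sigma2_resid, x$H2))
  cat("  strains:", x$n_strains, " observations:", x$n_obs, "\n")
  if (x$truncated) cat("  note: negative strain variance truncated to 0\n")
  invisible(x)
}
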