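trait_cols_of <- function(data) {
  intersect(trait_columns(), names(data))
}

#' Remove assay-plate and well-position nuisance effects
#'
#' Per trait, ordinary least squares on categorical plate, row and column
#' main effects; the residuals (which keep the trait centred at zero) replace
#' the raw values. The R-squared of each nuisance model is logged in
#' `attr(, "nuisance_r2")`.
#'
#' @param summaries Well-summary tibble ([summarize_wells()] output): columns
#'   `plate_id`, `row`, `col`, `strain`, `condition` and trait columns.
#' @param traits Trait columns to regress; defaults to all recognised trait
#'   columns present.
#' @param covariates Nuisance covariates, any of `plate_id`, `row`, `col`.
#' @return The tibble with trait columns replaced by residuals.
#' @export
regress_nuisance <- function(summaries, traits = trait_cols_of(summaries),
                             covariates = c("plate_id", "row", "col")) {
  covs <- match.arg(covariates, c("plate_id", "row", "col"),
                    several.ok = TRUE)
  varying <- covs[vapply(covs, function(v) length(unique(summaries[[v]])) > 1L,
                         logical(1))]
  if (length(varying) == 0L) {
    abort("degenerate design: plate and position are constant")
  }
  X <- summaries
  for (v in varying) X[[v]] <- factor(X[[v]])
  form <- stats::as.formula(paste("value ~", paste(varying, collapse = " + ")))

  r2 <- numeric(0)
  out <- summaries
  for (tr in traits) {
    X$value <- summaries[[tr]]
    ok <- is.finite(X$value)
    if (sum(ok) == 0L) next
    fit <- lm(form, data = X[ok, , drop = FALSE])
    if (stats::df.residual(fit) <= 0L) {
      abort("saturated nuisance design: one observation per plate/position cell")
    }
    res <- rep(NA_real_, nrow(X))
    res[ok] <- residuals(fit)
    out[[tr]] <- res
    r2[tr] <- summary(fit)$r.squared
  }
  attr(out, "nuisance_r2") <- tibble(trait = names(r2), r2 = unname(r2))
  out
}

#' Aggregate replicate wells per strain
#'
#' Arithmetic mean of replicate values per strain, condition and trait;
#' replicate counts are logged in `attr(, "replicates")`.
#'
#' @param data Well-level tibble with `strain`, `condition` and trait columns.
#' @param traits Trait columns to aggregate.
#' @return One row per strain x condition.
#' @export
aggregate_replicates <- function(data, traits = trait_cols_of(data)) {
  out <- data %>%
    group_by(.data$strain, .data$condition) %>%
    summarise(across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  for (tr in traits) out[[tr]][is.nan(out[[tr]])] <- NA_real_
  reps <- data %>%
    group_by(.data$strain, .data$condition) %>%
    summarise(n_reps = n(), .groups = "drop")
  attr(out, "replicates") <- reps
  out
}

#' Scale traits to zero mean and unit variance
#'
#' Z-scores each trait over its non-missing strains using the population
#' (n-denominator) variance, making "variance of one" exact. Constant traits
#' cannot be scaled and are dropped with a warning.
#'
#' @param data Strain-level tibble with trait columns.
#' @param traits Trait columns to scale.
#' @return The tibble with scaled trait columns.
#' @export
scale_traits <- function(data, traits = trait_cols_of(data)) {
  out <- data
  dropped <- character(0)
  for (tr in traits) {
    x <- out[[tr]]
    ok <- is.finite(x)
    m <- mean(x[ok])
    v <- mean((x[ok] - m)^2)
    if (!is.finite(v) || v == 0) {
      dropped <- c(dropped, tr)
      out[[tr]] <- NULL
      next
    }
    out[[tr]] <- (x - m) / sqrt(v)
  }
  if (length(dropped) > 0L) {
    warn(paste("constant traits dropped:", paste(dropped, collapse = ", ")))
  }
  out
}

#' Residualize treatment traits on their control counterparts
#'
#' For each trait shared by the two tables, fits OLS of the treatment value
#' on the control value across strains and returns the residuals, re-scaled
#' to zero mean and unit variance. This isolates treatment-specific variation
#' so that its QTL are not re-discoveries of control-condition loci. Slopes
#' and R-squared values are logged in `attr(, "regressions")`.
#'
#' @param treatment,control Strain-level tibbles with `strain` and matching
#'   trait columns.
#' @param traits Trait columns to residualize.
#' @return Tibble of residual traits (strains present in both inputs).
#' @export
condition_residuals <- function(treatment, control,
                                traits = intersect(trait_cols_of(treatment),
                                                   trait_cols_of(control))) {
  shared <- intersect(treatment$strain, control$strain)
  if (length(shared) < 10L) abort("need at least 10 overlapping strains")
  tr_ <- treatment[match(shared, treatment$strain), , drop = FALSE]
  ct_ <- control[match(shared, control$strain), , drop = FALSE]
  out <- tibble(strain = shared)
  log <- list()
  for (tr in traits) {
    y <- tr_[[tr]]; x <- ct_[[tr]]
    ok <- is.finite(y) & is.finite(x)
    res <- rep(NA_real_, length(y))
    if (sum(ok) >= 3L) {
      fit <- lm(y[ok] ~ x[ok])
      res[ok] <- residuals(fit)
      # summary() warns on an exactly proportional pair; the zero residuals
      # are still the right answer there
      r2 <- suppressWarnings(summary(fit)$r.squared)
      log[[tr]] <- tibble(trait = tr, slope = coef(fit)[2], r2 = r2)
    }
    out[[tr]] <- res
  }
  # residuals of an exactly proportional pair are identically zero; such
  # degenerate traits are dropped by the rescale with its usual warning
  nonconst <- vapply(traits, function(tr) {
    x <- out[[tr]]; ok <- is.finite(x)
    any(ok) && mean((x[ok] - mean(x[ok]))^2) > 1e-24
  }, logical(1))
  out2 <- scale_traits(out, traits[nonconst])
  for (tr in traits[!nonconst]) out2[[tr]] <- out[[tr]]
  out2 <- out2[, c("strain", traits)]
  attr(out2, "regressions") <- bind_rows(log)
  out2
}
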