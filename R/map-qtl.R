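#' Map QTL for a trait matrix
#'
#' The full linkage-mapping workflow: a joint-permutation FDR threshold
#' ([permutation_fdr()]), iterated conditional scans per trait
#' ([iterative_scan()]), and for every detected peak a 1.5-LOD-drop
#' confidence interval plus the variance explained (and, when heritabilities
#' are supplied, the fraction of heritable variance accounted for).
#'
#' @param genos Imputed genotype tibble.
#' @param traits Strain-level trait tibble (`strain` + numeric trait columns).
#' @param n_perm Permutations for the FDR threshold.
#' @param target_fdr Target FDR (default 0.05).
#' @param seed Integer seed for the permutations.
#' @param h2 Optional named numeric vector of per-trait broad-sense
#'   heritabilities (e.g. `attr(h2_report(...), "mean_H2")` per trait).
#' @param threshold Optional fixed LOD threshold; skips the permutations.
#' @return A `qtl_peaks` tibble: one row per detected QTL with `trait`,
#'   `chrom`, `marker`, `pos_bp`, `lod`, confidence-interval bounds,
#'   `var_explained`, `fraction_h2`. The scan, the FDR result and the
#'   threshold ride along as attributes.
#' @examples
#' map <- sim_genetic_map(120)
#' g <- simulate_cross(cross_design(60, seed = 1), map)
#' y <- simulate_phenotypes(
#'   g, pheno_model(qtl = tibble::tibble(marker = g$marker[60], ve = 0.3),
#'                  h2 = 0.5), seed = 2)
#' tr <- tibble::tibble(strain = unique(y$strain),
#'                      fec = tapply(y$value, y$strain, mean))
#' peaks <- map_qtl(g, tr, n_perm = 100, seed = 3)
#' @export
map_qtl <- function(genos, traits, n_perm = 1000, target_fdr = 0.05,
                    seed = NULL, h2 = NULL, threshold = NULL) {
  fdr <- NULL
  if (is.null(threshold)) {
    fdr <- permutation_fdr(genos, traits, n_perm = n_perm,
                           target_fdr = target_fdr, seed = seed)
    threshold <- fdr$threshold
  }
  scan <- iterative_scan(genos, traits, threshold = threshold)
  peaks <- attr(scan, "peaks")
  if (is.null(peaks) || nrow(peaks) == 0L) {
    out <- tibble(trait = character(0), chrom = character(0),
                  marker = character(0), pos_bp = numeric(0), lod = numeric(0))
  } else {
    Y <- traits_to_matrix(traits)
    out <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
      pk <- peaks[i, ]
      ci <- ci_lod_drop(scan, peak = pk)
      ytr <- Y[, pk$trait]
      ve <- cor(geno_matrix(genos)[names(ytr), pk$marker], ytr,
                use = "complete.obs")^2
      frac <- if (!is.null(h2) && pk$trait %in% names(h2)) {
        min(1, ve / h2[[pk$trait]])
      } else NA_real_
      tibble(trait = pk$trait, chrom = pk$chrom, marker = pk$marker,
             pos_bp = pk$pos_bp, lod = pk$lod,
             ci_lo_marker = ci$ci_lo_marker, ci_hi_marker = ci$ci_hi_marker,
             ci_lo_bp = ci$ci_lo_bp, ci_hi_bp = ci$ci_hi_bp,
             var_explained = ve, fraction_h2 = frac)
    })
  }
  class(out) <- c("qtl_peaks", class(out))
  attr(out, "scan") <- scan
  attr(out, "fdr") <- fdr
  attr(out, "threshold") <- threshold
  out
}
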