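LOG10X2 <- 2 * log(10)

lod_from_r <- function(r, n) -n * log(1 - r^2) / LOG10X2

#' Correlation LOD score at one marker
#'
#' The linkage statistic used throughout: for Pearson correlation `r` between
#' the +1/-1 genotype codes and the trait over `n` complete pairs,
#' `LOD = -n * ln(1 - r^2) / (2 * ln 10)`. Missing values are removed
#' pairwise. Perfect correlation gives `Inf` (flagged with a `"perfect"`
#' attribute); zero genotype or trait variance gives `NA` with a `"reason"`
#' attribute.
#'
#' @param geno Numeric genotype codes (+1 = N2, -1 = CB) for one marker.
#' @param trait Numeric trait values, same strains in the same order.
#' @return The LOD score, with the pair count in `attr(, "n")`.
#' @examples
#' lod_score(c(1, 1, -1, -1), c(2.1, 1.9, -2, -2.2))
#' @export
lod_score <- function(geno, trait) {
  ok <- is.finite(geno) & is.finite(trait)
  n <- sum(ok)
  if (n < 3L) abort("need at least 3 complete genotype-trait pairs")
  g <- geno[ok]; y <- trait[ok]
  if (var(g) == 0) return(structure(NA_real_, reason = "zero genotype variance", n = n))
  if (var(y) == 0) return(structure(NA_real_, reason = "zero trait variance", n = n))
  r <- cor(g, y)
  if (1 - r^2 < 1e-12) {
    return(structure(Inf, perfect = TRUE, n = n))
  }
  out <- -n * log1p(-r^2) / LOG10X2
  attr(out, "n") <- n
  out
}

# vectorized scan core: G strains x markers (complete), Y strains x traits
# (may contain NA; traits with NA fall back to pairwise deletion per marker)
scan_core <- function(G, Y) {
  n_all <- nrow(G)
  lod <- matrix(NA_real_, ncol(G), ncol(Y),
                dimnames = list(colnames(G), colnames(Y)))
  n_used <- integer(ncol(Y))
  complete <- !colSums(is.na(Y))
  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    Gc <- sweep(G, 2, colMeans(G))
    Ycc <- sweep(Yc, 2, colMeans(Yc))
    gs <- sqrt(colSums(Gc^2))
    ys <- sqrt(colSums(Ycc^2))
    r <- crossprod(Gc, Ycc) / outer(gs, ys)
    r[gs == 0, ] <- NA
    r[, ys == 0] <- NA
    r2 <- pmin(r^2, 1)
    lod[, complete] <- -n_all * log1p(-r2) / LOG10X2
    n_used[complete] <- n_all
  }
  for (j in which(!complete)) {
    ok <- is.finite(Y[, j])
    n <- sum(ok)
    n_used[j] <- n
    if (n < 3L) next
    sub <- scan_core(G[ok, , drop = FALSE], Y[ok, j, drop = FALSE])
    lod[, j] <- sub$lod
  }
  list(lod = lod, n = n_used)
}

traits_to_matrix <- function(traits) {
  if (is.numeric(traits)) {
    return(matrix(traits, ncol = 1, dimnames = list(names(traits), "trait")))
  }
  stopifnot("strain" %in% names(traits))
  cols <- setdiff(names(traits), c("strain", "condition"))
  Y <- as.matrix(traits[, cols])
  rownames(Y) <- traits$strain
  storage.mode(Y) <- "double"
  Y
}

#' Genome-wide LOD scan
#'
#' Computes [lod_score()] at every marker for one or many traits. The scan is
#' invariant to swapping the two genotype labels and to affine transforms of
#' the trait. Strains are aligned by name between the genotype and trait
#' tables; missing trait values are dropped pairwise and the per-trait `n`
#' used enters the LOD formula.
#'
#' @param genos Imputed genotype tibble.
#' @param traits Strain-level tibble (`strain` plus numeric trait columns) or
#'   a named numeric vector for a single trait.
#' @return A `qtl_scan` tibble: `trait`, `marker`, `chrom`, `pos_bp`,
#'   `pos_cM`, `lod`, `n`.
#' @export
scan_qtl <- function(genos, traits) {
  G <- geno_matrix(genos)
  Y <- traits_to_matrix(traits)
  shared <- intersect(rownames(G), rownames(Y))
  if (length(shared) < 20L) abort("need at least 20 strains shared between genotypes and traits")
  G <- G[shared, , drop = FALSE]
  if (anyNA(G)) abort("genotypes must be imputed (no NA) before scanning")
  Y <- Y[shared, , drop = FALSE]
  res <- scan_core(G, Y)
  meta <- genos[, c("marker", "chrom", "pos_bp", "pos_cM")]
  out <- purrr::map_dfr(seq_len(ncol(Y)), function(j) {
    mutate(meta, trait = colnames(Y)[j], lod = unname(res$lod[, j]),
           n = res$n[j])
  })
  out <- out[, c("trait", "marker", "chrom", "pos_bp", "pos_cM", "lod", "n")]
  class(out) <- c("qtl_scan", class(out))
  out
}

#' Per-chromosome peak markers above a threshold
#'
#' A peak is the maximum-LOD marker of a (trait, chromosome) pair whose LOD
#' reaches the threshold; ties break to the lowest physical position.
#'
#' @param scan A `qtl_scan` tibble.
#' @param threshold LOD threshold.
#' @return Tibble `trait`, `chrom`, `marker`, `pos_bp`, `pos_cM`, `lod`.
#' @export
find_peaks <- function(scan, threshold) {
  scan %>%
    filter(!is.na(.data$lod)) %>%
    group_by(.data$trait, .data$chrom) %>%
    filter(.data$lod == max(.data$lod), .data$lod >= threshold) %>%
    slice_min(.data$pos_bp, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("trait", "chrom", "marker", "pos_bp", "pos_cM", "lod")
}

#' Iterated conditional scans
#'
#' Repeats the genome scan up to `max_iter` times (default 3): after each
#' pass, the per-chromosome maxima that clear the threshold join the set of
#' detected peaks, the trait is residualized on the genotype codes of all
#' detected peak markers, and the residual is rescanned. This lets a second
#' QTL on an already-occupied chromosome emerge once the first is absorbed.
#' The reported statistic per marker is the maximum LOD across iterations,
#' and iteration stops early when a pass adds no new peak.
#'
#' @param genos Imputed genotype tibble.
#' @param traits Strain-level trait tibble or named vector.
#' @param threshold LOD threshold for declaring peaks between iterations.
#' @param max_iter Maximum scan passes.
#' @return A `qtl_scan` tibble of the combined (max over iterations) LOD,
#'   with detected peaks in `attr(, "peaks")` (including the iteration at
#'   which each was found).
#' @export
iterative_scan <- function(genos, traits, threshold, max_iter = 3) {
  stopifnot(threshold >= 0)
  Y <- traits_to_matrix(traits)
  G <- geno_matrix(genos)
  shared <- intersect(rownames(G), rownames(Y))
  G <- G[shared, , drop = FALSE]

  combined <- NULL
  all_peaks <- list()
  for (tr in colnames(Y)) {
    y <- Y[shared, tr]
    peaks_tr <- NULL
    best <- NULL
    for (it in seq_len(max_iter)) {
      ytbl <- tibble(strain = shared, value = y)
      names(ytbl)[2] <- tr
      sc <- scan_qtl(genos, ytbl)
      best <- if (is.null(best)) sc else
        mutate(best, lod = pmax(.data$lod, sc$lod, na.rm = TRUE))
      pk <- find_peaks(sc, threshold)
      pk <- pk[!pk$marker %in% peaks_tr$marker, , drop = FALSE]
      if (nrow(pk) == 0L) break
      pk$iteration <- it
      peaks_tr <- bind_rows(peaks_tr, pk)
      if (it == max_iter) break
      # residualize the original trait on all detected peak genotypes
      X <- cbind(1, G[, unique(peaks_tr$marker), drop = FALSE])
      y0 <- Y[shared, tr]
      ok <- is.finite(y0)
      y <- rep(NA_real_, length(y0))
      y[ok] <- stats::lm.fit(X[ok, , drop = FALSE], y0[ok])$residuals
    }
    all_peaks[[tr]] <- peaks_tr
    combined <- bind_rows(combined, best)
  }
  class(combined) <- c("qtl_scan", class(combined))
  attr(combined, "peaks") <- bind_rows(all_peaks)
  attr(combined, "threshold") <- threshold
  combined
}

#' 1.5-LOD-drop confidence interval
#'
#' The maximal contiguous run of markers containing the peak whose LOD stays
#' within 1.5 of the peak LOD, reported with marker ids and physical bounds.
#'
#' @param scan A `qtl_scan` tibble (one trait).
#' @param trait,chrom Which profile to use; defaulted from the peak row when
#'   `peak` is given.
#' @param peak Optional one-row tibble from [find_peaks()].
#' @param drop LOD drop defining the interval (default 1.5).
#' @return One-row tibble: `trait`, `chrom`, `peak_marker`, `peak_lod`,
#'   `ci_lo_marker`, `ci_hi_marker`, `ci_lo_bp`, `ci_hi_bp`, `n_markers`.
#' @export
ci_lod_drop <- function(scan, trait = NULL, chrom = NULL, peak = NULL,
                        drop = 1.5) {
  if (!is.null(peak)) {
    trait <- peak$trait; chrom <- peak$chrom
  }
  prof <- scan %>%
    filter(.data$trait == !!trait, .data$chrom == !!chrom) %>%
    arrange(.data$pos_bp)
  if (nrow(prof) == 0L) abort("no markers for that trait/chromosome")
  lod <- prof$lod
  lod[!is.finite(lod) & !is.infinite(lod)] <- -Inf
  ipk <- if (!is.null(peak)) match(peak$marker, prof$marker) else which.max(lod)
  keep <- lod >= lod[ipk] - drop
  # contiguous run containing the peak
  lo <- ipk
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- ipk
  while (hi < length(keep) && keep[hi + 1L]) hi <- hi + 1L
  tibble(
    trait = trait, chrom = chrom,
    peak_marker = prof$marker[ipk], peak_lod = lod[ipk],
    ci_lo_marker = prof$marker[lo], ci_hi_marker = prof$marker[hi],
    ci_lo_bp = prof$pos_bp[lo], ci_hi_bp = prof$pos_bp[hi],
    n_markers = hi - lo + 1L
  )
}

#' Variance explained by a QTL and its share of heritability
#'
#' The variance explained is the squared marker-trait correlation on the
#' scaled trait; dividing by the broad-sense heritability gives the fraction
#' of the heritable variance the QTL accounts for (capped at 1 with a
#' warning, since a winner's-curse-inflated estimate can exceed it).
#'
#' @param genos Imputed genotype tibble.
#' @param traits Strain-level trait tibble or named vector (one trait).
#' @param marker Peak marker id.
#' @param h2 Broad-sense heritability of the trait (> 0).
#' @return Tibble `marker`, `var_explained`, `fraction_h2`.
#' @export
variance_explained <- function(genos, traits, marker, h2) {
  if (h2 <= 0) abort("h2 must be positive")
  Y <- traits_to_matrix(traits)
  G <- geno_matrix(genos)
  if (!marker %in% colnames(G)) abort("marker not found")
  shared <- intersect(rownames(G), rownames(Y))
  g <- G[shared, marker]
  y <- Y[shared, 1]
  ok <- is.finite(g) & is.finite(y)
  ve <- cor(g[ok], y[ok])^2
  frac <- ve / h2
  if (frac > 1) {
    warn("variance explained exceeds heritability; fraction capped at 1")
    frac <- 1
  }
  tibble(marker = marker, var_explained = ve, fraction_h2 = frac)
}
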