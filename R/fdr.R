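chrom_maxima <- function(lod_mat, chrom_index) {
  # lod_mat: markers x traits; returns (n_chrom*traits) maxima as a matrix
  rowsum_max <- lapply(chrom_index, function(rows) {
    apply(lod_mat[rows, , drop = FALSE], 2, max, na.rm = TRUE)
  })
  do.call(rbind, rowsum_max)   # chrom x traits
}

#' Joint-permutation FDR threshold for LOD peaks
#'
#' Estimates the genome-wide LOD threshold that controls the false discovery
#' rate over all (trait, chromosome) peaks at `target_fdr`. Each of the
#' `n_perm` permutations applies one shared row permutation to the whole
#' trait matrix - preserving the correlation structure among traits - and
#' reruns the per-chromosome-maximum scan for every trait. A peak at
#' candidate threshold `T` is a (trait, chromosome) maximum `>= T`; the
#' expected count is the permutation mean, and `FDR(T)` is expected/observed.
#' The selected threshold is the smallest `T` on a 0.01-LOD grid whose FDR is
#' defined (observed > 0) and `<= target_fdr`; if no grid point qualifies the
#' threshold escalates to just above the largest observed peak, so nothing is
#' called.
#'
#' @param genos Imputed genotype tibble.
#' @param traits Strain-level trait tibble (>= 2 traits make the shared
#'   permutation meaningful; a single trait is allowed and degenerate).
#' @param n_perm Number of permutations (default 1000; < 100 draws a warning).
#' @param target_fdr Target false discovery rate (default 0.05).
#' @param seed Integer seed (mandatory: permutation results enter the
#'   record).
#' @param grid Candidate thresholds (default `seq(1, 6, 0.01)`).
#' @param chunk Permutations evaluated per matrix multiplication (memory
#'   knob).
#' @return An `fdr_result` list: `curve` (tibble `threshold`, `observed`,
#'   `expected`, `fdr`), `threshold`, `peaks` (observed peaks at the selected
#'   threshold), `n_perm`, `seed`.
#' @export
permutation_fdr <- function(genos, traits, n_perm = 1000, target_fdr = 0.05,
                            seed, grid = seq(1, 6, by = 0.01), chunk = 100L) {
  if (missing(seed) || is.null(seed)) abort("a seed is required for the permutation record")
  if (n_perm < 100) warn("fewer than 100 permutations: FDR estimates will be noisy")
  set.seed(seed)

  G <- geno_matrix(genos)
  Y <- traits_to_matrix(traits)
  shared <- intersect(rownames(G), rownames(Y))
  G <- G[shared, , drop = FALSE]
  Y <- Y[shared, , drop = FALSE]
  if (anyNA(G)) abort("genotypes must be imputed (no NA) before scanning")
  n <- nrow(G); p <- ncol(Y)

  chrom_index <- map_chrom_split(genos)
  Gc <- sweep(G, 2, colMeans(G))
  gs <- sqrt(colSums(Gc^2))

  lod_of <- function(Ymat) {
    Yc <- sweep(Ymat, 2, colMeans(Ymat))
    ys <- sqrt(colSums(Yc^2))
    r <- crossprod(Gc, Yc) / outer(gs, ys)
    r[gs == 0, ] <- NA
    -n * log1p(-pmin(r^2, 1)) / LOG10X2
  }

  if (anyNA(Y)) {
    # pairwise deletion is incompatible with one shared permutation; strains
    # with any missing trait are dropped for threshold estimation
    keep <- stats::complete.cases(Y)
    G <- G[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
    n <- nrow(G)
    Gc <- sweep(G, 2, colMeans(G))
    gs <- sqrt(colSums(Gc^2))
  }

  obs_max <- as.vector(chrom_maxima(lod_of(Y), chrom_index))   # trait x chrom maxima
  observed <- vapply(grid, function(t_) sum(obs_max >= t_), numeric(1))

  exp_counts <- numeric(length(grid))
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    perms <- replicate(k, sample.int(n))
    bigY <- Y[as.vector(perms), , drop = FALSE]
    # reshape: k stacked permuted copies -> n x (p*k)
    bigY <- matrix(bigY, nrow = n)          # column-major: perm-major blocks
    dim(bigY) <- c(n, p * k)
    lods <- lod_of(bigY)
    mx <- chrom_maxima(lods, chrom_index)   # chrom x (p*k)
    for (i in seq_along(grid)) {
      exp_counts[i] <- exp_counts[i] + sum(mx >= grid[i])
    }
    done <- done + k
  }
  expected <- exp_counts / n_perm
  fdr <- ifelse(observed > 0, expected / observed, NA_real_)

  ok <- !is.na(fdr) & fdr <= target_fdr
  threshold <- if (any(ok)) grid[which(ok)[1]] else max(obs_max) + 0.01

  curve <- tibble(threshold = grid, observed = observed,
                  expected = expected, fdr = fdr)
  sc <- scan_qtl(genos, traits)
  structure(
    list(curve = curve, threshold = threshold,
         peaks = find_peaks(sc, threshold),
         target_fdr = target_fdr, n_perm = n_perm, seed = seed),
    class = "fdr_result"
  )
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("Permutation FDR threshold\n")
  cat("  permutations:", x$n_perm, " target FDR:", x$target_fdr, "\n")
  cat("  selected LOD threshold:", format(x$threshold), "\n")
  cat("  peaks called:", nrow(x$peaks), "\n")
  invisible(x)
}
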