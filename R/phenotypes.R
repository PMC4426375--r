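#' Specify a phenotype-generating model
#'
#' Parameterizes the synthetic phenotypes: planted additive QTL, broad-sense
#' heritability, replicate structure, and the sorter-level observation model
#' used by [simulate_well_events()].
#'
#' All variances are on the scale of a unit-variance trait: each planted QTL
#' is given as the fraction `ve` of total phenotypic variance it explains
#' (its additive effect on the +1/-1 genotype code is `sqrt(ve)`), a strain-
#' level polygenic background brings the total genetic variance up to `h2`,
#' and replicate-level noise supplies the remaining `1 - h2`.
#'
#' @param qtl Tibble of planted QTL with columns `marker` and `ve` (fraction
#'   of phenotypic variance), or `NULL` for none.
#' @param h2 Target broad-sense heritability in (0, 1]. Must be at least
#'   `sum(qtl$ve)`.
#' @param n_reps Replicates per strain.
#' @param stage_qtl Optional tibble (`marker`, `effect`) of loci that shift
#'   developmental-stage occupancy (log-odds of the oldest stage class).
#' @param stage_probs Baseline occupancy of the five stage classes (L1-L4 and
#'   young adult); must sum to 1.
#' @param tof_mean,tof_sd Per-stage time-of-flight (body length) normal
#'   parameters, instrument units.
#' @param brood_mean,brood_effect Baseline expected offspring per well and the
#'   change in that expectation per unit of the (unit-variance) fecundity
#'   value.
#' @param ext_slope Slope of optical density (EXT) on TOF.
#' @param thickness_sd Per-animal relative thickness variation multiplying the
#'   EXT slope.
#' @param ext_sd Additive EXT measurement noise, instrument units.
#' @param bubble_rate Expected fraction of emitted objects that are bubbles.
#' @return A list of class `pheno_model`.
#' @export
pheno_model <- function(qtl = NULL,
                        h2 = 0.5,
                        n_reps = 1,
                        stage_qtl = NULL,
                        stage_probs = c(0.10, 0.20, 0.30, 0.25, 0.15),
                        tof_mean = c(80, 120, 170, 240, 320),
                        tof_sd = 0.10 * tof_mean,
                        brood_mean = 25,
                        brood_effect = 5,
                        ext_slope = 1.2,
                        thickness_sd = 0.05,
                        ext_sd = 8,
                        bubble_rate = 0.02) {
  if (h2 <= 0 || h2 > 1) abort("h2 must lie in (0, 1]")
  if (!is.null(qtl)) {
    stopifnot(all(c("marker", "ve") %in% names(qtl)))
    if (any(qtl$ve < 0)) abort("QTL variance fractions must be non-negative")
    if (sum(qtl$ve) > h2 + 1e-12) {
      abort("planted QTL variance exceeds the target heritability")
    }
  }
  if (abs(sum(stage_probs) - 1) > 1e-8) abort("stage_probs must sum to 1")
  if (bubble_rate < 0 || bubble_rate >= 1) abort("bubble_rate must lie in [0, 1)")
  structure(
    list(qtl = qtl, h2 = h2, n_reps = as.integer(n_reps),
         stage_qtl = stage_qtl, stage_probs = stage_probs,
         tof_mean = tof_mean, tof_sd = tof_sd,
         brood_mean = brood_mean, brood_effect = brood_effect,
         ext_slope = ext_slope, thickness_sd = thickness_sd, ext_sd = ext_sd,
         bubble_rate = bubble_rate),
    class = "pheno_model"
  )
}

qtl_effects <- function(genos, qtl) {
  G <- geno_matrix(genos)
  miss <- setdiff(qtl$marker, colnames(G))
  if (length(miss) > 0L) {
    abort(paste("planted QTL markers absent from genotypes:",
                paste(miss, collapse = ", ")))
  }
  codes <- G[, qtl$marker, drop = FALSE]
  drop(codes %*% sqrt(qtl$ve))
}

#' Simulate replicate phenotypes with known architecture
#'
#' Draws per-strain, per-replicate trait values from the additive model of
#' [pheno_model()]: strain value = planted QTL effects + polygenic strain
#' noise; each replicate adds residual noise. Noise variances are set so the
#' expected broad-sense heritability equals the model's `h2` (genotype codes
#' have variance ~1 in an unselected panel).
#'
#' @param genos Genotype tibble containing all planted QTL markers.
#' @param model A [pheno_model()].
#' @param seed Integer seed.
#' @return Tibble with columns `strain`, `rep`, `value` and the latent
#'   `genetic_value` (QTL + polygenic strain effect).
#' @examples
#' map <- sim_genetic_map(60)
#' g <- simulate_cross(cross_design(40, seed = 1), map)
#' m <- pheno_model(qtl = tibble::tibble(marker = g$marker[10], ve = 0.2),
#'                  h2 = 0.6, n_reps = 2)
#' simulate_phenotypes(g, m, seed = 2)
#' @export
simulate_phenotypes <- function(genos, model, seed = NULL) {
  stopifnot(inherits(model, "pheno_model"))
  if (!is.null(seed)) set.seed(seed)
  strains <- genotype_strains(genos)
  n <- length(strains)
  v_qtl <- if (is.null(model$qtl)) 0 else sum(model$qtl$ve)
  g_qtl <- if (is.null(model$qtl)) rep(0, n) else qtl_effects(genos, model$qtl)
  v_bg <- model$h2 - v_qtl
  v_res <- 1 - model$h2
  genetic <- g_qtl + rnorm(n, sd = sqrt(max(v_bg, 0)))
  out <- tidyr::expand_grid(strain = strains, rep = seq_len(model$n_reps))
  out$genetic_value <- rep(genetic, each = model$n_reps)
  out$value <- out$genetic_value + rnorm(nrow(out), sd = sqrt(max(v_res, 0)))
  out[, c("strain", "rep", "value", "genetic_value")]
}

#' Simulate a correlated multi-trait panel
#'
#' Emulates the strain x trait matrix produced by a high-throughput sorter
#' assay: 25 traits (one fecundity measure plus three size parameters times
#' eight summary statistics) organised in blocks of strongly correlated
#' traits, a subset of which carry planted QTL. Traits from the same size
#' parameter share both genetic background and measurement error, which the
#' block factor captures; each trait has unit total variance.
#'
#' @param genos Genotype tibble.
#' @param qtl `"default"` for five planted loci of 8-12% variance on
#'   chromosomes I-V, `NULL` for a pure noise panel, or a tibble with columns
#'   `block`, `marker`, `ve`. A locus acts on every trait of its block -
#'   summary statistics of the same underlying size distribution detect the
#'   same loci, so one real locus surfaces as a set of peaks across its
#'   correlated traits.
#' @param blocks Integer block id per trait; defaults to fecundity plus three
#'   blocks of eight summary statistics.
#' @param block_cor Within-block correlation of the non-genetic part (shared
#'   biology plus shared measurement, since a block's statistics summarise
#'   the same animals).
#' @param seed Integer seed.
#' @return Tibble `strain` x 25 trait columns (`t01`..`t25`), with the planted
#'   truth in `attr(, "qtl")`.
#' @export
sim_trait_panel <- function(genos,
                            qtl = "default",
                            blocks = c(1L, rep(2L, 8), rep(3L, 8), rep(4L, 8)),
                            block_cor = 0.8,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strains <- genotype_strains(genos)
  n <- length(strains)
  p <- length(blocks)
  if (identical(qtl, "default")) qtl <- default_panel_qtl(genos)
  if (!is.null(qtl)) stopifnot(all(c("block", "marker", "ve") %in% names(qtl)))
  if (block_cor < 0 || block_cor >= 1) abort("block_cor must lie in [0, 1)")

  # per-block genetic value and its variance
  gval <- matrix(0, n, max(blocks))
  vg <- rep(0, max(blocks))
  if (!is.null(qtl)) {
    G <- geno_matrix(genos)
    for (k in seq_len(nrow(qtl))) {
      b <- qtl$block[k]
      gval[, b] <- gval[, b] + G[strains, qtl$marker[k]] * sqrt(qtl$ve[k])
      vg[b] <- vg[b] + qtl$ve[k]
    }
    if (any(vg >= 1)) abort("planted variance per block must stay below 1")
  }

  # trait = block QTL value + sqrt(1 - ve_block) * (shared factor + idio):
  # unit total variance; null within-block correlation = block_cor
  fac <- matrix(rnorm(n * max(blocks)), n, max(blocks))
  Y <- sapply(seq_len(p), function(j) {
    b <- blocks[j]
    gval[, b] + sqrt(1 - vg[b]) *
      (sqrt(block_cor) * fac[, b] + rnorm(n, sd = sqrt(1 - block_cor)))
  })
  colnames(Y) <- sprintf("t%02d", seq_len(p))
  out <- bind_cols(tibble(strain = strains), as_tibble(Y))
  attr(out, "qtl") <- qtl
  attr(out, "blocks") <- blocks
  out
}

#' @rdname sim_trait_panel
#' @export
default_panel_qtl <- function(genos) {
  mid_marker <- function(chr) {
    rows <- which(genos$chrom == chr)
    if (length(rows) == 0L) abort(paste("no markers on chromosome", chr))
    genos$marker[rows[ceiling(length(rows) / 2)]]
  }
  tibble(
    block = c(1L, 2L, 3L, 4L, 4L),
    marker = vapply(c("IV", "I", "II", "III", "V"), mid_marker, character(1)),
    ve = c(0.12, 0.10, 0.08, 0.10, 0.09)
  )
}
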