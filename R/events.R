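#' Build a 96-well plate layout
#'
#' Assigns strains to wells of an 8 x 12 plate, with designated wash columns
#' (wells that contain buffer only, used between genotypes to limit
#' carry-over). Strains are filled column-major into the non-wash wells,
#' recycling if fewer strains than wells are given.
#'
#' @param strains Character vector of strain names to plate.
#' @param plate_id Plate identifier.
#' @param condition Condition label (e.g. `"control"` or `"paraquat"`).
#' @param wash_cols Columns containing wash wells (default 4, 8, 12).
#' @return Tibble with columns `plate_id`, `row`, `col`, `strain`,
#'   `condition`, `wash`.
#' @export
plate_layout <- function(strains, plate_id = "p1", condition = "control",
                         wash_cols = c(4L, 8L, 12L)) {
  grid <- tidyr::expand_grid(col = 1:12, row = LETTERS[1:8]) %>%
    mutate(wash = .data$col %in% wash_cols)
  usable <- which(!grid$wash)
  strain <- rep(NA_character_, nrow(grid))
  strain[usable] <- rep_len(strains, length(usable))
  grid %>%
    mutate(plate_id = plate_id, strain = strain, condition = condition) %>%
    select("plate_id", "row", "col", "strain", "condition", "wash")
}

# A stage-occupancy shift redistributes mass between the two oldest stage
# classes only (faster/slower maturation into adulthood); the absolute
# occupancies of the younger stages are untouched, so a late-stage locus
# moves the upper quantiles of the length distribution without disturbing
# the lower ones.
sample_stages <- function(k, probs, shift) {
  p <- probs
  s <- length(p)
  top <- p[s - 1L] + p[s]
  frac_adult <- stats::plogis(stats::qlogis(p[s] / top) + shift)
  p[s] <- top * frac_adult
  p[s - 1L] <- top - p[s]
  sample.int(s, k, replace = TRUE, prob = p)
}

#' Simulate a sorter event file for one plate
#'
#' Emulates the flat event table a large-particle sorter emits for a 96-well
#' plate: each well holds the offspring of one hermaphrodite, each animal gets
#' a developmental stage (older stages are longer), a TOF draw from its
#' stage's normal, and EXT proportional to TOF with thickness variation and
#' noise. Bubbles, which are optically thin for their size, are injected at
#' the model's contamination rate; wash wells contain only bubbles.
#'
#' @param latent Tibble with columns `strain` and `value` (unit-variance
#'   fecundity value, e.g. from [simulate_phenotypes()]), and optionally
#'   `stage_shift` (log-odds shift of the oldest stage class, e.g. a
#'   stage-QTL effect).
#' @param model A [pheno_model()].
#' @param layout A [plate_layout()] tibble.
#' @param seed Integer seed; fixed seeds give byte-identical event tables.
#' @return Event tibble with columns `plate_id`, `row`, `col`, `TOF`, `EXT`,
#'   `green`, `yellow`, `red` and a hidden truth column `truth`
#'   (`"animal"`/`"bubble"`) for tests.
#' @export
simulate_well_events <- function(latent, model, layout, seed = NULL) {
  stopifnot(inherits(model, "pheno_model"))
  if (!is.null(seed)) set.seed(seed)
  missing_strains <- setdiff(stats::na.omit(layout$strain), latent$strain)
  if (length(missing_strains) > 0L) {
    abort(paste("layout strains without phenotypes:",
                paste(unique(missing_strains), collapse = ", ")))
  }
  if (!"stage_shift" %in% names(latent)) latent$stage_shift <- 0

  wells <- layout %>%
    left_join(latent, by = "strain") %>%
    arrange(.data$plate_id, .data$col, .data$row)

  one_well <- function(plate_id, row, col, wash, value, stage_shift) {
    if (wash || is.na(value)) {
      n_animal <- 0L
      n_bubble <- if (model$bubble_rate > 0) rpois(1L, 3) else 0L
    } else {
      mu <- max(0, model$brood_mean + model$brood_effect * value)
      n_animal <- rpois(1L, mu)
      n_bubble <- if (model$bubble_rate > 0) {
        rpois(1L, model$bubble_rate / (1 - model$bubble_rate) * max(n_animal, 1L))
      } else 0L
    }
    if (n_animal + n_bubble == 0L) return(NULL)
    if (n_animal > 0L) {
      stage <- sample_stages(n_animal, model$stage_probs, stage_shift)
      tof_a <- pmax(20, rnorm(n_animal, model$tof_mean[stage], model$tof_sd[stage]))
      thick <- rnorm(n_animal, 0, model$thickness_sd)
      ext_a <- pmax(0, model$ext_slope * tof_a * (1 + thick) + rnorm(n_animal, 0, model$ext_sd))
    } else {
      tof_a <- ext_a <- numeric(0)
    }
    if (n_bubble > 0L) {
      tof_b <- runif(n_bubble, 100, 1200)
      ext_b <- pmax(0, 0.15 * tof_b + rnorm(n_bubble, 0, 5))
    } else {
      tof_b <- ext_b <- numeric(0)
    }
    k <- n_animal + n_bubble
    tibble(
      plate_id = plate_id, row = row, col = col,
      TOF = c(tof_a, tof_b), EXT = c(ext_a, ext_b),
      green = abs(rnorm(k, 5, 2)), yellow = abs(rnorm(k, 5, 2)),
      red = abs(rnorm(k, 8, 3)),
      truth = rep(c("animal", "bubble"), c(n_animal, n_bubble))
    )
  }

  out <- purrr::pmap(
    list(wells$plate_id, wells$row, wells$col, wells$wash,
         wells$value, wells$stage_shift),
    one_well
  )
  bind_rows(out)
}

#' Stage-occupancy shifts from genotype
#'
#' Computes the per-strain log-odds shift of the oldest developmental stage
#' implied by the model's stage QTL (effect x +1/-1 genotype code, summed over
#' loci), for use as the `stage_shift` column of [simulate_well_events()].
#'
#' @param genos Genotype tibble.
#' @param stage_qtl Tibble with columns `marker`, `effect`.
#' @return Tibble `strain`, `stage_shift`.
#' @export
stage_shifts <- function(genos, stage_qtl) {
  G <- geno_matrix(genos)
  miss <- setdiff(stage_qtl$marker, colnames(G))
  if (length(miss) > 0L) abort("stage QTL markers absent from genotypes")
  shift <- drop(G[, stage_qtl$marker, drop = FALSE] %*% stage_qtl$effect)
  tibble(strain = rownames(G), stage_shift = shift)
}

#' Parameters for simulated SNP intensity data
#'
#' One-dimensional cluster model for array genotyping intensities: each
#' genotype draws from its cluster's normal; a `missing_rate` fraction of
#' values is replaced by uniform draws in a narrow band around the midpoint
#' between the cluster means (failed hybridization gives signal for neither
#' allele, landing between the clusters); a `label_noise` fraction draws from
#' the wrong cluster.
#'
#' @param mean_N2,mean_CB Cluster means (must differ).
#' @param sd_N2,sd_CB Cluster standard deviations (> 0).
#' @param missing_rate,label_noise Rates in \[0, 1\].
#' @return List of class `intensity_sim_params`.
#' @export
intensity_sim_params <- function(mean_N2 = 0.1, mean_CB = 0.9,
                                 sd_N2 = 0.05, sd_CB = 0.05,
                                 missing_rate = 0.01, label_noise = 0) {
  if (mean_N2 == mean_CB) abort("cluster means must be distinct")
  if (sd_N2 <= 0 || sd_CB <= 0) abort("cluster sds must be positive")
  if (missing_rate < 0 || missing_rate > 1 || label_noise < 0 || label_noise > 1) {
    abort("rates must lie in [0, 1]")
  }
  structure(list(mean_N2 = mean_N2, mean_CB = mean_CB,
                 sd_N2 = sd_N2, sd_CB = sd_CB,
                 missing_rate = missing_rate, label_noise = label_noise),
            class = "intensity_sim_params")
}

#' Simulate SNP intensities from a genotype panel
#'
#' @param genos Genotype tibble (the truth).
#' @param params An [intensity_sim_params()].
#' @param seed Integer seed.
#' @return Intensity tibble shaped like the genotype table but with numeric
#'   values in the strain columns. The truth calls are kept in
#'   `attr(, "truth")`; masks of disturbed cells are in `attr(, "missing_mask")`
#'   and `attr(, "noised_mask")` (markers x strains logical matrices).
#' @export
simulate_intensities <- function(genos, params, seed = NULL) {
  stopifnot(inherits(params, "intensity_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  strains <- genotype_strains(genos)
  truth <- as.matrix(genos[, strains])
  is_n2 <- truth == "N2"

  noised <- matrix(runif(length(truth)) < params$label_noise, nrow(truth))
  use_n2 <- xor(is_n2, noised)
  vals <- matrix(rnorm(length(truth),
                       mean = ifelse(use_n2, params$mean_N2, params$mean_CB),
                       sd = ifelse(use_n2, params$sd_N2, params$sd_CB)),
                 nrow(truth))
  missing <- matrix(runif(length(truth)) < params$missing_rate, nrow(truth))
  lo <- min(params$mean_N2, params$mean_CB)
  hi <- max(params$mean_N2, params$mean_CB)
  mid <- (lo + hi) / 2
  vals[missing] <- runif(sum(missing), mid - 0.05 * (hi - lo), mid + 0.05 * (hi - lo))
  colnames(vals) <- strains

  out <- bind_cols(genos[, c("marker", "chrom", "pos_bp", "pos_cM")],
                   as_tibble(vals))
  attr(out, "truth") <- truth
  attr(out, "missing_mask") <- missing
  attr(out, "noised_mask") <- noised
  out
}
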