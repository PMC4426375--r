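#' Impute missing genotypes with a two-state HMM
#'
#' Per chromosome, a hidden Markov model over the two parental states fills
#' every `NA` call by posterior decoding. The transition probability between
#' adjacent markers is the empirical discordance rate between adjacent
#' observed calls across strains (floored at 1e-4 and capped at 0.45), so the
#' model adapts to the panel's realized recombination density rather than
#' assuming a theoretical map expansion. Emission: an observed call equals
#' the hidden state with probability `1 - epsilon`; `NA` is uninformative.
#' Observed calls are overturned only when their posterior falls below
#' `1 - epsilon`; such flips are logged.
#'
#' @param genos Genotype tibble (markers map-ordered within chromosome).
#' @param cfg A [calling_config()]; only `epsilon` is used.
#' @return Genotype tibble with no `NA` at markers that had any information
#'   (a strain-chromosome with zero observed calls stays `NA` and is listed
#'   in `attr(, "uninformative")`). Flipped calls are in `attr(, "flips")`.
#' @examples
#' map <- sim_genetic_map(60)
#' g <- simulate_cross(cross_design(30, seed = 1), map)
#' g[[5]][3] <- NA   # knock out one call
#' imp <- hmm_impute(g)
#' imp[[5]][3]
#' @export
hmm_impute <- function(genos, cfg = calling_config()) {
  eps <- cfg$epsilon
  strains <- genotype_strains(genos)
  calls <- as.matrix(genos[, strains])          # markers x strains
  state <- matrix(NA_integer_, nrow(calls), ncol(calls))
  state[calls == "N2"] <- 1L
  state[calls == "CB"] <- 2L

  out_state <- state
  flips <- list()
  uninformative <- list()

  for (rows in map_chrom_split(genos)) {
    obs <- state[rows, , drop = FALSE]          # L x S, 1/2/NA
    L <- nrow(obs); S <- ncol(obs)
    if (L == 1L) {
      # single marker: nothing to borrow; majority state fills NAs
      maj <- if (sum(obs == 1L, na.rm = TRUE) >= sum(obs == 2L, na.rm = TRUE)) 1L else 2L
      fill <- is.na(obs)
      out_state[rows, ][fill] <- maj
      next
    }
    # empirical discordance between adjacent markers over strains observed at
    # both, with an add-half pseudo-count so a zero-discordance interval in a
    # finite panel is not taken as literally recombination-free
    trans <- vapply(seq_len(L - 1L), function(i) {
      a <- obs[i, ]; b <- obs[i + 1L, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) 0.01 else (sum(a[ok] != b[ok]) + 0.5) / (sum(ok) + 1)
    }, numeric(1))
    trans <- pmin(pmax(trans, 1e-4), 0.45)

    # emission likelihoods, L x S per state
    e1 <- matrix(1, L, S); e2 <- matrix(1, L, S)
    e1[obs == 1L] <- 1 - eps; e1[obs == 2L] <- eps
    e2[obs == 2L] <- 1 - eps; e2[obs == 1L] <- eps

    # forward-backward vectorized across strains
    a1 <- 0.5 * e1[1L, ]; a2 <- 0.5 * e2[1L, ]
    sc <- a1 + a2
    alpha1 <- matrix(0, L, S); alpha2 <- matrix(0, L, S)
    alpha1[1L, ] <- a1 / sc; alpha2[1L, ] <- a2 / sc
    for (i in 2:L) {
      t_ <- trans[i - 1L]
      p1 <- alpha1[i - 1L, ] * (1 - t_) + alpha2[i - 1L, ] * t_
      p2 <- alpha1[i - 1L, ] * t_ + alpha2[i - 1L, ] * (1 - t_)
      a1 <- p1 * e1[i, ]; a2 <- p2 * e2[i, ]
      sc <- a1 + a2
      alpha1[i, ] <- a1 / sc; alpha2[i, ] <- a2 / sc
    }
    beta1 <- matrix(1, L, S); beta2 <- matrix(1, L, S)
    for (i in (L - 1L):1L) {
      t_ <- trans[i]
      b1n <- beta1[i + 1L, ] * e1[i + 1L, ]
      b2n <- beta2[i + 1L, ] * e2[i + 1L, ]
      b1 <- (1 - t_) * b1n + t_ * b2n
      b2 <- t_ * b1n + (1 - t_) * b2n
      sc <- b1 + b2
      beta1[i, ] <- b1 / sc; beta2[i, ] <- b2 / sc
    }
    g1 <- alpha1 * beta1
    g2 <- alpha2 * beta2
    post1 <- g1 / (g1 + g2)

    dec <- ifelse(post1 >= 0.5, 1L, 2L)
    new_state <- obs
    # fill NAs by max posterior
    new_state[is.na(obs)] <- dec[is.na(obs)]
    # overturn an observed call only when its posterior is below 1 - eps AND
    # the other state is strongly supported: an isolated discordant call is
    # indistinguishable from a genuine double recombinant, and near-even
    # posteriors should not erase real recombination events
    obs_post <- ifelse(obs == 1L, post1, 1 - post1)
    flip <- !is.na(obs) & obs_post < 1 - eps & (1 - obs_post) > 0.8
    new_state[flip] <- dec[flip]
    if (any(flip)) {
      idx <- which(flip, arr.ind = TRUE)
      flips[[length(flips) + 1L]] <- tibble(
        marker = genos$marker[rows[idx[, 1]]],
        strain = strains[idx[, 2]],
        from = c("N2", "CB")[obs[flip]],
        to = c("N2", "CB")[new_state[flip]]
      )
    }
    # strain-chromosomes with zero observed calls carry no information
    empty <- colSums(!is.na(obs)) == 0L
    if (any(empty)) {
      new_state[, empty] <- NA_integer_
      uninformative[[length(uninformative) + 1L]] <- tibble(
        strain = strains[empty], chrom = genos$chrom[rows[1L]]
      )
    }
    out_state[rows, ] <- new_state
  }

  out_calls <- matrix(c("N2", "CB")[out_state], nrow(calls),
                      dimnames = list(NULL, strains))
  out <- bind_cols(genos[, c("marker", "chrom", "pos_bp", "pos_cM")],
                   as_tibble(out_calls))
  class(out) <- c("genotype_tbl", class(out))
  attr(out, "flips") <- if (length(flips)) bind_rows(flips) else
    tibble(marker = character(0), strain = character(0),
           from = character(0), to = character(0))
  attr(out, "uninformative") <- if (length(uninformative)) bind_rows(uninformative) else
    tibble(strain = character(0), chrom = character(0))
  out
}

#' Full calling pipeline
#'
#' [call_genotypes()], then [allele_frequency_filter()], then [hmm_impute()],
#' in that order (frequency skews are removed before they can distort the
#' imputation).
#'
#' @inheritParams call_genotypes
#' @return Imputed genotype tibble.
#' @export
genotype_pipeline <- function(intensities, cfg = calling_config(), anchors = NULL) {
  called <- call_genotypes(intensities, cfg, anchors)
  filtered <- allele_frequency_filter(called, cfg)
  hmm_impute(filtered, cfg)
}
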