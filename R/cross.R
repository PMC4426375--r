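#' Specify a RIAIL breeding design
#'
#' Describes the advanced-intercross construction of a recombinant inbred
#' panel: reciprocal parental crosses, `n_intercross_gens` generations of
#' random single-pair mating with equal contribution of each pair, then
#' `n_selfing_gens` generations of selfing of a randomly chosen hermaphrodite
#' per line. A one-locus hybrid incompatibility (a sperm-delivered toxin whose
#' zygotic antidote is carried by the N2 allele, as in the *peel-1*/*zeel-1*
#' element) is modelled as selective death of embryos homozygous CB at the
#' locus when the sperm parent is heterozygous there, with the given
#' penetrance.
#'
#' @param n_lines Number of inbred lines to output (also the number of mating
#'   pairs maintained during the intercross phase).
#' @param n_intercross_gens Generations of random pair mating after the F1
#'   founders (default 10).
#' @param n_selfing_gens Generations of selfing (default 10).
#' @param incompatibility_locus Marker id of the incompatibility locus, or
#'   `NULL` for none.
#' @param incompatibility_penetrance Probability in \[0, 1\] that a susceptible
#'   embryo (homozygous CB with a heterozygous sperm parent) dies.
#' @param attempt_cap Maximum resampling attempts per offspring before the
#'   simulator gives up (guards against impossible matings at penetrance 1).
#' @param seed Optional integer seed; when given, [simulate_cross()] is fully
#'   reproducible.
#'
#' @return A list of class `cross_design`.
#' @export
cross_design <- function(n_lines,
                         n_intercross_gens = 10,
                         n_selfing_gens = 10,
                         incompatibility_locus = NULL,
                         incompatibility_penetrance = 0,
                         attempt_cap = 100,
                         seed = NULL) {
  stopifnot(n_lines >= 1, n_intercross_gens >= 0, n_selfing_gens >= 0,
            attempt_cap >= 1)
  if (incompatibility_penetrance < 0 || incompatibility_penetrance > 1) {
    abort("incompatibility_penetrance must lie in [0, 1]")
  }
  structure(
    list(
      n_lines = as.integer(n_lines),
      n_intercross_gens = as.integer(n_intercross_gens),
      n_selfing_gens = as.integer(n_selfing_gens),
      incompatibility_locus = incompatibility_locus,
      incompatibility_penetrance = incompatibility_penetrance,
      attempt_cap = as.integer(attempt_cap),
      seed = seed
    ),
    class = "cross_design"
  )
}

# One meiotic product from a pair of haplotypes (0 = CB, 1 = N2).
# Crossover count is Poisson with mean = chromosome length in Morgans
# (Haldane, no interference); crossover positions are uniform.
meiose <- function(h1, h2, pos_M, len_M) {
  n_xo <- rpois(1L, len_M)
  start <- sample.int(2L, 1L)
  if (n_xo == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  xo <- sort(runif(n_xo, 0, len_M))
  phase <- (start - 1L + findInterval(pos_M, xo)) %% 2L
  out <- h1
  out[phase == 1L] <- h2[phase == 1L]
  out
}

# sex chromosome handling: hermaphrodites are XX, males X0 (single X,
# transmitted intact or not at all)
new_individual <- function(haps, sex, mito) list(haps = haps, sex = sex, mito = mito)

geno_at <- function(ind, chr_idx, marker_pos) {
  h <- ind$haps[[chr_idx]]
  c(h$h1[marker_pos], if (is.null(h$h2)) NULL else h$h2[marker_pos])
}

#' Simulate a recombinant inbred advanced intercross panel
#'
#' Runs the breeding design of [cross_design()] forward over a genetic map and
#' returns fully inbred two-state genotypes for each line. Founders are the
#' four F1 classes of the reciprocal parental crosses (which differ in their
#' mitochondrial and X-chromosome origin); each intercross generation randomly
#' re-pairs males with hermaphrodites and every pair contributes exactly one
#' hermaphrodite and one male to the next generation. Selfing halves
#' heterozygosity each generation; any heterozygosity remaining after the last
#' selfing generation is resolved by a fair coin per contiguous heterozygous
#' run, so that output genotypes are strictly two-state.
#'
#' @param design A [cross_design()].
#' @param map A [genetic_map()] with at least one marker per chromosome. A
#'   chromosome labelled `"X"` is treated as the sex chromosome: males carry a
#'   single X that is transmitted without recombination.
#'
#' @return A genotype tibble (class `genotype_tbl`): one row per marker with
#'   columns `marker`, `chrom`, `pos_bp`, `pos_cM` and one column per line
#'   holding `"N2"` or `"CB"`. Attributes record heterozygosity at the end of
#'   the intercross phase (`het_after_intercross`), after selfing and before
#'   run resolution (`het_after_selfing`), and the number of residual
#'   heterozygous runs resolved (`n_het_runs_resolved`).
#' @examples
#' map <- sim_genetic_map(60)
#' g <- simulate_cross(cross_design(20, seed = 1), map)
#' dim(g)
#' @export
simulate_cross <- function(design, map) {
  stopifnot(inherits(design, "cross_design"))
  assert_genetic_map(map)
  if (nrow(map) == 0L) abort("empty genetic map")
  if (!is.null(design$seed)) set.seed(design$seed)

  chroms <- unique(map$chrom)
  idx_by_chrom <- map_chrom_split(map)
  pos_M <- lapply(idx_by_chrom, function(i) map$pos_cM[i] / 100)
  len_M <- vapply(pos_M, function(p) max(p), numeric(1))
  x_chr <- match("X", chroms)
  n_chr <- length(chroms)

  inc <- NULL
  if (!is.null(design$incompatibility_locus) &&
      design$incompatibility_penetrance > 0) {
    w <- match(design$incompatibility_locus, map$marker)
    if (is.na(w)) abort("incompatibility locus not found in map")
    chr <- match(map$chrom[w], chroms)
    inc <- list(chr = chr, pos = match(w, idx_by_chrom[[chr]]),
                pen = design$incompatibility_penetrance)
  }

  n_pairs <- design$n_lines
  f1_herm <- function(mito) {
    haps <- lapply(seq_len(n_chr), function(ci) {
      L <- length(pos_M[[ci]])
      list(h1 = rep(1L, L), h2 = rep(0L, L))
    })
    new_individual(haps, "H", mito)
  }
  f1_male <- function(mother) {
    # X0 male: the single X comes from the mother
    haps <- lapply(seq_len(n_chr), function(ci) {
      L <- length(pos_M[[ci]])
      if (!is.na(x_chr) && ci == x_chr) {
        list(h1 = rep(if (mother == "N2") 1L else 0L, L), h2 = NULL)
      } else {
        list(h1 = rep(1L, L), h2 = rep(0L, L))
      }
    })
    new_individual(haps, "M", mother)
  }
  herms <- lapply(seq_len(n_pairs), function(i) f1_herm(if (i %% 2 == 0) "N2" else "CB"))
  males <- lapply(seq_len(n_pairs), function(i) f1_male(if (i %% 2 == 0) "N2" else "CB"))

  embryo_dies <- function(haps, father) {
    if (is.null(inc)) return(FALSE)
    fh <- father$haps[[inc$chr]]
    if (is.null(fh$h2)) return(FALSE)           # hemizygous X father: not het
    father_het <- fh$h1[inc$pos] != fh$h2[inc$pos]
    if (!father_het) return(FALSE)
    e <- haps[[inc$chr]]
    hom_cb <- e$h1[inc$pos] == 0L && (!is.null(e$h2) && e$h2[inc$pos] == 0L)
    hom_cb && runif(1) < inc$pen
  }

  make_offspring <- function(mother, father, sex) {
    for (attempt in seq_len(design$attempt_cap)) {
      haps <- vector("list", n_chr)
      for (ci in seq_len(n_chr)) {
        mh <- mother$haps[[ci]]
        ovum <- meiose(mh$h1, mh$h2, pos_M[[ci]], len_M[[ci]])
        if (!is.na(x_chr) && ci == x_chr) {
          # male sperm: the intact X for hermaphrodite offspring, none for male
          haps[[ci]] <- if (sex == "H") {
            list(h1 = ovum, h2 = father$haps[[ci]]$h1)
          } else {
            list(h1 = ovum, h2 = NULL)
          }
        } else {
          fh <- father$haps[[ci]]
          sperm <- meiose(fh$h1, fh$h2, pos_M[[ci]], len_M[[ci]])
          haps[[ci]] <- list(h1 = ovum, h2 = sperm)
        }
      }
      if (!embryo_dies(haps, father)) {
        return(new_individual(haps, sex, mother$mito))
      }
    }
    abort("attempt cap exceeded: no viable offspring under the incompatibility")
  }

  # intercross phase: random pairing, one hermaphrodite + one male per pair
  for (gen in seq_len(design$n_intercross_gens)) {
    perm <- sample.int(n_pairs)
    new_h <- vector("list", n_pairs)
    new_m <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      mo <- herms[[i]]
      fa <- males[[perm[i]]]
      new_h[[i]] <- make_offspring(mo, fa, "H")
      new_m[[i]] <- make_offspring(mo, fa, "M")
    }
    herms <- new_h
    males <- new_m
  }

  het_fraction <- function(inds) {
    tot <- 0; het <- 0
    for (ind in inds) {
      for (ci in seq_len(n_chr)) {
        h <- ind$haps[[ci]]
        if (is.null(h$h2)) next
        tot <- tot + length(h$h1)
        het <- het + sum(h$h1 != h$h2)
      }
    }
    het / tot
  }
  het_ic <- het_fraction(herms)

  self_offspring <- function(ind) {
    for (attempt in seq_len(design$attempt_cap)) {
      haps <- vector("list", n_chr)
      for (ci in seq_len(n_chr)) {
        h <- ind$haps[[ci]]
        haps[[ci]] <- list(
          h1 = meiose(h$h1, h$h2, pos_M[[ci]], len_M[[ci]]),
          h2 = meiose(h$h1, h$h2, pos_M[[ci]], len_M[[ci]])
        )
      }
      if (!embryo_dies(haps, ind)) return(new_individual(haps, "H", ind$mito))
    }
    abort("attempt cap exceeded: no viable offspring under the incompatibility")
  }
  for (gen in seq_len(design$n_selfing_gens)) {
    herms <- lapply(herms, self_offspring)
  }
  het_self <- het_fraction(herms)

  # resolve residual heterozygosity: fair coin per contiguous heterozygous run
  n_runs <- 0L
  geno <- matrix(NA_integer_, nrow = nrow(map), ncol = n_pairs)
  for (i in seq_len(n_pairs)) {
    for (ci in seq_len(n_chr)) {
      h <- herms[[i]]$haps[[ci]]
      g <- h$h1
      if (!is.null(h$h2)) {
        het <- h$h1 != h$h2
        if (any(het)) {
          r <- rle(het)
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1L
          for (k in which(r$values)) {
            n_runs <- n_runs + 1L
            if (runif(1) < 0.5) {
              g[starts[k]:ends[k]] <- h$h2[starts[k]:ends[k]]
            }
          }
        }
      }
      geno[idx_by_chrom[[ci]], i] <- g
    }
  }

  strains <- sprintf("QX%03d", seq_len(n_pairs))
  calls <- matrix(ifelse(geno == 1L, "N2", "CB"), nrow = nrow(map),
                  dimnames = list(NULL, strains))
  out <- bind_cols(
    tibble(marker = map$marker, chrom = map$chrom,
           pos_bp = map$pos_bp, pos_cM = map$pos_cM),
    as_tibble(calls)
  )
  class(out) <- c("genotype_tbl", class(out))
  attr(out, "het_after_intercross") <- het_ic
  attr(out, "het_after_selfing") <- het_self
  attr(out, "n_het_runs_resolved") <- n_runs
  out
}

#' Count recombination breakpoints per line and chromosome
#'
#' @param genos A genotype tibble as returned by [simulate_cross()] or
#'   [hmm_impute()].
#' @return A tibble with columns `strain`, `chrom`, `n_breakpoints`.
#' @export
count_breakpoints <- function(genos) {
  strains <- genotype_strains(genos)
  genos %>%
    tidyr::pivot_longer(dplyr::all_of(strains), names_to = "strain",
                        values_to = "call") %>%
    group_by(.data$strain, .data$chrom) %>%
    summarise(
      n_breakpoints = {
        x <- .data$call[!is.na(.data$call)]
        if (length(x) < 2L) 0L else sum(x[-1] != x[-length(x)])
      },
      .groups = "drop"
    )
}
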