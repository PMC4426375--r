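#' Genotype-calling configuration
#'
#' @param posterior_cutoff Calls whose winning posterior falls below this are
#'   set `NA` ("poor differentiation"). Default 0.95.
#' @param max_freq_N2,max_freq_CB Allele-frequency filter: markers whose
#'   non-missing call fraction is strictly greater than these are set wholly
#'   `NA` (defaults 0.65 N2 and 0.60 CB).
#' @param epsilon HMM emission error rate used by [hmm_impute()].
#' @param blacklist Character vector of marker ids dropped before calling.
#' @return List of class `calling_config`.
#' @export
calling_config <- function(posterior_cutoff = 0.95,
                           max_freq_N2 = 0.65,
                           max_freq_CB = 0.60,
                           epsilon = 0.01,
                           blacklist = character(0)) {
  stopifnot(posterior_cutoff > 0.5, posterior_cutoff <= 1,
            max_freq_N2 > 0.5, max_freq_N2 < 1,
            max_freq_CB > 0.5, max_freq_CB < 1,
            epsilon >= 0, epsilon < 0.5)
  structure(list(posterior_cutoff = posterior_cutoff,
                 max_freq_N2 = max_freq_N2, max_freq_CB = max_freq_CB,
                 epsilon = epsilon, blacklist = blacklist),
            class = "calling_config")
}

#' Two-component univariate normal mixture by EM
#'
#' Fits a two-component Gaussian mixture to a vector of genotyping
#' intensities by expectation-maximization, iterating until the
#' log-likelihood improves by less than `tol` (default 1e-8) or `max_iter`
#' iterations. The components share one variance (the homoscedastic model
#' usual for two-allele intensity clusters; it also keeps a lone mid-gap
#' value from being absorbed into an artificially widened cluster).
#' Components are relabelled so that component 1 is the lower-mean component
#' (the N2 cluster when unanchored). The log-likelihood is non-decreasing
#' across iterations by construction and is returned for verification.
#'
#' @param values Numeric vector (>= 4 finite values, not all identical).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations (default 500).
#' @param var_equal Share one variance across components (default `TRUE`).
#' @return List with `mean`, `sd`, `weight` (each length 2, component 1 =
#'   lower mean), `posterior` (n x 2 matrix of membership probabilities for
#'   the finite values), `loglik` (trace, one value per iteration),
#'   `converged`.
#' @examples
#' x <- c(rnorm(200, 0.1, 0.05), rnorm(200, 0.9, 0.05))
#' fit <- em_two_component(x)
#' fit$mean
#' @export
em_two_component <- function(values, tol = 1e-8, max_iter = 500,
                             var_equal = TRUE) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4L) abort("need at least 4 finite values")
  if (diff(range(x)) == 0) abort("degenerate input: all values identical")

  # moment-based start: split at the midrange
  split <- mean(range(x))
  lo <- x <= split
  if (sum(lo) < 2L || sum(!lo) < 2L) {
    ord <- order(x)
    lo <- seq_len(n) %in% ord[seq_len(floor(n / 2))]
  }
  mu <- c(mean(x[lo]), mean(x[!lo]))
  sg <- pmax(c(sd(x[lo]), sd(x[!lo])), diff(range(x)) * 1e-3)
  sg[is.na(sg)] <- diff(range(x)) * 1e-3
  if (var_equal) {
    pooled <- sqrt((sum((x[lo] - mu[1])^2) + sum((x[!lo] - mu[2])^2)) / n)
    sg <- rep(max(pooled, diff(range(x)) * 1e-3), 2)
  }
  w <- c(mean(lo), 1 - mean(lo))

  sd_floor <- diff(range(x)) * 1e-6
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    loglik <- c(loglik, sum(log(tot)))
    r <- d1 / tot
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break      # a component died: keep last fit
    mu_new <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    if (var_equal) {
      s2 <- (sum(r * (x - mu_new[1])^2) + sum((1 - r) * (x - mu_new[2])^2)) / n
      sg_new <- rep(sqrt(s2), 2)
    } else {
      sg_new <- sqrt(c(sum(r * (x - mu_new[1])^2) / n1,
                       sum((1 - r) * (x - mu_new[2])^2) / n2))
    }
    sg_new <- pmax(sg_new, sd_floor)
    w_new <- c(n1, n2) / n
    mu <- mu_new; sg <- sg_new; w <- w_new
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); w <- rev(w)
  }
  d1 <- w[1] * dnorm(x, mu[1], sg[1])
  d2 <- w[2] * dnorm(x, mu[2], sg[2])
  tot <- pmax(d1 + d2, .Machine$double.xmin)
  post <- cbind(d1 / tot, d2 / tot)
  list(mean = mu, sd = sg, weight = w, posterior = post,
       loglik = loglik, converged = converged)
}

#' Call two-state genotypes from an intensity table
#'
#' Fits [em_two_component()] per marker and assigns each strain the
#' max-posterior genotype; calls whose winning posterior is below the
#' configured cutoff become `NA`. The lower-mean component is N2 unless
#' anchor strains of known genotype are supplied, in which case the component
#' containing the majority of the N2 anchors is labelled N2. Markers on the
#' blacklist, or where the EM fit fails, are dropped and logged.
#'
#' @param intensities Intensity tibble (as from [simulate_intensities()] or
#'   [read_genotypes()]-shaped numeric table).
#' @param cfg A [calling_config()].
#' @param anchors Optional named list with character vectors `N2` and/or `CB`
#'   of control strain columns used to orient components.
#' @return Genotype tibble with `NA`s; dropped markers with reasons in
#'   `attr(, "dropped")`.
#' @export
call_genotypes <- function(intensities, cfg = calling_config(), anchors = NULL) {
  stopifnot(inherits(cfg, "calling_config"))
  strains <- genotype_strains(intensities)
  vals <- as.matrix(intensities[, strains])
  n_mark <- nrow(vals)
  calls <- matrix(NA_character_, n_mark, length(strains),
                  dimnames = list(NULL, strains))
  dropped <- list()

  keep <- !(intensities$marker %in% cfg$blacklist)
  for (m in which(!keep)) {
    dropped[[length(dropped) + 1L]] <-
      tibble(marker = intensities$marker[m], reason = "blacklisted")
  }

  for (m in which(keep)) {
    x <- vals[m, ]
    fin <- is.finite(x)
    fit <- tryCatch(em_two_component(x[fin]), error = function(e) NULL)
    if (is.null(fit)) {
      keep[m] <- FALSE
      dropped[[length(dropped) + 1L]] <-
        tibble(marker = intensities$marker[m], reason = "em_failure")
      next
    }
    lab <- c("N2", "CB")
    if (!is.null(anchors)) {
      comp1 <- fit$posterior[, 1] >= 0.5
      names(comp1) <- strains[fin]
      if (!is.null(anchors$N2) && any(anchors$N2 %in% names(comp1))) {
        if (mean(comp1[intersect(anchors$N2, names(comp1))]) < 0.5) lab <- c("CB", "N2")
      } else if (!is.null(anchors$CB) && any(anchors$CB %in% names(comp1))) {
        if (mean(comp1[intersect(anchors$CB, names(comp1))]) >= 0.5) lab <- c("CB", "N2")
      }
    }
    best <- max.col(fit$posterior)
    pmax_ <- fit$posterior[cbind(seq_len(nrow(fit$posterior)), best)]
    call_m <- lab[best]
    call_m[pmax_ < cfg$posterior_cutoff] <- NA_character_
    calls[m, fin] <- call_m
  }

  out <- bind_cols(
    intensities[keep, c("marker", "chrom", "pos_bp", "pos_cM")],
    as_tibble(calls[keep, , drop = FALSE])
  )
  class(out) <- c("genotype_tbl", class(out))
  attr(out, "dropped") <- if (length(dropped)) bind_rows(dropped) else
    tibble(marker = character(0), reason = character(0))
  out
}

#' Allele-frequency filter
#'
#' Markers whose non-missing call fraction is strictly greater than the
#' configured N2 or CB maxima (defaults: 65% N2, 60% CB) have all calls set
#' `NA`. Such skews indicate systematic miscalls; the markers are retained as
#' map positions so that imputation can bridge them. The per-marker
#' frequencies and filter outcomes are logged in `attr(, "filter_log")`.
#'
#' @param genos Genotype tibble with calls.
#' @param cfg A [calling_config()].
#' @return Genotype tibble of the same shape.
#' @export
allele_frequency_filter <- function(genos, cfg = calling_config()) {
  freq <- allele_frequencies(genos)
  fail <- !is.na(freq$freq_N2) &
    (freq$freq_N2 > cfg$max_freq_N2 | freq$freq_CB > cfg$max_freq_CB)
  strains <- genotype_strains(genos)
  out <- genos
  out[fail, strains] <- NA_character_
  attr(out, "filter_log") <- mutate(freq, filtered = fail)
  out
}
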