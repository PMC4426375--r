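#' Construct a genetic map
#'
#' A genetic map is a tibble with one row per marker, ordered by chromosome and
#' genetic position. It is the coordinate system shared by the breeding
#' simulator, the genotype caller/imputer and the linkage scans.
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chrom Character vector of chromosome labels. A chromosome labelled
#'   `"X"` is treated as the sex chromosome by [simulate_cross()].
#' @param pos_cM Numeric genetic positions in centimorgans, non-decreasing
#'   within chromosome.
#' @param pos_bp Integer physical positions (1-based), non-decreasing within
#'   chromosome.
#'
#' @return A tibble of class `genetic_map` with columns `marker`, `chrom`,
#'   `pos_cM`, `pos_bp`.
#' @seealso [sim_genetic_map()] for a synthetic map with *C. elegans*-like
#'   chromosome sizes.
#' @export
genetic_map <- function(marker, chrom, pos_cM, pos_bp) {
  if (length(marker) == 0L) abort("a genetic map needs at least one marker")
  if (anyDuplicated(marker)) abort("marker ids must be unique")
  map <- tibble(
    marker = as.character(marker),
    chrom = as.character(chrom),
    pos_cM = as.numeric(pos_cM),
    pos_bp = as.numeric(pos_bp)
  )
  map <- dplyr::arrange(map, factor(.data$chrom, levels = unique(map$chrom)),
                        .data$pos_cM, .data$pos_bp)
  bad <- map %>%
    group_by(.data$chrom) %>%
    summarise(ok = !is.unsorted(.data$pos_cM) && !is.unsorted(.data$pos_bp)) %>%
    filter(!.data$ok)
  if (nrow(bad) > 0L) abort("positions must be non-decreasing within chromosome")
  class(map) <- c("genetic_map", class(map))
  map
}

#' Synthetic genetic map with C. elegans-like chromosomes
#'
#' Builds an evenly spaced marker map over six chromosomes (I-V and X) with
#' physical sizes close to the *C. elegans* genome and a uniform 50 cM genetic
#' length per chromosome. Markers are allocated to chromosomes proportionally
#' to physical size, which reproduces the marker density of a ~1500-SNP
#' GoldenGate panel when `n_markers = 1454`.
#'
#' @param n_markers Total number of markers across the genome.
#' @return A `genetic_map` tibble.
#' @examples
#' sim_genetic_map(120)
#' @export
sim_genetic_map <- function(n_markers = 1454) {
  if (n_markers < 6L) abort("need at least one marker per chromosome")
  chroms <- c("I", "II", "III", "IV", "V", "X")
  size_mb <- c(15.1, 15.3, 13.8, 17.5, 20.9, 17.7)
  len_cM <- rep(50, 6)
  n_per <- pmax(1L, round(n_markers * size_mb / sum(size_mb)))
  # adjust rounding drift so the total is exact
  while (sum(n_per) != n_markers) {
    i <- if (sum(n_per) > n_markers) which.max(n_per) else which.min(n_per)
    n_per[i] <- n_per[i] + sign(n_markers - sum(n_per))
  }
  pieces <- purrr::pmap(
    list(chroms, size_mb, len_cM, n_per),
    function(chr, mb, cm, k) {
      frac <- (seq_len(k) - 0.5) / k
      tibble(
        marker = sprintf("M%s_%04d", chr, seq_len(k)),
        chrom = chr,
        pos_cM = frac * cm,
        pos_bp = round(frac * mb * 1e6)
      )
    }
  )
  map <- bind_rows(pieces)
  genetic_map(map$marker, map$chrom, map$pos_cM, map$pos_bp)
}

map_chrom_split <- function(map) split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))

assert_genetic_map <- function(map) {
  need <- c("marker", "chrom", "pos_cM", "pos_bp")
  if (!all(need %in% names(map))) {
    abort("`map` must have columns marker, chrom, pos_cM, pos_bp")
  }
  invisible(map)
}
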