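#' Strain columns of a genotype tibble
#'
#' @param genos A genotype tibble (markers in rows; `marker`, `chrom`,
#'   `pos_bp`, `pos_cM` metadata columns followed by one column per strain).
#' @return Character vector of strain column names.
#' @export
genotype_strains <- function(genos) {
  setdiff(names(genos), c("marker", "chrom", "pos_bp", "pos_cM"))
}

#' Numeric genotype matrix for mapping
#'
#' Converts two-state calls to the numeric coding used by the linkage scans:
#' N2 = +1, CB = -1, `NA` preserved. Rows are strains, columns markers.
#'
#' @inheritParams genotype_strains
#' @return A strains x markers numeric matrix with dimnames.
#' @export
geno_matrix <- function(genos) {
  strains <- genotype_strains(genos)
  m <- as.matrix(genos[, strains])
  num <- matrix(NA_real_, nrow = nrow(m), ncol = ncol(m))
  num[m == "N2"] <- 1
  num[m == "CB"] <- -1
  t(matrix(num, nrow = nrow(m), dimnames = list(genos$marker, strains)))
}

#' Read / write delimited genotype tables
#'
#' Genotype tables are tab-separated text with one row per marker: columns
#' `marker`, `chrom`, `pos_bp`, `pos_cM`, then one column per strain with
#' values `N2`, `CB` or `NA`. Physical positions are 1-based.
#'
#' @param path File path.
#' @return `read_genotypes()` returns a genotype tibble.
#' @export
read_genotypes <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("marker", "chrom", "pos_bp", "pos_cM")
  if (!all(need %in% names(out))) abort("not a genotype table: missing metadata columns")
  out <- mutate(out, chrom = as.character(.data$chrom))
  class(out) <- c("genotype_tbl", class(out))
  out
}

#' @rdname read_genotypes
#' @param genos A genotype tibble.
#' @export
write_genotypes <- function(genos, path) {
  readr::write_tsv(genos, path, progress = FALSE)
  invisible(path)
}

#' Marker allele frequencies
#'
#' Per-marker fraction of N2 and CB calls among non-missing calls.
#'
#' @inheritParams genotype_strains
#' @return Tibble with `marker`, `chrom`, `n_called`, `freq_N2`, `freq_CB`.
#' @export
allele_frequencies <- function(genos) {
  strains <- genotype_strains(genos)
  m <- as.matrix(genos[, strains])
  n_called <- rowSums(!is.na(m))
  n_n2 <- rowSums(m == "N2", na.rm = TRUE)
  tibble(
    marker = genos$marker,
    chrom = genos$chrom,
    n_called = n_called,
    freq_N2 = ifelse(n_called > 0, n_n2 / n_called, NA_real_),
    freq_CB = ifelse(n_called > 0, 1 - n_n2 / n_called, NA_real_)
  )
}
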