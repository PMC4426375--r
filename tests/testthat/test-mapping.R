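test_that("the LOD score follows the correlation formula exactly", {
  g <- panel_power()
  # r = 0: orthogonal trait gives LOD 0
  mk <- g$marker[1]
  y0 <- trait_with_exact_r(g, mk, 0, seed = 1)
  expect_equal(as.numeric(lod_score(geno_matrix(g)[, mk], y0)), 0,
               tolerance = 1e-12)
  # n = 357, r = 0.2: frozen high-precision evaluation of the formula
  y2 <- trait_with_exact_r(g, mk, 0.2, seed = 2)
  expect_equal(as.numeric(lod_score(geno_matrix(g)[, mk], y2)), 3.16459,
               tolerance = 1e-4)
  # |r| = 1 is flagged infinite
  code <- geno_matrix(g)[, mk]
  l1 <- lod_score(code, code * 2 + 1)
  expect_identical(as.numeric(l1), Inf)
  expect_true(attr(l1, "perfect"))
})

test_that("both algebraic forms of the LOD agree to 1e-12", {
  set.seed(3)
  for (k in 1:200) {
    n <- sample(10:500, 1)
    g <- sample(c(-1, 1), n, replace = TRUE)
    if (var(g) == 0) next
    y <- rnorm(n)
    r <- cor(g, y)
    implemented <- as.numeric(lod_score(g, y))
    alt <- (n / 2) * log10(1 / (1 - r^2))
    expect_lt(abs(implemented - alt), 1e-12)
  }
})

test_that("scans are invariant to label swaps, affine trait changes and marker duplication", {
  g <- panel_small()
  set.seed(4)
  tr <- tibble::tibble(strain = genotype_strains(g), y = rnorm(60))
  sc <- scan_qtl(g, tr)
  # swap N2 and CB everywhere
  strains <- genotype_strains(g)
  swapped <- g
  m <- as.matrix(g[, strains])
  swapped[, strains] <- tibble::as_tibble(ifelse(m == "N2", "CB", "N2"))
  sc_swap <- scan_qtl(swapped, tr)
  expect_equal(sc$lod, sc_swap$lod, tolerance = 1e-12)
  # affine transform of the trait
  sc_aff <- scan_qtl(g, dplyr::mutate(tr, y = 3 * y - 7))
  expect_equal(sc$lod, sc_aff$lod, tolerance = 1e-9)
  # duplicated marker column gives identical LODs
  dup <- g[c(1, 1:nrow(g)), ]
  dup$marker[1] <- "dup"
  sc_dup <- scan_qtl(dup, tr)
  expect_equal(sc_dup$lod[1], sc_dup$lod[2], tolerance = 1e-12)
})

test_that("scanning requires aligned strains and enough of them", {
  g <- panel_small()
  tr <- tibble::tibble(strain = genotype_strains(g)[1:10], y = rnorm(10))
  expect_error(scan_qtl(g, tr), "20 strains")
})

test_that("a permuted trait yields only modest LOD peaks", {
  g <- panel_power()
  qtl <- tibble::tibble(marker = default_panel_qtl(g)$marker[1], ve = 0.3)
  ph <- simulate_phenotypes(g, pheno_model(qtl = qtl, h2 = 0.6), seed = 5)
  set.seed(6)
  tr <- tibble::tibble(strain = ph$strain, y = sample(ph$value))
  sc <- scan_qtl(g, tr)
  expect_lt(max(sc$lod, na.rm = TRUE), 6)
})

test_that("iterated conditional scans split linked QTL a plain scan merges", {
  g <- panel_power()
  chromV <- g[g$chrom == "V", ]
  # two loci 40 cM apart on chromosome V, 10% and 6% of variance
  pick <- function(cm) chromV$marker[which.min(abs(chromV$pos_cM - cm))]
  mks <- c(pick(5), pick(45))
  G <- geno_matrix(g)[, mks]
  hits <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    set.seed(700 + s)
    y <- sqrt(0.10) * G[, 1] + sqrt(0.06) * G[, 2] +
      rnorm(nrow(G), sd = sqrt(0.84))
    tr <- tibble::tibble(strain = rownames(G), y = y)
    isc <- iterative_scan(g, tr, threshold = 3)
    pk <- attr(isc, "peaks")
    pos <- chromV$pos_cM[match(pk$marker[pk$chrom == "V"], chromV$marker)]
    found1 <- any(abs(pos - 5) < 15)
    found2 <- any(abs(pos - 45) < 15)
    hits <- hits + (found1 && found2)
  }
  expect_gte(hits / n_seeds, 0.70)
})

test_that("iteration adds nothing for a single-QTL trait and an infinite threshold", {
  g <- panel_power()
  qtl <- tibble::tibble(marker = default_panel_qtl(g)$marker[1], ve = 0.2)
  ph <- simulate_phenotypes(g, pheno_model(qtl = qtl, h2 = 0.5), seed = 8)
  tr <- tibble::tibble(strain = ph$strain, y = ph$value)
  isc <- iterative_scan(g, tr, threshold = 3)
  pk <- attr(isc, "peaks")
  expect_true(all(pk$iteration == 1))
  plain <- scan_qtl(g, tr)
  inf <- iterative_scan(g, tr, threshold = Inf)
  expect_equal(inf$lod, plain$lod, tolerance = 1e-12)
})

test_that("the 1.5-LOD-drop interval follows the profile", {
  prof <- tibble::tibble(
    trait = "y", marker = paste0("m", 1:6), chrom = "I",
    pos_bp = 1:6 * 1e6, pos_cM = 1:6, n = 100,
    lod = c(1.0, 2.0, 4.0, 3.1, 2.4, 1.0))
  class(prof) <- c("qtl_scan", class(prof))
  ci <- ci_lod_drop(prof, trait = "y", chrom = "I")
  expect_identical(ci$ci_lo_marker, "m3")   # 2.0 < 2.5 excludes m2
  expect_identical(ci$ci_hi_marker, "m4")   # 2.4 < 2.5 excludes m5
  # flat profile: whole chromosome
  flat <- dplyr::mutate(prof, lod = 3)
  class(flat) <- c("qtl_scan", class(flat))
  cif <- ci_lod_drop(flat, trait = "y", chrom = "I")
  expect_identical(c(cif$ci_lo_marker, cif$ci_hi_marker), c("m1", "m6"))
  # peak at the chromosome end: one-sided interval
  edge <- dplyr::mutate(prof, lod = c(6, 5.2, 4, 3, 2, 1))
  class(edge) <- c("qtl_scan", class(edge))
  cie <- ci_lod_drop(edge, trait = "y", chrom = "I")
  expect_identical(cie$ci_lo_marker, "m1")
  expect_identical(cie$peak_marker, "m1")
})

test_that("variance explained and heritability fractions divide as stated", {
  g <- panel_power()
  mk <- g$marker[10]
  y <- trait_with_exact_r(g, mk, 0.346, seed = 9)
  tr <- tibble::tibble(strain = names(y), y = y)
  ve <- variance_explained(g, tr, mk, h2 = 0.495)
  expect_equal(ve$var_explained, 0.1197, tolerance = 1e-3)
  expect_equal(ve$fraction_h2, 0.1197 / 0.495, tolerance = 1e-2)
  # zero correlation gives a zero fraction
  y0 <- trait_with_exact_r(g, mk, 0, seed = 10)
  ve0 <- variance_explained(g, tibble::tibble(strain = names(y0), y = y0),
                            mk, h2 = 0.495)
  expect_equal(ve0$fraction_h2, 0, tolerance = 1e-12)
  expect_error(variance_explained(g, tr, mk, h2 = 0), "positive")
  # inflated estimates cap at the heritability with a warning
  y1 <- trait_with_exact_r(g, mk, 0.9, seed = 11)
  expect_warning(
    ve1 <- variance_explained(g, tibble::tibble(strain = names(y1), y = y1),
                              mk, h2 = 0.3),
    "capped")
  expect_identical(ve1$fraction_h2, 1)
})
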