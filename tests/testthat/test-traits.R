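well_table <- function(n_plates = 2, n_per = 24, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(plate_id = paste0("p", seq_len(n_plates)),
                     idx = seq_len(n_per)) |>
    dplyr::mutate(row = LETTERS[(idx - 1) %% 8 + 1],
                  col = (idx - 1) %/% 8 + 1,
                  strain = sprintf("s%02d", idx),
                  condition = "control") |>
    dplyr::select(-idx)
}

test_that("plate effects vanish after nuisance regression", {
  d <- well_table()
  d$n <- rnorm(nrow(d), 50, 2) + ifelse(d$plate_id == "p1", 2, 0)
  out <- regress_nuisance(d, traits = "n", covariates = "plate_id")
  means <- tapply(out$n, out$plate_id, mean)
  expect_lt(abs(diff(means)), 0.05)
  expect_lt(abs(mean(out$n)), 1e-9)
  r2 <- attr(out, "nuisance_r2")
  expect_gt(r2$r2[r2$trait == "n"], 0.1)
})

test_that("values constant across plates come back centred", {
  d <- well_table()
  vals <- rnorm(24)
  d$n <- vals[as.integer(sub("s", "", d$strain))]  # same value on both plates
  out <- regress_nuisance(d, traits = "n", covariates = "plate_id")
  expect_equal(out$n, d$n - mean(d$n), tolerance = 1e-9)
})

test_that("degenerate nuisance designs are rejected", {
  d <- well_table(n_plates = 1)
  d$plate_id <- "p1"; d$row <- "A"; d$col <- 1
  d$n <- rnorm(nrow(d))
  expect_error(regress_nuisance(d, traits = "n"), "constant|degenerate")
  # saturated: as many model cells as observations
  d2 <- tibble::tibble(plate_id = c("p1", "p1", "p2", "p2"),
                       row = c("A", "B", "A", "B"), col = c(1, 2, 2, 1),
                       strain = "s", condition = "control",
                       n = rnorm(4))
  expect_error(regress_nuisance(d2, traits = "n"), "saturated")
})

test_that("replicate aggregation averages and logs counts", {
  d <- tibble::tibble(strain = c("a", "a", "b"), condition = "control",
                      n = c(1, 3, 7))
  out <- aggregate_replicates(d, traits = "n")
  expect_equal(out$n, c(2, 7))
  expect_equal(attr(out, "replicates")$n_reps, c(2L, 1L))
  # replicate noise shrinks as sigma/sqrt(k)
  set.seed(2)
  k <- 4; sigma <- 2
  d2 <- tidyr::expand_grid(strain = sprintf("s%04d", 1:2000),
                           rep = seq_len(k)) |>
    dplyr::mutate(condition = "control", n = rnorm(dplyr::n(), sd = sigma))
  out2 <- aggregate_replicates(d2, traits = "n")
  expect_lt(abs(sd(out2$n) - sigma / sqrt(k)), 0.05)
})

test_that("trait scaling is an exact population z-score and idempotent", {
  d <- tibble::tibble(strain = c("a", "b", "c"), n = c(2, 4, 6))
  out <- scale_traits(d, traits = "n")
  expect_equal(out$n, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  out2 <- scale_traits(out, traits = "n")
  expect_equal(out$n, out2$n, tolerance = 1e-12)
  dc <- tibble::tibble(strain = c("a", "b"), n = c(1, 1))
  expect_warning(out3 <- scale_traits(dc, traits = "n"), "constant")
  expect_false("n" %in% names(out3))
})

test_that("proportional control is regressed out exactly", {
  set.seed(3)
  ctrl <- tibble::tibble(strain = sprintf("s%02d", 1:40), n = rnorm(40))
  trt <- dplyr::mutate(ctrl, n = 0.8 * n)
  out <- condition_residuals(trt, ctrl, traits = "n")
  expect_true(all(abs(out$n) < 1e-9))
})

test_that("condition residualization is idempotent and handles uncorrelated controls", {
  set.seed(4)
  ctrl <- tibble::tibble(strain = sprintf("s%02d", 1:60), n = rnorm(60))
  trt <- tibble::tibble(strain = ctrl$strain, n = rnorm(60))
  out <- condition_residuals(trt, ctrl, traits = "n")
  reg <- attr(out, "regressions")
  expect_lt(abs(reg$slope), 0.3)
  expect_gt(cor(out$n, trt$n), 0.9)            # essentially centred treatment
  out2 <- condition_residuals(out, ctrl, traits = "n")
  expect_equal(out$n, out2$n, tolerance = 1e-9)
  expect_error(condition_residuals(trt[1:5, ], ctrl[1:5, ], traits = "n"),
               "10")
})

test_that("treatment-specific signal maps to its own locus after residualization", {
  g <- panel_power()
  G <- geno_matrix(g)
  mk <- default_panel_qtl(g)$marker[c(2, 5)]       # chr I (control), chr V (treatment)
  set.seed(5)
  strains <- rownames(G)
  ctrl_val <- sqrt(0.20) * G[, mk[1]] + rnorm(length(strains), sd = sqrt(0.80))
  trt_val <- ctrl_val + sqrt(0.15) * G[, mk[2]] + rnorm(length(strains), sd = 0.3)
  ctrl <- tibble::tibble(strain = strains, n = ctrl_val)
  trt <- tibble::tibble(strain = strains, n = trt_val)
  resid <- condition_residuals(trt, ctrl, traits = "n")
  sc <- scan_qtl(g, resid)
  pk <- find_peaks(sc, threshold = 3)
  expect_true("V" %in% pk$chrom)
  expect_false("I" %in% pk$chrom)                 # control locus removed
})

test_that("a control+treatment run yields 25 + 25 + 25 trait columns", {
  lay_c <- plate_layout(sprintf("s%02d", 1:18), condition = "control")
  lay_t <- plate_layout(sprintf("s%02d", 1:18), plate_id = "p2",
                        condition = "paraquat")
  lat <- tibble::tibble(strain = sprintf("s%02d", 1:18), value = rnorm(18))
  m <- pheno_model(bubble_rate = 0)
  ws_c <- summarize_wells(read_events(simulate_well_events(lat, m, lay_c, 40), lay_c))
  ws_t <- summarize_wells(read_events(simulate_well_events(lat, m, lay_t, 41), lay_t))
  agg_c <- aggregate_replicates(ws_c)
  agg_t <- aggregate_replicates(ws_t)
  resid <- suppressWarnings(condition_residuals(agg_t, agg_c))
  expect_length(intersect(trait_columns(), names(agg_c)), 25L)
  expect_length(intersect(trait_columns(), names(agg_t)), 25L)
  expect_length(setdiff(names(resid), "strain"), 25L)
})
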