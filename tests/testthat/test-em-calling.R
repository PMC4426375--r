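test_that("EM recovers well-separated cluster parameters", {
  set.seed(1)
  x <- c(rnorm(200, 0.1, 0.05), rnorm(200, 0.9, 0.05))
  fit <- em_two_component(x)
  expect_lt(abs(fit$mean[1] - 0.1), 0.02)
  expect_lt(abs(fit$mean[2] - 0.9), 0.02)
  expect_true(fit$converged)
})

test_that("EM posteriors agree with Bayes' rule on the fitted parameters", {
  set.seed(2)
  x <- c(rnorm(300, 0.1, 0.05), rnorm(300, 0.9, 0.05))
  fit <- em_two_component(x)
  d1 <- fit$weight[1] * dnorm(x, fit$mean[1], fit$sd[1])
  d2 <- fit$weight[2] * dnorm(x, fit$mean[2], fit$sd[2])
  expect_equal(fit$posterior[, 1], d1 / (d1 + d2), tolerance = 1e-12)
  # a value near the low cluster is confidently low
  i <- which.min(abs(x - 0.12))
  expect_gt(fit$posterior[i, 1], 0.999)
})

test_that("a symmetric bimodal sample gets near-equal weights", {
  set.seed(3)
  x <- c(rnorm(400, 0.2, 0.04), rnorm(400, 0.8, 0.04))
  fit <- em_two_component(x)
  expect_lt(abs(fit$weight[1] - 0.5), 0.05)
})

test_that("the EM log-likelihood never decreases", {
  set.seed(4)
  for (k in 1:20) {
    mu <- sort(runif(2))
    x <- c(rnorm(sample(20:200, 1), mu[1], runif(1, 0.02, 0.2)),
           rnorm(sample(20:200, 1), mu[2], runif(1, 0.02, 0.2)))
    fit <- em_two_component(x)
    expect_true(all(diff(fit$loglik) > -1e-8))
  }
})

test_that("EM agrees with an independent mixture-model fit", {
  withr::local_package("mclust")
  set.seed(5)
  x <- c(rnorm(250, 0.15, 0.06), rnorm(150, 0.85, 0.05))
  fit <- em_two_component(x)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(fit$mean) - sort(ref$parameters$mean))), 0.02)
})

test_that("EM rejects degenerate inputs", {
  expect_error(em_two_component(c(1, 2, 3)), "at least 4")
  expect_error(em_two_component(rep(1, 10)), "identical")
})

test_that("calling a clean simulated table is nearly exact", {
  g <- panel_small()
  ints <- simulate_intensities(g, intensity_sim_params(missing_rate = 0), seed = 7)
  called <- call_genotypes(ints)
  truth <- attr(ints, "truth")
  cm <- as.matrix(called[, genotype_strains(called)])
  expect_gte(mean(cm == truth, na.rm = TRUE), 0.99)
})

test_that("a midpoint value is not called", {
  set.seed(8)
  # mirror-symmetric clusters keep the fitted mixture symmetric, so the
  # midpoint posterior is exactly 1/2 and falls below the call cutoff
  base <- rnorm(30, 0.1, 0.05)
  vals <- c(base, 1 - base, 0.5)
  ints <- tibble::tibble(marker = "m1", chrom = "I", pos_bp = 1, pos_cM = 0) |>
    dplyr::bind_cols(tibble::as_tibble(as.list(setNames(vals, sprintf("s%02d", 1:61)))))
  called <- call_genotypes(ints)
  expect_true(is.na(called$s61))
})

test_that("blacklisted markers are dropped and logged", {
  g <- panel_small()
  ints <- simulate_intensities(g, intensity_sim_params(), seed = 9)
  bad <- ints$marker[5]
  called <- call_genotypes(ints, calling_config(blacklist = bad))
  expect_false(bad %in% called$marker)
  drops <- attr(called, "dropped")
  expect_identical(drops$reason[drops$marker == bad], "blacklisted")
})

test_that("allele-frequency filter applies strict 65/60 thresholds", {
  strains <- sprintf("s%03d", 1:100)
  mk <- function(n_n2) rep(c("N2", "CB"), c(n_n2, 100 - n_n2))
  genos <- dplyr::bind_cols(
    tibble::tibble(marker = c("m70", "m65", "m39"), chrom = "I",
                   pos_bp = 1:3, pos_cM = c(0, 1, 2)),
    tibble::as_tibble(t(matrix(c(mk(70), mk(65), mk(39)), ncol = 3,
                               dimnames = list(strains, NULL))))
  )
  out <- allele_frequency_filter(genos)
  m <- as.matrix(out[, strains])
  expect_true(all(is.na(m[1, ])))      # 70% N2 > 65%: all NA
  expect_false(anyNA(m[2, ]))          # exactly 65%: retained (strict >)
  expect_true(all(is.na(m[3, ])))      # 61% CB > 60%: all NA
  log <- attr(out, "filter_log")
  expect_equal(log$freq_N2, c(0.70, 0.65, 0.39), tolerance = 1e-12)
})

test_that("anchor strains orient the components", {
  set.seed(10)
  # N2 anchors sit in the HIGH cluster here; anchoring must flip the labels
  strains <- c("N2ref", sprintf("s%02d", 1:59))
  vals <- c(0.9, rnorm(30, 0.9, 0.04), rnorm(29, 0.1, 0.04))
  ints <- dplyr::bind_cols(
    tibble::tibble(marker = "m1", chrom = "I", pos_bp = 1, pos_cM = 0),
    tibble::as_tibble(as.list(setNames(vals, strains))))
  unanchored <- call_genotypes(ints)
  anchored <- call_genotypes(ints, anchors = list(N2 = "N2ref"))
  expect_identical(unanchored$N2ref, "CB")   # lower-mean-is-N2 default
  expect_identical(anchored$N2ref, "N2")
})
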