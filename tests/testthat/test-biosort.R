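simple_events <- function(df) {
  defaults <- tibble::tibble(plate_id = "p1", row = "A", col = 1L,
                             TOF = 100, EXT = 120, green = 5, yellow = 5,
                             red = 8)
  out <- df
  for (nm in setdiff(names(defaults), names(df))) out[[nm]] <- defaults[[nm]]
  out
}

test_that("events join the layout, wash wells are flagged, bad rows skipped", {
  lay <- plate_layout(c("sA", "sB"))
  ev <- simple_events(tibble::tibble(
    row = c("A", "A", "B"), col = c(1L, 4L, 2L), TOF = c(100, 90, -5)))
  f <- tempfile(fileext = ".csv")
  readr::write_csv(ev, f)
  expect_message(out <- read_events(f, lay), "skipped")
  expect_identical(nrow(out), 2L)                 # negative TOF dropped
  expect_identical(nrow(attr(out, "skipped")), 1L)
  expect_true(out$wash[out$col == 4])
  expect_false(is.na(out$strain[out$col == 1]))
  # unknown wells raise with the offending address
  ev2 <- simple_events(tibble::tibble(plate_id = "p9", row = "A", col = 1L))
  expect_error(read_events(ev2, lay), "p9")
  # empty file warns and returns an empty table
  f0 <- tempfile(fileext = ".csv")
  readr::write_csv(ev[0, ], f0)
  expect_warning(out0 <- read_events(f0, lay), "empty")
  expect_identical(nrow(out0), 0L)
})

test_that("hardware minimums are inclusive at EXT 50 and TOF 20", {
  ev <- simple_events(tibble::tibble(TOF = c(19, 20, 300), EXT = c(100, 50, 49)))
  out <- hardware_filter(ev)
  expect_identical(nrow(out), 1L)
  expect_identical(out$TOF, 20)
  all_pass <- simple_events(tibble::tibble(TOF = c(50, 60), EXT = c(80, 90)))
  expect_identical(hardware_filter(all_pass), all_pass)
})

test_that("a separable fixture is classified perfectly", {
  ev <- bubble_fixture(seed = 21)
  clf <- train_bubble_classifier(ev)
  expect_identical(clf$training_accuracy, 1)
  out <- classify_events(dplyr::mutate(ev, wash = FALSE, strain = "s",
                                       condition = "control"), clf)
  expect_identical(out$object_class, out$truth)
})

test_that("near-overlapping classes are separated at their Bayes rate", {
  train <- bubble_fixture(n_animal = 2000, n_bubble = 2000, seed = 22)
  test_ <- bubble_fixture(n_animal = 2000, n_bubble = 2000, seed = 23)
  clf <- train_bubble_classifier(train)
  out <- classify_events(dplyr::mutate(test_, wash = FALSE, strain = "s",
                                       condition = "control"), clf)
  expect_gte(mean(out$object_class == out$truth), 0.995)
})

test_that("permuted labels give chance-level held-out accuracy", {
  # the null control: destroy the label-feature link, train on one half,
  # score on the held-out half against its (equally random) labels
  ev <- bubble_fixture(n_animal = 600, n_bubble = 600, seed = 24)
  set.seed(25)
  ev$truth <- sample(ev$truth)
  idx <- sample(nrow(ev), nrow(ev) / 2)
  clf <- train_bubble_classifier(ev[idx, ])
  held <- dplyr::mutate(ev[-idx, ], wash = FALSE, strain = "s",
                        condition = "control")
  out <- classify_events(held, clf)
  acc <- mean(out$object_class == out$truth)
  baseline <- max(table(ev$truth)) / nrow(ev)
  expect_lt(abs(acc - baseline), 0.12)
})

test_that("classifier training demands both classes in numbers", {
  ev <- bubble_fixture(n_animal = 200, n_bubble = 30, seed = 27)
  expect_error(train_bubble_classifier(ev), "50")
  ev2 <- bubble_fixture(n_animal = 200, n_bubble = 0, seed = 28)
  expect_error(train_bubble_classifier(ev2), "class")
})

test_that("well summaries match hand-computed type-7 quantiles", {
  ev <- simple_events(tibble::tibble(
    TOF = as.numeric(1:10), EXT = as.numeric(1:10) * 2)) |>
    dplyr::mutate(strain = "sA", condition = "control", wash = FALSE,
                  object_class = "animal")
  ws <- summarize_wells(ev)
  expect_identical(ws$n, 10)
  expect_identical(ws$q50_TOF, 5.5)
  expect_identical(ws$iqr_TOF, 4.5)
  expect_identical(ws$mean_TOF, 5.5)
  expect_equal(ws$var_TOF, var(1:10))
  # EXT = 2 * TOF exactly: every normalized-density statistic is the
  # constant 2 with zero variance
  expect_identical(ws$q10_EXTpTOF, 2)
  expect_identical(ws$q90_EXTpTOF, 2)
  expect_identical(ws$var_EXTpTOF, 0)
  expect_identical(ws$iqr_EXTpTOF, 0)
})

test_that("single-animal wells give NA variance and degenerate quantiles", {
  ev <- simple_events(tibble::tibble(TOF = 123, EXT = 100)) |>
    dplyr::mutate(strain = "sA", condition = "control", wash = FALSE,
                  object_class = "animal")
  ws <- summarize_wells(ev)
  expect_identical(ws$n, 1)
  expect_true(is.na(ws$var_TOF))
  expect_identical(ws$q10_TOF, 123)
  expect_identical(ws$q90_TOF, 123)
})

test_that("the well summary has exactly 25 trait columns", {
  expect_length(trait_columns(), 25L)
  lay <- plate_layout(sprintf("s%02d", 1:9))
  lat <- tibble::tibble(strain = sprintf("s%02d", 1:9), value = 0)
  ev <- simulate_well_events(lat, pheno_model(bubble_rate = 0), lay, seed = 30)
  ws <- summarize_wells(read_events(ev, lay))
  expect_true(all(trait_columns() %in% names(ws)))
  expect_length(setdiff(names(ws), c("plate_id", "row", "col", "strain",
                                     "condition")), 25L)
})

test_that("summaries are invariant to event order and count planted offspring", {
  lay <- plate_layout(sprintf("s%02d", 1:9))
  lat <- tibble::tibble(strain = sprintf("s%02d", 1:9), value = rnorm(9))
  ev <- read_events(
    simulate_well_events(lat, pheno_model(bubble_rate = 0), lay, seed = 31),
    lay)
  ws1 <- summarize_wells(ev)
  set.seed(32)
  ws2 <- summarize_wells(ev[sample.int(nrow(ev)), ])
  key <- function(w) order(w$plate_id, w$row, w$col)
  expect_equal(as.data.frame(ws1[key(ws1), ]),
               as.data.frame(ws2[key(ws2), ]))
  # with no bubbles, n recovers the per-well object count exactly
  truth_n <- dplyr::count(ev, plate_id, row, col)
  joined <- dplyr::left_join(ws1, truth_n, by = c("plate_id", "row", "col"))
  expect_identical(joined$n.x, as.numeric(joined$n.y))
})
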