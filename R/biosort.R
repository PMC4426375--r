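#' Read a sorter event file
#'
#' Reads a comma-separated flat event file (one row per measured object with
#' `plate_id`, `row`, `col`, `TOF`, `EXT` and three fluorescence channels)
#' and joins it to a plate layout. Malformed rows (non-finite or negative TOF
#' or EXT, well addresses outside the 8 x 12 grid) are skipped and logged.
#'
#' @param path Path to a CSV event file, or a tibble of events.
#' @param layout A [plate_layout()] tibble declaring strain/condition/wash per
#'   well.
#' @return Event tibble joined to the layout, with `wash` flagged. Skipped
#'   rows are in `attr(, "skipped")`.
#' @export
read_events <- function(path, layout) {
  ev <- if (is.data.frame(path)) as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(ev) == 0L) {
    warn("empty event file")
    out <- bind_cols(ev, layout[0, c("strain", "condition", "wash")])
    attr(out, "skipped") <- ev
    return(out)
  }
  need <- c("plate_id", "row", "col", "TOF", "EXT")
  if (!all(need %in% names(ev))) abort("event file missing required columns")

  bad <- !is.finite(ev$TOF) | !is.finite(ev$EXT) | ev$TOF < 0 | ev$EXT < 0 |
    !(ev$row %in% LETTERS[1:8]) | !(ev$col %in% 1:12)
  skipped <- ev[bad, , drop = FALSE]
  if (nrow(skipped) > 0L) {
    inform(paste(nrow(skipped), "malformed event rows skipped"))
  }
  ev <- ev[!bad, , drop = FALSE]

  known <- paste(layout$plate_id, layout$row, layout$col)
  offenders <- setdiff(unique(paste(ev$plate_id, ev$row, ev$col)), known)
  if (length(offenders) > 0L) {
    abort(paste("events in wells absent from the layout:",
                paste(offenders, collapse = "; ")))
  }
  out <- left_join(ev, layout, by = c("plate_id", "row", "col"))
  attr(out, "skipped") <- skipped
  out
}

#' Instrument hardware filter
#'
#' Retains objects meeting the sorter acquisition minimums: extinction
#' (EXT) >= 50 and time of flight (TOF) >= 20.
#'
#' @param events Event tibble.
#' @param min_ext,min_tof Acquisition minimums.
#' @return Filtered event tibble.
#' @export
hardware_filter <- function(events, min_ext = 50, min_tof = 20) {
  filter(events, .data$EXT >= min_ext, .data$TOF >= min_tof)
}

event_features <- function(events) {
  tof <- events$TOF
  tibble(TOF = tof, EXT = events$EXT,
         ratio = ifelse(tof > 0, events$EXT / tof, 0))
}

#' Train the bubble/animal classifier
#'
#' Fits a maximum-margin linear separator (support vector machine with linear
#' kernel, hinge loss, L2 penalty, cost fixed at 1) on standardized
#' `(TOF, EXT, EXT/TOF)` features. Bubbles are optically thin for their size,
#' so EXT relative to TOF carries most of the signal; the raw features let
#' the fitted weights show what dominates.
#'
#' @param events Labelled event tibble with a `truth` column
#'   (`"animal"`/`"bubble"`); both classes need >= 50 examples.
#' @param seed Integer seed (training is deterministic for a linear SVM, the
#'   seed pins any internal shuffling).
#' @return Object of class `bubble_classifier` wrapping the SVM, with the
#'   separating-plane weights on the standardized feature scale in `$weights`
#'   and training accuracy in `$training_accuracy`.
#' @export
train_bubble_classifier <- function(events, seed = 1) {
  if (!"truth" %in% names(events)) abort("training events need a `truth` column")
  y <- factor(events$truth, levels = c("bubble", "animal"))
  counts <- table(y)
  if (length(unique(events$truth)) < 2L) abort("both classes must be present")
  if (any(counts < 50L)) abort("need at least 50 examples of each class")
  X <- event_features(events)
  set.seed(seed)
  fit <- e1071::svm(x = as.matrix(X), y = y, kernel = "linear", cost = 1,
                    scale = TRUE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  pred <- predict(fit, as.matrix(X))
  structure(
    list(svm = fit, weights = w, bias = -fit$rho,
         training_accuracy = mean(pred == y)),
    class = "bubble_classifier"
  )
}

#' Classify events as animals or bubbles
#'
#' @param events Event tibble.
#' @param clf A trained [train_bubble_classifier()] object.
#' @return The events with an `object_class` column (`"animal"`/`"bubble"`).
#'   Per-well bubble fractions are logged in `attr(, "bubble_fractions")`.
#' @export
classify_events <- function(events, clf) {
  stopifnot(inherits(clf, "bubble_classifier"))
  if (nrow(events) == 0L) {
    return(mutate(events, object_class = character(0)))
  }
  X <- event_features(events)
  out <- mutate(events,
                object_class = as.character(predict(clf$svm, as.matrix(X))))
  attr(out, "bubble_fractions") <- out %>%
    group_by(.data$plate_id, .data$row, .data$col) %>%
    summarise(bubble_fraction = mean(.data$object_class == "bubble"),
              .groups = "drop")
  out
}

well_stats <- function(x, prefix) {
  n <- length(x)
  q <- if (n > 0) quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7,
                           names = FALSE) else rep(NA_real_, 5)
  vals <- c(
    mean = if (n > 0) mean(x) else NA_real_,
    var = if (n > 1) var(x) else NA_real_,
    iqr = q[4] - q[2],
    q10 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q90 = q[5]
  )
  setNames(vals, paste0(names(vals), "_", prefix))
}

#' Summarize wells into phenotype traits
#'
#' Per non-wash well: `n`, the animal count (the fecundity measure: every
#' object in the well is an offspring of the founding hermaphrodite), and
#' eight summary statistics (mean, variance, IQR and the 10/25/50/75/90th
#' quantiles, type-7 linear interpolation) for each of TOF, EXT and the
#' per-animal length-normalized optical density EXT/TOF - 25 trait columns in
#' all. Wells with no animals keep `n = 0` and `NA` size summaries; variance
#' uses the n-1 denominator and is `NA` for single-animal wells.
#'
#' @param events Classified event tibble (from [classify_events()], or any
#'   event table with an `object_class` column; a `truth` column is used when
#'   `object_class` is absent).
#' @return Tibble with `plate_id`, `row`, `col`, `strain`, `condition` and the
#'   25 trait columns.
#' @export
summarize_wells <- function(events) {
  cls <- if ("object_class" %in% names(events)) events$object_class else
    if ("truth" %in% names(events)) events$truth else
      abort("events must be classified first")
  ev <- events[cls == "animal", , drop = FALSE]
  wells <- events %>%
    filter(!.data$wash) %>%
    distinct(.data$plate_id, .data$row, .data$col, .data$strain, .data$condition)

  per_well <- ev %>%
    filter(!.data$wash) %>%
    group_by(.data$plate_id, .data$row, .data$col, .data$strain, .data$condition) %>%
    summarise(
      stats = {
        tof <- .data$TOF
        ext <- .data$EXT
        ratio <- ext / tof
        list(c(n = dplyr::n(),
               well_stats(tof, "TOF"),
               well_stats(ext, "EXT"),
               well_stats(ratio, "EXTpTOF")))
      },
      .groups = "drop"
    ) %>%
    tidyr::unnest_wider("stats")

  out <- left_join(wells, per_well,
                   by = c("plate_id", "row", "col", "strain", "condition"))
  out$n[is.na(out$n)] <- 0
  out
}

#' Names of the 25 sorter trait columns
#' @return Character vector: `n` plus 8 statistics x 3 parameters.
#' @export
trait_columns <- function() {
  stats <- c("mean", "var", "iqr", "q10", "q25", "q50", "q75", "q90")
  c("n", as.vector(outer(stats, c("TOF", "EXT", "EXTpTOF"), paste, sep = "_")))
}
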