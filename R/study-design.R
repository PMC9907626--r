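# Study-design bookkeeping: enumerating the expected acquisitions of a
# models x products x repetitions x operators x time-points design and
# accounting for missing images when forming before/after pairs.

#' Repeatability/reproducibility study design
#'
#' The reference design: 3 products applied to 9 models, 2 repetitions on
#' different days, 2 operators duplicating every imager acquisition, plus a
#' single-operator spectroradiometer, at 2 time points (before and
#' immediately after application).
#'
#' @param n_models number of panel models.
#' @param products character vector of product labels (unique).
#' @param n_repetitions number of test repetitions.
#' @param operators operator labels (imager acquisitions are duplicated per
#'   operator; the spectroradiometer is operated once).
#' @param instruments instrument labels; `"HSI"` rows are per-operator,
#'   `"PR-650"` rows are not.
#' @param time_points time point labels.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_models = 9, products = c("A", "B", "C"),
                         n_repetitions = 2, operators = c("Op.1", "Op.2"),
                         instruments = c("HSI", "PR-650"),
                         time_points = c("T0", "Timm")) {
  if (n_models < 1 || n_repetitions < 1 || length(products) < 1)
    stop_validation("all design counts must be >= 1")
  if (anyDuplicated(products)) stop_validation("product labels must be unique")
  structure(list(n_models = n_models, products = products,
                 n_repetitions = n_repetitions, operators = operators,
                 instruments = instruments, time_points = time_points),
            class = "study_design")
}

#' Enumerate the expected acquisitions of a design
#'
#' Imager acquisitions number models x products x time points x repetitions
#' x operators; spectroradiometer spectra drop the operator factor; the
#' number of independent tests is products x repetitions x instruments. The
#' reference design gives 216 images, 108 spectra and 12 independent tests.
#'
#' @param design a [study_design()].
#' @return List with `n_hsi_images`, `n_spectra`, `n_independent_tests`, and
#'   `acquisitions`, a data frame of every expected acquisition (columns
#'   `instrument`, `model`, `product`, `repetition`, `operator`,
#'   `timepoint`).
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  models <- sprintf("M%02d", seq_len(design$n_models))
  reps <- seq_len(design$n_repetitions)
  acq <- list()
  if ("HSI" %in% design$instruments) {
    acq$hsi <- expand.grid(instrument = "HSI", model = models,
                           product = design$products, repetition = reps,
                           operator = design$operators,
                           timepoint = design$time_points,
                           stringsAsFactors = FALSE)
  }
  if ("PR-650" %in% design$instruments) {
    acq$pr <- expand.grid(instrument = "PR-650", model = models,
                          product = design$products, repetition = reps,
                          operator = "-", timepoint = design$time_points,
                          stringsAsFactors = FALSE)
  }
  acquisitions <- do.call(rbind, acq)
  rownames(acquisitions) <- NULL
  list(n_hsi_images = sum(acquisitions$instrument == "HSI"),
       n_spectra = sum(acquisitions$instrument == "PR-650"),
       n_independent_tests = length(design$products) * design$n_repetitions *
         length(design$instruments),
       acquisitions = acquisitions)
}

#' Pair before/after acquisitions, accounting for missing images
#'
#' A `(T0, Timm)` pair survives only if both images of the session (same
#' instrument, model, product, repetition and operator) exist, so removing
#' either image of a session removes exactly that one pair. Starting from
#' the full 216-image design, removing 3 images from distinct sessions
#' leaves 105 pairs.
#'
#' @param records data frame of acquired images with the key columns
#'   `instrument`, `model`, `product`, `repetition`, `operator`,
#'   `timepoint`; keys must be unique.
#' @param design optional [study_design()] used to report expected counts.
#' @return List with `pairs` (data frame of complete sessions), `n_pairs`,
#'   `n_records`, `n_incomplete`, and a per-instrument summary.
#' @export
account_missing <- function(records, design = NULL) {
  keys <- c("instrument", "model", "product", "repetition", "operator")
  need <- c(keys, "timepoint")
  if (!all(need %in% names(records)))
    stop_structural("records need columns %s", paste(need, collapse = ", "))
  full_key <- do.call(paste, c(records[need], sep = "\r"))
  if (anyDuplicated(full_key))
    stop_validation("duplicate acquisition keys in records")
  session <- do.call(paste, c(records[keys], sep = "\r"))
  tp <- split(records$timepoint, session)
  complete <- names(tp)[vapply(tp, function(x) length(unique(x)) >= 2, logical(1))]
  pairs <- unique(records[session %in% complete, keys])
  rownames(pairs) <- NULL
  expected <- if (!is.null(design)) enumerate_design(design) else NULL
  list(pairs = pairs, n_pairs = nrow(pairs), n_records = nrow(records),
       n_incomplete = length(tp) - length(complete),
       by_instrument = table(pairs$instrument),
       expected = expected)
}
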