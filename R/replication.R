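# End-to-end study analysis: per instrument-repetition-operator subset,
# ANOVA + Tukey grouping of the product effects for each color parameter,
# plus operator-vs-operator and repetition-vs-repetition correlations.

#' Full repeatability/reproducibility analysis of an effects table
#'
#' For every `instrument x repetition x operator` subset of the effect
#' records, products are grouped by one-way ANOVA + Tukey HSD for each of
#' `dL`, `da`, `db`, `dE` and rendered as ranking strings. Correlation
#' analyses compare operators (matched on model, product, repetition within
#' each instrument) and repetitions (matched on model, product, operator).
#'
#' @param effects data frame with columns `model`, `product`, `repetition`,
#'   `operator`, `instrument`, `dL`, `da`, `db`, `dE`.
#' @param alpha significance level for ANOVA and Tukey tests.
#' @param params which effect columns to analyse.
#' @return List of class `hsi_replication`: `groupings` (data frame with
#'   instrument, repetition, operator, parameter, ranking, n_groups, F, p),
#'   `correlations` (data frame of comparison, parameter, slope, intercept,
#'   r, rho, mean_abs_diff, percent_nl, n), and `alpha`.
#' @export
run_replication <- function(effects, alpha = 0.01,
                            params = c("dL", "da", "db", "dE")) {
  need <- c("model", "product", "repetition", "operator", "instrument", params)
  if (!all(need %in% names(effects)))
    stop_structural("effects need columns %s", paste(need, collapse = ", "))

  subsets <- unique(effects[, c("instrument", "repetition", "operator")])
  g_rows <- list()
  for (s in seq_len(nrow(subsets))) {
    sel <- effects$instrument == subsets$instrument[s] &
      effects$repetition == subsets$repetition[s] &
      effects$operator == subsets$operator[s]
    sub <- effects[sel, ]
    for (p in params) {
      raw <- split(sub[[p]], sub$product)
      if (length(raw) < 2 || any(vapply(raw, length, integer(1)) < 2)) {
        warning(sprintf("subset %s/rep %s/%s skipped for %s: insufficient samples",
                        subsets$instrument[s], subsets$repetition[s],
                        subsets$operator[s], p), call. = FALSE)
        next
      }
      gr <- tukey_grouping(raw, alpha = alpha)
      g_rows[[length(g_rows) + 1]] <- data.frame(
        instrument = subsets$instrument[s], repetition = subsets$repetition[s],
        operator = subsets$operator[s], parameter = p,
        ranking = gr$ranking_string, n_groups = gr$n_groups,
        F = gr$anova$F, p = gr$anova$p)
    }
  }
  groupings <- if (length(g_rows)) do.call(rbind, g_rows) else NULL

  c_rows <- list()
  add_corr <- function(df1, df2, keys, label) {
    m <- merge(df1, df2, by = keys, suffixes = c(".1", ".2"))
    for (p in setdiff(params, "dE")) {
      x <- m[[paste0(p, ".1")]]; y <- m[[paste0(p, ".2")]]
      if (length(x) < 3 || sd(x) == 0) next
      cr <- correlate(x, y, group = m$product)
      nl <- percent_nonlinearity(x, y, fit = cr)
      c_rows[[length(c_rows) + 1]] <<- data.frame(
        comparison = label, parameter = p, slope = cr$slope,
        intercept = cr$intercept, r = cr$pearson_r, rho = cr$spearman_rho,
        mean_abs_diff = cr$mean_abs_diff, mae_group_means = cr$mae_group_means,
        percent_nl = nl$percent_nl, n = cr$n)
    }
  }
  for (ins in unique(effects$instrument)) {
    sub <- effects[effects$instrument == ins, ]
    ops <- sort(unique(sub$operator))
    if (length(ops) == 2) {
      add_corr(sub[sub$operator == ops[1], ], sub[sub$operator == ops[2], ],
               c("model", "product", "repetition"),
               sprintf("%s %s vs %s", ins, ops[2], ops[1]))
    }
    reps <- sort(unique(sub$repetition))
    if (length(reps) == 2) {
      add_corr(sub[sub$repetition == reps[1], ], sub[sub$repetition == reps[2], ],
               c("model", "product", "operator"),
               sprintf("%s rep %s vs %s", ins, reps[2], reps[1]))
    }
  }
  correlations <- if (length(c_rows)) do.call(rbind, c_rows) else NULL
  structure(list(groupings = groupings, correlations = correlations,
                 alpha = alpha),
            class = "hsi_replication")
}

#' @export
print.hsi_replication <- function(x, ...) {
  cat(sprintf("Replication analysis (alpha = %g)\n", x$alpha))
  if (!is.null(x$groupings)) {
    cat("Product groupings:\n")
    print(x$groupings, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$correlations)) {
    cat("Correlations:\n")
    print(x$correlations[, c("comparison", "parameter", "slope", "r", "rho",
                             "mean_abs_diff")], row.names = FALSE, digits = 3)
  }
  invisible(x)
}
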