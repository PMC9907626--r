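# One-way ANOVA (raw samples or published group summaries) and Tukey HSD
# grouping of products into statistically distinct subsets, rendered as
# compact ranking strings ("AC,B": ascending by mean, commas between
# statistical groups).

#' One-way ANOVA from raw samples or group summaries
#'
#' The summary-statistic path computes the classical decomposition from
#' per-group means, SDs and sizes alone:
#' `SSB = sum n_i (mean_i - grand)^2`, `SSW = sum (n_i - 1) sd_i^2`,
#' so results from published summary tables are exactly those a raw-data
#' ANOVA would give when the summaries derive from the raw samples.
#'
#' @param groups either a named list of numeric vectors (raw samples, each
#'   of length >= 2) or a data frame with columns `group`, `mean`, `sd`,
#'   `n` (`n >= 2`).
#' @return An object of class `hsi_anova`: `F`, `p`, `df_between`,
#'   `df_within`, `msw`, and the per-group `summaries`.
#' @export
anova_oneway <- function(groups) {
  summ <- as_group_summaries(groups)
  k <- nrow(summ)
  if (k < 2) stop_validation("ANOVA needs at least 2 groups")
  if (any(summ$n < 2)) stop_validation("every group needs n >= 2")
  N <- sum(summ$n)
  grand <- sum(summ$n * summ$mean) / N
  ssb <- sum(summ$n * (summ$mean - grand)^2)
  ssw <- sum((summ$n - 1) * summ$sd^2)
  df_b <- k - 1
  df_w <- N - k
  msb <- ssb / df_b
  msw <- ssw / df_w
  Fv <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  p <- if (is.infinite(Fv)) 0 else pf(Fv, df_b, df_w, lower.tail = FALSE)
  structure(list(F = Fv, p = p, df_between = df_b, df_within = df_w,
                 msw = msw, grand_mean = grand, summaries = summ),
            class = "hsi_anova")
}

as_group_summaries <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "mean", "sd", "n") %in% names(groups)))
      stop_structural("summary data frame needs columns group, mean, sd, n")
    summ <- groups[, c("group", "mean", "sd", "n")]
  } else if (is.list(groups)) {
    if (is.null(names(groups)) || any(names(groups) == ""))
      stop_structural("raw sample list must be named by group")
    summ <- data.frame(group = names(groups),
                       mean = vapply(groups, mean, numeric(1)),
                       sd = vapply(groups, sd, numeric(1)),
                       n = vapply(groups, length, numeric(1)))
  } else stop_structural("groups must be a named list or a summary data frame")
  if (anyDuplicated(summ$group)) stop_validation("group labels must be unique")
  rownames(summ) <- NULL
  summ
}

#' @export
print.hsi_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey HSD grouping of products into statistically distinct subsets
#'
#' Runs [anova_oneway()], then all-pairs Tukey HSD using the studentized
#' range distribution (Tukey--Kramer standard error for unequal group
#' sizes). Statistical groups are the maximal cliques of mutually
#' non-significant products -- the compact-letter-display convention -- and
#' `n_groups` counts those cliques. The ranking string orders products
#' ascending by mean (most negative first) with commas between groups; a
#' product whose membership overlaps two groups appears in each.
#'
#' @inheritParams anova_oneway
#' @param alpha significance level for the pairwise tests (default 0.01).
#' @return An object of class `hsi_grouping`: the `anova` result, the
#'   `pairwise` table (difference, studentized q, adjusted p, significance),
#'   `groups` (list of product vectors, ascending by mean), `n_groups`,
#'   `ranking_string`, and `means`.
#' @export
tukey_grouping <- function(groups, alpha = 0.01) {
  an <- anova_oneway(groups)
  summ <- an$summaries
  k <- nrow(summ)
  ord <- order(summ$mean)
  summ <- summ[ord, ]
  pw <- expand.grid(i = seq_len(k), j = seq_len(k))
  pw <- pw[pw$i < pw$j, ]
  se <- sqrt(an$msw / 2 * (1 / summ$n[pw$i] + 1 / summ$n[pw$j]))
  q <- abs(summ$mean[pw$i] - summ$mean[pw$j]) / se
  p_adj <- ptukey(q, k, an$df_within, lower.tail = FALSE)
  pairwise <- data.frame(group1 = summ$group[pw$i], group2 = summ$group[pw$j],
                         diff = summ$mean[pw$j] - summ$mean[pw$i],
                         q = q, p_adj = p_adj,
                         significant = p_adj < alpha)
  # adjacency of NON-significant pairs (self-loops implicit)
  ns <- matrix(FALSE, k, k)
  for (r in seq_len(nrow(pairwise)))
    if (!pairwise$significant[r]) {
      i <- match(pairwise$group1[r], summ$group)
      j <- match(pairwise$group2[r], summ$group)
      ns[i, j] <- ns[j, i] <- TRUE
    }
  diag(ns) <- TRUE
  cliques <- maximal_cliques(ns)
  # order cliques by the mean of their members; members are already mean-ordered
  cl_means <- vapply(cliques, function(ix) mean(summ$mean[ix]), numeric(1))
  cliques <- cliques[order(cl_means)]
  groups_out <- lapply(cliques, function(ix) summ$group[sort(ix)])
  ranking <- paste(vapply(groups_out, paste, character(1), collapse = ""),
                   collapse = ",")
  structure(list(anova = an, alpha = alpha, pairwise = pairwise,
                 groups = groups_out, n_groups = length(groups_out),
                 ranking_string = ranking,
                 means = setNames(summ$mean, summ$group)),
            class = "hsi_grouping")
}

# All maximal cliques of an undirected graph given as a logical adjacency
# matrix (Bron--Kerbosch without pivoting; product counts are small).
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      out[[length(out) + 1]] <<- sort(R)
      return()
    }
    while (length(P) > 0) {
      v <- P[1]
      nb <- which(adj[v, ] & seq_len(n) != v)
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- P[-1]
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out
}

#' @export
print.hsi_grouping <- function(x, ...) {
  cat(sprintf("Tukey HSD grouping (alpha = %g): \"%s\" (%d group%s); ANOVA p = %.3g\n",
              x$alpha, x$ranking_string, x$n_groups,
              if (x$n_groups == 1) "" else "s", x$anova$p))
  invisible(x)
}

#' Parse a ranking string back to its group structure
#'
#' Inverse of the ranking-string rendering: `"AC,B"` becomes
#' `list(c("A", "C"), "B")`. Product labels are single characters.
#'
#' @param ranking a ranking string.
#' @return List of character vectors, one per statistical group.
#' @export
parse_ranking <- function(ranking) {
  lapply(strsplit(ranking, ",", fixed = TRUE)[[1]],
         function(tok) strsplit(tok, "", fixed = TRUE)[[1]])
}
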