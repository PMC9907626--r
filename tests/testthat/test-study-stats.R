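# Design accounting, ANOVA/Tukey grouping, correlation metrics and the
# end-to-end replication analysis.

test_that("the reference design enumerates to the expected dataset sizes", {
  en <- enumerate_design(study_design())
  expect_equal(en$n_hsi_images, 216)
  expect_equal(en$n_spectra, 108)
  expect_equal(en$n_independent_tests, 12)
})

test_that("pairing survives exactly the sessions with both time points", {
  en <- enumerate_design(study_design())
  hsi <- en$acquisitions[en$acquisitions$instrument == "HSI", ]
  full <- account_missing(hsi)
  expect_equal(full$n_pairs, 108)
  # remove three images from distinct sessions -> 105 pairs
  t0_rows <- which(hsi$timepoint == "T0")[c(1, 5, 9)]
  expect_equal(account_missing(hsi[-t0_rows, ])$n_pairs, 105)
  # removing both images of one session still costs exactly one pair
  key <- paste(hsi$model, hsi$product, hsi$repetition, hsi$operator)
  both <- which(key == key[1])
  expect_equal(account_missing(hsi[-both, ])$n_pairs, 107)
  expect_error(account_missing(rbind(hsi, hsi[1, ])), "duplicate")
})

test_that("summary-statistic ANOVA reproduces published group comparisons", {
  # second-repetition imager/operator-2 lightness effects
  res <- anova_oneway(data.frame(group = c("A", "B", "C"),
                                 mean = c(0.27, 3.95, 1.46),
                                 sd = c(0.69, 1.04, 0.77), n = 9))
  expect_equal(res$F, 44.3, tolerance = 0.01)
  expect_lt(res$p, 1e-7)
  # identical constant groups: F = 0, p = 1
  same <- anova_oneway(list(A = rep(2, 5), B = rep(2, 5), C = rep(2, 5)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(anova_oneway(list(A = 1:3)), "2 groups")
  expect_error(anova_oneway(list(A = 1:3, B = 2)), "n >= 2")
})

test_that("summary and raw ANOVA agree exactly, and match stats::aov", {
  set.seed(101)
  for (i in 1:10) {
    raw <- list(A = rnorm(9, 0, 1), B = rnorm(7, 1, 1.5), C = rnorm(11, 0.5, 0.8))
    from_raw <- anova_oneway(raw)
    summ <- data.frame(group = names(raw),
                       mean = sapply(raw, mean), sd = sapply(raw, sd),
                       n = sapply(raw, length))
    from_summ <- anova_oneway(summ)
    expect_equal(from_raw$F, from_summ$F, tolerance = 1e-10)
    expect_equal(from_raw$p, from_summ$p, tolerance = 1e-10)
    # independent oracle: classical aov on the same data
    df <- data.frame(y = unlist(raw),
                     g = rep(names(raw), sapply(raw, length)))
    ref <- summary(stats::aov(y ~ g, df))[[1]]
    expect_equal(from_raw$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(from_raw$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("Tukey grouping separates what the data can separate", {
  # well-separated groups -> three singletons, ascending ranking
  wide <- tukey_grouping(data.frame(group = c("A", "B", "C"),
                                    mean = c(10, -10, 0), sd = 1, n = 9))
  expect_equal(wide$n_groups, 3)
  expect_equal(wide$ranking_string, "B,C,A")
  # indistinguishable groups -> one token
  flat <- tukey_grouping(data.frame(group = c("A", "B", "C"),
                                    mean = c(0.1, 0, 0.05), sd = 1, n = 9))
  expect_equal(flat$n_groups, 1)
  expect_false(grepl(",", flat$ranking_string))
  # published lightness summaries: A and C share a group, B stands apart
  dl <- tukey_grouping(data.frame(group = c("A", "B", "C"),
                                  mean = c(0.27, 3.95, 1.46),
                                  sd = c(0.69, 1.04, 0.77), n = 9))
  expect_equal(dl$ranking_string, "AC,B")
  expect_equal(dl$n_groups, 2)
})

test_that("clique grouping matches the brute-force studentized-range oracle", {
  set.seed(202)
  for (i in 1:40) {
    k <- sample(3:5, 1)
    summ <- random_summaries(k = k, n = sample(5:12, 1))
    got <- tukey_grouping(summ, alpha = 0.01)
    want <- brute_tukey_groups(summ, alpha = 0.01)
    norm <- function(gs) sort(vapply(gs, function(g) paste(sort(g), collapse = ""), character(1)))
    expect_equal(norm(got$groups), norm(want))
  }
})

test_that("grouping letters agree with multcomp's compact letter display", {
  set.seed(303)
  for (i in 1:10) {
    raw <- list(A = rnorm(9, 0), B = rnorm(9, sample(c(0, 2, 4), 1)),
                C = rnorm(9, sample(c(0, 1, 3), 1)))
    got <- tukey_grouping(raw, alpha = 0.01)
    df <- data.frame(y = unlist(raw), g = factor(rep(names(raw), each = 9)))
    fit <- multcomp::glht(stats::aov(y ~ g, df), multcomp::mcp(g = "Tukey"))
    cld <- multcomp::cld(fit, level = 0.01)$mcletters$Letters
    # same number of statistical groups (distinct letters)
    expect_equal(got$n_groups, length(unique(unlist(strsplit(cld, "")))))
    # same membership structure: products sharing a letter share a clique
    share_letter <- outer(cld, cld, Vectorize(function(x, y)
      any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])))
    share_clique <- outer(names(raw), names(raw), Vectorize(function(x, y)
      any(vapply(got$groups, function(g) all(c(x, y) %in% g), logical(1)))))
    expect_equal(unname(share_clique), unname(share_letter))
  }
})

test_that("ranking strings round-trip to their group structure", {
  set.seed(404)
  for (i in 1:20) {
    gr <- tukey_grouping(random_summaries(k = sample(3:4, 1)), alpha = 0.05)
    expect_equal(parse_ranking(gr$ranking_string), gr$groups)
  }
})

test_that("correlation metrics match hand-computed values", {
  x <- 0:4; y <- c(0, 1, 2, 3, 5)
  cr <- correlate(x, y)
  expect_equal(cr$slope, 1.2)
  expect_equal(cr$intercept, -0.2)
  ident <- correlate(1:10, 1:10 * 1.0)
  expect_equal(c(ident$slope, ident$intercept, ident$pearson_r,
                 ident$spearman_rho, ident$mean_abs_diff), c(1, 0, 1, 1, 0))
  expect_equal(correlate(1:10, -(1:10))$pearson_r, -1)
  expect_error(correlate(1:2, 1:2), "3 matched")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("percent nonlinearity spans the extreme residuals over max signal", {
  x <- 0:4; y <- c(0, 1, 2, 3, 5)
  nl <- percent_nonlinearity(x, y)
  expect_equal(nl$delta_plus, 0.4)
  expect_equal(nl$delta_minus, -0.4)
  expect_equal(nl$percent_nl, 16)
  # perfectly linear -> 0; scale invariance
  lin <- percent_nonlinearity(x, 2 * x + 1)
  expect_equal(lin$percent_nl, 0, tolerance = 1e-12)
  dbl <- percent_nonlinearity(2 * x, 2 * y)
  expect_equal(dbl$percent_nl, nl$percent_nl, tolerance = 1e-12)
  expect_error(percent_nonlinearity(x, rep(0, 5) + c(-1, 1, 0, 1, -1) * 1e-9,
                                    max_signal = 0), "zero")
})

test_that("boxplot summaries follow the quartile and whisker rules", {
  bs <- boxplot_summary(1:9)
  expect_equal(bs$median, 5)
  expect_equal(c(bs$q1, bs$q3), unname(quantile(1:9, c(0.25, 0.75))))
  expect_length(bs$outliers, 0)
  const <- boxplot_summary(rep(3, 6))
  expect_equal(c(const$q1, const$q3, const$whisker_low, const$whisker_high),
               rep(3, 4))
  out <- boxplot_summary(c(0, 0, 0, 0, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 0)
})

test_that("null simulations reject at about the nominal 1% rate", {
  set.seed(505)
  n_sim <- 600
  rejections <- 0
  for (i in 1:n_sim) {
    raw <- list(A = rnorm(9), B = rnorm(9), C = rnorm(9))
    if (tukey_grouping(raw, alpha = 0.01)$n_groups > 1) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  # binomial 3-sigma band around 0.01 for n = 600
  expect_lte(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / n_sim))
})

test_that("the nominal strong-lightening effect is resolved at panel size", {
  set.seed(606)
  separated <- 0
  for (i in 1:100) {
    raw <- list(A = rnorm(9, 0.3, 1), B = rnorm(9, 3.9, 1), C = rnorm(9, 1.5, 1))
    gr <- tukey_grouping(raw, alpha = 0.01)
    apart <- !any(vapply(gr$groups, function(g) all(c("A", "B") %in% g), logical(1)))
    if (apart) separated <- separated + 1
  }
  expect_gte(separated, 95)
})

test_that("replication analysis is deterministic and structured per subset", {
  sim <- simulate_study(seed = 7, spatial = FALSE,
                        design = study_design(instruments = "HSI"))
  rep1 <- run_replication(sim$effects)
  rep2 <- run_replication(sim$effects[sample(nrow(sim$effects)), ])
  expect_equal(nrow(rep1$groupings), 16) # 2 reps x 2 operators x 4 params
  ord <- function(g) g[order(g$repetition, g$operator, g$parameter), ]
  expect_equal(ord(rep1$groupings)$ranking, ord(rep2$groupings)$ranking)
  # lightness ranking ascends A, C, B in every subset at the injected effects
  dl <- rep1$groupings[rep1$groupings$parameter == "dL", ]
  expect_true(all(gsub(",", "", dl$ranking) == "ACB"))
  expect_equal(nrow(rep1$correlations), 6)
  expect_true(all(abs(rep1$correlations$r) <= 1))
  expect_true(all(abs(rep1$correlations$rho) <= 1))
})
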