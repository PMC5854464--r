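#' Segregation statistics for score tables
#'
#' Summaries and tests comparing observed progeny counts to theoretical
#' Mendelian ratios: per-subline percentages and across-subline mean +/- SD
#' in the layout of the mating-procedure result table, one-sample two-tailed
#' t-tests of the class means against the theoretical percentages, per-brood
#' multinomial goodness-of-fit, the insertion-number and homozygous-viability
#' classification rules, and the germline recombination efficiency
#' estimator.
#'
#' @name stats_module
NULL

#' Round half away from zero
#'
#' Percentage formatting used throughout: one-decimal values rounded half
#' away from zero (e.g. 46/96 -> 47.9, 0.25 at one decimal -> 0.3), the
#' convention that reproduces the printed per-subline percentages.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-subline class percentages
#'
#' @param scores score table (`step`, `subline`, `class`, `count`).
#' @param digits decimal places for the percentage.
#' @return data frame `step`, `subline`, `class`, `count`, `total`, `pct`.
#'   Zero-total broods are excluded with a warning.
#' @export
score_percentages <- function(scores, digits = 1) {
  stopifnot(all(c("step", "subline", "class", "count") %in% names(scores)))
  if ("sex" %in% names(scores)) {
    scores <- stats::aggregate(count ~ step + subline + class, data = scores,
                               FUN = sum)
  }
  totals <- stats::aggregate(count ~ step + subline, data = scores, FUN = sum)
  names(totals)[3] <- "total"
  zero <- totals[totals$total == 0L, , drop = FALSE]
  if (nrow(zero) > 0L) {
    warning(sprintf("excluding %d zero-total brood(s): %s", nrow(zero),
                    paste(zero$step, zero$subline, sep = "/", collapse = ", ")),
            call. = FALSE)
  }
  out <- merge(scores, totals, by = c("step", "subline"))
  out <- out[out$total > 0L, , drop = FALSE]
  out$pct <- round_half_away(100 * out$count / out$total, digits)
  out[order(out$step, out$subline, match(out$class, phenotype_classes())), ]
}

#' One-sample two-tailed Student's t-test
#'
#' Tests whether the arithmetic mean of `x` differs from `mu`;
#' `t = (mean - mu) / (SD / sqrt(n))` with `df = n - 1` and sample SD
#' (n-1 denominator). Implemented through [stats::t.test()]. When the
#' sample has zero spread the test degenerates: an exact match is reported
#' as `t = 0, p = 1`, a constant sample away from `mu` as infinite `t`
#' with `p = 0`.
#'
#' @param x numeric sample (n >= 2).
#' @param mu theoretical value.
#' @return list with `statistic`, `df`, `p_value`, `mean`, `sd`.
#' @export
one_sample_ttest <- function(x, mu) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("t-test requires n >= 2", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    exact <- isTRUE(all.equal(mean(x), mu))
    return(list(statistic = if (exact) 0 else sign(mean(x) - mu) * Inf,
                df = length(x) - 1L,
                p_value = if (exact) 1 else 0,
                mean = mean(x), sd = 0))
  }
  tt <- stats::t.test(x, mu = mu, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean = mean(x), sd = s)
}

.theoretical_pcts <- function(theoretical) {
  if (inherits(theoretical, "crossing_plan")) {
    theoretical <- run_exact(theoretical)
  }
  if (inherits(theoretical, "plan_result")) {
    out <- lapply(theoretical, function(r) {
      stats::setNames(100 * as.numeric(r$classes$probs), r$classes$labels)
    })
    return(out)
  }
  theoretical  # named list: step -> named percent vector
}

#' Class summaries across sublines, with t-tests against theory
#'
#' Per (step, class): the per-subline percentages (classes absent from a
#' subline count as 0), their mean and sample SD (n-1) displayed to one
#' decimal, and -- when a theoretical distribution is supplied -- the
#' one-sample two-tailed t-test of the per-subline percentages against the
#' theoretical percentage. Mean, SD and the t-test operate on the rounded
#' one-decimal percentages, i.e. on the values a reader of the printed
#' result table sees.
#'
#' @param scores score table.
#' @param theoretical optional: a [crossing_plan()], a `plan_result`, or a
#'   named list mapping step id to a named vector of theoretical
#'   percentages.
#' @param digits decimal places.
#' @return data frame `step`, `class`, `n_sublines`, `mean_pct`, `sd_pct`,
#'   `theoretical_pct`, `statistic`, `df`, `p_value` (test columns `NA`
#'   without theory, for single sublines, or for classes with no theoretical
#'   expectation).
#' @export
summarize_scores <- function(scores, theoretical = NULL, digits = 1) {
  pcts <- score_percentages(scores, digits)
  theo <- if (is.null(theoretical)) NULL else .theoretical_pcts(theoretical)
  out <- list()
  for (id in unique(pcts$step)) {
    sub <- pcts[pcts$step == id, , drop = FALSE]
    sublines <- unique(sub$subline)
    classes <- unique(sub$class)
    if (!is.null(theo) && !is.null(theo[[id]])) {
      classes <- union(classes, names(theo[[id]])[theo[[id]] > 0])
    }
    classes <- classes[order(match(classes, phenotype_classes()))]
    for (cl in classes) {
      vals <- vapply(sublines, function(s) {
        v <- sub$pct[sub$subline == s & sub$class == cl]
        if (length(v) == 0L) 0 else v
      }, numeric(1))
      n <- length(vals)
      mu <- if (!is.null(theo) && !is.null(theo[[id]])) {
        # match() rather than name-indexing: the wild-type class label is ""
        idx <- match(cl, names(theo[[id]]))
        if (is.na(idx)) NA_real_ else unname(theo[[id]][idx])
      } else NA_real_
      tt <- if (!is.na(mu) && n >= 2L) one_sample_ttest(vals, mu) else NULL
      out[[length(out) + 1L]] <- data.frame(
        step = id, class = cl, n_sublines = n,
        mean_pct = round_half_away(mean(vals), digits),
        sd_pct = if (n >= 2L) round_half_away(stats::sd(vals), digits)
                 else NA_real_,
        theoretical_pct = mu,
        statistic = if (is.null(tt)) NA_real_ else tt$statistic,
        df = if (is.null(tt)) NA_real_ else tt$df,
        p_value = if (is.null(tt)) NA_real_ else tt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pooled-deviation t-test per step
#'
#' Alternative reading of "means vs theoretical ratios": for one step, all
#' (subline, class) percentage deviations from theory form a single sample
#' tested against zero. Deviations within a brood sum to ~0 by construction,
#' so this variant is far less sensitive than the per-class tests and is
#' provided for comparison only.
#'
#' @param scores score table.
#' @param theoretical as in [summarize_scores()].
#' @return data frame `step`, `n`, `statistic`, `df`, `p_value`.
#' @export
pooled_deviation_test <- function(scores, theoretical) {
  pcts <- score_percentages(scores)
  theo <- .theoretical_pcts(theoretical)
  out <- list()
  for (id in intersect(unique(pcts$step), names(theo))) {
    sub <- pcts[pcts$step == id, , drop = FALSE]
    classes <- names(theo[[id]])[theo[[id]] > 0]
    devs <- unlist(lapply(unique(sub$subline), function(s) {
      vapply(classes, function(cl) {
        v <- sub$pct[sub$subline == s & sub$class == cl]
        (if (length(v) == 0L) 0 else v) -
          theo[[id]][match(cl, names(theo[[id]]))]
      }, numeric(1))
    }))
    if (length(devs) < 2L) next
    tt <- one_sample_ttest(devs, 0)
    out[[length(out) + 1L]] <- data.frame(
      step = id, n = length(devs), statistic = tt$statistic, df = tt$df,
      p_value = tt$p_value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Multinomial goodness of fit for one brood
#'
#' Chi-square statistic against the theoretical class distribution, with an
#' exact multinomial p-value (probability, under theory, of an outcome at
#' most as probable as the observed one) when the brood is small enough to
#' enumerate -- total at most 200 and at most `max_outcomes` compositions --
#' and the asymptotic chi-square p-value otherwise. A class observed with
#' zero theoretical probability is a model violation, reported as such
#' rather than as a p-value.
#'
#' @param counts named integer vector of class counts.
#' @param dist theoretical distribution: [pmf()] or named numeric
#'   probabilities.
#' @param max_outcomes enumeration budget for the exact test.
#' @return list with `statistic`, `df`, `p_value`, `method`
#'   (`"exact multinomial"` or `"chi-square"`), and on violation
#'   `violation = TRUE` with the offending `classes`.
#' @export
multinomial_gof <- function(counts, dist, max_outcomes = 5e5) {
  if (inherits(dist, "pmf")) {
    dist <- stats::setNames(as.numeric(dist$probs), dist$labels)
  }
  stopifnot(!is.null(names(counts)), !is.null(names(dist)))
  n <- sum(counts)
  if (n <= 0L) stop("total count must be positive", call. = FALSE)

  p_obs <- dist[match(names(counts), names(dist))]
  p_obs[is.na(p_obs)] <- 0
  bad <- names(counts)[counts > 0 & p_obs == 0]
  if (length(bad) > 0L) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                method = "model violation", violation = TRUE, classes = bad))
  }

  # align to the support of the theoretical distribution
  support <- names(dist)[dist > 0]
  x <- stats::setNames(integer(length(support)), support)
  hit <- match(names(counts), support)
  x[hit[!is.na(hit)]] <- counts[!is.na(hit)]
  p <- unname(dist[match(support, names(dist))])
  p <- p / sum(p)
  k <- length(support)
  expected <- n * p
  statistic <- sum((x - expected)^2 / expected)
  df <- k - 1L

  n_outcomes <- choose(n + k - 1, k - 1)
  if (n <= 200L && n_outcomes <= max_outcomes && k >= 2L) {
    compositions <- .compositions(n, k)
    logp <- lgamma(n + 1) - rowSums(lgamma(compositions + 1)) +
      compositions %*% log(p)
    obs_logp <- lgamma(n + 1) - sum(lgamma(x + 1)) + sum(x * log(p))
    p_value <- sum(exp(logp[logp <= obs_logp + 1e-9]))
    p_value <- min(1, p_value)
    method <- "exact multinomial"
  } else {
    p_value <- stats::pchisq(statistic, df, lower.tail = FALSE)
    method <- "chi-square"
  }
  list(statistic = unname(statistic), df = df, p_value = unname(p_value),
       method = method, violation = FALSE)
}

# all length-k compositions of n, as a matrix (rows), via stars and bars
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  bars <- utils::combn(n + k - 1L, k - 1L)
  b <- rbind(rep(0L, ncol(bars)), bars, rep(n + k, ncol(bars)))
  t(b[-1L, , drop = FALSE] - b[-nrow(b), , drop = FALSE] - 1L)
}

#' Classify insertion number from a hemizygote x wild-type cross
#'
#' A single unlinked insertion transmits to 50% of progeny; two or more
#' independent insertions to 75% or more. The decision rule: a transgene
#' distribution of 60% or less (inclusive) among scored progeny is a single
#' insertion.
#'
#' @param carrier_fraction proportion of progeny carrying the transgene.
#' @return `"single"` or `"multiple"`.
#' @export
classify_insertions <- function(carrier_fraction) {
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1)
  if (carrier_fraction <= 0.60) "single" else "multiple"
}

#' Classify homozygous viability from a hemizygote x hemizygote cross
#'
#' Full viability gives an expected carrier fraction of 3/4; homozygous
#' lethality reduces the survivor-conditional carrier fraction to 2/3.
#' The decision rule: 70% or more (inclusive) is homozygous viable.
#'
#' @param carrier_fraction proportion of progeny carrying the transgene.
#' @return `"homozygous-viable"` or `"suspect"`.
#' @export
classify_viability <- function(carrier_fraction) {
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1)
  if (carrier_fraction >= 0.70) "homozygous-viable" else "suspect"
}

#' Estimate germline recombination efficiency from a post-recombination step
#'
#' Among transgene carriers in the post-recombination generation, the
#' fraction still displaying both markers estimates the unresolved fraction:
#' `p_hat = 1 - both-marker carriers / transgene carriers`, with a
#' Clopper-Pearson interval from the binomial count of unresolved carriers.
#'
#' @param scores score table.
#' @param step id of the post-recombination step.
#' @param conf_level confidence level for the interval.
#' @return list with `p_hat`, `ci` (length 2), `both`, `carriers`,
#'   `total`, and `residual_both_fraction` (both-marker progeny among all
#'   progeny of the step).
#' @export
estimate_recombination_efficiency <- function(scores, step,
                                              conf_level = 0.95) {
  rows <- scores[scores$step == step, , drop = FALSE]
  if (nrow(rows) == 0L) stop(sprintf("no rows for step '%s'", step),
                             call. = FALSE)
  carriers <- sum(rows$count[.is_carrier_class(rows$class)])
  both <- sum(rows$count[.has_both_markers(rows$class)])
  total <- sum(rows$count)
  if (carriers == 0L) stop("no transgene carriers in step", call. = FALSE)
  bt <- stats::binom.test(both, carriers, conf.level = conf_level)
  list(p_hat = 1 - both / carriers,
       ci = rev(1 - bt$conf.int),
       both = as.integer(both), carriers = as.integer(carriers),
       total = as.integer(total),
       residual_both_fraction = both / total)
}
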