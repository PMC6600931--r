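#' Zero out non-significant effects
#'
#' @param estimate,se Effect estimates and standard errors. Effects with a
#'   missing standard error (e.g. terms dropped from a model) count as
#'   non-significant.
#' @param se_factor Effects with `|estimate| <= se_factor * se` are set to 0.
#' @return Numeric vector.
#' @export
zero_nonsig <- function(estimate, se, se_factor = 2) {
  ifelse(is.na(se) | abs(estimate) <= se_factor * se, 0, estimate)
}

orient_effects <- function(e) {
  if (all(e == 0)) return(e)
  s <- sign(e[which.max(abs(e))])
  e * s
}

#' Best-site and worst-site allelic effects
#'
#' Effects are oriented so the largest-magnitude effect is positive (the
#' allele is viewed from its best site); `best` is the maximum effect and
#' `worst` is the absolute effect at the worst-performing site. With
#' `zero_nonsig = TRUE` (default) effects within two SEs of zero are zeroed
#' first, so a conditionally neutral allele has `worst = 0` while an
#' antagonistically pleiotropic one has `worst > 0` from its reversed site.
#'
#' @param estimate Per-site effects for one QTL/contrast (>= 2 sites).
#' @param se Standard errors (required when `zero_nonsig` is TRUE).
#' @param zero_nonsig Zero effects within `se_factor` SEs of zero first.
#' @param se_factor Significance gate (default 2).
#' @return Named vector: best, worst.
#' @export
best_worst <- function(estimate, se = NULL, zero_nonsig = TRUE,
                       se_factor = 2) {
  assert_that(length(estimate) >= 2, "need at least 2 sites")
  e <- estimate
  if (zero_nonsig) {
    assert_that(!is.null(se), "se needed to zero non-significant effects")
    e <- zero_nonsig(e, se, se_factor)
  }
  e <- orient_effects(e)
  c(best = max(e), worst = abs(min(e)))
}

#' Benefit and cost sums across sites
#'
#' Under the same orientation and significance-zeroing as [best_worst()],
#' the benefit is the sum of effects over sites where the allele helps and
#' the cost the sum where it has effects in the opposite direction.
#'
#' @inheritParams best_worst
#' @return Named vector: benefit, cost (cost <= 0).
#' @export
benefit_cost_sums <- function(estimate, se = NULL, zero_nonsig = TRUE,
                              se_factor = 2) {
  e <- estimate
  if (zero_nonsig) {
    assert_that(!is.null(se), "se needed to zero non-significant effects")
    e <- zero_nonsig(e, se, se_factor)
  }
  e <- orient_effects(e)
  c(benefit = sum(pmax(e, 0)), cost = sum(pmin(e, 0)))
}

#' Trade-off summaries for every QTL x contrast
#'
#' @param effects Tibble: qtl, term (contrast), env, estimate, se.
#' @param zero_nonsig,se_factor Passed to [best_worst()].
#' @return Tibble: qtl, term, best, worst, benefit_sum, cost_sum.
#' @export
tradeoff_table <- function(effects, zero_nonsig = TRUE, se_factor = 2) {
  effects |>
    dplyr::group_by(.data$qtl, .data$term) |>
    dplyr::summarise(
      best = best_worst(.data$estimate, .data$se, zero_nonsig, se_factor)[1],
      worst = best_worst(.data$estimate, .data$se, zero_nonsig, se_factor)[2],
      benefit_sum = benefit_cost_sums(.data$estimate, .data$se,
                                      zero_nonsig, se_factor)[1],
      cost_sum = benefit_cost_sums(.data$estimate, .data$se,
                                   zero_nonsig, se_factor)[2],
      .groups = "drop"
    )
}

#' Directional concordance of effects between the two cross contrasts
#'
#' An effect is called significant when it lies at least `sd_threshold`
#' standard deviations from the mean of the pooled effect distribution of
#' its contrast. Among QTL x site pairs where both contrasts are
#' significant, reports the proportion with the same sign and a two-sided
#' exact binomial test against 0.5.
#'
#' @param effects_a,effects_a2 Equal-length vectors of paired signed effects
#'   (one entry per QTL x site) for the two cross contrasts.
#' @param sd_threshold Significance cutoff in pooled SDs (default 2).
#' @return Tibble: n_pairs, n_same, prop_same, p_value. Zero qualifying
#'   pairs yields NA with a warning.
#' @export
cross_concordance <- function(effects_a, effects_a2, sd_threshold = 2) {
  assert_that(length(effects_a) == length(effects_a2),
              "paired effect vectors must have equal length")
  sig_a <- abs(effects_a - mean(effects_a)) >= sd_threshold * stats::sd(effects_a)
  sig_a2 <- abs(effects_a2 - mean(effects_a2)) >=
    sd_threshold * stats::sd(effects_a2)
  both <- sig_a & sig_a2
  n <- sum(both)
  if (n == 0) {
    warning("no QTL x site pair significant in both contrasts")
    return(tibble::tibble(n_pairs = 0L, n_same = NA_integer_,
                          prop_same = NA_real_, p_value = NA_real_))
  }
  same <- sum(sign(effects_a[both]) == sign(effects_a2[both]))
  bt <- stats::binom.test(same, n, p = 0.5, alternative = "two.sided")
  tibble::tibble(n_pairs = n, n_same = same, prop_same = same / n,
                 p_value = bt$p.value)
}

#' Survival contrast between two groups
#'
#' Odds ratio of survival `(alive1/dead1) / (alive2/dead2)` with a
#' two-sided Fisher exact P value (hypergeometric). Counts may be rates per
#' 100; the Fisher test rounds to integers. A zero cell triggers the
#' Haldane-Anscombe 0.5 correction for the odds ratio.
#'
#' @param dead1,alive1,dead2,alive2 Cell counts (margins must be positive).
#' @return One-row tibble: odds_ratio, p_value, corrected.
#' @export
survival_contrast <- function(dead1, alive1, dead2, alive2) {
  counts <- c(dead1, alive1, dead2, alive2)
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(dead1 + alive1 > 0 && dead2 + alive2 > 0,
              "each group needs observations")
  corrected <- any(counts == 0)
  cc <- if (corrected) counts + 0.5 else counts
  or <- (cc[2] / cc[1]) / (cc[4] / cc[3])
  tab <- matrix(round(counts), 2, byrow = TRUE)
  p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    stats::fisher.test(tab)$p.value
  } else NA_real_
  tibble::tibble(odds_ratio = or, p_value = p, corrected = corrected)
}
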