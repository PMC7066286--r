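#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Small-sample group comparison reporting both the rank-sum `W` of the first
#' sample and the Mann-Whitney `U = W - n1 * (n1 + 1) / 2`. The p-value is
#' exact (no-ties enumeration) when `n1 + n2 <= 20` and there are no ties,
#' otherwise a normal approximation with tie correction is used. `tail =
#' "greater"` tests whether `x` tends to exceed `y`.
#'
#' @param x,y Numeric samples (nonempty).
#' @param tail `"two-sided"`, `"greater"` or `"less"`.
#' @return One-row tibble of class `group_result`: `n_x`, `n_y`,
#'   `rank_sum_w`, `u_statistic`, `p_value`, `tail`, `exact`, and group
#'   descriptives (`mean_x`, `sd_x`, `mean_y`, `sd_y`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6), tail = "less")
rank_sum_test <- function(x, y, tail = c("two-sided", "greater", "less")) {
  tail <- match.arg(tail)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be nonempty.", class = "oddlock_parameter_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (n1 + n2) <= 20
  alt <- switch(tail, "two-sided" = "two.sided", greater = "greater",
                less = "less")
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = exact, correct = TRUE)
  )
  u <- unname(ht$statistic)                    # R's W is the Mann-Whitney U
  w <- u + n1 * (n1 + 1) / 2                   # rank-sum of x
  out <- tibble(
    n_x = n1, n_y = n2,
    rank_sum_w = w,
    u_statistic = u,
    p_value = unname(ht$p.value),
    tail = tail,
    exact = exact,
    mean_x = mean(x), sd_x = sd(x),
    mean_y = mean(y), sd_y = sd(y)
  )
  class(out) <- c("group_result", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (sort ascending, multiply by `m / i`, enforce
#' monotonicity from the largest down, cap at 1), returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].",
          class = "oddlock_parameter_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Mid-ranks for ties; exact two-sided p for `n <= 9` without ties, the
#' t-approximation otherwise (the `stats::cor.test` conventions).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return One-row tibble of class `correlation_cell`: `rho`, `p_two_sided`,
#'   `n`, `degenerate` (constant input).
#' @export
#' @examples
#' spearman_cor(1:4, c(2, 1, 4, 3))
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort("Need equal-length samples with n >= 3.",
          class = "oddlock_parameter_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input: Spearman correlation undefined.")
    out <- tibble(rho = NA_real_, p_two_sided = NA_real_, n = n,
                  degenerate = TRUE)
  } else {
    ht <- suppressWarnings(
      cor.test(x, y, method = "spearman", alternative = "two.sided")
    )
    out <- tibble(rho = unname(ht$estimate), p_two_sided = unname(ht$p.value),
                  n = n, degenerate = FALSE)
  }
  class(out) <- c("correlation_cell", class(out))
  out
}

#' Spearman correlation matrix over outcome change scores
#'
#' Pairwise Spearman correlations (with two-sided p-values) between the
#' pre-to-post change scores of the requested measures — the relational
#' check that P300 amplitude change tracks behavioral change.
#'
#' @param changes A change table from [change_table()] (or any tibble with
#'   `subject`, `measure`, `comparison`, `value`).
#' @param comparison Which comparison to correlate (default `"pre-to-post"`).
#' @return A tibble with one row per unordered measure pair: `measure_1`,
#'   `measure_2`, `rho`, `p_two_sided`, `n`.
#' @export
correlate_changes <- function(changes, comparison = "pre-to-post") {
  wide <- changes |>
    dplyr::filter(.data$comparison == !!comparison) |>
    tidyr::pivot_wider(id_cols = "subject", names_from = "measure",
                       values_from = "value")
  measures <- setdiff(names(wide), "subject")
  pairs <- utils::combn(measures, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    cc <- spearman_cor(wide[[pr[1]]], wide[[pr[2]]])
    tibble(measure_1 = pr[1], measure_2 = pr[2],
           rho = cc$rho, p_two_sided = cc$p_two_sided, n = cc$n)
  })
}

#' Run the full hypothesis-testing plan on an outcome table
#'
#' Implements the study's inference plan on change scores:
#' * Amplitude hypothesis: right-tailed rank-sum test (stim > sham) on the
#'   relative pre-to-post P300 amplitude change, uncorrected.
#' * Behavioral hypotheses: left-tailed tests (stim < sham, a hypothesized
#'   decrease) on pre-to-post and pre-to-during change, two-sided on
#'   during-to-post; within each measure the three comparisons are BH
#'   FDR-corrected.
#' * ERSP hypothesis: right-tailed test on the relative pre-to-post change
#'   of the windowed ERSP maximum, uncorrected.
#'
#' Commission errors are dropped from inference when no condition exceeds
#' `commission_min` presses in either group (rare false alarms carry no
#' rankable signal).
#'
#' @param outcomes An `outcome_set` (long format, both groups present).
#' @param behavioral_measures Named basis vector for the behavioral measures
#'   (see [change_table()]).
#' @param commission_min Per-condition commission count at or below which the
#'   commission measure is excluded (default 4).
#' @return A tibble of class `hypothesis_suite`: `measure`, `comparison`,
#'   `tail`, `rank_sum_w`, `u_statistic`, `p_raw`, `p_adjusted` (`NA` where
#'   no correction applies), `mean_stim`, `sd_stim`, `mean_sham`, `sd_sham`.
#' @export
run_hypothesis_suite <- function(outcomes,
                                 behavioral_measures = c(
                                   rt_mean_ms = "relative",
                                   rt_sd_ms = "relative",
                                   omissions = "absolute",
                                   commissions = "absolute"),
                                 commission_min = 4) {
  if (!all(c("stim", "sham") %in% outcomes$group)) {
    abort("Both groups (`stim`, `sham`) must be present.",
          class = "oddlock_parameter_error")
  }
  if ("commissions" %in% names(behavioral_measures) &&
      "commissions" %in% names(outcomes) &&
      max(outcomes$commissions, na.rm = TRUE) <= commission_min) {
    inform(sprintf(
      "Commission errors <= %d in every condition; excluded from inference.",
      commission_min))
    behavioral_measures <-
      behavioral_measures[names(behavioral_measures) != "commissions"]
  }

  one_test <- function(ch, measure, cmp, tail) {
    sub <- ch[ch$measure == measure & ch$comparison == cmp, ]
    if (nrow(sub) == 0) return(NULL)
    res <- rank_sum_test(sub$value[sub$group == "stim"],
                         sub$value[sub$group == "sham"], tail = tail)
    tibble(measure = measure, comparison = cmp, tail = tail,
           rank_sum_w = res$rank_sum_w, u_statistic = res$u_statistic,
           p_raw = res$p_value, p_adjusted = NA_real_,
           mean_stim = res$mean_x, sd_stim = res$sd_x,
           mean_sham = res$mean_y, sd_sham = res$sd_y)
  }

  rows <- list()
  # amplitude hypothesis: pre-to-post relative change, right-tailed
  if ("p3_amp_uv" %in% names(outcomes)) {
    ch_amp <- change_table(outcomes, measures = c(p3_amp_uv = "relative"),
                           comparisons = "pre-to-post")
    rows$amp <- one_test(ch_amp, "p3_amp_uv", "pre-to-post", "greater")
  }
  # ERSP hypothesis: pre-to-post relative change of the windowed maximum
  if ("ersp_max_db" %in% names(outcomes) &&
      !all(is.na(outcomes$ersp_max_db))) {
    ch_ersp <- change_table(outcomes, measures = c(ersp_max_db = "relative"),
                            comparisons = "pre-to-post")
    rows$ersp <- one_test(ch_ersp, "ersp_max_db", "pre-to-post", "greater")
  }
  # behavioral hypotheses: three time comparisons per measure, BH within
  if (length(behavioral_measures) > 0 && "during" %in%
      as.character(outcomes$condition)) {
    ch_beh <- change_table(outcomes, measures = behavioral_measures)
    tails <- c("pre-to-post" = "less", "pre-to-during" = "less",
               "during-to-post" = "two-sided")
    for (m in names(behavioral_measures)) {
      tests <- purrr::compact(purrr::imap(tails, function(tl, cmp) {
        one_test(ch_beh, m, cmp, tl)
      }))
      if (length(tests) == 0) next
      block <- dplyr::bind_rows(tests)
      block$p_adjusted <- bh_adjust(block$p_raw)
      rows[[m]] <- block
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hypothesis_suite", class(out))
  out
}

#' @export
tidy.group_result <- function(x, ...) {
  tibble(statistic = x$rank_sum_w, u_statistic = x$u_statistic,
         p.value = x$p_value, alternative = x$tail,
         method = if (x$exact) "exact rank-sum" else
           "rank-sum (normal approximation)")
}

#' @export
glance.group_result <- function(x, ...) {
  tibble(n_x = x$n_x, n_y = x$n_y, p.value = x$p_value, exact = x$exact)
}

#' @export
tidy.hypothesis_suite <- function(x, ...) {
  tibble(measure = x$measure, comparison = x$comparison,
         statistic = x$rank_sum_w, p.value = x$p_raw,
         p.adjusted = x$p_adjusted, alternative = x$tail)
}

#' @export
glance.hypothesis_suite <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_significant_raw = sum(x$p_raw < 0.05),
         n_significant_adjusted = sum(
           dplyr::coalesce(x$p_adjusted, x$p_raw) < 0.05))
}
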