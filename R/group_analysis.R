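#' Group-level detectability test for one task and filter setup
#'
#' Tests whether the SNR is significantly above the SNR-wall across
#' subjects. Because each subject contributes a matched (SNR, wall) pair,
#' the default is a one-sided *paired* t-test on the differences
#' `d_i = snr_i - wall_i` with H1: mean d > 0; an independent-samples
#' (Welch) variant is available behind `paired = FALSE`. Pairs with a
#' non-finite wall (e.g. -Inf from rho = 1) are excluded with a count.
#'
#' @param pairs Tibble with columns `subject`, `snr_db`, `wall_db` (and
#'   optionally `task`, `filter_setup`), one row per subject, for a single
#'   task x filter cell.
#' @param alpha Significance level (default 0.05).
#' @param paired Paired (default) or independent-samples t-test.
#' @return A one-row tibble of class `bci_group_result`: `task`,
#'   `filter_setup`, `n`, `n_excluded`, `mean_snr_db`, `sd_snr_db`,
#'   `mean_wall_db`, `sd_wall_db`, `mean_diff_db`, `t_stat`, `p_value`,
#'   `significant`, `test`. A zero-variance positive difference is flagged
#'   via `degenerate = TRUE` with `p_value` reported as 0 (below machine
#'   floor).
#' @export
task_test <- function(pairs, alpha = 0.05, paired = TRUE) {
  need <- c("subject", "snr_db", "wall_db")
  if (!all(need %in% names(pairs))) {
    abort(sprintf("`pairs` needs columns: %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(pairs$subject)) {
    abort("`pairs` must hold one row per subject (unmatched/duplicated subjects).")
  }
  ok <- is.finite(pairs$snr_db) & is.finite(pairs$wall_db)
  n_excluded <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  n <- nrow(pairs)
  if (n < 2L) abort("need at least 2 subjects with finite SNR and wall.")
  d <- pairs$snr_db - pairs$wall_db
  degenerate <- isTRUE(all.equal(stats::sd(d), 0)) ||
    (!paired && stats::sd(pairs$snr_db) == 0 && stats::sd(pairs$wall_db) == 0)
  if (degenerate) {
    t_stat <- if (mean(d) > 0) Inf else if (mean(d) < 0) -Inf else NaN
    p_value <- if (mean(d) > 0) 0 else 1
    warn("zero-variance differences: p-value reported as a hard 0/1 bound.")
  } else if (paired) {
    tt <- t.test(d, alternative = "greater", mu = 0)
    t_stat <- unname(tt$statistic)
    p_value <- tt$p.value
  } else {
    tt <- t.test(pairs$snr_db, pairs$wall_db, alternative = "greater")
    t_stat <- unname(tt$statistic)
    p_value <- tt$p.value
  }
  out <- tibble(
    task = first_or_na(pairs, "task"),
    filter_setup = first_or_na(pairs, "filter_setup"),
    n = n, n_excluded = n_excluded,
    mean_snr_db = mean(pairs$snr_db), sd_snr_db = stats::sd(pairs$snr_db),
    mean_wall_db = mean(pairs$wall_db), sd_wall_db = stats::sd(pairs$wall_db),
    mean_diff_db = mean(d),
    t_stat = t_stat, p_value = p_value,
    significant = p_value < alpha,
    degenerate = degenerate,
    test = if (paired) "paired one-sided t" else "Welch one-sided t"
  )
  class(out) <- c("bci_group_result", class(out))
  out
}

first_or_na <- function(df, col) {
  if (col %in% names(df)) as.character(df[[col]][1]) else NA_character_
}

#' Group tests across all task x filter cells
#'
#' Splits a long table of per-subject (SNR, wall) pairs by task and filter
#' setup and applies [task_test()] to each cell. No multiple-testing
#' correction is applied to the per-cell decisions (matching per-cell
#' p < alpha reporting); a Holm-adjusted column `p_holm` is emitted
#' alongside for transparency.
#'
#' @param pairs Tibble with columns `subject`, `task`, `filter_setup`,
#'   `snr_db`, `wall_db`.
#' @param alpha Significance level.
#' @param paired Passed to [task_test()].
#' @return A tibble with one [task_test()] row per cell plus `p_holm`.
#' @export
group_test <- function(pairs, alpha = 0.05, paired = TRUE) {
  need <- c("subject", "task", "filter_setup", "snr_db", "wall_db")
  if (!all(need %in% names(pairs))) {
    abort(sprintf("`pairs` needs columns: %s", paste(need, collapse = ", ")))
  }
  cells <- pairs |>
    group_by(.data$task, .data$filter_setup) |>
    dplyr::group_split()
  out <- list_rbind(map(cells, task_test, alpha = alpha, paired = paired))
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  class(out) <- c("bci_group_result", class(out))
  out
}

#' Star table of detectability by task and filter setup
#'
#' Rows are tasks, columns the filter setups; a cell holds `"*"` iff the
#' group test found the SNR significantly above the SNR-wall there, else
#' an empty string.
#'
#' @param results Output of [group_test()] (or rows of [task_test()] with
#'   `task`/`filter_setup` filled in).
#' @return A tibble with a `task` column and one column per filter setup.
#' @export
detectability_table <- function(results) {
  need <- c("task", "filter_setup", "significant")
  if (!all(need %in% names(results))) {
    abort("`results` must carry task, filter_setup and significant columns.")
  }
  results |>
    as_tibble() |>
    mutate(cell = ifelse(.data$significant, "*", "")) |>
    select("task", "filter_setup", "cell") |>
    tidyr::pivot_wider(names_from = "filter_setup", values_from = "cell",
                       values_fill = "")
}

#' Per-subject wall/SNR pair for one task recording
#'
#' Convenience wrapper running the whole per-subject pipeline: filter the
#' task recording with the configured chain, compute its noise profile and
#' SNR (using a P300 peak amplitude estimated from a separate oddball
#' session or supplied directly), and return one row ready for
#' [group_test()].
#'
#' @param rec Raw task `bci_recording`.
#' @param c_max Conscious peak amplitude in volts for this subject
#'   (typically from [evoked_average()] on an oddball session).
#' @param config An [analysis_config()]; `filter_setup` selects the chain.
#' @param subject,task Labels for the output row.
#' @return One-row tibble: `subject`, `task`, `filter_setup`, `snr_db`,
#'   `wall_db`, `rho`, `c_max`.
#' @export
subject_pair <- function(rec, c_max, config = analysis_config(),
                         subject = NA_character_, task = NA_character_) {
  filt <- apply_chain(rec, config$filter_setup, mains_hz = config$mains_hz)
  prof <- profile_recording(filt, config)
  snr <- estimate_snr(filt, c_max = c_max, config = config)
  tibble(subject = subject, task = task,
         filter_setup = config$filter_setup,
         snr_db = snr$snr_db, wall_db = prof$snr_wall_db,
         rho = prof$rho, c_max = c_max)
}
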