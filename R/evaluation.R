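#' Trial-stratified train/test split
#'
#' Splits the per-beat dataset into training and test partitions such that
#' all beats of a trial land in the same partition (the beats of one trial
#' share a single cuff label, so a beat-level split would leak labels).
#' Deterministic given `seed`. The default sizes follow the acquisition
#' protocol: 150 pairs per subject, 120 for training and 30 for testing.
#'
#' @param trial_index Trial label of each pair (length `n_train + n_test`).
#' @param n_train,n_test Partition sizes.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(trial_index, n_train = 120, n_test = 30, seed = 0) {
  n <- length(trial_index)
  if (n != n_train + n_test) {
    stop("size mismatch: expected ", n_train + n_test, " pairs (",
         n_train, " train + ", n_test, " test) but got ", n, call. = FALSE)
  }
  counts <- table(trial_index)
  k <- unique(as.integer(counts))
  if (length(k) != 1L) {
    stop("trials have unequal beat counts; cannot stratify exactly",
         call. = FALSE)
  }
  if (n_test %% k != 0) {
    stop("n_test = ", n_test, " is not a multiple of the ", k,
         " beats per trial", call. = FALSE)
  }
  trials <- names(counts)
  test_trials <- with_local_seed(seed, sample(trials, n_test / k))
  test <- which(as.character(trial_index) %in% test_trials)
  train <- setdiff(seq_len(n), test)
  stopifnot(length(train) == n_train, length(test) == n_test)
  list(train = train, test = test)
}

#' Mean error and its standard deviation
#'
#' `ME = mean(y - x)` with the sample (n-1) standard deviation of the
#' per-pair differences.
#'
#' @param y Predictions, mmHg.
#' @param x References, mmHg.
#' @return Named vector `c(ME, SD)`.
#' @export
mean_error <- function(y, x) {
  check_pairs(y, x)
  d <- y - x
  c(ME = mean(d), SD = stats::sd(d))
}

#' Mean absolute error and its standard deviation
#'
#' `MAE = mean(|y - x|)` with the sample standard deviation of the
#' per-pair absolute differences.
#'
#' @inheritParams mean_error
#' @return Named vector `c(MAE, SD)`.
#' @export
mean_absolute_error <- function(y, x) {
  check_pairs(y, x)
  d <- abs(y - x)
  c(MAE = mean(d), SD = stats::sd(d))
}

check_pairs <- function(y, x) {
  if (length(y) != length(x) || length(y) == 0L) {
    stop("y and x must be non-empty vectors of equal length", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference) and 1.96-SD limits of agreement between a
#' prediction and a reference method, with the per-pair (mean, difference)
#' table used for plotting.
#'
#' @inheritParams mean_error
#' @return List of class `bland_altman`: `bias`, `loa_low`, `loa_high`
#'   (mmHg) and `table` (data frame with columns `mean`, `diff`).
#' @export
bland_altman <- function(y, x) {
  check_pairs(y, x)
  d <- y - x
  s <- if (length(d) > 1L) stats::sd(d) else 0
  structure(list(bias = mean(d),
                 loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s,
                 table = data.frame(mean = (y + x) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f mmHg, limits of agreement [%.2f, %.2f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' AAMI accuracy criterion
#'
#' Device-accuracy bound of the Association for the Advancement of Medical
#' Instrumentation: mean error within +/- 5 mmHg and error SD at most
#' 8 mmHg.
#'
#' @param ME Mean error, mmHg.
#' @param SD Standard deviation of the errors, mmHg.
#' @return List: `pass` (logical), `ME`, `SD`, `me_limit`, `sd_limit`.
#' @examples
#' aami_check(1.69, 3.28)$pass  # TRUE
#' @export
aami_check <- function(ME, SD) {
  stopifnot(is.finite(ME), is.finite(SD))
  list(pass = abs(ME) <= 5 && SD <= 8, ME = ME, SD = SD,
       me_limit = 5, sd_limit = 8)
}

#' Five-number box-plot summary using quartile conventions
#'
#' @param values Numeric vector (>= 4 values).
#' @return Named vector `c(min, Q1, median, Q3, max)`.
#' @export
box_stats <- function(values) {
  q <- compute_quartiles(values)
  c(min = min(values), Q1 = q[["Q1"]], median = q[["Q2"]], Q3 = q[["Q3"]],
    max = max(values))
}

#' Full accuracy evaluation of one target
#'
#' Computes the accuracy battery for one BP target: mean error +/- SD,
#' mean absolute error +/- SD, Bland-Altman bias and limits of agreement,
#' and the AAMI verdict.
#'
#' @param y Predictions, mmHg.
#' @param x Cuff references, mmHg.
#' @param target `"SBP"` or `"DBP"` label.
#' @return Object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(y, x, target = "SBP") {
  me <- mean_error(y, x)
  mae <- mean_absolute_error(y, x)
  ba <- bland_altman(y, x)
  aami <- aami_check(me[["ME"]], me[["SD"]])
  structure(list(target = target, n = length(y),
                 ME = me[["ME"]], ME_SD = me[["SD"]],
                 MAE = mae[["MAE"]], MAE_SD = mae[["SD"]],
                 bland_altman = ba, aami_pass = aami$pass),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s accuracy on %d test pairs\n", x$target, x$n))
  cat(sprintf("  ME  %+.2f +/- %.2f mmHg\n", x$ME, x$ME_SD))
  cat(sprintf("  MAE  %.2f +/- %.2f mmHg\n", x$MAE, x$MAE_SD))
  cat(sprintf("  Bland-Altman bias %+.2f, LoA [%.2f, %.2f] mmHg\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  cat(sprintf("  AAMI (|ME| <= 5, SD <= 8): %s\n",
              ifelse(x$aami_pass, "PASS", "FAIL")))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with the bias
#' and 1.96-SD limits of agreement. Requires ggplot2.
#'
#' @param ba A [bland_altman()] result.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = "Bland-Altman agreement") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- data.frame(pair_mean = ba$table$mean, pair_diff = ba$table$diff)
  ggplot2::ggplot(df, ggplot2::aes(x = pair_mean, y = pair_diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_low, ba$loa_high),
                        linetype = c("solid", "dashed", "dashed")) +
    ggplot2::labs(title = title, x = "Mean of methods (mmHg)",
                  y = "Difference (mmHg)") +
    ggplot2::theme_minimal()
}
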