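#' Evaluate the discriminant by repeated leave-one-out cross-validation
#'
#' Repeats the following protocol `repetitions` times: draw
#' `samples_per_rep` labelled voxels from the pool without replacement,
#' then, for each drawn sample, refit the discriminant on the remaining
#' `samples_per_rep - 1` samples and classify the held-out one. Accuracy,
#' sensitivity, specificity and precision are computed per repetition and
#' averaged; cortical is the positive class. Folds whose training remainder
#' loses a class entirely, or whose pooled variance vanishes, are skipped
#' and counted.
#'
#' The leave-one-out refits use exact rank-one downdates of the class sums
#' and sums of squares, so each repetition costs O(n).
#'
#' @param training A [training_set()] serving as the sampling pool.
#' @param repetitions Number of random training sets (default 50).
#' @param samples_per_rep Samples drawn per repetition (default 1000).
#' @param prior Shared class prior (default 0.5).
#' @param seed Integer seed; all draws flow from it.
#' @return An object of class `classifier_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `precision` (means over repetitions),
#'   `per_repetition` (data frame), `skipped_folds`, `repetitions`,
#'   `samples_per_repetition`.
#' @export
loocv_evaluate <- function(training, repetitions = 50, samples_per_rep = 1000,
                           prior = 0.5, seed = 1L) {
  stopifnot(inherits(training, "training_set"))
  pool_n <- nrow(training)
  if (pool_n < samples_per_rep)
    stop(sprintf("loocv_evaluate: pool has %d samples, %d requested per repetition",
                 pool_n, samples_per_rep))
  if (repetitions < 1) stop("loocv_evaluate: repetitions must be >= 1")

  per_rep <- matrix(NA_real_, nrow = repetitions, ncol = 4,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity", "precision")))
  skipped <- 0L
  rep_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L, repetitions))

  for (r in seq_len(repetitions)) {
    pick <- with_seed(rep_seeds[r], sample.int(pool_n, samples_per_rep))
    x <- training$hu[pick]
    is_c <- training$label[pick] == "C"
    n <- samples_per_rep
    n_c <- sum(is_c); n_t <- n - n_c
    s_c <- sum(x[is_c]); s_t <- sum(x[!is_c])
    q_c <- sum(x[is_c]^2); q_t <- sum(x[!is_c]^2)

    # leave-one-out class statistics for every fold at once
    n_c_i <- ifelse(is_c, n_c - 1L, n_c)
    n_t_i <- ifelse(is_c, n_t, n_t - 1L)
    s_c_i <- ifelse(is_c, s_c - x, s_c)
    s_t_i <- ifelse(is_c, s_t, s_t - x)
    q_c_i <- ifelse(is_c, q_c - x^2, q_c)
    q_t_i <- ifelse(is_c, q_t, q_t - x^2)

    valid <- n_c_i >= 1L & n_t_i >= 1L
    mu_c <- s_c_i / n_c_i
    mu_t <- s_t_i / n_t_i
    ss <- (q_c_i - s_c_i^2 / n_c_i) + (q_t_i - s_t_i^2 / n_t_i)
    s2 <- ss / (n - 1L - 2L)
    valid <- valid & is.finite(s2) & s2 > 0
    if (!any(valid)) { skipped <- skipped + sum(!valid); next }
    skipped <- skipped + sum(!valid)

    # cortical iff L_C >= L_T: (beta_C - beta_T) x + (alpha_C - alpha_T) >= 0
    dbeta <- (mu_c - mu_t) / s2
    dalpha <- -(mu_c^2 - mu_t^2) / (2 * s2)
    pred_c <- dbeta * x + dalpha >= 0

    v <- valid
    tp <- sum(pred_c[v] & is_c[v]);  fn <- sum(!pred_c[v] & is_c[v])
    tn <- sum(!pred_c[v] & !is_c[v]); fp <- sum(pred_c[v] & !is_c[v])
    per_rep[r, ] <- c((tp + tn) / sum(v),
                      if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                      if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                      if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }
  if (skipped > 0)
    warning(sprintf("loocv_evaluate: %d leave-one-out folds skipped (degenerate training remainder)",
                    skipped))
  means <- colMeans(per_rep, na.rm = TRUE)
  structure(list(accuracy = means[["accuracy"]],
                 sensitivity = means[["sensitivity"]],
                 specificity = means[["specificity"]],
                 precision = means[["precision"]],
                 per_repetition = as.data.frame(per_rep),
                 skipped_folds = skipped,
                 repetitions = repetitions,
                 samples_per_repetition = samples_per_rep),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(paste0("<classifier_metrics> %d repetitions x %d samples (LOOCV)\n",
                     "  accuracy %.4f  sensitivity %.4f  specificity %.4f  precision %.4f\n"),
              x$repetitions, x$samples_per_repetition,
              x$accuracy, x$sensitivity, x$specificity, x$precision))
  if (x$skipped_folds > 0)
    cat(sprintf("  (%d degenerate folds skipped)\n", x$skipped_folds))
  invisible(x)
}
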