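#' Ordinary least-squares regression with R-squared
#'
#' Fits `y ~ x` by least squares and reports slope, intercept,
#' `R^2 = 1 - SS_res / SS_tot` and the two-sided p-value of the slope from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 2); `x` must not be
#'   constant.
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
least_squares <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("least_squares: x and y lengths differ")
  if (length(x) < 2L) stop("least_squares: need at least 2 points")
  if (stats::sd(x) == 0) stop("least_squares: x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (length(x) >= 3L) sm$coefficients["x", "Pr(>|t|)"] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope %.6g, intercept %.6g, R^2 %.4f, p %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Paired t-test between two measurement vectors
#'
#' Classical paired t on the element-wise differences with a two-sided
#' p-value, as used to compare tracer-derived marrow volumes subject by
#' subject. Zero-variance differences make t undefined; the result is then
#' flagged rather than fabricated.
#'
#' @param a,b Numeric vectors of equal length (>= 2), paired by position.
#' @return List with `t`, `p`, `mean_difference`, `df`, `undefined`
#'   (logical: `TRUE` when the differences have zero variance).
#' @export
paired_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired_t_test: vectors differ in length")
  if (length(a) < 2L) stop("paired_t_test: need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, mean_difference = mean(d),
                df = length(d) - 1L, undefined = TRUE))
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_difference = unname(ht$estimate), df = unname(ht$parameter),
       undefined = FALSE)
}

#' Compare a measurement across groups (two-sample t / one-way ANOVA)
#'
#' One-way ANOVA F and p across the groups; with exactly two groups the
#' equivalent pooled-variance two-sample t statistic is also reported
#' (`F = t^2`).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; every group needs >= 2 members.
#' @return List with `f`, `p`, `df_between`, `df_within`, and for two
#'   groups also `t`.
#' @export
group_compare <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("group_compare: values and groups differ in length")
  if (nlevels(groups) < 2L) stop("group_compare: need at least 2 groups")
  if (any(table(groups) < 2L))
    stop("group_compare: every group needs at least 2 members")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  out <- list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
              df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
  gm <- tapply(values, groups, mean)
  if (diff(range(gm)) <= .Machine$double.eps * (max(abs(gm)) + 1) * 10) {
    out$f <- 0  # group means coincide: no between-group variance
    out$p <- 1
  }
  if (nlevels(groups) == 2L) {
    out$t <- tryCatch(unname(stats::t.test(values ~ groups,
                                           var.equal = TRUE)$statistic),
                      error = function(e) NA_real_)  # constant data
    if (out$f == 0) out$t <- 0
  }
  out
}

#' Ideal body weight (Devine formula)
#'
#' `50 kg` (male) or `45.5 kg` (female) plus `2.3 kg` per inch of height
#' above 5 ft (152.4 cm), floored at the sex-specific base for shorter
#' heights.
#'
#' @param sex `"M"` or `"F"` (vectorised).
#' @param height_cm Height in cm (> 0).
#' @return Ideal body weight in kg.
#' @export
ideal_body_weight <- function(sex, height_cm) {
  if (!all(sex %in% c("M", "F")))
    stop("ideal_body_weight: sex must be 'M' or 'F'")
  if (any(height_cm <= 0)) stop("ideal_body_weight: height must be positive")
  base <- ifelse(sex == "M", 50, 45.5)
  base + 2.3 * pmax(height_cm - 152.4, 0) / 2.54
}

#' Cohort-level statistical panel
#'
#' Runs, on a cohort table of per-subject per-tracer volume reports, the
#' standard analysis panel: per-tracer regressions of RBV/YBV/IBV and red
#' fraction against weight, height, BMI and ideal body weight; paired
#' t-tests between two tracers for each volume measure; and two-group sex
#' comparisons per tracer. An optional subset filter (e.g. males only)
#' restricts the regressions.
#'
#' @param cohort Data frame with columns `id`, `sex` ("M"/"F"),
#'   `weight_kg`, `height_cm`, `tracer`, `rbv_ml`, `ybv_ml`, `ibv_ml`,
#'   `red_fraction`, and optionally `bmi`, `spinal_mean_suv`,
#'   `rob_mean_suv`. BMI and ideal body weight are derived when absent.
#' @param tracers Character vector of the (one or two) tracer tags to
#'   analyse; defaults to those present.
#' @param subset Optional logical vector over subjects (recycled per
#'   tracer) restricting regressions, e.g. `cohort$sex == "M"`.
#' @param alpha Significance level annotated on the results (default 0.05).
#' @return List with components `regressions` (data frame), `paired`
#'   (data frame, when two tracers), `sex_comparisons` (data frame),
#'   `alpha`.
#' @export
cohort_analysis <- function(cohort, tracers = NULL, subset = NULL,
                            alpha = 0.05) {
  need <- c("id", "sex", "weight_kg", "height_cm", "tracer",
            "rbv_ml", "ybv_ml", "ibv_ml", "red_fraction")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop(sprintf("cohort_analysis: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  if (is.null(cohort$bmi))
    cohort$bmi <- cohort$weight_kg / (cohort$height_cm / 100)^2
  cohort$ibw_kg <- ideal_body_weight(cohort$sex, cohort$height_cm)
  if (is.null(tracers)) tracers <- unique(cohort$tracer)
  if (is.null(subset)) subset <- rep(TRUE, nrow(cohort))

  measures <- c("rbv_ml", "ybv_ml", "ibv_ml", "red_fraction")
  covariates <- c("weight_kg", "height_cm", "bmi", "ibw_kg")

  regs <- list()
  for (tr in tracers) {
    sub <- cohort[cohort$tracer == tr & subset, ]
    for (m in measures) for (cv in covariates) {
      if (nrow(sub) < 3L || stats::sd(sub[[cv]]) == 0) next
      r <- least_squares(sub[[cv]], sub[[m]])
      regs[[length(regs) + 1L]] <- data.frame(
        tracer = tr, measure = m, covariate = cv,
        slope = r$slope, intercept = r$intercept,
        r_squared = r$r_squared, p_value = r$p_value, n = r$n,
        significant = !is.na(r$p_value) && r$p_value < alpha)
    }
  }
  regressions <- if (length(regs)) do.call(rbind, regs) else NULL

  paired <- NULL
  if (length(tracers) == 2L) {
    a <- cohort[cohort$tracer == tracers[1], ]
    b <- cohort[cohort$tracer == tracers[2], ]
    common <- intersect(a$id, b$id)
    if (length(common) >= 2L) {
      a <- a[match(common, a$id), ]; b <- b[match(common, b$id), ]
      rows <- lapply(measures, function(m) {
        tt <- paired_t_test(a[[m]], b[[m]])
        data.frame(measure = m, mean_difference = tt$mean_difference,
                   t = tt$t, p = tt$p, n = length(common),
                   significant = !is.na(tt$p) && tt$p < alpha)
      })
      paired <- do.call(rbind, rows)
    }
  }

  sexes <- list()
  for (tr in tracers) {
    sub <- cohort[cohort$tracer == tr, ]
    if (nlevels(factor(sub$sex)) == 2L && all(table(sub$sex) >= 2L)) {
      for (m in measures) {
        gc <- group_compare(sub[[m]], sub$sex)
        sexes[[length(sexes) + 1L]] <- data.frame(
          tracer = tr, measure = m, f = gc$f, t = gc$t, p = gc$p,
          significant = !is.na(gc$p) && gc$p < alpha)
      }
    }
  }
  sex_comparisons <- if (length(sexes)) do.call(rbind, sexes) else NULL

  list(regressions = regressions, paired = paired,
       sex_comparisons = sex_comparisons, alpha = alpha)
}
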