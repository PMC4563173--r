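#' Build a labelled training set of Hounsfield values
#'
#' @param hu Numeric vector of Hounsfield values.
#' @param label Vector of class labels, `"C"` (cortical) or `"T"`
#'   (trabecular), one per sample.
#' @param voxel_index Optional integer matrix (n x 3) recording the voxel
#'   provenance of each sample.
#' @return An object of class `training_set`: a data frame with columns
#'   `hu` and `label`.
#' @export
training_set <- function(hu, label, voxel_index = NULL) {
  hu <- as.numeric(hu)
  label <- as.character(label)
  if (length(hu) != length(label))
    stop("training_set: 'hu' and 'label' lengths differ")
  if (!all(label %in% c("C", "T")))
    stop("training_set: labels must be 'C' (cortical) or 'T' (trabecular)")
  if (any(!is.finite(hu)))
    stop("training_set: non-finite Hounsfield values")
  n_c <- sum(label == "C"); n_t <- sum(label == "T")
  if (n_c < 2L || n_t < 2L)
    stop("training_set: need at least 2 samples per class to estimate the pooled variance")
  out <- data.frame(hu = hu, label = factor(label, levels = c("C", "T")))
  if (!is.null(voxel_index)) attr(out, "voxel_index") <- voxel_index
  class(out) <- c("training_set", "data.frame")
  out
}

#' Train the cortical/trabecular linear discriminant
#'
#' Fits the one-dimensional two-class Gaussian linear discriminant with
#' pooled within-class variance to labelled Hounsfield samples. With class
#' means `mu_C`, `mu_T` and pooled variance `s2` (denominator n - 2), the
#' discriminant coefficients are `beta_k = mu_k / s2` and
#' `alpha_k = -mu_k^2 / (2 s2)`, so the linear score of a voxel with
#' Hounsfield value `hv` is `alpha_k + beta_k * hv + log(prior)`. With a
#' shared prior the decision boundary sits at the midpoint of the class
#' means, `(mu_C + mu_T) / 2`.
#'
#' @param training A [training_set()].
#' @param prior Class prior probability in (0, 1); 0.5 by default, i.e. a
#'   skeleton voxel is a priori equally likely cortical or trabecular.
#' @return An object of class `lda_model` with elements `alpha_C`, `beta_C`,
#'   `alpha_T`, `beta_T`, `prior`, `mu_C`, `mu_T`, `pooled_var`, `n`.
#' @export
train_lda <- function(training, prior = 0.5) {
  stopifnot(inherits(training, "training_set"))
  if (!is.finite(prior) || prior <= 0 || prior >= 1)
    stop("train_lda: prior must lie strictly inside (0, 1)")
  hu_c <- training$hu[training$label == "C"]
  hu_t <- training$hu[training$label == "T"]
  n_c <- length(hu_c); n_t <- length(hu_t); n <- n_c + n_t
  mu_c <- mean(hu_c); mu_t <- mean(hu_t)
  ss <- sum((hu_c - mu_c)^2) + sum((hu_t - mu_t)^2)
  s2 <- ss / (n - 2L)
  if (s2 <= 0)
    stop("train_lda: pooled within-class variance is zero; the discriminant boundary is degenerate")
  structure(list(alpha_C = -mu_c^2 / (2 * s2), beta_C = mu_c / s2,
                 alpha_T = -mu_t^2 / (2 * s2), beta_T = mu_t / s2,
                 prior = prior, mu_C = mu_c, mu_T = mu_t,
                 pooled_var = s2, n = n),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> alpha_C=%.6g beta_C=%.6g alpha_T=%.6g beta_T=%.6g prior=%.3g\n",
              x$alpha_C, x$beta_C, x$alpha_T, x$beta_T, x$prior))
  cat(sprintf("  class means %.4g (C) / %.4g (T) HU, pooled var %.6g, boundary %.6g HU\n",
              x$mu_C, x$mu_T, x$pooled_var, lda_boundary(x)))
  invisible(x)
}

#' Decision boundary of a trained discriminant
#'
#' Hounsfield value at which the cortical and trabecular linear scores are
#' equal. With a shared prior this is the midpoint of the class means.
#'
#' @param model An `lda_model`.
#' @return Scalar HU.
#' @export
lda_boundary <- function(model) {
  (model$alpha_T - model$alpha_C) / (model$beta_C - model$beta_T)
}

#' Linear discriminant scores for Hounsfield values
#'
#' `L_k(hv) = alpha_k + beta_k * hv + log(prior)` for both classes.
#'
#' @param model An `lda_model`.
#' @param hv Numeric vector (or array) of Hounsfield values.
#' @return List with elements `L_C` and `L_T`, same shape as `hv`.
#' @export
linear_scores <- function(model, hv) {
  stopifnot(inherits(model, "lda_model"))
  lp <- log(model$prior)
  list(L_C = model$alpha_C + model$beta_C * hv + lp,
       L_T = model$alpha_T + model$beta_T * hv + lp)
}

#' Posterior probability maps over the bone compartment
#'
#' Converts the two linear scores into per-voxel posterior probabilities,
#' `p_C = exp(L_C) / (exp(L_C) + exp(L_T))`, evaluated overflow-safely as a
#' logistic of the score difference. Voxels outside the bone mask are `NA`.
#'
#' @param model An `lda_model`.
#' @param ct CT-role `voxel_grid`.
#' @param bone Logical bone mask on the CT geometry.
#' @return An object of class `posterior_maps`: list with `p_cortical` and
#'   `p_trabecular` arrays (NA off the mask) and the `bone` mask.
#' @export
posterior_map <- function(model, ct, bone) {
  stopifnot(inherits(ct, "voxel_grid"))
  bone <- as_mask_array(bone, dim(ct$data), "bone mask")
  hv <- ct$data[bone]
  sc <- linear_scores(model, hv)
  # p_C = 1 / (1 + exp(L_T - L_C)); stable for any score magnitude
  p_c <- stats::plogis(sc$L_C - sc$L_T)
  pc <- pt <- array(NA_real_, dim(ct$data))
  pc[bone] <- p_c
  pt[bone] <- 1 - p_c
  structure(list(p_cortical = pc, p_trabecular = pt, bone = bone),
            class = "posterior_maps")
}

#' Assign bone voxels to cortical or trabecular compartments
#'
#' A voxel is cortical when its cortical posterior is at least as large as
#' its trabecular posterior (exact ties resolve to cortical, which never
#' inflates the marrow-bearing trabecular volume). The two output masks
#' partition the bone mask.
#'
#' @param posteriors A [posterior_map()] result.
#' @param bone Optional logical bone mask; defaults to the mask stored in
#'   `posteriors`.
#' @return An object of class `compartment_masks`: list of logical arrays
#'   `bone`, `cortical`, `trabecular`.
#' @export
classify_compartments <- function(posteriors, bone = NULL) {
  stopifnot(inherits(posteriors, "posterior_maps"))
  if (is.null(bone)) bone <- posteriors$bone
  bone <- as_mask_array(bone, dim(posteriors$p_cortical), "bone mask")
  cortical <- array(FALSE, dim(bone))
  cortical[bone] <- posteriors$p_cortical[bone] >= posteriors$p_trabecular[bone]
  trabecular <- bone & !cortical
  structure(list(bone = bone, cortical = cortical, trabecular = trabecular),
            class = "compartment_masks")
}

#' Sample a labelled training set from compartment label masks
#'
#' Draws `n` voxels without replacement from the union of the cortical and
#' trabecular label masks (proportionally to their sizes) and records their
#' Hounsfield values, emulating the manual labelling of skeleton voxels that
#' trains the discriminant.
#'
#' @param ct CT-role `voxel_grid`.
#' @param cortical,trabecular Logical label masks on the CT geometry.
#' @param n Number of voxels to draw (default 1000).
#' @param seed Integer seed governing the draw.
#' @return A [training_set()] with voxel provenance.
#' @export
sample_training_voxels <- function(ct, cortical, trabecular, n = 1000, seed = 1L) {
  stopifnot(inherits(ct, "voxel_grid"))
  cortical <- as_mask_array(cortical, dim(ct$data), "cortical mask")
  trabecular <- as_mask_array(trabecular, dim(ct$data), "trabecular mask")
  if (any(cortical & trabecular))
    stop("sample_training_voxels: cortical and trabecular label masks overlap")
  idx <- c(which(cortical), which(trabecular))
  lab <- rep(c("C", "T"), c(sum(cortical), sum(trabecular)))
  if (length(idx) < n)
    stop(sprintf("sample_training_voxels: only %d labelled voxels available, %d requested",
                 length(idx), n))
  pick <- with_seed(seed, sample.int(length(idx), n))
  training_set(ct$data[idx[pick]], lab[pick],
               voxel_index = arrayInd(idx[pick], dim(ct$data)))
}

#' Serialize / restore a trained discriminant as JSON
#'
#' @param model An `lda_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_lda_model` returns the `lda_model`.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("alpha_C", "beta_C", "alpha_T", "beta_T", "prior")
  if (!all(need %in% names(m)))
    stop("read_lda_model: file lacks the discriminant coefficients")
  structure(m[intersect(c(need, "mu_C", "mu_T", "pooled_var", "n"), names(m))],
            class = "lda_model")
}
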