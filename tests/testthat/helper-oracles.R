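# Independent oracles used across the test suite. These deliberately avoid
# the code paths they check.

# Brute-force flood-fill connected-component labelling: frontier-expansion
# BFS over an explicit neighbour offset table.
flood_fill_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ord <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[ord == 1, , drop = FALSE],
                 "18" = offs[ord <= 2, , drop = FALSE],
                 "26" = offs)
  lab <- array(0L, d)
  unvisited <- mask
  next_lab <- 0L
  repeat {
    seed <- which(unvisited)[1]
    if (is.na(seed)) break
    next_lab <- next_lab + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    lab[seed] <- next_lab
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        cbind(co[, 1] + offs[k, 1], co[, 2] + offs[k, 2], co[, 3] + offs[k, 3])))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      lin <- unique(nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
                      (nb[ok, 3] - 1L) * d[1] * d[2])
      lin <- lin[unvisited[lin]]
      if (length(lin)) {
        unvisited[lin] <- FALSE
        lab[lin] <- next_lab
        frontier <- lin
      } else frontier <- integer(0)
    }
  }
  lab
}

# Island filtering on top of the flood-fill oracle.
flood_fill_filter <- function(mask, min_size, connectivity = 26) {
  lab <- flood_fill_components(mask, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  sizes <- tabulate(lab[lab > 0L])
  array(lab > 0L & sizes[pmax(lab, 1L)] >= min_size, dim(mask))
}

# A small, fast phantom for unit tests: two vertebrae and one long bone on
# a 48 x 48 x 72 voxel grid (2 mm).
small_phantom_spec <- function(seed = 7L, ...) {
  els <- list(
    bone_element("cylinder", c(48, 48, 20), c(14, 12), 3, "long_bone"),
    bone_element("cylinder", c(48, 48, 60), c(15, 10), 2, "vertebra_lumbar"),
    bone_element("cylinder", c(48, 48, 90), c(15, 10), 2, "vertebra_thoracic"))
  phantom_spec(shape = c(48, 48, 72), spacing_mm = c(2, 2, 2), elements = els,
               seed = seed, ...)
}

# Ordinary least squares by explicit closed-form arithmetic.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tval <- slope / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

# Paired t by explicit arithmetic on the differences.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), df = n - 1), mean_difference = mean(d))
}

# One-way ANOVA by explicit sums of squares.
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}
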