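# Independent brute-force oracles. Each deliberately uses a different
# algorithm from the implementation it checks.

# connected-component labelling by iterative minimum-label propagation
# (face connectivity), instead of the package's BFS flood fill
oracle_label <- function(mask) {
  dm <- dim(mask)
  nd <- length(dm)
  lab <- array(0L, dim = dm)
  lab[mask != 0] <- seq_len(sum(mask != 0))
  repeat {
    old <- lab
    for (a in seq_len(nd)) {
      lo <- slice_shift(lab, a, 1L)   # neighbour at +1 along axis a
      hi <- slice_shift(lab, a, -1L)
      for (nb in list(lo, hi)) {
        upd <- lab > 0L & nb > 0L & nb < lab
        lab[upd] <- nb[upd]
      }
    }
    if (identical(old, lab)) break
  }
  # renumber compactly in first-encounter order
  ids <- unique(lab[lab > 0L])
  out <- array(0L, dim = dm)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# shift an array by one cell along axis `a` (dir = +1 brings the next cell),
# padding with 0
slice_shift <- function(x, a, dir) {
  dm <- dim(x)
  idx_from <- lapply(dm, seq_len)
  idx_to <- idx_from
  if (dir > 0) {
    idx_from[[a]] <- 2:dm[a]; idx_to[[a]] <- 1:(dm[a] - 1L)
  } else {
    idx_from[[a]] <- 1:(dm[a] - 1L); idx_to[[a]] <- 2:dm[a]
  }
  out <- array(0L, dim = dm)
  out_idx <- do.call(`[<-`, c(list(out), idx_to,
                              list(do.call(`[`, c(list(x), idx_from)))))
  out_idx
}

# do two labelings describe the same partition of foreground cells?
# (canonicalise each by first-occurrence renumbering in scan order)
same_partition <- function(a, b) {
  if (!identical(which(a > 0L), which(b > 0L))) return(FALSE)
  canon <- function(l) { f <- l[l > 0L]; match(f, unique(f)) }
  identical(canon(a), canon(b))
}

# slice-wise impairment by explicit per-slice loops
oracle_impairment <- function(lesion_arr, subset_arr) {
  nz <- dim(subset_arr)[3]
  best <- 0; best_z <- NA_integer_
  for (z in seq_len(nz)) {
    les <- lesion_arr[, , z] != 0
    tr <- subset_arr[, , z] != 0
    ov <- sum(les & tr)
    if (ov > 0) {
      r <- 100 * ov / sum(tr)
      if (r > best) { best <- r; best_z <- z }
    }
  }
  list(percentage = best, argmax_slice = best_z)
}

# literal Benjamini-Yekutieli step-up by scanning i = m..1
oracle_by <- function(p, q) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  k <- 0L
  for (i in m:1) {
    if (p[ord[i]] <= i * q / (m * cm)) { k <- i; break }
  }
  rej <- logical(m)
  if (k > 0L) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# partial correlation via the regression-t route (not residual correlation)
oracle_partial_r <- function(x, y, Z) {
  fit <- stats::lm(y ~ x + Z)
  tt <- summary(fit)$coefficients["x", "t value"]
  df <- fit$df.residual
  sign(tt) * sqrt(tt^2 / (tt^2 + df))
}

# closed-form REML for the balanced random-intercept model with a common
# time vector across subjects (ANOVA estimators)
oracle_balanced_reml <- function(ymat, times) {
  k <- nrow(ymat); n <- ncol(ymat)
  sm <- colMeans(ymat)
  ct <- times - mean(times)
  within <- sweep(ymat, 2, sm)
  b1 <- sum(within * ct) / (n * sum(ct^2))
  rssw <- sum((within - outer(ct, rep(b1, n)))^2)
  s2e <- rssw / (n * (k - 1) - 1)
  msb <- k * stats::var(sm)
  s2b <- max(0, (msb - s2e) / k)
  b0 <- mean(sm) - b1 * mean(times)
  list(beta0 = b0, beta1 = b1, sigma2_e = s2e, sigma2_b = s2b)
}

# small shared fixtures
toy_grid <- function(shape = c(16L, 16L, 16L), voxel = 2)
  grid_spec(shape, voxel)

random_mask <- function(grid, p = 0.1) {
  lesion_mask(grid, array(stats::runif(prod(grid$shape)) < p,
                          dim = grid$shape))
}

std_grid_atlas <- local({
  g <- grid_spec()
  a <- make_fiber_atlas(g, seed = 11)
  list(grid = g, atlas = a)
})
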