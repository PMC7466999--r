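# Independent brute-force oracles used to verify the package's own
# implementations. These deliberately share no code with R/.

# 4-connected component labeling by breadth-first search.
bfs_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# Direct per-pixel Perona-Malik update (flux form, Neumann boundary).
diffuse_oracle <- function(x, n_iter, kappa, lambda = 0.25) {
  nr <- nrow(x); nc <- ncol(x)
  for (it in seq_len(n_iter)) {
    out <- x
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        a <- i + d[1]; b <- j + d[2]
        if (a < 1 || a > nr || b < 1 || b > nc) next
        dv <- x[a, b] - x[i, j]
        out[i, j] <- out[i, j] + lambda * exp(-(dv / kappa)^2) * dv
      }
    }
    x <- out
  }
  x
}

# Direct edge-truncated moving-median surface.
moving_median_oracle <- function(m, half) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- median(m[max(1, i - half):min(nrow(m), i + half),
                          max(1, j - half):min(ncol(m), j + half)], na.rm = TRUE)
  }
  out
}

# Iterated-bisquare robust local linear regression (independent of
# stats::lowess): centered window of `window` nearest points, tricube
# distance weights, bisquare robustness reweighting.
rlowess_oracle <- function(y, window, iters = 4) {
  n <- length(y); x <- seq_len(n)
  fit <- numeric(n)
  rw <- rep(1, n)
  for (it in 0:iters) {
    for (i in seq_len(n)) {
      d <- abs(x - i)
      idx <- order(d)[seq_len(min(window, n))]
      h <- max(d[idx]); if (h == 0) h <- 1
      w <- (1 - pmin(d[idx] / h, 1)^3)^3 * rw[idx]
      if (sum(w > 0) < 2) { fit[i] <- y[i]; next }
      xi <- x[idx] - i
      sw <- sum(w); swx <- sum(w * xi); swx2 <- sum(w * xi^2)
      swy <- sum(w * y[idx]); swxy <- sum(w * xi * y[idx])
      den <- sw * swx2 - swx^2
      fit[i] <- if (abs(den) < 1e-12) swy / sw else (swx2 * swy - swx * swxy) / den
    }
    r <- y - fit
    s <- median(abs(r))
    if (s <= 0) break
    rw <- pmax(1 - (r / (6 * s))^2, 0)^2
  }
  fit
}

# Brute-force Benjamini-Hochberg / Storey step-up construction.
stepup_oracle <- function(p, pi0 = 1) {
  m <- length(p)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m); out[o] <- pmin(q, 1)
  out
}

# Exhaustive hypergeometric upper tail by enumerating all C(K, N) draws.
hyper_enum_upper <- function(x, M, K, N) {
  draws <- combn(K, N)
  mean(colSums(draws <= M) >= x)
}

# Analytic logistic / two-phase logistic curves (closed form, independent
# of the simulator's integrator).
logistic_curve <- function(times, K, r, tm) K / (1 + exp(-r * (times - tm)))
two_phase_curve <- function(times, K, r, tm, t_stall, f) {
  v <- logistic_curve(times, K, r, tm)
  Is <- logistic_curve(t_stall, K, r, tm)
  late <- times > t_stall
  v[late] <- K / (1 + (K / Is - 1) * exp(-r * f * (times[late] - t_stall)))
  v
}

# Small shared simulated experiment for module tests (memoised).
.tiny_env <- new.env()
tiny_experiment <- function() {
  if (is.null(.tiny_env$ex)) {
    cfg <- sim_config(n_strains = 48, n_replicates = 6, plate_nrow = 6, plate_ncol = 8,
                      total_hours = 24, seed = 99)
    .tiny_env$ex <- simulate_curves(cfg)
  }
  .tiny_env$ex
}
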