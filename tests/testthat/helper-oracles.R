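# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: numerical integration instead of qbeta,
# exhaustive enumeration instead of wilcox.test/cor.test, brute-force
# geometry instead of the vectorized rasterizer.

# Clopper-Pearson lower bound: solve P(X >= k | p) = alpha for p, with the
# binomial tail computed by direct summation (no pbinom/qbeta)
oracle_cp_lower <- function(k, n, alpha = 0.025) {
  if (k == 0) return(0)
  tail <- function(p) sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
  stats::uniroot(function(p) tail(p) - alpha, c(1e-12, 1 - 1e-12),
                 tol = 1e-12)$root
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  obs <- u_stat(seq_len(n))
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, u_stat)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# exact two-sided Spearman p by full permutation enumeration (small n)
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rho <- function(a, b) stats::cor(rank(a), rank(b))
  obs <- rho(x, y)
  perms <- gtools_permutations(n)
  rhos <- apply(perms, 1, function(p) rho(x, y[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# brute-force min distance from a point to the 9 emitter axes (axial slab)
oracle_axis_distance <- function(p, centers, axes, max_len) {
  ds <- vapply(1:9, function(k) {
    d <- p - centers[k, ]
    t_ax <- sum(d * axes[k, ])
    if (t_ax < 0 || t_ax > max_len) return(Inf)
    sqrt(max(sum(d * d) - t_ax^2, 0))
  }, numeric(1))
  min(ds)
}

# brute-force rasterization: label of one voxel centre
oracle_cyl_label <- function(p, centers, axes, r_eff, l_eff) {
  best <- Inf; lab <- 0L
  for (k in 1:9) {
    d <- p - centers[k, ]
    t_ax <- sum(d * axes[k, ])
    rad <- sqrt(max(sum(d * d) - t_ax^2, 0))
    if (t_ax >= 0 && t_ax <= l_eff && rad <= r_eff && rad < best) {
      best <- rad; lab <- k
    }
  }
  lab
}

# generic-alignment test grid: quarter-voxel origin offset so no voxel
# centre sits exactly on an emitter axis or cylinder boundary
generic_grid <- function(n = 81, vox = 1, depth = NULL) {
  nz <- if (is.null(depth)) n else depth
  half <- (n - 1) / 2 * vox
  voxel_grid(c(n, n, nz), voxel_mm = vox,
             origin_mm = c(-half + 0.25 * vox, -half + 0.25 * vox,
                           0.25 * vox))
}

# small phantom shared across scoring/synth tests (fits all 9 cylinders)
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(68, 68, 60), voxel_mm = 1.5, cavity_radius_mm = 0,
               ...)
}
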