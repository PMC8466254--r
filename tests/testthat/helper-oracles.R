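# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: brute-force norms, a generic numeric
# optimizer over rotation parameters, and a permutation resampler.

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function(max_deg = 180) {
  rotation_axis_angle(rnorm(3), runif(1, 0, max_deg))
}

random_transform <- function(max_deg = 180, max_trans = 50) {
  rigid_transform(random_rotation(max_deg), runif(3, -max_trans, max_trans))
}

random_implant_df <- function(id = "i1", length_mm = runif(1, 6, 16)) {
  p <- runif(3, -30, 30)
  a <- p + length_mm * random_unit_vector()
  data.frame(id = id, px = p[1], py = p[2], pz = p[3],
             ax = a[1], ay = a[2], az = a[3])
}

# n random non-collinear points (general position with probability 1).
random_points <- function(n, spread = 20) {
  matrix(runif(n * 3, -spread, spread), n, 3)
}

corr_df <- function(S, T) {
  data.frame(sx = S[, 1], sy = S[, 2], sz = S[, 3],
             tx = T[, 1], ty = T[, 2], tz = T[, 3])
}

# Least-squares objective of a rigid registration instance.
rigid_objective <- function(R, t, S, T) {
  fitted <- S %*% t(R) + matrix(t, nrow(S), 3, byrow = TRUE)
  sum((fitted - T)^2)
}

# Rotation from a rotation vector (Rodrigues), used only by the optimizer
# oracle so its parameterization is independent of the package's.
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Brute-force numeric optimizer over (rotation vector, translation).
# Polishes from several starts and returns the best objective found.
optimizer_oracle <- function(S, T, n_starts = 4) {
  obj <- function(par) {
    rigid_objective(rotvec_to_matrix(par[1:3]), par[4:6], S, T)
  }
  starts <- list(c(rep(0, 3), colMeans(T) - colMeans(S)))
  for (i in seq_len(n_starts - 1)) {
    starts[[i + 1]] <- c(rnorm(3, 0, 0.5), colMeans(T) - colMeans(S) + rnorm(3, 0, 1))
  }
  best <- Inf
  best_par <- NULL
  for (s in starts) {
    fit <- optim(s, obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-16))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-16))
    if (fit$value < best) {
      best <- fit$value
      best_par <- fit$par
    }
  }
  list(value = best,
       rotation = rotvec_to_matrix(best_par[1:3]),
       translation = best_par[4:6])
}

# Two-sided permutation p-value for a difference in group means.
permutation_p <- function(x, y, n_perm = 99999) {
  z <- c(x, y)
  n1 <- length(x)
  n <- length(z)
  obs <- abs(mean(x) - mean(y))
  idx <- replicate(n_perm, sample.int(n, n1))
  m1 <- colMeans(matrix(z[idx], n1))
  m2 <- (sum(z) - m1 * n1) / (n - n1)
  (1 + sum(abs(m1 - m2) >= obs - 1e-12)) / (n_perm + 1)
}

max_abs <- function(x) max(abs(x))
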