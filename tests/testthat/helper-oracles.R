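# Small configurations and independent oracles shared across tests.

tiny_cfg <- function(...) {
  sim_config(n_trials_per_task = 5, seed = 1, ...)
}

# Magnitude response of a digital filter evaluated directly from its
# coefficients; independent of the package's filtering path.
digital_gain <- function(flt, f, fs) {
  w <- 2 * pi * f / fs
  eb <- exp(-1i * w * (seq_along(flt$b) - 1))
  ea <- exp(-1i * w * (seq_along(flt$a) - 1))
  Mod(sum(flt$b * eb) / sum(flt$a * ea))
}

# Amplitude of a sinusoid at frequency f in a series, by least squares on a
# sine/cosine basis (immune to phase).
fitted_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# Exact-permutation Friedman p-value for small tables: enumerate every
# within-subject rank assignment (k!^n), recompute the statistic for each,
# and count how often it reaches the observed one.
friedman_exact_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  stat_of <- function(r) {
    12 * sum((colSums(r) - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  }
  obs <- stat_of(t(apply(m, 1, rank)))
  perms <- asplit(gtools_permutations(k), 1)
  grid <- do.call(expand.grid, rep(list(seq_along(perms)), n))
  count <- 0
  for (i in seq_len(nrow(grid))) {
    r <- do.call(rbind, lapply(unlist(grid[i, ]), function(j) perms[[j]]))
    if (stat_of(r) >= obs - 1e-12) count <- count + 1
  }
  count / nrow(grid)
}

# All permutations of 1..k as a matrix (tiny k only).
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}
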