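# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive so they can vouch for the package implementations.

# Step-up FDR adjustment written directly from the definition.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n, na)
# assignments of the pooled ranks (tie-free inputs only).
bf_rank_sum <- function(x, y) {
  na <- length(x); nb <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2L, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(statistic = u_obs, p.value = min(1, p))
}

# Two-point linear interpolation in log10 time.
bf_log_interp <- function(t1, f1, t2, f2, t) {
  f1 + (f2 - f1) * (log10(t) - log10(t1)) / (log10(t2) - log10(t1))
}

# A clean monotone OJIP-like transient sampled exactly at the JIP
# convention times plus a tail.
toy_transient <- function(id = "toy") {
  fluorescence_transient(
    id,
    times = c(5e-5, 3e-4, 2e-3, 3e-2, 0.3, 1),
    fluorescence = c(5000, 6600, 13000, 20000, 24000, 25000))
}

# Factorial design with strongly separated cell kinetics, for tests that
# condition on cell-mean separation of at least 4 within-group SDs.
separated_design <- function(seed) {
  cells <- list()
  for (pop in c("Norway", "France")) for (season in c("summer", "winter"))
    for (period in c("day", "night")) {
      F0 <- if (pop == "Norway") 5000 else 6800
      FM <- if (season == "summer") 5.2 * F0 else 3.2 * F0
      w <- if (period == "day") c(0.40, 0.32, 0.28) else c(0.62, 0.23, 0.15)
      cells[[length(cells) + 1L]] <- list(
        population = pop, season = season, period = period, n = 10L,
        kinetics = kinetic_spec(F0, FM, w, c(1500, 80, 4)))
    }
  design_spec(cells, seed = seed)
}

# Smallest centroid separation between any two groups, in units of the
# pooled within-group SD along the line joining the centroids.
min_directional_separation <- function(X, g) {
  Z <- scale(X)
  gs <- unique(g)
  worst <- Inf
  for (i in 1:(length(gs) - 1)) for (j in (i + 1):length(gs)) {
    a <- Z[g == gs[i], , drop = FALSE]
    b <- Z[g == gs[j], , drop = FALSE]
    d <- colMeans(a) - colMeans(b)
    u <- d / sqrt(sum(d^2))
    sdp <- sqrt((var(a %*% u) * (nrow(a) - 1) + var(b %*% u) * (nrow(b) - 1)) /
                  (nrow(a) + nrow(b) - 2))
    worst <- min(worst, sqrt(sum(d^2)) / sdp)
  }
  worst
}
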