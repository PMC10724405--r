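# Brute-force O(N^2) event-driven reference engine, independent of the
# cell-list C++ engine: at every step it scans all pairs (and all 27
# periodic images) for the earliest contact, advances the whole system
# analytically, and applies the restitution impulse.  Elastic,
# un-thermostatted, fixed diameters.  Used as the oracle for
# event-sequence equivalence and conservation checks.

.ref_images <- as.matrix(expand.grid(ix = -1:1, iy = -1:1, iz = -1:1))

ref_pair_time <- function(r1, v1, r2, v2, sig, L) {
  dr0 <- r1 - r2
  dv <- v1 - v2
  drs <- sweep(.ref_images * L, 2, dr0, `+`)      # 27 x 3 image separations
  A <- sum(dv * dv)
  B <- drs %*% dv
  C <- rowSums(drs * drs) - sig^2
  taus <- rep(Inf, nrow(drs))
  ov <- C <= 0
  taus[ov & B < 0] <- 0
  disc <- B^2 - A * C
  cand <- !ov & B < 0 & disc >= 0
  taus[cand] <- C[cand] / (-B[cand] + sqrt(disc[cand]))
  min(taus)
}

ref_run_edmd <- function(pos, vel, diam, mass, L, n_collisions, e = 1) {
  n <- nrow(pos)
  t_now <- 0
  events <- data.frame(time = numeric(0), i = integer(0), j = integer(0))
  for (step in seq_len(n_collisions)) {
    tmin <- Inf
    besti <- bestj <- NA_integer_
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      tau <- ref_pair_time(pos[i, ], vel[i, ], pos[j, ], vel[j, ],
                           (diam[i] + diam[j]) / 2, L)
      if (tau < tmin) { tmin <- tau; besti <- i; bestj <- j }
    }
    if (!is.finite(tmin)) break
    pos <- pos + vel * tmin
    pos <- pos - L * floor(pos / L)
    t_now <- t_now + tmin
    i <- besti; j <- bestj
    dr <- pos[i, ] - pos[j, ]
    dr <- dr - L * round(dr / L)
    nrm <- dr / sqrt(sum(dr^2))
    vn <- sum((vel[i, ] - vel[j, ]) * nrm)
    mu <- mass[i] * mass[j] / (mass[i] + mass[j])
    J <- -mu * (1 + e) * vn
    vel[i, ] <- vel[i, ] + J / mass[i] * nrm
    vel[j, ] <- vel[j, ] - J / mass[j] * nrm
    events <- rbind(events,
                    data.frame(time = t_now, i = min(i, j), j = max(i, j)))
  }
  list(positions = pos, velocities = vel, events = events, time = t_now)
}
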