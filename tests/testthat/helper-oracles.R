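# Independent oracles used by the tests. These deliberately reimplement
# the geometric quantities in pure R through different routes than the
# package internals (quaternion algebra, brute-force summation, numeric
# quadrature, finite differences).

# ---- tiny quaternion algebra -------------------------------------------

quat <- function(w, v) c(w, v)
quat_mul <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] + pracma::cross(p[2:4], q[2:4]))
}
quat_conj <- function(q) c(q[1], -q[2:4])
quat_axis_angle <- function(axis, ang) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(ang / 2), sin(ang / 2) * axis)
}
quat_from_matrix <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
      (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
    q
  }
}

# quaternion-based frame-transport oracle for the junction twist angle
oracle_dihedral <- function(chain, v) {
  pos <- chain$positions
  n <- nrow(pos)
  p <- if (v == 1) n else v - 1
  nx <- if (v == n) 1 else v + 1
  t0 <- pos[v, ] - pos[p, ];  t0 <- t0 / sqrt(sum(t0^2))
  t1 <- pos[nx, ] - pos[v, ]; t1 <- t1 / sqrt(sum(t1^2))
  f0 <- chain$frames[p, ]; f1 <- chain$frames[v, ]
  ax <- pracma::cross(t0, t1)
  s <- sqrt(sum(ax^2)); c_ <- sum(t0 * t1)
  qP <- if (s < 1e-14) quat(1, c(0, 0, 0)) else
    quat_axis_angle(ax, atan2(s, c_))
  M0 <- cbind(t0, f0, pracma::cross(t0, f0))
  M1 <- cbind(t1, f1, pracma::cross(t1, f1))
  q_total <- quat_from_matrix(M1 %*% t(M0))
  q_twist <- quat_mul(q_total, quat_conj(qP))
  ang <- 2 * atan2(sum(q_twist[2:4] * t1), q_twist[1])
  # principal branch (-pi, pi]
  ang - 2 * pi * floor((ang + pi) / (2 * pi))
}

# ---- pure-R frame transport (for the finite-difference oracle) ----------

r_transport_frames <- function(pos_old, pos_new, frames) {
  n <- nrow(pos_old)
  out <- frames
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a <- pos_old[j, ] - pos_old[i, ]; a <- a / sqrt(sum(a^2))
    b <- pos_new[j, ] - pos_new[i, ]; b <- b / sqrt(sum(b^2))
    ax <- pracma::cross(a, b)
    s <- sqrt(sum(ax^2)); c_ <- sum(a * b)
    f <- frames[i, ]
    if (s >= 1e-14) {
      u <- ax / s
      f <- c_ * f + s * pracma::cross(u, f) + sum(u * f) * (1 - c_) * u
    }
    f <- f - sum(f * b) * b
    out[i, ] <- f / sqrt(sum(f^2))
  }
  out
}

# transport-consistent central finite differences of the total energy
oracle_fd_forces <- function(sys, ff, h = 1e-6) {
  n <- nrow(sys$positions)
  rings0 <- sys$rings
  rings0[, 1] <- rings0[, 1] - 1L
  ffl <- coilsim:::.ff_list(sys, ff)
  en <- function(pos) {
    frm <- r_transport_frames(sys$positions, pos, sys$frames)
    coilsim:::cs_energy(pos, frm, rings0, ffl)$total
  }
  F <- matrix(0, n, 3)
  for (i in seq_len(n)) for (k in 1:3) {
    p1 <- sys$positions; p1[i, k] <- p1[i, k] + h
    p2 <- sys$positions; p2[i, k] <- p2[i, k] - h
    F[i, k] <- -(en(p1) - en(p2)) / (2 * h)
  }
  F
}

oracle_fd_torques <- function(sys, ff, h = 1e-6) {
  n <- nrow(sys$positions)
  rings0 <- sys$rings
  rings0[, 1] <- rings0[, 1] - 1L
  ffl <- coilsim:::.ff_list(sys, ff)
  rot <- function(frm, i, ang) {
    j <- if (i == n) 1 else i + 1
    t <- sys$positions[j, ] - sys$positions[i, ]
    t <- t / sqrt(sum(t^2))
    f <- frm[i, ]
    frm[i, ] <- cos(ang) * f + sin(ang) * pracma::cross(t, f) +
      sum(t * f) * (1 - cos(ang)) * t
    frm
  }
  vapply(seq_len(n), function(i) {
    e1 <- coilsim:::cs_energy(sys$positions, rot(sys$frames, i, h), rings0, ffl)$total
    e2 <- coilsim:::cs_energy(sys$positions, rot(sys$frames, i, -h), rings0, ffl)$total
    -(e1 - e2) / (2 * h)
  }, numeric(1))
}

# ---- brute-force total-energy oracle (pure R) ---------------------------

oracle_energy <- function(sys, ff) {
  pos <- sys$positions
  n <- nrow(pos)
  nxt <- c(2:n, 1)
  bl <- sqrt(rowSums((pos[nxt, ] - pos)^2))
  e_bond <- sum(0.5 * ff$k_bond * (bl - ff$rest_length)^2)
  tang <- (pos[nxt, ] - pos) / bl
  prv <- c(n, 1:(n - 1))
  cosb <- rowSums(tang[prv, ] * tang)
  e_bend <- sum(ff$k_bend * (1 - cosb))
  phis <- vapply(seq_len(n), function(v) oracle_dihedral(sys, v), numeric(1))
  e_tor <- sum(0.5 * ff$k_dihedral * (1 - cos(phis - ff$phi0)))
  e_ev <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (j == i + 1 || (i == 1 && j == n)) next
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (r < ff$sigma_ev * 2^(1 / 6)) {
      sr6 <- (ff$sigma_ev / r)^6
      e_ev <- e_ev + 4 * ff$eps_ev * (sr6^2 - sr6) + ff$eps_ev
    }
  }
  e_aff <- 0
  ap <- sys$affinity_pairs
  if (nrow(ap)) for (k in seq_len(nrow(ap))) {
    r <- sqrt(sum((pos[ap$a[k], ] - pos[ap$b[k], ])^2))
    if (r < ff$r_cut) {
      sr6 <- (ff$sigma_lj / r)^6
      e_aff <- e_aff + 4 * ap$epsilon[k] * (sr6^2 - sr6)
    }
  }
  list(bond = e_bond, bend = e_bend, torsion = e_tor, excluded_volume = e_ev,
       affinity = e_aff,
       total = e_bond + e_bend + e_tor + e_ev + e_aff)
}

# ---- Gauss-integral writhe by numeric double quadrature -----------------

oracle_writhe_quadrature <- function(pos, n_nodes = 8) {
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  n <- nrow(pos)
  nxt <- c(2:n, 1)
  seg <- pos[nxt, ] - pos
  # composite nodes: subdivide a segment into m equal pieces
  nodes <- function(m) {
    x <- as.vector(outer(gl$x / m, (seq_len(m) - 1) / m, `+`))
    w <- rep(gl$w / m, m)
    list(x = x, w = w)
  }
  wr <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (j == i + 1 || (i == 1 && j == n)) next
    tij <- pracma::cross(seg[i, ], seg[j, ])
    # close approaches need finer panels for the 1/r^3 kernel
    dmin <- min(sqrt(sum((pos[i, ] - pos[j, ])^2)),
                sqrt(sum((pos[i, ] - pos[nxt[j], ])^2)),
                sqrt(sum((pos[nxt[i], ] - pos[j, ])^2)),
                sqrt(sum((pos[nxt[i], ] - pos[nxt[j], ])^2)))
    L <- max(sqrt(sum(seg[i, ]^2)), sqrt(sum(seg[j, ]^2)))
    m <- min(8L, max(1L, ceiling(3 * L / max(dmin, 1e-6))))
    nd <- nodes(m)
    r1 <- outer(nd$x, seg[i, ]) + rep(1, length(nd$x)) %o% pos[i, ]
    r2 <- outer(nd$x, seg[j, ]) + rep(1, length(nd$x)) %o% pos[j, ]
    acc <- 0
    for (a in seq_along(nd$x)) {
      d <- sweep(-r2, 2, r1[a, ], `+`)
      acc <- acc + nd$w[a] * sum(nd$w * (d %*% tij) / rowSums(d^2)^1.5)
    }
    wr <- wr + acc
  }
  2 * wr / (4 * pi)
}

# ---- pivot-move Monte Carlo equilibration of open chains ----------------
# independent of the BD integrator: rigid tail rotations with Metropolis
# acceptance on the bend + excluded-volume energy

pivot_equilibrate <- function(sys, ff, n_moves = 1500, seed = 1) {
  set.seed(seed)
  pos <- sys$positions
  n <- nrow(pos)
  rings0 <- sys$rings
  rings0[, 1] <- rings0[, 1] - 1L
  ffl <- coilsim:::.ff_list(sys, ff)
  frm <- matrix(0, n, 3)
  en <- function(p) coilsim:::cs_energy(p, frm, rings0, ffl)$total
  E <- en(pos)
  for (mv in seq_len(n_moves)) {
    piv <- sample(2:(n - 1), 1)
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    R <- coilsim:::.rotation_about(ax, runif(1, -pi, pi))
    cand <- pos
    tail_idx <- (piv + 1):n
    cand[tail_idx, ] <- sweep(sweep(pos[tail_idx, , drop = FALSE], 2,
                                    pos[piv, ]) %*% t(R), 2, pos[piv, ], `+`)
    E2 <- en(cand)
    if (log(runif(1)) < -(E2 - E)) {
      pos <- cand
      E <- E2
    }
  }
  sys$positions <- pos
  sys
}

# ---- random smooth closed loops -----------------------------------------

random_fourier_loop <- function(n, n_modes = 3, scale = 1.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(cos(th), sin(th), 0) * scale * n / (2 * pi)
  for (k in 2:n_modes) {
    amp <- scale * n / (2 * pi) * 0.25 / k
    pos <- pos + cbind(rnorm(1, 0, amp) * cos(k * th) + rnorm(1, 0, amp) * sin(k * th),
                       rnorm(1, 0, amp) * cos(k * th) + rnorm(1, 0, amp) * sin(k * th),
                       rnorm(1, 0, amp) * cos(k * th) + rnorm(1, 0, amp) * sin(k * th))
  }
  pos
}
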