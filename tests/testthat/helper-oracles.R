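# Independent brute-force oracles used by the tests.  These deliberately
# avoid the package's C++ kernels: plain R, naive loops, closed forms.

# closed-form truncated 12-6 LJ
oracle_lj <- function(r, sigma, eps, cutoff) {
  ifelse(r >= cutoff, 0, 4 * eps * ((sigma / r)^12 - (sigma / r)^6))
}

# naive term-by-term energy of a conformation, optionally restricted to
# terms touching at least one masked residue
oracle_energy <- function(coords, topo, p, force_pn = 0,
                          axis = c(1, 0, 0), fixed = 1, pulled = nrow(coords),
                          mask = NULL) {
  n <- nrow(coords)
  touches <- function(idx) is.null(mask) || any(mask[idx])
  dist <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  e <- 0
  for (i in seq_len(n - 1))
    if (touches(c(i, i + 1)))
      e <- e + 0.5 * p$bond_k * (dist(i, i + 1) - p$bond_r0)^2
  if (n >= 3 && p$angle_k > 0) {
    for (j in 2:(n - 1)) {
      if (!touches((j - 1):(j + 1))) next
      u <- coords[j - 1, ] - coords[j, ]; v <- coords[j + 1, ] - coords[j, ]
      ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      th <- acos(max(-1, min(1, ct)))
      e <- e + 0.5 * p$angle_k * (th - p$angle_theta0)^2
    }
  }
  is_cys <- seq_len(n) %in% topo$cysteines
  ss <- topo$disulfide
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j >= i + 3 && touches(c(i, j))) {
        if (!is.null(ss) && setequal(c(i, j), ss)) next
        r <- dist(i, j)
        e <- e + if (is_cys[i] && is_cys[j])
          oracle_softcore(r, p) else oracle_lj(r, p$sigma, p$epsilon,
                                               p$lj_cutoff)
      }
  nc <- topo$native_contacts
  if (!is.null(nc) && p$contact_epsilon > 0)
    for (k in seq_len(nrow(nc)))
      if (touches(c(nc[k, 1], nc[k, 2]))) {
        dr <- dist(nc[k, 1], nc[k, 2]) - nc[k, 3]
        if (dr <= 6 * p$contact_width)
          e <- e - p$contact_epsilon *
            exp(-0.5 * dr^2 / p$contact_width^2)
      }
  if (!is.null(ss) && touches(ss))
    e <- e + 0.5 * p$crosslink_k * (dist(ss[1], ss[2]) - p$crosslink_r0)^2
  if (force_pn != 0 && touches(c(fixed, pulled)))
    e <- e - force_pn * 0.6022140857 *
      sum((coords[pulled, ] - coords[fixed, ]) * axis)
  unname(e)
}

# piecewise softcore closed form, written out independently
oracle_softcore <- function(r, p) {
  rc <- p$crossover
  if (r >= rc) return(oracle_lj(r, p$sigma, p$epsilon, p$lj_cutoff))
  vc <- oracle_lj(rc, p$sigma, p$epsilon, p$lj_cutoff)
  dv <- 4 * p$epsilon * (-12 * p$sigma^12 / rc^13 + 6 * p$sigma^6 / rc^7)
  a <- dv / (2 * rc)
  vc + a * (r^2 - rc^2)
}

# frame-by-frame exhaustive first-passage scan over stored frames
oracle_first_passage <- function(traj, topo, cutoff) {
  out <- NULL
  for (ft in topo$free_thiols)
    for (m in topo$disulfide) {
      for (f in seq_len(n_frames(traj))) {
        d <- sqrt(sum((traj$coords[ft, , f] - traj$coords[m, , f])^2))
        if (d < cutoff) {
          out <- rbind(out, data.frame(thiol = ft, member = m, frame = f,
                                       d = d))
          break
        }
      }
    }
  out
}

# Monte-Carlo surface-integration SASA oracle (random sphere points)
oracle_sasa_mc <- function(coords, radii, probe, n_mc = 50000L, seed = 7) {
  set.seed(seed)
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  total <- 0
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    z <- matrix(rnorm(3 * n_mc), ncol = 3)
    z <- z / sqrt(rowSums(z^2))
    pts <- sweep(z * ri, 2, coords[i, ], `+`)
    exposed <- rep(TRUE, n_mc)
    for (j in seq_len(n)[-i]) {
      rj <- radii[j] + probe
      exposed <- exposed &
        rowSums(sweep(pts, 2, coords[j, ])^2) > rj^2
    }
    total <- total + mean(exposed) * 4 * pi * ri^2
  }
  total
}

# delta-method standard error of the ratio X/(n-X), X ~ Bin(n, p)
oracle_ratio_se <- function(n55, n24) {
  n <- n55 + n24
  p <- n55 / n
  sqrt(p * (1 - p) / n) / (1 - p)^2
}

# small helper chain: a zig-zag with cysteines, used across tests
toy_system <- function(n = 12, cys = c(2L, 6L, 10L), ss = c(2L, 10L),
                       b = 0.38) {
  topo <- chain_topology(n, cys, ss)
  coords <- cbind(seq_len(n) * b, rep(c(0, 0.1), length.out = n), 0)
  # pull the crosslinked pair together so the bond is physical
  coords[ss[2], ] <- coords[ss[1], ] + c(0.3, 0.25, 0)
  list(topology = topo, frame = cg_frame(coords))
}

# seeded random-walk trajectory for a toy topology (synthetic stream)
toy_trajectory <- function(topo, n_frames = 100, step = 0.12, seed = 1) {
  set.seed(seed)
  n <- topo$n_residues
  coords <- array(0, c(n, 3, n_frames))
  x <- cbind(seq_len(n) * 0.38, 0, 0)
  for (f in seq_len(n_frames)) {
    x <- x + matrix(rnorm(3 * n, sd = step), ncol = 3)
    coords[, , f] <- x
  }
  cg_trajectory(coords, seq_len(n_frames), topo)
}

# synthetic stream helpers: a 3-bead reactive geometry we can script

scripted_trajectory <- function(d32_55, d32_24, topo = NULL) {
  # topology: 8 beads, cysteines 2 (ss), 5 (thiol), 8 (ss); bond 2-8
  if (is.null(topo)) topo <- chain_topology(8, c(2L, 5L, 8L), c(2L, 8L))
  nf <- length(d32_55)
  co <- array(0, c(8, 3, nf))
  for (f in seq_len(nf)) {
    x <- cbind(seq_len(8) * 10, 0, 0)  # spread everything far apart
    x[2, ] <- c(0, 0, 0)
    x[8, ] <- c(0.39, 0, 0)
    x[5, ] <- c(0.39 + d32_55[f], 0, 0)        # distance to bead 8
    # bead 5 to bead 2 distance is then 0.39 + d32_55; override via y when
    # an explicit second distance is wanted
    if (!is.null(d32_24)) {
      # place attacker so that |a - 8| = d32_55 and |a - 2| = d32_24
      a <- d32_55[f]; b <- d32_24[f]; c0 <- 0.39
      px <- (b^2 - a^2 + c0^2) / (2 * c0)
      py2 <- max(0, b^2 - px^2)
      x[5, ] <- c(px, sqrt(py2), 0)
    }
    co[, , f] <- x
  }
  cg_trajectory(co, seq_len(nf), topo)
}

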