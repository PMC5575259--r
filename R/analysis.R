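# Downstream statistics: distance distributions, regioselectivity with
# bootstrap errors, attack-angle survival curves, unfolding statistics,
# loop PCA, and SASA with Kolmogorov-Smirnov group comparison.

as_trajectory_list <- function(trajectories) {
  if (inherits(trajectories, "cg_trajectory")) list(trajectories)
  else trajectories
}

#' Sulfur-sulfur distance distributions
#'
#' Histograms of the distance between each free thiol and each disulfide
#' sulfur (six pairs for the five-cysteine fixture), pooled over
#' trajectories and normalized to densities, with a close-up below
#' `close_cutoff`.
#'
#' @param trajectories a `cg_trajectory` or list of them
#' @param topology a `chain_topology` (defaults to the first trajectory's)
#' @param breaks histogram breaks (nm) passed to [hist()]
#' @param close_cutoff upper edge (nm) of the close-up panel
#' @return object of class `ss_distance_distributions`: per-pair raw
#'   distances, density histograms, and close-up histograms
#' @export
ss_distance_distributions <- function(trajectories, topology = NULL,
                                      breaks = seq(0, 30, by = 0.1),
                                      close_cutoff = 0.5) {
  trajs <- as_trajectory_list(trajectories)
  stopifnot(length(trajs) >= 1)
  if (is.null(topology)) topology <- trajs[[1]]$topology
  dd <- do.call(rbind, lapply(trajs, ss_pair_distances, topology = topology))
  pairs <- unique(dd[, c("thiol", "member")])
  pairs <- pairs[order(pairs$thiol, pairs$member), ]
  hists <- list(); close <- list(); raw <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste0(pairs$thiol[i], "-", pairs$member[i])
    d <- dd$d[dd$thiol == pairs$thiol[i] & dd$member == pairs$member[i]]
    raw[[key]] <- d
    br <- breaks
    if (max(d) >= max(br)) br <- c(br, max(d) + 0.1)
    hists[[key]] <- hist(d, breaks = br, plot = FALSE)
    dcl <- d[d < close_cutoff]
    close[[key]] <- if (length(dcl))
      hist(dcl, breaks = seq(0, close_cutoff, length.out = 26), plot = FALSE)
    else NULL
  }
  structure(list(pairs = pairs, histograms = hists, close = close,
                 distances = raw, close_cutoff = close_cutoff),
            class = "ss_distance_distributions")
}

#' @export
print.ss_distance_distributions <- function(x, ...) {
  cat("<ss_distance_distributions>", nrow(x$pairs), "pairs\n")
  for (key in names(x$distances)) {
    d <- x$distances[[key]]
    cat(sprintf("  %-7s n=%6d  mean=%5.2f nm  min=%5.2f  frac<%.2f=%.4f\n",
                key, length(d), mean(d), min(d), x$close_cutoff,
                mean(d < x$close_cutoff)))
  }
  invisible(x)
}

#' @export
plot.ss_distance_distributions <- function(x, ...) {
  old <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (key in names(x$histograms))
    plot(x$histograms[[key]], freq = FALSE, main = key,
         xlab = "d_S-S (nm)", ...)
  invisible(x)
}

#' Regioselectivity of the attacked disulfide sulfur, with bootstrap error
#'
#' Counts per-trajectory swap events by attacked sulfur and forms the
#' ratio `N55 / N24` (more generally `targets[1] / targets[2]`).  The
#' standard error is obtained by resampling trajectories (one counted
#' event each) with replacement; resamples with a zero denominator are
#' redrawn and their frequency reported.
#'
#' @param events a list of `swap_event` or a data.frame with columns
#'   `target` and `trajectory` (one counted event per trajectory); events
#'   with other verdicts than `"accepted"`/`"detected"` are ignored
#' @param n_bootstrap number of bootstrap resamples
#' @param seed seed for the bootstrap stream (point estimate is unaffected)
#' @param targets length-2 vector: numerator and denominator residue
#' @param cutoff detection cutoff recorded with the result (nm)
#' @return object of class `regioselectivity_result` with fields `n55`,
#'   `n24`, `ratio`, `bootstrap_se`, `n_bootstrap`, `cutoff`, `infinite`
#'   (flag: zero denominator) and `n_redrawn`
#' @export
regioselectivity <- function(events, n_bootstrap = 10000L, seed = 1L,
                             targets = c(55L, 24L), cutoff = 0.5) {
  tab <- if (is.data.frame(events)) events else events_table(events)
  if (nrow(tab) > 0 && "verdict" %in% names(tab))
    tab <- tab[tab$verdict %in% c("accepted", "detected"), , drop = FALSE]
  tgt <- tab$target
  n55 <- sum(tgt == targets[1])
  n24 <- sum(tgt == targets[2])
  infinite <- n24 == 0L
  ratio <- if (infinite) Inf else n55 / n24
  se <- NA_real_
  n_redrawn <- 0L
  if (!infinite && nrow(tab) > 0 && n_bootstrap > 0) {
    se_draws <- with_seed(seed, {
      m <- length(tgt)
      draws <- numeric(n_bootstrap)
      for (b in seq_len(n_bootstrap)) {
        repeat {
          s <- tgt[sample.int(m, m, replace = TRUE)]
          d24 <- sum(s == targets[2])
          if (d24 > 0L) { draws[b] <- sum(s == targets[1]) / d24; break }
          n_redrawn <- n_redrawn + 1L
        }
      }
      draws
    })
    se <- sd(se_draws)
  }
  structure(list(n55 = n55, n24 = n24, ratio = ratio, bootstrap_se = se,
                 n_bootstrap = as.integer(n_bootstrap), cutoff = cutoff,
                 infinite = infinite, n_redrawn = n_redrawn,
                 targets = targets),
            class = "regioselectivity_result")
}

#' @export
print.regioselectivity_result <- function(x, ...) {
  cat(sprintf("<regioselectivity> N%d = %d, N%d = %d, ratio = %s",
              x$targets[1], x$n55, x$targets[2], x$n24,
              if (x$infinite) "Inf (flagged)" else sprintf("%.3f", x$ratio)))
  if (!is.na(x$bootstrap_se))
    cat(sprintf(" +/- %.3f (bootstrap, n = %d)", x$bootstrap_se,
                x$n_bootstrap))
  cat("\n")
  invisible(x)
}

#' Reactive conformations: sub-cutoff attack geometries with angles
#'
#' All frames in which a free thiol lies within `d_cutoff` of a disulfide
#' sulfur, with the corresponding attack angle.  This is the post-hoc
#' conformational set used for angle survival curves and SASA grouping
#' (every qualifying frame, not just first passages).
#'
#' @param trajectories a `cg_trajectory` or list
#' @param topology a `chain_topology`
#' @param d_cutoff distance threshold (nm)
#' @param attacker optionally restrict to one attacking residue
#' @return data.frame: `trajectory`, `frame`, `time`, `attacker`, `target`,
#'   `leaving`, `d_ss`, `angle`
#' @export
attack_conformations <- function(trajectories, topology = NULL,
                                 d_cutoff = 0.5, attacker = NULL) {
  trajs <- as_trajectory_list(trajectories)
  if (is.null(topology)) topology <- trajs[[1]]$topology
  out <- list()
  for (ti in seq_along(trajs)) {
    tr <- trajs[[ti]]
    dd <- ss_pair_distances(tr, topology)
    dd <- dd[dd$d < d_cutoff, , drop = FALSE]
    if (!is.null(attacker)) dd <- dd[dd$thiol %in% attacker, , drop = FALSE]
    if (nrow(dd) == 0) next
    ang <- vapply(seq_len(nrow(dd)), function(i) {
      lv <- setdiff(topology$disulfide, dd$member[i])
      attack_angle(tr$coords[, , dd$frame[i]], dd$thiol[i], dd$member[i], lv)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      trajectory = ti, frame = dd$frame, time = tr$times[dd$frame],
      attacker = dd$thiol, target = dd$member,
      leaving = vapply(dd$member, function(m)
        setdiff(topology$disulfide, m), integer(1)),
      d_ss = dd$d, angle = ang)
  }
  if (length(out) == 0)
    return(data.frame(trajectory = integer(), frame = integer(),
                      time = numeric(), attacker = integer(),
                      target = integer(), leaving = integer(),
                      d_ss = numeric(), angle = numeric()))
  do.call(rbind, out)
}

#' Survival probability of the attack angle, P(angle > theta)
#'
#' For each attacked sulfur, the fraction of reactive conformations whose
#' attack angle exceeds theta, over a grid of theta values, plus the ratio
#' of the two survival curves.
#'
#' @param conformations data.frame with columns `target` and `angle`
#'   (e.g. from [attack_conformations()]) or a list of `swap_event`
#' @param theta_grid angle grid in degrees
#' @param targets the two attacked sulfurs compared (ratio =
#'   `targets[1] / targets[2]`)
#' @return object of class `angle_probability`: data.frame `curves` with
#'   columns `theta`, `p_<target>` ... and `ratio`; empty conformational
#'   sets are flagged via the `undefined` field
#' @export
angle_probability <- function(conformations, theta_grid = seq(0, 180, 5),
                              targets = c(55L, 24L)) {
  tab <- if (is.data.frame(conformations)) conformations
         else events_table(conformations)
  curves <- data.frame(theta = theta_grid)
  undefined <- character(0)
  for (t in targets) {
    a <- tab$angle[tab$target == t & !is.na(tab$angle)]
    col <- paste0("p_", t)
    if (length(a) == 0) {
      undefined <- c(undefined, as.character(t))
      curves[[col]] <- NA_real_
    } else {
      curves[[col]] <- vapply(theta_grid, function(th) mean(a > th),
                              numeric(1))
    }
  }
  curves$ratio <- curves[[paste0("p_", targets[1])]] /
    curves[[paste0("p_", targets[2])]]
  structure(list(curves = curves, targets = targets, undefined = undefined,
                 n = table(factor(tab$target, levels = targets))),
            class = "angle_probability")
}

#' Unfolding statistics from end-to-end distance series
#'
#' First crossing of the end-to-end distance above `threshold` per
#' trajectory (the chain is deemed unfolded beyond it), the fraction of
#' trajectories that unfold, and the monotone cumulative-frequency curve of
#' unfolding times.
#'
#' @param trajectories a `cg_trajectory` or list
#' @param threshold end-to-end distance separating folded from unfolded (nm)
#' @return object of class `unfolding_statistics` with `times` (per
#'   trajectory, `NA` = never unfolded), `fraction`, and `curve`
#'   (data.frame `time`, `cumfreq` over all trajectories)
#' @export
unfolding_statistics <- function(trajectories, threshold = 20) {
  stopifnot(threshold > 0)
  trajs <- as_trajectory_list(trajectories)
  times <- vapply(trajs, function(tr) {
    e <- end_to_end(tr)
    i <- which(e > threshold)[1]
    if (is.na(i)) NA_real_ else tr$times[i]
  }, numeric(1))
  unfolded <- sort(times[!is.na(times)])
  curve <- if (length(unfolded))
    data.frame(time = unfolded,
               cumfreq = seq_along(unfolded) / length(trajs))
  else data.frame(time = numeric(), cumfreq = numeric())
  structure(list(times = times, fraction = mean(!is.na(times)),
                 threshold = threshold, curve = curve),
            class = "unfolding_statistics")
}

#' @export
print.unfolding_statistics <- function(x, ...) {
  cat(sprintf("<unfolding_statistics> %d/%d trajectories unfolded (%.0f%%), threshold %.0f nm\n",
              sum(!is.na(x$times)), length(x$times), 100 * x$fraction,
              x$threshold))
  invisible(x)
}

#' @export
plot.unfolding_statistics <- function(x, ...) {
  plot(x$curve$time, x$curve$cumfreq, type = "s", xlab = "time (ps)",
       ylab = "cumulative frequency", ylim = c(0, 1), ...)
  invisible(x)
}

# frames (loop coords, centered flattened) from the unfolded parts of the
# trajectories
collect_loop_frames <- function(trajs, loop_range, unfolded_only,
                                threshold) {
  mats <- list()
  for (tr in trajs) {
    keep <- seq_len(n_frames(tr))
    if (unfolded_only) {
      e <- end_to_end(tr)
      first <- which(e >= threshold)[1]
      if (is.na(first)) next  # never unfolded: discarded entirely
      keep <- keep[keep >= first & e[keep] >= threshold]
    }
    for (i in keep) mats[[length(mats) + 1L]] <- tr$coords[loop_range, , i]
  }
  mats
}

#' Principal component analysis of the disulfide-enclosed loop
#'
#' Iterative optimal superposition (each conformation is rotated/translated
#' onto the running mean, the mean recomputed, until convergence) followed
#' by eigendecomposition of the positional covariance of the loop beads.
#' When `unfolded_only` is set the folded prefix of each trajectory
#' (end-to-end below `threshold`) is discarded and never-unfolding
#' trajectories are skipped.
#'
#' @param trajectories a `cg_trajectory` or list
#' @param loop_range residue indices of the loop (default 24:55)
#' @param unfolded_only restrict to unfolded segments
#' @param threshold unfolded end-to-end threshold in nm
#' @param frame_stride keep every `frame_stride`-th qualifying frame
#'   (1 = all); large campaigns subsample for the eigensolve
#' @param max_iter,tol superposition iteration controls
#' @return object of class `pca_result`: `mean_structure` (m x 3),
#'   `eigenvectors` (columns, orthonormal), `eigenvalues` (nm^2,
#'   non-increasing), `projections` (frames x modes),
#'   `variance_fraction_12`, and `superposed` (frames x 3m matrix)
#' @export
loop_pca <- function(trajectories, loop_range = 24:55,
                     unfolded_only = TRUE, threshold = 20,
                     frame_stride = 1L, max_iter = 20L, tol = 1e-8) {
  trajs <- as_trajectory_list(trajectories)
  mats <- collect_loop_frames(trajs, loop_range, unfolded_only, threshold)
  if (frame_stride > 1L && length(mats) > 0)
    mats <- mats[seq(1, length(mats), by = frame_stride)]
  if (length(mats) < 2) stop("need at least two frames for PCA")
  m <- length(loop_range)
  if (length(mats) < 3 * m)
    warning("fewer frames than loop coordinates: rank-deficient spectrum")
  ref <- sweep(mats[[1]], 2, colMeans(mats[[1]]))
  for (it in seq_len(max_iter)) {
    fitted <- lapply(mats, kabsch, Q = ref)
    newref <- Reduce(`+`, fitted) / length(fitted)
    newref <- sweep(newref, 2, colMeans(newref))
    if (sqrt(mean((newref - ref)^2)) < tol) { ref <- newref; break }
    ref <- newref
  }
  fitted <- lapply(mats, kabsch, Q = ref)
  X <- do.call(rbind, lapply(fitted, as.vector))  # frames x 3m
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  structure(list(mean_structure = matrix(mu, m, 3),
                 eigenvectors = eg$vectors, eigenvalues = ev,
                 projections = Xc %*% eg$vectors,
                 variance_fraction_12 = if (sum(ev) > 0)
                   sum(ev[1:2]) / sum(ev) else NA_real_,
                 superposed = X, loop_range = loop_range),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d frames, %d loop beads; modes 1-2 carry %.1f%% of the positional variance\n",
              nrow(x$projections), nrow(x$mean_structure),
              100 * x$variance_fraction_12))
  invisible(x)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Test points on a quasi-uniform sphere of radius `r_i + probe` around
#' each bead; points inside any neighbor's expanded sphere are buried; the
#' bead's area is the exposed fraction of `4 pi (r_i + probe)^2`.  Beads
#' coincident with an earlier bead contribute no area (so two fully
#' overlapping identical beads count once).
#'
#' @param frame a `cg_frame` or n x 3 coordinate matrix (nm)
#' @param radii bead radii in nm (scalar or per bead)
#' @param probe probe radius in nm
#' @param n_points test points per bead
#' @return total area in nm^2, with per-bead areas as attribute `per_bead`
#' @export
sasa <- function(frame, radii = 0.235, probe = 0.14, n_points = 960L) {
  coords <- if (inherits(frame, "cg_frame")) frame$coords else as.matrix(frame)
  n <- nrow(coords)
  stopifnot(all(radii > 0), probe >= 0)
  radii <- rep_len(radii, n)
  pts0 <- fibonacci_sphere(n_points)
  per <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (radii + probe + ri)^2 & seq_len(n) != i)
    # coincident duplicate of an earlier bead: contributes nothing
    if (any(d2[nb] < 1e-20 & nb < i)) { per[i] <- 0; next }
    nb <- nb[d2[nb] >= 1e-20]
    exposed <- rep(TRUE, n_points)
    if (length(nb)) {
      pts <- sweep(pts0 * ri, 2, coords[i, ], `+`)
      for (j in nb) {
        if (!any(exposed)) break
        rj <- radii[j] + probe
        dj2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
        exposed <- exposed & dj2 > rj^2
      }
    }
    per[i] <- mean(exposed) * 4 * pi * ri^2
  }
  structure(sum(per), per_bead = per)
}

#' SASA time series over a set of frames
#' @param trajectories a `cg_trajectory` or list
#' @param frames optional data.frame with columns `trajectory`, `frame`
#'   restricting which frames are evaluated (e.g. reactive conformations)
#' @param stride evaluate every `stride`-th frame when `frames` is `NULL`
#' @inheritParams sasa
#' @return numeric vector of areas (nm^2)
#' @export
sasa_series <- function(trajectories, frames = NULL, stride = 1L,
                        radii = 0.235, probe = 0.14, n_points = 960L) {
  trajs <- as_trajectory_list(trajectories)
  if (is.null(frames)) {
    frames <- do.call(rbind, lapply(seq_along(trajs), function(ti)
      data.frame(trajectory = ti,
                 frame = seq(1, n_frames(trajs[[ti]]), by = stride))))
  }
  vapply(seq_len(nrow(frames)), function(i)
    as.numeric(sasa(trajs[[frames$trajectory[i]]]$coords[, , frames$frame[i]],
                    radii, probe, n_points)),
    numeric(1))
}

#' Decorrelation stride of a series
#'
#' First lag at which the autocorrelation function crosses zero; sampling
#' at this stride gives approximately independent values (the analogue of
#' sampling SASA every 2 ns in an all-atom run).
#'
#' @param x numeric series
#' @return integer lag (at least 1)
#' @export
decorrelation_stride <- function(x) {
  if (length(x) < 3 || sd(x) == 0) return(1L)
  a <- acf(x, lag.max = min(length(x) - 1, 200), plot = FALSE)$acf[-1]
  z <- which(a <= 0)[1]
  if (is.na(z)) length(a) else max(1L, z)
}

#' Compare SASA distributions of reactive conformation groups
#'
#' Two-sample Kolmogorov-Smirnov tests between the SASA distributions of
#' the two reactive groups (e.g. conformations allowing a 32->24 versus a
#' 32->55 attack) and of each group against all conformations, on
#' decorrelated subsamples.
#'
#' @param sasa_all,sasa_g1,sasa_g2 numeric SASA series (nm^2): all
#'   conformations and the two reactive groups
#' @param stride subsampling stride applied to each series (`NULL`:
#'   determined per series via [decorrelation_stride()])
#' @param labels group labels
#' @return object of class `sasa_result` with the subsampled series, KS
#'   statistic and p-value for group1 vs group2 (`ks_statistic`,
#'   `p_value`), the auxiliary group-vs-all tests, and the effect
#'   direction; groups with fewer than 2 independent samples skip the test
#'   with a warning
#' @export
compare_sasa_groups <- function(sasa_all, sasa_g1, sasa_g2, stride = NULL,
                                labels = c("32->24", "32->55")) {
  sub <- function(x) {
    s <- if (is.null(stride)) decorrelation_stride(x) else stride
    x[seq(1, length(x), by = max(1L, s))]
  }
  g1 <- sub(sasa_g1); g2 <- sub(sasa_g2); all <- sub(sasa_all)
  if (length(g1) < 2 || length(g2) < 2) {
    warning("fewer than 2 independent samples in a group: KS test skipped")
    return(structure(list(groups = list(all = all, g1 = g1, g2 = g2),
                          labels = labels, ks_statistic = NA_real_,
                          p_value = NA_real_, direction = NA_character_,
                          vs_all = NULL),
                     class = "sasa_result"))
  }
  kt <- suppressWarnings(ks.test(g1, g2))
  vs_all <- lapply(list(g1, g2), function(g)
    if (length(all) >= 2) suppressWarnings(ks.test(g, all)) else NULL)
  direction <- if (mean(g1) < mean(g2))
    paste(labels[1], "more compact") else paste(labels[2], "more compact")
  structure(list(groups = list(all = all, g1 = g1, g2 = g2),
                 labels = labels,
                 ks_statistic = unname(kt$statistic),
                 p_value = kt$p.value, direction = direction,
                 vs_all = vs_all),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %s vs %s: D = %.3f, p = %.3g (%s)\n",
              x$labels[1], x$labels[2], x$ks_statistic, x$p_value,
              x$direction))
  cat(sprintf("  n(independent): %d / %d / %d (all / %s / %s)\n",
              length(x$groups$all), length(x$groups$g1), length(x$groups$g2),
              x$labels[1], x$labels[2]))
  invisible(x)
}
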