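# Overdamped Langevin force-clamp dynamics: one terminus restrained, a
# constant force pulling the other along a fixed axis.

#' Force-clamp simulation configuration
#'
#' Overdamped (Brownian) dynamics with an Euler-Maruyama integrator:
#' `dx = F/gamma dt + sqrt(2 kT dt / gamma) N(0,1)`.  Defaults reproduce the
#' study conditions: 480 pN clamp force, 300 K.
#'
#' @param force clamp force in pN
#' @param temperature thermostat temperature in K
#' @param friction friction coefficient gamma in kJ/mol ps/nm^2
#' @param timestep integration step in ps
#' @param n_steps number of integration steps
#' @param output_stride emit a frame every this many steps
#' @param seed integer seed; identical seeds give identical trajectories
#' @param fixed_residue bead restrained at its initial position (`NULL`
#'   disables the restraint)
#' @param pulled_residue bead the force acts on (`NULL` = last bead)
#' @param pulling_axis unit 3-vector
#' @param k_fix stiffness of the fixed-terminus restraint (kJ/mol/nm^2)
#' @param max_step per-step displacement cap in nm (numerical safeguard
#'   against excluded-volume overlaps in freshly built conformations)
#' @param skin Verlet-list skin in nm
#' @param stop_after_swap in [run_hybrid()], terminate the trajectory after
#'   the first accepted swap (a swap ends the topology segment)
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(force = 480, temperature = 300, friction = 100,
                              timestep = 0.001, n_steps = 700000L,
                              output_stride = 1000L, seed = 1L,
                              fixed_residue = 1L, pulled_residue = NULL,
                              pulling_axis = c(1, 0, 0), k_fix = 10000,
                              max_step = 0.05, skin = 0.3,
                              stop_after_swap = TRUE) {
  stopifnot(timestep > 0, output_stride >= 1, temperature > 0, friction > 0,
            n_steps >= 0)
  structure(list(force = force, temperature = temperature,
                 friction = friction, timestep = timestep,
                 n_steps = as.integer(n_steps),
                 output_stride = as.integer(output_stride),
                 seed = as.integer(seed),
                 fixed_residue = fixed_residue,
                 pulled_residue = pulled_residue,
                 pulling_axis = pulling_axis / sqrt(sum(pulling_axis^2)),
                 k_fix = k_fix, max_step = max_step, skin = skin,
                 stop_after_swap = isTRUE(stop_after_swap)),
            class = "simulation_config")
}

# Assemble the argument list handed to the C++ segment runner.
segment_cfg <- function(config, n, fixed_ref, n_steps, detect = FALSE,
                        d_cutoff = 0, t0 = 0) {
  pulled <- config$pulled_residue
  if (is.null(pulled)) pulled <- n
  fixed <- config$fixed_residue
  list(dt = config$timestep, gamma = config$friction,
       kT = kT(config$temperature), n_steps = as.integer(n_steps),
       stride = config$output_stride,
       fixed = as.integer(if (is.null(fixed)) 0L else fixed),
       pulled = as.integer(if (is.null(pulled)) 0L else pulled),
       axis = config$pulling_axis, force_kj = pn_to_kj(config$force),
       k_fix = config$k_fix, fixed_ref = fixed_ref,
       max_step = config$max_step, detect = detect, d_cutoff = d_cutoff,
       t0 = t0, skin = config$skin)
}

run_segment <- function(coords, topology, params, config, n_steps,
                        detect = FALSE, d_cutoff = 0, t0 = 0,
                        fixed_ref = NULL) {
  n <- nrow(coords)
  if (is.null(fixed_ref)) {
    fixed_ref <- if (!is.null(config$fixed_residue))
      coords[config$fixed_residue, ] else c(0, 0, 0)
  }
  is_cys <- as.integer(seq_len(n) %in% topology$cysteines)
  ss <- if (is.null(topology$disulfide)) integer(0) else topology$disulfide
  ft <- as.integer(topology$free_thiols)
  cpp_run_segment(coords, is_cys, ss, ft, unclass(params),
                  segment_cfg(config, n, fixed_ref, n_steps, detect,
                              d_cutoff, t0), contacts_matrix(topology))
}

#' Run a force-clamp Langevin trajectory
#'
#' Integrates the chain under the configured clamp force with the fixed
#' terminus harmonically restrained at its initial position.  Trajectories
#' are bit-reproducible from `(start, config, seed)`.
#'
#' @param start a `cg_frame` with the initial conformation
#' @param topology a `chain_topology`
#' @param params a `potential_params`
#' @param config a `simulation_config`
#' @return a `cg_trajectory` (the starting frame is included as frame 1)
#' @export
run_force_clamp <- function(start, topology, params = potential_params(),
                            config = simulation_config()) {
  stopifnot(inherits(start, "cg_frame"))
  if (!is.null(config$fixed_residue) && !is.null(config$pulled_residue) &&
      identical(config$fixed_residue, config$pulled_residue))
    stop("fixed and pulled residues must differ")
  # same dynamics sub-stream derivation as run_hybrid, so a hybrid run with
  # swapping disabled is bit-identical to the plain clamp at equal seeds
  seeds <- derive_seeds(config$seed, 2L)
  seg <- with_seed(seeds[1],
                   run_segment(start$coords, topology, params, config,
                               config$n_steps, detect = FALSE,
                               t0 = start$time))
  if (seg$status == 2L)
    stop("energy divergence: non-finite coordinates at step ", seg$steps_done)
  assemble_trajectory(start, list(seg), topology, config)
}

# Stack the start frame and one or more segment outputs into a trajectory.
assemble_trajectory <- function(start, segments, topology, config,
                                extra_meta = list()) {
  n <- nrow(start$coords)
  mats <- lapply(segments, function(s) {
    if (length(s$frames) == 0) NULL else s$frames
  })
  mats <- Filter(Negate(is.null), mats)
  all_frames <- c(list(as.vector(start$coords)), unlist(lapply(mats, function(m)
    lapply(seq_len(ncol(m)), function(j) m[, j])), recursive = FALSE))
  times <- c(start$time, unlist(lapply(segments, function(s) s$times)))
  coords <- array(unlist(all_frames), dim = c(n, 3, length(all_frames)))
  meta <- c(list(force = config$force, seed = config$seed, config = config),
            extra_meta)
  cg_trajectory(coords, times, topology, meta)
}

#' End-to-end distance series of a trajectory
#'
#' Per-frame distance between the fixed and pulled beads (defaulting to the
#' first and last residue).
#'
#' @param trajectory a `cg_trajectory`
#' @param from,to bead indices (defaults from the trajectory's config)
#' @return numeric vector, one value (nm) per frame
#' @export
end_to_end <- function(trajectory, from = NULL, to = NULL) {
  if (n_frames(trajectory) < 1) stop("empty trajectory")
  cfg <- trajectory$metadata$config
  n <- dim(trajectory$coords)[1]
  if (is.null(from))
    from <- if (!is.null(cfg) && !is.null(cfg$fixed_residue))
      cfg$fixed_residue else 1L
  if (is.null(to)) {
    to <- if (!is.null(cfg)) cfg$pulled_residue else n
    if (is.null(to)) to <- n
  }
  d <- trajectory$coords[to, , , drop = FALSE] -
    trajectory$coords[from, , , drop = FALSE]
  sqrt(colSums(matrix(as.vector(d), nrow = 3)^2))
}

# --- RMSD machinery -------------------------------------------------------

# Kabsch superposition of P onto Q (both m x 3); returns rotated+translated P.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(P0 %*% R, 2, cq, `+`)
}

#' Root-mean-square deviation after optimal superposition
#' @param P,Q m x 3 coordinate matrices (nm)
#' @return RMSD in nm
#' @export
rmsd_fit <- function(P, Q) {
  Pf <- kabsch(P, Q)
  sqrt(mean(rowSums((Pf - Q)^2)))
}

#' Cluster frames and pick representative starting conformations
#'
#' Greedy leader clustering on pairwise RMSD after optimal superposition:
#' a frame joins the first existing cluster whose leader lies within
#' `rmsd_cutoff`, otherwise it founds a new cluster.  One representative
#' (the medoid) is returned per cluster, largest clusters first.
#'
#' @param trajectory a `cg_trajectory`
#' @param rmsd_cutoff cluster radius in nm (default 0.1)
#' @param k maximum number of representatives returned
#' @return list of `cg_frame` objects, with an `assignments` attribute
#'   giving each frame's cluster id
#' @export
select_starting_conformations <- function(trajectory, rmsd_cutoff = 0.1,
                                          k = Inf) {
  stopifnot(rmsd_cutoff > 0)
  nf <- n_frames(trajectory)
  if (nf < 1) stop("empty trajectory")
  frames <- lapply(seq_len(nf), function(i) trajectory$coords[, , i])
  leaders <- integer(0)
  assign_to <- integer(nf)
  for (i in seq_len(nf)) {
    hit <- 0L
    for (j in seq_along(leaders)) {
      if (rmsd_fit(frames[[i]], frames[[leaders[j]]]) < rmsd_cutoff) {
        hit <- j; break
      }
    }
    if (hit == 0L) { leaders <- c(leaders, i); hit <- length(leaders) }
    assign_to[i] <- hit
  }
  sizes <- tabulate(assign_to, nbins = length(leaders))
  ord <- order(sizes, decreasing = TRUE)
  reps <- lapply(ord, function(cl) {
    members <- which(assign_to == cl)
    if (length(members) == 1L) {
      mi <- members
    } else {
      tot <- vapply(members, function(a)
        sum(vapply(members, function(b)
          rmsd_fit(frames[[a]], frames[[b]]), numeric(1))), numeric(1))
      mi <- members[which.min(tot)]
    }
    get_frame(trajectory, mi)
  })
  out <- head(reps, if (is.finite(k)) as.integer(k) else length(reps))
  attr(out, "assignments") <- assign_to
  out
}
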