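# The hybrid Monte Carlo step: first-passage detection of attack
# geometries, topology swap, frozen-environment local minimization, and
# Metropolis acceptance.

#' Thiol-disulfide swap criterion
#'
#' @param mode `"distance"`: the first sub-cutoff approach is a successful
#'   swap; `"metropolis"`: each sub-cutoff approach proposes a swap that is
#'   accepted with probability `min(1, exp(-dE/kT))` on locally minimized
#'   reactant/product energies, re-testing at subsequent steps until
#'   accepted
#' @param d_cutoff sulfur-sulfur first-passage threshold in nm (default 0.5)
#' @param angle_min optional lower bound (degrees) on the
#'   attacker-target-leaving angle for a detection to count; `NULL` (the
#'   default) disables the filter, matching the headline protocol in which
#'   angles are analyzed only post hoc
#' @param relax_radius radius (nm) around the three reactive cysteines
#'   within which residues may move during local minimization
#' @param temperature temperature (K) defining kT for the Metropolis rule
#' @param minimizer_tol steepest-descent convergence threshold on the
#'   maximum force (kJ/mol/nm)
#' @param minimizer_max_steps iteration cap for the minimizer
#' @return an object of class `swap_criterion`
#' @export
swap_criterion <- function(mode = c("distance", "metropolis"),
                           d_cutoff = 0.5, angle_min = NULL,
                           relax_radius = 0.5, temperature = 300,
                           minimizer_tol = 10, minimizer_max_steps = 500L) {
  mode <- match.arg(mode)
  stopifnot(d_cutoff >= 0, relax_radius > 0)
  if (!is.null(angle_min))
    stopifnot(angle_min >= 0, angle_min <= 180)
  structure(list(mode = mode, d_cutoff = d_cutoff, angle_min = angle_min,
                 relax_radius = relax_radius, temperature = temperature,
                 kT = kT(temperature), minimizer_tol = minimizer_tol,
                 minimizer_max_steps = as.integer(minimizer_max_steps)),
            class = "swap_criterion")
}

#' Attack angle at the attacked sulfur
#'
#' Interior angle between the attacker-target and leaving-target vectors,
#' in degrees.  The ideal S_N2 geometry is near 180 degrees.
#'
#' @param frame a `cg_frame` or n x 3 coordinate matrix
#' @param attacker,target,leaving residue indices (distinct)
#' @return angle in degrees, in `[0, 180]`
#' @export
attack_angle <- function(frame, attacker, target, leaving) {
  coords <- if (inherits(frame, "cg_frame")) frame$coords else as.matrix(frame)
  idx <- c(attacker, target, leaving)
  if (anyDuplicated(idx)) stop("attacker, target and leaving must differ")
  u <- coords[attacker, ] - coords[target, ]
  v <- coords[leaving, ] - coords[target, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined angle: coincident positions")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# distances from every free thiol to both disulfide sulfurs, all frames:
# returns a data.frame(frame, thiol, member, d)
ss_pair_distances <- function(trajectory, topology) {
  ss <- topology$disulfide
  if (is.null(ss)) stop("topology has no disulfide")
  nf <- n_frames(trajectory)
  out <- list()
  for (ft in topology$free_thiols) {
    for (m in ss) {
      d <- trajectory$coords[ft, , , drop = FALSE] -
        trajectory$coords[m, , , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        frame = seq_len(nf), thiol = ft, member = m,
        d = sqrt(colSums(matrix(as.vector(d), nrow = 3)^2)))
    }
  }
  do.call(rbind, out)
}

#' First-passage table for every thiol/disulfide-sulfur pair
#'
#' For each (free thiol, disulfide sulfur) pair, the first frame at which
#' the sulfur-sulfur distance drops below the cutoff, before the
#' one-counted-event truncation.  The per-pair event set is monotone in the
#' cutoff.
#'
#' @param trajectory a `cg_trajectory`
#' @param topology a `chain_topology` (defaults to the trajectory's)
#' @param d_cutoff threshold distance (nm)
#' @return data.frame with one row per pair that ever crosses:
#'   `thiol`, `member`, `frame`, `time`, `d`
#' @export
first_passage_table <- function(trajectory, topology = trajectory$topology,
                                d_cutoff = 0.5) {
  dd <- ss_pair_distances(trajectory, topology)
  hits <- dd[dd$d < d_cutoff, ]
  if (nrow(hits) == 0)
    return(data.frame(thiol = integer(), member = integer(),
                      frame = integer(), time = numeric(), d = numeric()))
  first <- do.call(rbind, lapply(split(hits, list(hits$thiol, hits$member),
                                       drop = TRUE),
                                 function(g) g[which.min(g$frame), ]))
  first$time <- trajectory$times[first$frame]
  rownames(first) <- NULL
  first[order(first$frame, first$d), c("thiol", "member", "frame", "time",
                                       "d")]
}

#' Detect the first-passage swap event in a recorded trajectory
#'
#' Scans the frames of a trajectory for the first time any free thiol comes
#' within `d_cutoff` of a disulfide sulfur.  Only the earliest crossing is
#' reported (the stretching force renders the reaction irreversible, so
#' later approaches are not counted); when both disulfide sulfurs are
#' within the cutoff in that frame, the nearer one is the target.
#'
#' @param trajectory a `cg_trajectory`
#' @param topology a `chain_topology` (defaults to the trajectory's)
#' @param criterion a `swap_criterion`; only `d_cutoff` and `angle_min` are
#'   used when scanning a stored trajectory
#' @return list of `swap_event` (verdict `"detected"`), empty if no
#'   approach crosses the cutoff
#' @export
detect_first_passage <- function(trajectory,
                                 topology = trajectory$topology,
                                 criterion = swap_criterion()) {
  fp <- first_passage_table(trajectory, topology, criterion$d_cutoff)
  if (!is.null(criterion$angle_min) && nrow(fp) > 0) {
    ang <- vapply(seq_len(nrow(fp)), function(i) {
      lv <- setdiff(topology$disulfide, fp$member[i])
      attack_angle(trajectory$coords[, , fp$frame[i]], fp$thiol[i],
                   fp$member[i], lv)
    }, numeric(1))
    fp <- fp[ang >= criterion$angle_min, , drop = FALSE]
  }
  if (nrow(fp) == 0) return(list())
  fp <- fp[order(fp$frame, fp$d), ]
  e <- fp[1, ]
  lv <- setdiff(topology$disulfide, e$member)
  ang <- attack_angle(trajectory$coords[, , e$frame], e$thiol, e$member, lv)
  list(swap_event(time = e$time, attacker = e$thiol, target = e$member,
                  leaving = lv, d_ss = e$d, angle = ang,
                  verdict = "detected"))
}

# residues whose beads lie within `radius` of any of the three reactive
# cysteines in `coords`
relax_region <- function(coords, reactive, radius) {
  n <- nrow(coords)
  mobile <- rep(FALSE, n)
  for (r in reactive) {
    d2 <- rowSums(sweep(coords, 2, coords[r, ])^2)
    mobile <- mobile | d2 <= radius^2
  }
  mobile
}

#' Metropolis decision for a proposed thiol-disulfide swap
#'
#' Builds the product topology, locally minimizes both reactant and product
#' conformations by steepest descent with only residues within
#' `relax_radius` of the three reactive cysteines mobile (all other beads
#' frozen; their coordinates are returned bit-identical), and accepts with
#' probability `min(1, exp(-dE/kT))` where `dE` is the product-minus-
#' reactant mobile-subsystem energy after minimization.
#'
#' @param frame a `cg_frame` at the detection step
#' @param topology the current `chain_topology`
#' @param event the detected `swap_event`
#' @param params a `potential_params`
#' @param criterion a `swap_criterion`
#' @param config a `simulation_config` (supplies the pulling term during
#'   minimization)
#' @return list with `verdict` (`"accepted"`/`"rejected"`), `dE` (kJ/mol),
#'   `reactant` and `product` minimized coordinate matrices, and
#'   `converged` flags; a non-converged minimization yields a rejection
#'   with a diagnostic
#' @export
metropolis_swap <- function(frame, topology, event,
                            params = potential_params(),
                            criterion = swap_criterion("metropolis"),
                            config = simulation_config()) {
  if (event$d_ss >= criterion$d_cutoff)
    stop("event distance is not below the cutoff")
  coords <- frame$coords
  n <- nrow(coords)
  reactive <- c(event$attacker, event$target, event$leaving)
  mobile <- relax_region(coords, reactive, criterion$relax_radius)
  is_cys <- as.integer(seq_len(n) %in% topology$cysteines)
  pulled <- config$pulled_residue
  if (is.null(pulled)) pulled <- n
  fixed <- if (is.null(config$fixed_residue)) 0L else config$fixed_residue
  fkj <- pn_to_kj(config$force)
  minz <- function(ss_pair) {
    cpp_minimize(coords, is_cys, as.integer(ss_pair), unclass(params), fkj,
                 config$pulling_axis, as.integer(fixed), as.integer(pulled),
                 mobile, criterion$minimizer_tol,
                 criterion$minimizer_max_steps, 0.005,
                 contacts_matrix(topology))
  }
  reac <- minz(topology$disulfide)
  prod_topo <- apply_swap(topology,
                          within_verdict(event, "accepted"))
  prod <- minz(prod_topo$disulfide)
  dE <- prod$energy - reac$energy
  if (!reac$converged || !prod$converged) {
    return(list(verdict = "rejected", dE = dE,
                reactant = reac$coords, product = prod$coords,
                converged = c(reactant = reac$converged,
                              product = prod$converged),
                diagnostic = "minimizer did not converge"))
  }
  accept <- metropolis_accept(dE, criterion$kT)
  list(verdict = if (accept) "accepted" else "rejected", dE = dE,
       reactant = reac$coords, product = prod$coords,
       converged = c(reactant = TRUE, product = TRUE))
}

#' Metropolis acceptance rule
#'
#' Accepts with probability `min(1, exp(-dE/kT))`, consuming one uniform
#' draw from the current RNG stream when `dE > 0`.
#'
#' @param dE energy difference (kJ/mol), product minus reactant
#' @param kT thermal energy (kJ/mol)
#' @return logical
#' @export
metropolis_accept <- function(dE, kT = 2.494) {
  dE <= 0 || runif(1) < exp(-dE / kT)
}

# copy of an event with a different verdict (events are immutable records)
within_verdict <- function(event, verdict) {
  event$verdict <- verdict
  event
}

#' Run the hybrid Monte Carlo / Langevin scheme
#'
#' Interleaves overdamped Langevin propagation with a per-step check of the
#' swap criterion.  On a distance-only criterion the first sub-cutoff
#' approach is accepted outright; with the Metropolis criterion the
#' proposal is decided on locally minimized energies and, if rejected, the
#' simulation continues and the criterion is re-tested at subsequent steps
#' until a proposal is accepted.  An accepted swap rewires the disulfide
#' (the crosslink moves to the new pair) and, by default, terminates the
#' trajectory segment.
#'
#' Randomness is split into sub-streams: one for the dynamics and one for
#' the Metropolis decisions, both derived from `config$seed`, so detection
#' and propagation are independently reproducible.
#'
#' @param start a `cg_frame`
#' @param topology a `chain_topology`
#' @param params a `potential_params`
#' @param config a `simulation_config`
#' @param criterion a `swap_criterion`
#' @param virtual count events without rewiring the topology: the first
#'   sub-cutoff approach is recorded as the (single) counted event and the
#'   trajectory then continues to full length with detection off.  This is
#'   the distance-criterion bookkeeping used when scanning plain
#'   force-clamp runs; actual bond rewiring is reserved for the
#'   Metropolis protocol
#' @return list with `trajectory` (a `cg_trajectory`), `events` (list of
#'   `swap_event`, rejected proposals included), and `topology` (the final,
#'   possibly rewired `chain_topology`)
#' @export
run_hybrid <- function(start, topology, params = potential_params(),
                       config = simulation_config(),
                       criterion = swap_criterion(), virtual = FALSE) {
  stopifnot(inherits(start, "cg_frame"))
  seeds <- derive_seeds(config$seed, 2L)
  events <- list()
  segments <- list()
  coords <- start$coords
  topo <- topology
  steps_left <- config$n_steps
  t0 <- start$time
  mc_count <- 0L
  detect <- criterion$d_cutoff > 0
  with_seed(seeds[1], {
    while (steps_left > 0L) {
      seg <- run_segment(coords, topo, params, config, steps_left,
                         detect = detect, d_cutoff = criterion$d_cutoff,
                         t0 = t0, fixed_ref = start$coords[
                           if (is.null(config$fixed_residue)) 1L
                           else config$fixed_residue, ])
      segments[[length(segments) + 1L]] <- seg
      steps_left <- steps_left - seg$steps_done
      t0 <- t0 + seg$steps_done * config$timestep
      coords <- seg$coords
      if (seg$status == 2L)
        stop("energy divergence: non-finite coordinates at step ",
             seg$steps_done)
      if (seg$status != 1L) break  # completed without detection
      ev <- seg$event
      ang_ok <- is.null(criterion$angle_min) ||
        (!is.na(ev$angle) && ev$angle >= criterion$angle_min)
      if (!ang_ok) next  # filtered geometry: not a detection, keep going
      event <- swap_event(time = ev$time, attacker = ev$attacker,
                          target = ev$target, leaving = ev$leaving,
                          d_ss = ev$d_ss, angle = ev$angle,
                          verdict = "detected")
      if (criterion$mode == "distance") {
        event$verdict <- "accepted"
        events[[length(events) + 1L]] <- event
        if (virtual) { detect <- FALSE; next }
        topo <- apply_swap(topo, event)
        if (config$stop_after_swap) break
      } else {
        mc_count <- mc_count + 1L
        dec <- with_seed((seeds[2] + mc_count) %% .Machine$integer.max,
                         metropolis_swap(cg_frame(coords, t0), topo, event,
                                         params, criterion, config))
        event$verdict <- dec$verdict
        event$dE <- dec$dE
        events[[length(events) + 1L]] <- event
        if (dec$verdict == "accepted") {
          topo <- apply_swap(topo, event)
          if (config$stop_after_swap) break
        }
        # rejected: continue propagation and re-test at subsequent steps
      }
    }
  })
  traj <- assemble_trajectory(start, segments, topology, config,
                              extra_meta = list(criterion = criterion))
  list(trajectory = traj, events = events, topology = topo)
}
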