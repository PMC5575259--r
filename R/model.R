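# Domain types: chain topology, frames, trajectories, swap events, and the
# I27*-like five-cysteine fixture.

#' Chain topology of a coarse-grained cysteine-bearing chain
#'
#' One bead per residue; cysteine beads double as sulfur positions.  At most
#' one disulfide crosslink is tracked, together with the set of free (reduced)
#' thiols.  Thiol protonation is bookkeeping, not an explicit particle.
#'
#' @param n_residues number of beads (residues), 1-based indexing
#' @param cysteines integer vector of cysteine residue indices
#' @param disulfide length-2 integer vector naming the crosslinked pair, or
#'   `NULL` for a fully reduced chain
#' @return an object of class `chain_topology` with fields `n_residues`,
#'   `cysteines`, `disulfide`, `free_thiols` and `bead_classes`
#' @export
chain_topology <- function(n_residues, cysteines = integer(),
                           disulfide = NULL) {
  n_residues <- as.integer(n_residues)
  cysteines <- sort(unique(as.integer(cysteines)))
  stopifnot(n_residues >= 1, all(cysteines >= 1), all(cysteines <= n_residues))
  if (!is.null(disulfide)) {
    disulfide <- sort(as.integer(disulfide))
    if (length(disulfide) != 2L || disulfide[1] == disulfide[2])
      stop("disulfide must name two distinct residues")
    if (!all(disulfide %in% cysteines))
      stop("disulfide members must be cysteines")
  }
  free_thiols <- setdiff(cysteines, disulfide)
  bead_classes <- rep("generic", n_residues)
  bead_classes[cysteines] <- "cysteine"
  structure(list(n_residues = n_residues, cysteines = cysteines,
                 disulfide = disulfide, free_thiols = free_thiols,
                 bead_classes = bead_classes),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat("<chain_topology> ", x$n_residues, " residues; cysteines: ",
      paste(x$cysteines, collapse = ", "), "\n", sep = "")
  if (!is.null(x$disulfide))
    cat("  disulfide: ", paste(x$disulfide, collapse = "-"),
        "; free thiols: ", paste(x$free_thiols, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' A single conformation (one bead per residue, coordinates in nm)
#'
#' @param coords numeric n x 3 matrix of bead positions in nm
#' @param time time stamp in ps
#' @return an object of class `cg_frame`
#' @export
cg_frame <- function(coords, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("coords must be finite")
  structure(list(time = as.numeric(time), coords = unname(coords)),
            class = "cg_frame")
}

#' Time-ordered trajectory of conformations
#'
#' Coordinates are held as an `n_residues x 3 x n_frames` array; the topology
#' is constant within a trajectory (an accepted swap terminates the segment).
#'
#' @param coords n x 3 x n_frames array (nm)
#' @param times strictly increasing frame times (ps)
#' @param topology the `chain_topology` the frames belong to
#' @param metadata free-form list (force, seed, config, ...)
#' @return an object of class `cg_trajectory`
#' @export
cg_trajectory <- function(coords, times, topology, metadata = list()) {
  if (length(dim(coords)) != 3L) stop("coords must be an n x 3 x nf array")
  if (dim(coords)[3] != length(times)) stop("times/frames length mismatch")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(coords = coords, times = as.numeric(times),
                 topology = topology, metadata = metadata),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", n_frames(x), " frames, ", dim(x$coords)[1],
      " beads, t = [", min(x$times), ", ", max(x$times), "] ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `cg_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame of a trajectory
#' @param trajectory a `cg_trajectory`
#' @param i frame index
#' @return a `cg_frame`
#' @export
get_frame <- function(trajectory, i) {
  cg_frame(trajectory$coords[, , i], trajectory$times[i])
}

#' First-passage swap event record
#'
#' @param time event time (ps)
#' @param attacker residue index of the attacking free thiol
#' @param target attacked disulfide sulfur (residue index)
#' @param leaving the other disulfide member
#' @param d_ss attacker-target sulfur distance (nm)
#' @param angle attacker-target-leaving angle at the attacked sulfur
#'   (degrees)
#' @param verdict one of `"detected"`, `"accepted"`, `"rejected"`
#' @param dE product-minus-reactant minimized energy (kJ/mol), `NA` unless a
#'   Metropolis decision was taken
#' @param trajectory replicate/trajectory identifier
#' @return an object of class `swap_event`
#' @export
swap_event <- function(time, attacker, target, leaving, d_ss, angle = NA,
                       verdict = c("detected", "accepted", "rejected"),
                       dE = NA, trajectory = NA) {
  verdict <- match.arg(verdict)
  if (!is.na(angle) && (angle < 0 || angle > 180))
    stop("angle must lie in [0, 180]")
  structure(list(time = time, attacker = as.integer(attacker),
                 target = as.integer(target), leaving = as.integer(leaving),
                 d_ss = d_ss, angle = angle, verdict = verdict, dE = dE,
                 trajectory = trajectory),
            class = "swap_event")
}

#' @export
print.swap_event <- function(x, ...) {
  cat(sprintf("<swap_event> t=%.3f ps  %d -> %d (leaving %d)  d=%.3f nm  %s\n",
              x$time, x$attacker, x$target, x$leaving, x$d_ss, x$verdict))
  invisible(x)
}

#' Tabulate a list of swap events
#' @param events list of `swap_event` objects (or a single one)
#' @return data.frame with one row per event
#' @export
events_table <- function(events) {
  if (inherits(events, "swap_event")) events <- list(events)
  if (length(events) == 0)
    return(data.frame(trajectory = integer(), time = numeric(),
                      attacker = integer(), target = integer(),
                      leaving = integer(), d_ss = numeric(),
                      angle = numeric(), verdict = character(),
                      dE = numeric()))
  do.call(rbind, lapply(events, function(e)
    data.frame(trajectory = e$trajectory, time = e$time,
               attacker = e$attacker, target = e$target,
               leaving = e$leaving, d_ss = e$d_ss,
               angle = as.numeric(e$angle), verdict = e$verdict,
               dE = as.numeric(e$dE))))
}

#' Build the I27*-like five-cysteine fixture chain
#'
#' Constructs an 89-bead chain with cysteines at residues 24, 32, 47, 55 and
#' 63 and the native 24-55 disulfide, together with a seeded compact
#' self-avoiding starting conformation standing in for the folded state.
#' The construction restrains the free thiols to the folded-state mean
#' sulfur-disulfide distances (1.2, 2.2 and 2.1 nm for residues 32, 47 and
#' 63) so that, as in the folded domain, no thiol starts within attack range
#' of the bond.
#'
#' @param bond_length Calpha-Calpha spacing in nm (default 0.38)
#' @param seed integer seed; identical seeds give identical coordinates
#' @param params optional `potential_params` used for the construction
#'   relaxation
#' @return list with elements `topology` (a `chain_topology`) and `frame`
#'   (a `cg_frame` at time 0)
#' @export
build_i27_star <- function(bond_length = 0.38, seed = 1, params = NULL) {
  stopifnot(bond_length > 0)
  if (is.null(params)) params <- potential_params(bond_r0 = bond_length)
  topo <- chain_topology(89L, cysteines = c(24L, 32L, 47L, 55L, 63L),
                         disulfide = c(24L, 55L))
  coords <- with_seed(seed, {
    x <- saw_collapse(89L, bond_length, r_max = 1.7)
    relax_fixture(x, topo, params)
  })
  topo$native_contacts <- native_contacts(coords, topo)
  list(topology = topo, frame = cg_frame(coords, time = 0))
}

#' Native-contact map of a conformation
#'
#' Structure-based (Go-type) contact list: all bead pairs at least three
#' residues apart in sequence that lie within `contact_cutoff` in the given
#' conformation, excluding the crosslinked pair.  During dynamics each
#' contact contributes an attractive Gaussian well centered at its native
#' distance, which holds the folded stand-in together until the clamp force
#' ruptures the network.
#'
#' @param coords n x 3 coordinate matrix (nm)
#' @param topology a `chain_topology`
#' @param contact_cutoff native distance cutoff in nm
#' @return matrix with columns `i`, `j`, `d0`
#' @export
native_contacts <- function(coords, topology, contact_cutoff = 0.8) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n - 3L)) {
    j <- (i + 3L):n
    d <- sqrt(rowSums(sweep(coords[j, , drop = FALSE], 2, coords[i, ])^2))
    keep <- j[d <= contact_cutoff]
    dk <- d[d <= contact_cutoff]
    if (!is.null(topology$disulfide) && i %in% topology$disulfide) {
      drop <- keep %in% setdiff(topology$disulfide, i)
      keep <- keep[!drop]; dk <- dk[!drop]
    }
    if (length(keep))
      out[[length(out) + 1L]] <- cbind(i = i, j = keep, d0 = dk)
  }
  if (length(out) == 0) return(matrix(numeric(), 0, 3,
                                      dimnames = list(NULL, c("i", "j", "d0"))))
  do.call(rbind, out)
}

# contact matrix in the layout the C++ kernels expect
contacts_matrix <- function(topology) {
  nc <- topology$native_contacts
  if (is.null(nc)) matrix(numeric(), 0, 3) else unname(as.matrix(nc))
}

# Compact self-avoiding random walk inside a sphere of radius r_max.
saw_collapse <- function(n, b, r_max = 1.7, min_sep = 0.35, max_try = 60L) {
  x <- matrix(0, n, 3)
  for (i in 2:n) {
    placed <- FALSE
    for (k in seq_len(max_try)) {
      d <- rnorm(3)
      # bias steps back toward the origin to keep the walk compact
      r <- sqrt(sum(x[i - 1, ]^2))
      if (r > 0.5 * r_max) d <- d - 1.5 * x[i - 1, ] / r
      d <- d / sqrt(sum(d^2))
      cand <- x[i - 1, ] + b * d
      if (sqrt(sum(cand^2)) > r_max) next
      prev <- x[seq_len(max(1, i - 2)), , drop = FALSE]
      d2 <- rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2)
      if (i > 2 && min(d2) < min_sep^2) next
      x[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) x[i, ] <- x[i - 1, ] + b * d  # tolerate rare clashes
  }
  x
}

# Construction relaxation: the standard chain energy plus (i) harmonic
# restraints pulling each free thiol to its folded-state mean distance from
# the disulfide midpoint and (ii) a radius-of-gyration restraint keeping the
# stand-in compact.  Plain steepest descent; used only at build time.
relax_fixture <- function(coords, topo, params,
                          thiol_targets = c(`32` = 1.2, `47` = 2.2,
                                            `63` = 2.1),
                          k_rest = 400, rg_target = 1.3, k_rg = 500,
                          n_iter = 400L) {
  n <- nrow(coords)
  is_cys <- as.integer(seq_len(n) %in% topo$cysteines)
  x <- coords
  h <- 0.01
  e_tot <- function(x) {
    eg <- cpp_energy(x, is_cys, topo$disulfide, unclass(params), 0,
                     c(1, 0, 0), 0L, 0L, NULL, matrix(numeric(), 0, 3))
    e <- eg$energy
    g <- eg$forces  # forces = -gradient
    mid <- colMeans(x[topo$disulfide, , drop = FALSE])
    for (nm in names(thiol_targets)) {
      i <- as.integer(nm)
      v <- x[i, ] - mid
      d <- sqrt(sum(v^2))
      if (d > 0) {
        e <- e + 0.5 * k_rest * (d - thiol_targets[[nm]])^2
        gi <- -k_rest * (d - thiol_targets[[nm]]) * v / d
        g[i, ] <- g[i, ] + gi
        g[topo$disulfide[1], ] <- g[topo$disulfide[1], ] - gi / 2
        g[topo$disulfide[2], ] <- g[topo$disulfide[2], ] - gi / 2
      }
    }
    xc <- sweep(x, 2, colMeans(x))
    rg <- sqrt(mean(rowSums(xc^2)))
    e <- e + 0.5 * k_rg * (rg - rg_target)^2
    g <- g - k_rg * (rg - rg_target) * xc / (n * rg)
    list(e = e, g = g)
  }
  cur <- e_tot(x)
  for (it in seq_len(n_iter)) {
    fmax <- max(sqrt(rowSums(cur$g^2)))
    if (fmax < 5) break
    xtry <- x + h * cur$g / fmax
    trial <- e_tot(xtry)
    if (is.finite(trial$e) && trial$e < cur$e) {
      x <- xtry; cur <- trial; h <- min(h * 1.2, 0.05)
    } else {
      h <- h * 0.5
      if (h < 1e-8) break
    }
  }
  x
}

#' Rewire the topology after an accepted thiol-disulfide swap
#'
#' Pure function: assigns the new disulfide (attacker-target), releases the
#' leaving sulfur as a free thiol, and transfers the thiol flag from the
#' attacker.  Disulfide and thiol counts are conserved.
#'
#' @param topology a `chain_topology` with exactly one disulfide
#' @param event a `swap_event` with `verdict == "accepted"` whose attacker is
#'   a current free thiol and whose target/leaving pair is the current
#'   disulfide
#' @return a new `chain_topology`; the input is unmodified
#' @export
apply_swap <- function(topology, event) {
  if (!inherits(event, "swap_event")) stop("event must be a swap_event")
  if (event$verdict != "accepted")
    stop("apply_swap requires an accepted event")
  if (is.null(topology$disulfide)) stop("topology has no disulfide")
  if (!(event$attacker %in% topology$free_thiols))
    stop("attacker must be a free thiol (is it disulfide-bonded?)")
  if (!setequal(c(event$target, event$leaving), topology$disulfide))
    stop("target/leaving must be the current disulfide pair")
  out <- chain_topology(topology$n_residues, topology$cysteines,
                        disulfide = c(event$attacker, event$target))
  out$native_contacts <- topology$native_contacts
  out
}
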