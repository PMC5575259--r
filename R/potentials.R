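# Energy terms of the coarse-grained model: bonds, bends, excluded volume,
# the disulfide crosslink, the pulling work term, and the softcore
# sulfur-sulfur interaction.

#' Potential parameters of the coarse-grained model
#'
#' Defaults follow one-bead-per-residue conventions: 0.38 nm Calpha spacing,
#' 0.47 nm bead diameter with 1 kJ/mol excluded-volume well, a stiff 0.39 nm
#' disulfide crosslink, and a 1 nm Lennard-Jones cutoff.  Sulfur-sulfur
#' pairs interact through a softcore potential that is finite (in energy and
#' force) down to r = 0 and coincides exactly with the plain Lennard-Jones
#' form at distances at and beyond the `crossover` (0.35 nm).  The
#' `softcore_alpha`, `softcore_lambda` and `softcore_power` values (0.3,
#' 0.9, 1) are stored and reported for provenance; the implemented core is a
#' piecewise C1 construction honoring the crossover-identity contract.
#'
#' @param sigma Lennard-Jones sigma (nm)
#' @param epsilon Lennard-Jones epsilon (kJ/mol)
#' @param lj_cutoff nonbonded truncation distance (nm)
#' @param softcore_alpha,softcore_lambda,softcore_power provenance softcore
#'   parameters (dimensionless)
#' @param crossover distance at and beyond which softcore equals plain LJ (nm)
#' @param bond_k,bond_r0 backbone bond stiffness (kJ/mol/nm^2) and rest
#'   length (nm)
#' @param angle_k,angle_theta0 bending stiffness (kJ/mol/rad^2) and rest
#'   angle (rad)
#' @param crosslink_k,crosslink_r0 disulfide crosslink stiffness and rest
#'   length
#' @param contact_epsilon depth (kJ/mol) of the Gaussian native-contact
#'   wells of the structure-based folded stand-in (0 disables the term)
#' @param contact_width width (nm) of the native-contact wells
#' @return an object of class `potential_params`
#' @export
potential_params <- function(sigma = 0.47, epsilon = 1.0, lj_cutoff = 1.0,
                             softcore_alpha = 0.3, softcore_lambda = 0.9,
                             softcore_power = 1L, crossover = 0.35,
                             bond_k = 10000, bond_r0 = 0.38,
                             angle_k = 10, angle_theta0 = pi,
                             crosslink_k = 10000, crosslink_r0 = 0.39,
                             contact_epsilon = 4.0, contact_width = 0.05) {
  stopifnot(sigma > 0, epsilon >= 0, lj_cutoff > 0, bond_k > 0,
            angle_k >= 0, crosslink_k > 0,
            softcore_lambda > 0, softcore_lambda < 1,
            crossover > 0, crossover < lj_cutoff)
  structure(list(sigma = sigma, epsilon = epsilon, lj_cutoff = lj_cutoff,
                 softcore_alpha = softcore_alpha,
                 softcore_lambda = softcore_lambda,
                 softcore_power = as.integer(softcore_power),
                 crossover = crossover, bond_k = bond_k, bond_r0 = bond_r0,
                 angle_k = angle_k, angle_theta0 = angle_theta0,
                 crosslink_k = crosslink_k, crosslink_r0 = crosslink_r0,
                 contact_epsilon = contact_epsilon,
                 contact_width = contact_width),
            class = "potential_params")
}

#' @export
print.potential_params <- function(x, ...) {
  cat("<potential_params> sigma =", x$sigma, "nm, epsilon =", x$epsilon,
      "kJ/mol, cutoff =", x$lj_cutoff, "nm\n")
  cat("  softcore: alpha =", x$softcore_alpha, ", lambda =",
      x$softcore_lambda, ", power =", x$softcore_power,
      "; identical to LJ beyond", x$crossover, "nm\n")
  invisible(x)
}

#' Truncated 12-6 Lennard-Jones potential
#'
#' Standard form `4 eps ((sigma/r)^12 - (sigma/r)^6)`, zero at and beyond the
#' cutoff.
#'
#' @param r distance(s) in nm, must be positive
#' @param sigma,epsilon LJ parameters
#' @param cutoff truncation distance (nm)
#' @return energy in kJ/mol, vectorized over `r`
#' @export
lj <- function(r, sigma = 0.47, epsilon = 1.0, cutoff = 1.0) {
  if (any(r <= 0)) stop("lj: r must be positive")
  vapply(r, cpp_lj, numeric(1), sigma = sigma, epsilon = epsilon,
         cutoff = cutoff)
}

#' Softcore sulfur-sulfur potential
#'
#' Exactly equals [lj()] for `r >= params$crossover`; below the crossover a
#' bounded quadratic core matches the LJ value and slope at the crossover
#' and its force decreases linearly to zero at r = 0, so both energy and
#' force stay finite at contact.
#'
#' @param r distance(s) in nm; zero is allowed
#' @param params a `potential_params` object
#' @return energy in kJ/mol, vectorized over `r`
#' @export
softcore_lj <- function(r, params = potential_params()) {
  if (any(r < 0)) stop("softcore_lj: r must be non-negative")
  vapply(r, cpp_softcore, numeric(1), sigma = params$sigma,
         epsilon = params$epsilon, cutoff = params$lj_cutoff,
         crossover = params$crossover)
}

#' Softcore force -dV/dr
#' @inheritParams softcore_lj
#' @return force in kJ/mol/nm, vectorized over `r`
#' @export
softcore_force <- function(r, params = potential_params()) {
  vapply(r, cpp_softcore_force, numeric(1), sigma = params$sigma,
         epsilon = params$epsilon, cutoff = params$lj_cutoff,
         crossover = params$crossover)
}

#' Tabulate the softcore potential
#'
#' Writes the (r, V, -dV/dr) table of the sulfur-sulfur softcore
#' interaction, mirroring a tabulated-potential mechanism.
#'
#' @param params a `potential_params`
#' @param r_max largest distance (defaults to the LJ cutoff)
#' @param dr grid spacing in nm
#' @param path optional file; when given the table is written as TSV
#' @return data.frame with columns `r`, `V`, `F` (invisibly when written)
#' @export
softcore_table <- function(params = potential_params(), r_max = NULL,
                           dr = 0.002, path = NULL) {
  if (is.null(r_max)) r_max <- params$lj_cutoff
  r <- seq(0, r_max, by = dr)
  tab <- data.frame(r = r, V = softcore_lj(r, params),
                    F = softcore_force(r, params))
  if (!is.null(path)) {
    write.table(format(tab, digits = 10), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Total coarse-grained energy of a conformation
#'
#' Sum of backbone bonds, bends, nonbonded excluded volume (softcore for
#' sulfur-sulfur pairs, plain LJ otherwise; first and second backbone
#' neighbors and the crosslinked pair excluded), the harmonic disulfide
#' crosslink, and the pulling work term `-F ((r_pulled - r_fixed) . axis)`.
#' With `moving_mask` given, only terms involving at least one masked
#' residue are summed (the frozen-environment subsystem energy used for
#' Metropolis comparisons).
#'
#' @param frame a `cg_frame` (or bare n x 3 coordinate matrix)
#' @param topology a `chain_topology`
#' @param params a `potential_params`
#' @param force pulling force in pN
#' @param moving_mask optional logical vector (length n) of mobile residues
#' @param pulling_axis unit 3-vector of the pulling direction
#' @param fixed_residue,pulled_residue endpoint bead indices for the pulling
#'   term (defaults: 1 and n; ignored when `force == 0`)
#' @param gradient when TRUE also return the forces (negative gradient)
#' @return energy in kJ/mol, or `list(energy, forces)` when
#'   `gradient = TRUE`
#' @export
total_energy <- function(frame, topology, params = potential_params(),
                         force = 0, moving_mask = NULL,
                         pulling_axis = c(1, 0, 0), fixed_residue = 1,
                         pulled_residue = topology$n_residues,
                         gradient = FALSE) {
  coords <- if (inherits(frame, "cg_frame")) frame$coords else as.matrix(frame)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  n <- nrow(coords)
  if (n != topology$n_residues) stop("coordinate count != n_residues")
  if (!is.null(moving_mask)) {
    moving_mask <- as.logical(moving_mask)
    if (length(moving_mask) != n) stop("moving_mask must have length n")
  }
  is_cys <- as.integer(seq_len(n) %in% topology$cysteines)
  ss <- if (is.null(topology$disulfide)) integer(0) else topology$disulfide
  ax <- pulling_axis / sqrt(sum(pulling_axis^2))
  out <- cpp_energy(coords, is_cys, ss, unclass(params), pn_to_kj(force),
                    ax, as.integer(if (is.null(fixed_residue)) 0 else fixed_residue),
                    as.integer(if (is.null(pulled_residue)) 0 else pulled_residue),
                    moving_mask, contacts_matrix(topology))
  if (gradient) out else out$energy
}
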