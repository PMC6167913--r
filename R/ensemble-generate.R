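#' Configuration for the synthetic conformational-ensemble generator
#'
#' Defines how conformers are sampled around a starting backbone.  The
#' generator perturbs backbone dihedrals and rebuilds the chain at the start
#' frame's internal geometry — a lightweight stand-in for constraint-based
#' conformational sampling: covalent geometry is conserved while torsional
#' degrees of freedom explore conformational space.  An optional planted
#' displacement mode (a per-atom 3-vector field with a seeded amplitude
#' schedule) injects a known dominant collective motion for
#' parameter-recovery studies.
#'
#' @param n_conformers Number of frames to generate (default 500, the
#'   ensemble size of the emulated study conditions).
#' @param backbone_noise Standard deviation of the per-dihedral Gaussian
#'   perturbation, degrees (default 5).
#' @param planted_mode Optional list with `field` (an `n_atoms x 3` matrix of
#'   displacements in nm) and optionally `amplitudes` (length
#'   `n_conformers`); if amplitudes are absent they are drawn uniformly from
#'   \[-1, 1\] under the seed.
#' @param constraint_tolerance Maximum fractional deviation of any covalent
#'   bond length from the start frame, in (0, 0.1\] (default 0.05).
#' @param seed Integer seed; all randomness flows through it.
#' @return A list of class `ensemble_gen_config`.
#' @export
ensemble_gen_config <- function(n_conformers = 500, backbone_noise = 5,
                                planted_mode = NULL,
                                constraint_tolerance = 0.05, seed = 1) {
  if (n_conformers < 1) {
    abort("n_conformers must be >= 1", class = "abloopr_config_error")
  }
  if (constraint_tolerance <= 0 || constraint_tolerance > 0.1) {
    abort("constraint_tolerance must lie in (0, 0.1]",
          class = "abloopr_config_error")
  }
  if (!is.null(planted_mode)) {
    stopifnot(is.list(planted_mode), is.matrix(planted_mode$field),
              ncol(planted_mode$field) == 3)
  }
  structure(list(n_conformers = as.integer(n_conformers),
                 backbone_noise = backbone_noise,
                 planted_mode = planted_mode,
                 constraint_tolerance = constraint_tolerance,
                 seed = as.integer(seed)),
            class = "ensemble_gen_config")
}

# move single atoms along violated bonds back to the start-frame length;
# returns repaired coordinates or NULL when a bond cannot be repaired
repair_bonds <- function(coords, bonds, ref_len, tol, max_pass = 100) {
  for (pass in seq_len(max_pass)) {
    ok <- TRUE
    for (b in seq_len(nrow(bonds))) {
      a <- coords[bonds[b, 1], ]; z <- coords[bonds[b, 2], ]
      len <- vnorm(z - a)
      if (abs(len - ref_len[b]) / ref_len[b] > tol * 0.5) {
        coords[bonds[b, 2], ] <- a + (z - a) * ref_len[b] / len
        ok <- FALSE
      }
    }
    if (ok) return(coords)
  }
  # final check at the full tolerance
  for (b in seq_len(nrow(bonds))) {
    len <- vnorm(coords[bonds[b, 2], ] - coords[bonds[b, 1], ])
    if (abs(len - ref_len[b]) / ref_len[b] > tol) return(list(bad = b))
  }
  coords
}

#' Generate a conformational ensemble from a starting structure
#'
#' Produces `n_conformers` frames by Gaussian perturbation of the start
#' frame's backbone dihedrals (phi/psi), rebuilding each conformer at the
#' start frame's exact covalent geometry, then superimposing any planted
#' displacement mode and repairing bonds stretched beyond the constraint
#' tolerance.  With zero noise and no planted mode every frame equals the
#' start frame.  Identical configurations give identical ensembles.
#'
#' @param start A single-frame `loop_ensemble` (e.g. from
#'   [build_ideal_backbone()]).
#' @param config An [ensemble_gen_config()].
#' @return A `loop_ensemble` with `config$n_conformers` frames, carrying the
#'   start ensemble's roster and ground truth.
#' @examples
#' hp <- build_ideal_backbone("hairpin", 12)
#' generate_ensemble(hp, ensemble_gen_config(n_conformers = 10, seed = 1))
#' @export
generate_ensemble <- function(start, config) {
  stopifnot(inherits(start, "loop_ensemble"),
            inherits(config, "ensemble_gen_config"))
  if (n_frames(start) != 1) {
    abort("start ensemble must have exactly one frame",
          class = "abloopr_input_error")
  }
  n_res <- n_residues(start)
  n_atoms <- nrow(start$atoms)
  if (!is.null(config$planted_mode) &&
      nrow(config$planted_mode$field) != n_atoms) {
    abort("planted mode field must match the structure's atom count",
          class = "abloopr_config_error")
  }
  coords0 <- matrix(start$xyz[1, , ], ncol = 3)
  ic <- backbone_internal_coords(coords0, n_res)
  bonds <- backbone_bond_list(n_res)
  ref_len <- apply(bonds, 1, function(b)
    vnorm(coords0[b[2], ] - coords0[b[1], ]))

  withr::with_seed(config$seed, {
    amps <- if (!is.null(config$planted_mode)) {
      config$planted_mode$amplitudes %||% runif(config$n_conformers, -1, 1)
    }
    xyz <- array(NA_real_, dim = c(config$n_conformers, n_atoms, 3))
    for (f in seq_len(config$n_conformers)) {
      if (config$backbone_noise > 0) {
        phi <- ic$phi + rnorm(n_res, 0, config$backbone_noise)
        psi <- ic$psi + rnorm(n_res, 0, config$backbone_noise)
        coords <- backbone_rebuild(ic, phi, psi)
      } else {
        coords <- coords0
      }
      if (!is.null(config$planted_mode)) {
        coords <- coords + 10 * amps[f] * config$planted_mode$field  # nm -> A
        coords <- repair_bonds(coords, bonds, ref_len,
                               config$constraint_tolerance)
        if (is.list(coords)) {
          b <- coords$bad
          abort(sprintf(
            "bond %s(%d) - %s(%d) violates the constraint tolerance after repair",
            start$atoms$elety[bonds[b, 1]], bonds[b, 1],
            start$atoms$elety[bonds[b, 2]], bonds[b, 2]),
            class = "abloopr_generation_error")
        }
      }
      xyz[f, , ] <- coords
    }
    loop_ensemble(xyz, start$atoms, ground_truth = start$ground_truth)
  })
}

#' Planted displacement mode over the loop apex
#'
#' Builds a per-atom displacement field (nm) directed along a fixed axis and
#' tapered by a raised cosine over the central-third apex of the loop, with
#' smooth shoulders into the stems so that bond stretching under the planted
#' motion stays within the generator's constraint tolerance.  Used to inject
#' a known dominant collective motion for parameter-recovery studies.
#'
#' @param start A single-frame `loop_ensemble`.
#' @param magnitude_nm Peak displacement magnitude in nm (default 0.15).
#' @param direction Displacement axis (default +x).
#' @return An `n_atoms x 3` matrix suitable for
#'   [ensemble_gen_config()]'s `planted_mode$field`.
#' @export
planted_apex_mode <- function(start, magnitude_nm = 0.15,
                              direction = c(1, 0, 0)) {
  atoms <- start$atoms
  res_keys <- unique(paste(atoms$chain, atoms$resno, atoms$insert))
  n <- length(res_keys)
  seg <- segment_loop(n)
  w_res <- numeric(n)
  apex_idx <- which(seg == "apex")
  if (length(apex_idx) > 0) {
    t <- seq(0, 1, length.out = length(apex_idx) + 2)[-c(1, length(apex_idx) + 2)]
    w_res[apex_idx] <- sin(pi * t)^2
  }
  # smooth shoulders into the stems
  w_res <- stats::filter(c(0, 0, w_res, 0, 0), rep(1 / 3, 3), sides = 2)[3:(n + 2)]
  w_res[is.na(w_res)] <- 0
  atom_res <- match(paste(atoms$chain, atoms$resno, atoms$insert), res_keys)
  field <- outer(w_res[atom_res], unitv(direction)) * magnitude_nm
  field
}
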