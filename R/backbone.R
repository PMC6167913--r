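# Backbone geometry constants (angstrom / degrees): standard peptide values
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

# angle at b (degrees)
bond_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  rad2deg(acos(pmin(1, pmax(-1, sum(u * v)))))
}

# signed dihedral a-b-c-d (degrees)
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Natural extension reference frame: place atom d bonded to c with given
# bond length, angle b-c-d and dihedral a-b-c-d.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  rot <- cbind(bc, m, n)
  c + as.vector(rot %*% d_local)
}

#' Construct a conformational ensemble object
#'
#' Low-level constructor used by the generators and the PDB reader.  Frames
#' are stored as an `n_frames x n_atoms x 3` array of angstrom coordinates;
#' the atom roster is a tibble shared by all frames.
#'
#' @param xyz Numeric array `n_frames x n_atoms x 3` (angstrom).
#' @param atoms Tibble with one row per atom: `elety` (atom name), `resno`
#'   (residue number), `insert` (insertion code, `""` if none), `chain`,
#'   `resid` (3-letter residue name).
#' @param ground_truth Optional per-residue character vector of constructed
#'   secondary-structure categories (for synthetic fixtures).
#' @return An object of class `loop_ensemble`.
#' @export
loop_ensemble <- function(xyz, atoms, ground_truth = NULL) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[3] == 3,
            dim(xyz)[2] == nrow(atoms))
  if (!all(is.finite(xyz))) {
    abort("non-finite coordinates", class = "abloopr_input_error")
  }
  structure(list(xyz = xyz, atoms = as_tibble(atoms),
                 ground_truth = ground_truth),
            class = "loop_ensemble")
}

#' @export
print.loop_ensemble <- function(x, ...) {
  cat(sprintf("<loop_ensemble> %d frame(s), %d atoms, %d residues\n",
              n_frames(x), nrow(x$atoms), n_residues(x)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble A `loop_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$xyz)[1]

#' Number of residues in an ensemble
#' @param ensemble A `loop_ensemble`.
#' @return Integer count.
#' @export
n_residues <- function(ensemble) {
  length(unique(paste(ensemble$atoms$chain, ensemble$atoms$resno,
                      ensemble$atoms$insert)))
}

#' Per-frame coordinates as a tibble
#'
#' @param x A `loop_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per frame x atom: `frame`, atom roster
#'   columns, `x`, `y`, `z`.
#' @method tidy loop_ensemble
#' @export
tidy.loop_ensemble <- function(x, ...) {
  nf <- n_frames(x)
  na <- nrow(x$atoms)
  comp <- function(k) as.vector(t(matrix(x$xyz[, , k], nrow = nf)))
  tibble(
    frame = rep(seq_len(nf), each = na),
    bind_rows(replicate(nf, x$atoms, simplify = FALSE)),
    x = comp(1), y = comp(2), z = comp(3)
  )
}

# ideal (phi, psi) pairs per secondary-structure type
ideal_dihedrals <- function(ss_type, n, seed) {
  switch(ss_type,
    helix = list(phi = rep(-57, n), psi = rep(-47, n),
                 truth = rep("Helix", n)),
    strand = list(phi = rep(-139, n), psi = rep(135, n),
                  truth = rep("Beta", n)),
    hairpin = {
      if (n < 8) abort("hairpin needs >= 8 residues",
                       class = "abloopr_input_error")
      n1 <- ceiling((n - 4) / 2)
      n2 <- n - 4 - n1
      # 4-residue chain-reversing turn joining two antiparallel strands;
      # dihedrals chosen so the strands pair in hydrogen-bond register
      turn_phi <- c(60, 60, -90, -60)
      turn_psi <- c(45, -120, 0, -45)
      list(phi = c(rep(-139, n1), turn_phi, rep(-139, n2)),
           psi = c(rep(135, n1), turn_psi, rep(135, n2)),
           truth = c(rep("Beta", n1), rep("Turn", 4), rep("Beta", n2)))
    },
    coil = withr::with_seed(seed, {
      phi <- runif(n, -150, -60)
      psi <- ifelse(runif(n) < 0.5, runif(n, -60, 0), runif(n, 60, 180))
      list(phi = phi, psi = psi, truth = rep("Coil", n))
    }),
    abort(sprintf("unknown ss_type '%s'", ss_type),
          class = "abloopr_input_error")
  )
}

# build N/CA/C/O coordinates from per-residue (phi, psi), ideal geometry
backbone_from_dihedrals <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  omega <- omega %||% rep(180, n)
  coords <- matrix(NA_real_, nrow = 4 * n, ncol = 3)
  idx <- function(i, what) (i - 1) * 4 + match(what, c("N", "CA", "C", "O"))
  # first residue in a canonical frame
  coords[idx(1, "N"), ] <- c(0, 0, 0)
  coords[idx(1, "CA"), ] <- c(BOND_N_CA, 0, 0)
  th <- deg2rad(ANG_N_CA_C)
  coords[idx(1, "C"), ] <- coords[idx(1, "CA"), ] +
    BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    Ni <- coords[idx(i, "N"), ]; CAi <- coords[idx(i, "CA"), ]
    Ci <- coords[idx(i, "C"), ]
    if (i < n) {
      Nn <- place_atom(Ni, CAi, Ci, BOND_C_N, ANG_CA_C_N, psi[i])
      CAn <- place_atom(CAi, Ci, Nn, BOND_N_CA, ANG_C_N_CA, omega[i])
      Cn <- place_atom(Ci, Nn, CAn, BOND_CA_C, ANG_N_CA_C, phi[i + 1])
      coords[idx(i + 1, "N"), ] <- Nn
      coords[idx(i + 1, "CA"), ] <- CAn
      coords[idx(i + 1, "C"), ] <- Cn
    }
    coords[idx(i, "O"), ] <- place_atom(Ni, CAi, Ci, BOND_C_O, ANG_CA_C_O,
                                        psi[i] + 180)
  }
  coords
}

#' Build a single-frame ideal backbone
#'
#' Constructs an all-backbone (N, CA, C, O) peptide at ideal bond geometry
#' with repeating dihedrals defining a target secondary structure: `helix`
#' at (phi, psi) = (-57, -47), `strand` at (-139, 135), `hairpin` as two
#' antiparallel strands joined by a 4-residue chain-reversing turn, and
#' `coil` as seeded random dihedrals from the generously allowed region of
#' the Ramachandran map.  The constructed category of every residue is kept
#' as ground truth for downstream validation.
#'
#' @param ss_type One of `"helix"`, `"strand"`, `"hairpin"`, `"coil"`.
#' @param n_residues Chain length (>= 4; >= 8 for hairpin).
#' @param seed Integer seed (used by `coil` only).
#' @param chain Chain identifier for the roster (default `"H"`).
#' @param resno Residue numbers (default `1:n_residues`).
#' @return A single-frame `loop_ensemble` with a `ground_truth` attribute.
#' @examples
#' build_ideal_backbone("helix", 12)
#' @export
build_ideal_backbone <- function(ss_type = c("helix", "strand", "hairpin", "coil"),
                                 n_residues, seed = 1, chain = "H",
                                 resno = NULL) {
  ss_type <- match.arg(ss_type)
  if (n_residues < 4) {
    abort("chain must have at least 4 residues", class = "abloopr_input_error")
  }
  di <- ideal_dihedrals(ss_type, n_residues, seed)
  coords <- backbone_from_dihedrals(di$phi, di$psi)
  resno <- resno %||% seq_len(n_residues)
  atoms <- tibble(
    elety = rep(c("N", "CA", "C", "O"), n_residues),
    resno = rep(as.integer(resno), each = 4),
    insert = "",
    chain = chain,
    resid = "ALA"
  )
  xyz <- array(coords, dim = c(1, nrow(atoms), 3))
  xyz[1, , ] <- coords
  loop_ensemble(xyz, atoms, ground_truth = di$truth)
}

# Extract per-residue internal coordinates (all bonds, angles, phi/psi/omega
# and O placement parameters) from a single frame so a chain can be rebuilt
# exactly, or with perturbed dihedrals.
backbone_internal_coords <- function(coords, n) {
  idx <- function(i, what) (i - 1) * 4 + match(what, c("N", "CA", "C", "O"))
  g <- function(i, w) coords[idx(i, w), ]
  list(
    n = n,
    first3 = coords[c(idx(1, "N"), idx(1, "CA"), idx(1, "C")), ],
    phi = c(NA, sapply(seq(2, n), function(i)
      dihedral_angle(g(i - 1, "C"), g(i, "N"), g(i, "CA"), g(i, "C")))),
    psi = sapply(seq_len(n), function(i)
      if (i < n) dihedral_angle(g(i, "N"), g(i, "CA"), g(i, "C"), g(i + 1, "N"))
      else dihedral_angle(g(i, "N"), g(i, "CA"), g(i, "C"), g(i, "O")) - 180),
    omega = c(sapply(seq_len(n - 1), function(i)
      dihedral_angle(g(i, "CA"), g(i, "C"), g(i + 1, "N"), g(i + 1, "CA"))), NA),
    b_cn = sapply(seq_len(n - 1), function(i) vnorm(g(i + 1, "N") - g(i, "C"))),
    b_nca = sapply(seq_len(n), function(i) vnorm(g(i, "CA") - g(i, "N"))),
    b_cac = sapply(seq_len(n), function(i) vnorm(g(i, "C") - g(i, "CA"))),
    b_co = sapply(seq_len(n), function(i) vnorm(g(i, "O") - g(i, "C"))),
    a_cacn = sapply(seq_len(n - 1), function(i)
      bond_angle(g(i, "CA"), g(i, "C"), g(i + 1, "N"))),
    a_cnca = sapply(seq_len(n - 1), function(i)
      bond_angle(g(i, "C"), g(i + 1, "N"), g(i + 1, "CA"))),
    a_ncac = sapply(seq_len(n), function(i)
      bond_angle(g(i, "N"), g(i, "CA"), g(i, "C"))),
    a_caco = sapply(seq_len(n), function(i)
      bond_angle(g(i, "CA"), g(i, "C"), g(i, "O"))),
    o_dihed_off = sapply(seq_len(n), function(i) {
      d <- dihedral_angle(g(i, "N"), g(i, "CA"), g(i, "C"), g(i, "O"))
      if (i < n) d - dihedral_angle(g(i, "N"), g(i, "CA"), g(i, "C"),
                                    g(i + 1, "N"))
      else 180
    })
  )
}

# rebuild a backbone from internal coordinates (optionally with new phi/psi),
# anchored at the stored first three atoms
backbone_rebuild <- function(ic, phi = NULL, psi = NULL) {
  n <- ic$n
  phi <- phi %||% ic$phi
  psi <- psi %||% ic$psi
  coords <- matrix(NA_real_, nrow = 4 * n, ncol = 3)
  idx <- function(i, what) (i - 1) * 4 + match(what, c("N", "CA", "C", "O"))
  coords[c(idx(1, "N"), idx(1, "CA"), idx(1, "C")), ] <- ic$first3
  for (i in seq_len(n)) {
    Ni <- coords[idx(i, "N"), ]; CAi <- coords[idx(i, "CA"), ]
    Ci <- coords[idx(i, "C"), ]
    if (i < n) {
      Nn <- place_atom(Ni, CAi, Ci, ic$b_cn[i], ic$a_cacn[i], psi[i])
      CAn <- place_atom(CAi, Ci, Nn, ic$b_nca[i + 1], ic$a_cnca[i], ic$omega[i])
      Cn <- place_atom(Ci, Nn, CAn, ic$b_cac[i + 1], ic$a_ncac[i + 1],
                       phi[i + 1])
      coords[idx(i + 1, "N"), ] <- Nn
      coords[idx(i + 1, "CA"), ] <- CAn
      coords[idx(i + 1, "C"), ] <- Cn
    }
    o_dihed <- if (i < n) {
      dihedral_angle(Ni, CAi, Ci, coords[idx(i + 1, "N"), ]) + ic$o_dihed_off[i]
    } else {
      psi[n] + 180
    }
    coords[idx(i, "O"), ] <- place_atom(Ni, CAi, Ci, ic$b_co[i], ic$a_caco[i],
                                        o_dihed)
  }
  coords
}

# consecutive covalent backbone bonds as (from, to) atom indices
backbone_bond_list <- function(n) {
  idx <- function(i, what) (i - 1) * 4 + match(what, c("N", "CA", "C", "O"))
  from <- c(); to <- c()
  for (i in seq_len(n)) {
    from <- c(from, idx(i, "N"), idx(i, "CA"), idx(i, "C"))
    to <- c(to, idx(i, "CA"), idx(i, "C"), idx(i, "O"))
    if (i < n) {
      from <- c(from, idx(i, "C")); to <- c(to, idx(i + 1, "N"))
    }
  }
  cbind(from = from, to = to)
}
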