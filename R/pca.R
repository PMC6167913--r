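# flatten the frame array to a bio3d-style frames x 3N matrix (x,y,z per atom)
ensemble_flat <- function(ensemble) {
  nf <- n_frames(ensemble)
  na <- nrow(ensemble$atoms)
  flat <- matrix(NA_real_, nf, 3 * na)
  flat[, seq(1, 3 * na, 3)] <- ensemble$xyz[, , 1]
  flat[, seq(2, 3 * na, 3)] <- ensemble$xyz[, , 2]
  flat[, seq(3, 3 * na, 3)] <- ensemble$xyz[, , 3]
  flat
}

flat_to_array <- function(flat) {
  na <- ncol(flat) / 3
  xyz <- array(NA_real_, dim = c(nrow(flat), na, 3))
  xyz[, , 1] <- flat[, seq(1, 3 * na, 3)]
  xyz[, , 2] <- flat[, seq(2, 3 * na, 3)]
  xyz[, , 3] <- flat[, seq(3, 3 * na, 3)]
  xyz
}

# atom indices for a fit/analysis selection
resolve_atoms <- function(ensemble, selection) {
  atoms <- ensemble$atoms
  if (is.null(selection) || identical(selection, "all")) {
    return(seq_len(nrow(atoms)))
  }
  if (is.numeric(selection)) return(as.integer(selection))
  if (identical(selection, "calpha")) return(which(atoms$elety == "CA"))
  if (identical(selection, "stem")) {
    res_keys <- unique(paste(atoms$chain, atoms$resno, atoms$insert))
    seg <- segment_loop(length(res_keys))
    stem_res <- res_keys[seg != "apex"]
    return(which(paste(atoms$chain, atoms$resno, atoms$insert) %in% stem_res &
                 atoms$elety == "CA"))
  }
  abort("unknown atom selection", class = "abloopr_input_error")
}

#' Least-squares superposition of ensemble frames
#'
#' Iteratively fits every frame onto the ensemble mean structure by the
#' optimal rigid-body (Kabsch) rotation/translation computed over a fit
#' selection, recomputing the mean until it converges (mean shift below
#' 1e-5 angstrom, at most 10 iterations).  All atoms move; only the fit
#' selection defines the superposition.
#'
#' @param ensemble A `loop_ensemble`.
#' @param fit_selection Atom selection used for fitting: `"calpha"`
#'   (default), `"all"`, `"stem"` (CA atoms outside the central-third apex),
#'   or explicit atom indices.  At least 3 atoms are required.
#' @return The superposed `loop_ensemble`.
#' @export
superpose <- function(ensemble, fit_selection = "calpha") {
  stopifnot(inherits(ensemble, "loop_ensemble"))
  fit_atoms <- resolve_atoms(ensemble, fit_selection)
  if (length(fit_atoms) < 3) {
    abort("fit selection must contain at least 3 atoms",
          class = "abloopr_degenerate_fit_error")
  }
  inds <- as.vector(t(outer(fit_atoms, 1:3, function(a, k) 3 * (a - 1) + k)))
  flat <- ensemble_flat(ensemble)
  ref <- colMeans(flat)
  for (it in seq_len(50)) {
    fitted <- bio3d::fit.xyz(fixed = ref, mobile = flat,
                             fixed.inds = inds, mobile.inds = inds)
    new_mean <- colMeans(fitted)
    shift <- sqrt(mean((new_mean - ref)^2))
    flat <- fitted
    ref <- new_mean
    if (it > 1 && shift < 1e-10) break
  }
  loop_ensemble(flat_to_array(flat), ensemble$atoms,
                ground_truth = ensemble$ground_truth)
}

#' Principal component analysis of a conformational ensemble
#'
#' Eigen-decomposition of the Cartesian coordinate covariance of the
#' (superposed) ensemble about its mean structure, over an analysis
#' selection of atoms.  Eigenvalues are variances of collective motion in
#' nm^2, sorted descending; eigenvectors are orthonormal displacement
#' fields.  No mass weighting is applied.
#'
#' @param ensemble A superposed `loop_ensemble` with at least 2 frames.
#' @param analysis_selection Atom selection analysed (default `"all"`).
#' @return An object of class `ensemble_pca`: `eigenvalues` (nm^2),
#'   `eigenvectors` (3M x n_comp, unit norm), `mean` (3M, angstrom),
#'   `explained` (fractions summing to 1), `atoms` (roster of the analysed
#'   atoms), `atom_idx`.
#' @export
ensemble_pca <- function(ensemble, analysis_selection = "all") {
  stopifnot(inherits(ensemble, "loop_ensemble"))
  if (n_frames(ensemble) < 2) {
    abort("PCA needs at least 2 frames", class = "abloopr_input_error")
  }
  atoms_idx <- resolve_atoms(ensemble, analysis_selection)
  inds <- as.vector(t(outer(atoms_idx, 1:3, function(a, k) 3 * (a - 1) + k)))
  X <- ensemble_flat(ensemble)[, inds, drop = FALSE] / 10  # angstrom -> nm
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  eigenvalues <- sv$d^2 / (nrow(X) - 1)
  keep <- seq_len(min(nrow(X) - 1, ncol(X)))
  eigenvalues <- eigenvalues[keep]
  vectors <- sv$v[, keep, drop = FALSE]
  total <- sum(eigenvalues)
  structure(list(
    eigenvalues = eigenvalues,
    eigenvectors = vectors,
    mean = mu * 10,
    explained = if (total > 0) eigenvalues / total else rep(0, length(keep)),
    atoms = ensemble$atoms[atoms_idx, ],
    atom_idx = atoms_idx
  ), class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  cat(sprintf("<ensemble_pca> %d components over %d atoms\n",
              length(x$eigenvalues), nrow(x$atoms)))
  cat(sprintf("  PC1 %.4g nm^2 (%.1f%%), PC2 %.4g nm^2 (%.1f%%)\n",
              x$eigenvalues[1], 100 * x$explained[1],
              x$eigenvalues[2] %||% NA, 100 * (x$explained[2] %||% NA)))
  invisible(x)
}

#' Eigenvalue spectrum of an ensemble PCA
#'
#' @param x An `ensemble_pca`.
#' @param ... Unused.
#' @return A tibble with `component`, `eigenvalue` (nm^2), `explained`.
#' @method tidy ensemble_pca
#' @export
tidy.ensemble_pca <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         explained = x$explained)
}

#' One-line PCA summary
#'
#' @param x An `ensemble_pca`.
#' @param ... Unused.
#' @return A one-row tibble: `n_components`, `total_variance`,
#'   `pc1_explained`, `pc12_explained`.
#' @method glance ensemble_pca
#' @export
glance.ensemble_pca <- function(x, ...) {
  tibble(n_components = length(x$eigenvalues),
         total_variance = sum(x$eigenvalues),
         pc1_explained = x$explained[1],
         pc12_explained = sum(x$explained[seq_len(min(2, length(x$explained)))]))
}

#' Project a region onto the leading principal components
#'
#' Quantifies how much each atom of a region contributes to the collective
#' motion along the leading eigenvectors.  The contribution of atom `a` to
#' component `k` is the component's eigenvalue multiplied by the squared
#' eigenvector mass on that atom's x, y, z entries (units nm^2); summing
#' over all analysed atoms recovers the eigenvalue.  Residue contributions
#' are sums over their atoms, and residues are ranked by their combined
#' PC1 + PC2 contribution.
#'
#' @param pca An `ensemble_pca`.
#' @param region_atoms Atom indices (into the original ensemble roster) of
#'   the region, e.g. the CDR-H3 atoms; they must lie inside the analysed
#'   selection.
#' @param n_components Number of leading components to report (default 2).
#' @return A list of class `region_projection`: `atoms` (tibble with per-atom
#'   `pc1`, `pc2`, ... contributions) and `residues` (ranked tibble with
#'   summed contributions).
#' @export
project_region <- function(pca, region_atoms, n_components = 2) {
  stopifnot(inherits(pca, "ensemble_pca"))
  pos <- match(region_atoms, pca$atom_idx)
  if (length(pos) == 0 || any(is.na(pos))) {
    abort("region atoms must be part of the analysed selection",
          class = "abloopr_input_error")
  }
  k <- seq_len(min(n_components, length(pca$eigenvalues)))
  contrib <- sapply(k, function(ki) {
    v <- pca$eigenvectors[, ki]
    mass <- rowSums(matrix(v^2, ncol = 3, byrow = TRUE))
    pca$eigenvalues[ki] * mass[pos]
  })
  contrib <- matrix(contrib, nrow = length(pos))
  colnames(contrib) <- paste0("pc", k)
  atoms <- dplyr::bind_cols(pca$atoms[pos, ], as_tibble(contrib))
  residues <- atoms |>
    group_by(.data$chain, .data$resno, .data$insert, .data$resid) |>
    summarise(across(dplyr::starts_with("pc"), sum), .groups = "drop") |>
    mutate(total = rowSums(across(dplyr::starts_with("pc")))) |>
    arrange(desc(.data$total)) |>
    mutate(rank = dplyr::row_number(),
           label = paste0(.data$resno, .data$insert))
  structure(list(atoms = atoms, residues = residues),
            class = "region_projection")
}

#' @export
print.region_projection <- function(x, ...) {
  cat(sprintf("<region_projection> %d atoms, %d residues; top residue %s\n",
              nrow(x$atoms), nrow(x$residues), x$residues$label[1]))
  invisible(x)
}

#' Ranked residue contributions of a region projection
#'
#' @param x A `region_projection`.
#' @param ... Unused.
#' @return The ranked residue tibble.
#' @method tidy region_projection
#' @export
tidy.region_projection <- function(x, ...) x$residues

#' Per-residue contribution chart for a region projection
#'
#' @param object A `region_projection`.
#' @param ... Unused.
#' @return A ggplot of PC1/PC2 contributions (nm^2) per residue.
#' @method autoplot region_projection
#' @export
autoplot.region_projection <- function(object, ...) {
  d <- object$residues |>
    arrange(.data$resno, .data$insert) |>
    mutate(label = factor(.data$label, levels = unique(.data$label))) |>
    tidyr::pivot_longer(dplyr::starts_with("pc"),
                        names_to = "component", values_to = "contribution")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$contribution,
                                  fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "residue", y = expression(contribution ~ (nm^2))) +
    ggplot2::theme_minimal()
}
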