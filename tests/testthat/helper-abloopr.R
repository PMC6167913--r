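# shared fixtures and independent oracles for the test suite

# Batch reference DSSP (mdtraj) over PDB files; returns a list of
# per-residue 4-category vectors, one per input file.
reference_dssp <- function(paths) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, mdtraj",
    "for f in sys.argv[1:]:",
    "    d = mdtraj.compute_dssp(mdtraj.load(f), simplified=False)[0]",
    "    print(''.join(c if c != ' ' else 'C' for c in d))"
  ), script)
  out <- system2("python", c(script, paths), stdout = TRUE)
  lapply(out, function(s) {
    st <- strsplit(s, "")[[1]]
    ss_category(ifelse(st == "N", "C", st))
  })
}

# exhaustive-scan agglomerative clustering with complete linkage under the
# Minkowski metric; merges the lowest-index minimal pair first
brute_force_complete <- function(m, k, p = 4) {
  n <- nrow(m)
  clusters <- as.list(seq_len(n))
  d_cc <- function(a, b) {
    max(sapply(a, function(i) sapply(b, function(j)
      minkowski_distance(m[i, ], m[j, ], p))))
  }
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- d_cc(clusters[[i]], clusters[[j]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (c_i in seq_along(clusters)) out[clusters[[c_i]]] <- c_i
  out
}

# are two flat partitions identical up to label renaming?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# cluster purity: fraction of members in their cluster's majority phenotype
cluster_purity <- function(assignment_tbl, records) {
  d <- dplyr::left_join(assignment_tbl, records[, c("id", "phenotype")],
                        by = c(antibody_id = "id"))
  agg <- tapply(d$phenotype, d$cluster, function(ph) max(table(ph)))
  sum(agg) / nrow(d)
}

# random rigid-body transform of a frame (for superposition tests)
random_rigid <- function(coords, seed) {
  withr::with_seed(seed, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    t(R %*% t(coords)) + matrix(stats::rnorm(3, sd = 5), nrow(coords), 3,
                                byrow = TRUE)
  })
}

# synthetic binomial ss_assignment with known Beta probability
binomial_assignment <- function(p_beta, n_frames, n_res, seed) {
  cat_mat <- withr::with_seed(seed, {
    matrix(ifelse(stats::runif(n_frames * n_res) < p_beta, "Beta", "Coil"),
           n_frames, n_res)
  })
  structure(list(
    detailed = matrix("C", n_frames, n_res),
    category = cat_mat,
    residues = tibble::tibble(chain = "H", resno = seq_len(n_res),
                              insert = "", resid = "ALA")
  ), class = "ss_assignment")
}
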