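test_that("superposition removes rigid-body motion exactly", {
  hp <- build_ideal_backbone("hairpin", 12)
  ref <- matrix(hp$xyz[1, , ], ncol = 3)
  nf <- 6
  xyz <- array(NA_real_, dim = c(nf, nrow(ref), 3))
  for (f in 1:nf) xyz[f, , ] <- random_rigid(ref, seed = f)
  ens <- loop_ensemble(xyz, hp$atoms)
  sup <- superpose(ens, "calpha")
  for (f in 2:nf) {
    expect_lt(sqrt(mean((sup$xyz[f, , ] - sup$xyz[1, , ])^2)), 1e-6)
  }
  # translation-only ensembles collapse the same way
  for (f in 1:nf) xyz[f, , ] <- sweep(ref, 2, c(f, -f, 2 * f), "+")
  sup_t <- superpose(loop_ensemble(xyz, hp$atoms), "calpha")
  expect_lt(max(abs(sweep(sup_t$xyz, c(2, 3), sup_t$xyz[1, , ]))), 1e-6)
  expect_error(superpose(ens, integer(0)),
               class = "abloopr_degenerate_fit_error")
})

test_that("superposition is idempotent", {
  hp <- build_ideal_backbone("hairpin", 12)
  e <- generate_ensemble(hp, ensemble_gen_config(15, 4, seed = 6))
  s1 <- superpose(e, "calpha")
  s2 <- superpose(s1, "calpha")
  expect_lt(max(abs(s2$xyz - s1$xyz)), 1e-9)
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  withr::with_seed(31, {
    nf <- 20; na <- 8
    xyz <- array(rnorm(nf * na * 3), dim = c(nf, na, 3))
    atoms <- tibble::tibble(elety = "CA", resno = seq_len(na), insert = "",
                            chain = "H", resid = "ALA")
    ens <- loop_ensemble(xyz, atoms)
    p <- ensemble_pca(ens, "all")
    # explicit double-loop covariance in nm^2
    X <- matrix(NA_real_, nf, 3 * na)
    for (f in 1:nf) X[f, ] <- as.vector(t(xyz[f, , ])) / 10
    mu <- colMeans(X)
    C <- matrix(0, 3 * na, 3 * na)
    for (f in 1:nf) {
      d <- X[f, ] - mu
      for (i in seq_len(3 * na)) C[i, ] <- C[i, ] + d[i] * d
    }
    C <- C / (nf - 1)
    ev <- eigen(C, symmetric = TRUE)
    k <- length(p$eigenvalues)
    expect_equal(p$eigenvalues, ev$values[seq_len(k)], tolerance = 1e-8)
    # eigenvectors agree up to sign
    for (j in 1:3) {
      expect_equal(abs(sum(p$eigenvectors[, j] * ev$vectors[, j])), 1,
                   tolerance = 1e-6)
    }
  })
})

test_that("eigen spectra are orthonormal, ordered and trace-consistent", {
  hp <- build_ideal_backbone("hairpin", 14)
  e <- superpose(generate_ensemble(hp, ensemble_gen_config(30, 4, seed = 8)))
  p <- ensemble_pca(e, "all")
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_true(all(p$eigenvalues >= -1e-12))
  G <- crossprod(p$eigenvectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_equal(sum(p$explained), 1, tolerance = 1e-6)
  # total variance equals the mean squared deviation from the mean structure
  flat <- abloopr:::ensemble_flat(e) / 10
  msd <- sum(apply(flat, 2, stats::var))
  expect_equal(sum(tidy(p)$eigenvalue), msd, tolerance = 1e-8)
  # degenerate inputs
  e0 <- generate_ensemble(hp, ensemble_gen_config(5, 0, seed = 1))
  expect_true(all(ensemble_pca(e0)$eigenvalues < 1e-20))
  expect_error(ensemble_pca(loop_ensemble(hp$xyz, hp$atoms)),
               class = "abloopr_input_error")
})

test_that("region projections sum to the eigenvalues and find planted atoms", {
  hp <- build_ideal_backbone("hairpin", 16)
  field <- planted_apex_mode(hp, magnitude_nm = 0.3)
  e <- generate_ensemble(hp, ensemble_gen_config(
    40, 0.5, planted_mode = list(field = field), seed = 12))
  p <- ensemble_pca(superpose(e, "stem"), "all")
  pr <- project_region(p, seq_len(nrow(hp$atoms)))
  # conservation: per-atom contributions to PCk sum to eigenvalue_k
  expect_equal(sum(pr$atoms$pc1), p$eigenvalues[1], tolerance = 1e-8)
  expect_equal(sum(pr$atoms$pc2), p$eigenvalues[2], tolerance = 1e-8)
  # residue sums equal their atoms' sums
  expect_equal(sum(pr$residues$total), sum(pr$atoms$pc1 + pr$atoms$pc2),
               tolerance = 1e-10)
  # PC1 aligns with the planted displacement field
  f <- as.vector(t(field)); f <- f / sqrt(sum(f^2))
  expect_gte(abs(sum(p$eigenvectors[, 1] * f)), 0.95)
  # the top-ranked residues are those carrying the planted field
  fm <- rowsum(rowSums(field^2), rep(1:16, each = 4))[, 1]
  k <- sum(fm > 0.25 * max(fm))
  planted <- order(fm, decreasing = TRUE)[1:k]
  expect_setequal(head(pr$residues$resno, k), planted)
  # atoms far from the planted mode contribute near-nothing
  stem_res <- which(fm == 0)
  stem_contrib <- sum(pr$residues$total[pr$residues$resno %in% stem_res])
  expect_lt(stem_contrib / sum(pr$residues$total), 0.1)
  expect_error(project_region(p, 9999), class = "abloopr_input_error")
})
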