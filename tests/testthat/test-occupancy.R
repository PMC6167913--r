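test_that("occupancies normalise and collapse correctly in the limits", {
  hx <- build_ideal_backbone("helix", 12)
  e <- generate_ensemble(hx, ensemble_gen_config(20, 0, seed = 1))
  ss <- assign_secondary_structure(e)
  # interior of an ideal helix is pure Helix
  occ <- ss_occupancy(ss, region = 2:11, seed = 1)
  expect_equal(occ$probability[occ$category == "Helix"], 1)
  expect_equal(sum(occ$probability), 1, tolerance = 1e-9)
  # a constant ensemble has zero-width intervals
  expect_equal(occ$ci_lower, occ$ci_upper)
  # normalization holds on noisy ensembles too
  hp <- build_ideal_backbone("hairpin", 14)
  en <- generate_ensemble(hp, ensemble_gen_config(50, 6, seed = 3))
  occ2 <- ss_occupancy(assign_secondary_structure(en), seed = 2)
  expect_equal(sum(occ2$probability), 1, tolerance = 1e-9)
  expect_true(all(occ2$ci_lower <= occ2$probability + 1e-12))
  expect_true(all(occ2$ci_upper >= occ2$probability - 1e-12))
  expect_error(ss_occupancy(assign_secondary_structure(en), region = "H:99-98"),
               class = "abloopr_input_error")
})

test_that("regions can be selected by chain and residue-number range", {
  hp <- build_ideal_backbone("hairpin", 12, resno = 95:106)
  ss <- assign_secondary_structure(hp)
  occ_all <- ss_occupancy(ss, seed = 1)
  occ_rng <- ss_occupancy(ss, region = "H:95-106", seed = 1)
  expect_equal(occ_all$probability, occ_rng$probability)
  occ_sub <- ss_occupancy(ss, region = "H:98-103", seed = 1)
  expect_equal(attr(occ_sub, "n_residues"), 6L)
})

test_that("bootstrap intervals cover a known occupancy at the stated rate", {
  # binomial ground truth: each (frame, residue) is Beta with p = 0.3
  p_true <- 0.3
  cover <- vapply(1:500, function(s) {
    a <- binomial_assignment(p_true, n_frames = 40, n_res = 8, seed = s)
    occ <- ss_occupancy(a, n_boot = 100, seed = s + 1000)
    row <- occ[occ$category == "Beta", ]
    row$ci_lower <= p_true && p_true <= row$ci_upper
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("group contrasts are null on identical groups and sign-consistent", {
  hp <- build_ideal_backbone("hairpin", 12)
  e <- generate_ensemble(hp, ensemble_gen_config(40, 4, seed = 9))
  ss <- assign_secondary_structure(e)
  same <- contrast_groups(list(ss), list(ss), n_boot = 500, seed = 1)
  expect_equal(same$diff, rep(0, 4))
  expect_true(all(same$p_value[!is.na(same$rel_diff_pct)] > 0.9))
  # swapping groups flips the sign of defined differences
  co <- build_ideal_backbone("coil", 12, seed = 4)
  ec <- generate_ensemble(co, ensemble_gen_config(40, 4, seed = 10))
  sc <- assign_secondary_structure(ec)
  ab <- contrast_groups(list(ss), list(sc), n_boot = 500, seed = 2)
  ba <- contrast_groups(list(sc), list(ss), n_boot = 500, seed = 2)
  expect_equal(ab$diff, -ba$diff)
  expect_error(contrast_groups(list(), list(ss)),
               class = "abloopr_input_error")
})
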