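test_that("the five propensity classes partition the 20 amino acids", {
  cls <- beta_classes()
  members <- unlist(cls)
  expect_equal(sort(unname(members)),
               sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_equal(anyDuplicated(members), 0L)
  expect_equal(beta_class("V"), "strong_former")
  expect_equal(beta_class("E"), "strong_breaker")
  expect_equal(beta_class("G"), "indifferent")
  expect_equal(beta_class(c("H", "S", "K", "N", "P")), rep("breaker", 5))
  expect_error(beta_class("X"), class = "abloopr_classification_error")
})

test_that("segmentation covers every loop exactly with a centre-out apex", {
  for (n in 3:40) {
    seg <- propensity_profile(strrep("A", n))$segment
    expect_equal(length(seg), n)
    expect_gte(sum(seg == "apex"), ceiling(n / 3))
    expect_equal(sum(seg == "stem_n") + sum(seg == "apex") +
                   sum(seg == "stem_c"), n)
    # segments appear in order
    expect_equal(seg, seg[order(match(seg, c("stem_n", "apex", "stem_c")))])
  }
  # length 8: apex covers 0-based positions 3-5
  p <- propensity_profile("VVVEEVVV")
  expect_equal(which(p$segment == "apex"), 4:6)
  expect_equal(sum(p$residue == "E" & p$segment == "apex"), 2)
})

test_that("stem breaker score counts breakers and is monotone", {
  expect_equal(stem_breaker_score(propensity_profile("VVVAAAVVV")), 0)
  expect_equal(stem_breaker_score(propensity_profile("EEEAAAEEE")), 1)
  # replacing any stem former by a breaker never lowers the score
  base <- "VVVAAAVVV"
  s0 <- stem_breaker_score(propensity_profile(base))
  prof <- propensity_profile(base)
  stem_pos <- which(prof$segment != "apex")
  for (i in stem_pos) {
    mutated <- base
    substr(mutated, i, i) <- "K"
    expect_gte(stem_breaker_score(propensity_profile(mutated)), s0)
  }
  # exhaustive length-3 stems: all-former stems < all-breaker stems
  cls <- beta_classes()
  formers <- c(cls$strong_former, cls$former)
  breakers <- c(cls$breaker, cls$strong_breaker)
  f_scores <- sapply(formers, function(a)
    stem_breaker_score(propensity_profile(paste0(strrep(a, 3), "AAA",
                                                 strrep(a, 3)))))
  b_scores <- sapply(breakers, function(a)
    stem_breaker_score(propensity_profile(paste0(strrep(a, 3), "AAA",
                                                 strrep(a, 3)))))
  expect_true(all(f_scores == 0))
  expect_true(all(b_scores == 1))
})

test_that("promiscuous-style loops concentrate breakers at the apex", {
  hits <- sapply(1:50, function(s) {
    set <- generate_antibody_set(
      seq_gen_config(1, 0, stem_former_bias = 0.9, apex_breaker_bias = 0.8,
                     seed = s))
    prof <- profile_cdrs(annotate_cdr3(set, "H"))
    br <- prof$class %in% c("breaker", "strong_breaker")
    sum(br[prof$segment == "apex"]) > sum(br[prof$segment != "apex"])
  })
  expect_gt(mean(hits), 0.5)
})

test_that("profile summaries conserve loop length", {
  p <- propensity_profile("VIMFHSKEGARD")
  s <- propensity_summary(p)
  expect_equal(sum(s$n), 12L)
  expect_equal(nrow(s), 15L)  # 3 segments x 5 classes
  expect_error(propensity_profile("VV"), class = "abloopr_input_error")
})
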