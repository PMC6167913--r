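fake_features <- function(m, ids = NULL) {
  ids <- ids %||% sprintf("ab%d", seq_len(nrow(m)))
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(antibody_id = ids), tibble::as_tibble(m))
}

test_that("well-separated pairs are recovered and merge heights are monotone", {
  m <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  cl <- cluster_kidera(fake_features(m), p = 4, k = 2)
  a <- tidy(cl)$cluster
  expect_true(same_partition(a, c(1, 1, 2, 2)))
  withr::with_seed(21, {
    for (i in 1:10) {
      mm <- matrix(rnorm(7 * 5), 7, 5)
      cl2 <- cluster_kidera(fake_features(mm), p = 4, k = 3)
      expect_true(all(diff(cl2$hclust$height) >= -1e-12))
    }
  })
})

test_that("clustering agrees with an exhaustive agglomeration oracle", {
  withr::with_seed(22, {
    for (rep in 1:8) {
      n <- sample(5:8, 1)
      m <- matrix(rnorm(n * 4), n, 4)
      got <- tidy(cluster_kidera(fake_features(m), p = 4, k = 3))$cluster
      want <- brute_force_complete(m, k = 3, p = 4)
      expect_true(same_partition(got, want))
    }
  })
})

test_that("the partition and enrichment are invariant to input order", {
  set <- generate_antibody_set(seq_gen_config(4, 6, seed = 13))
  feats <- kidera_encode(annotate_cdr3(set))
  cl <- cluster_kidera(feats, k = 3)
  perm <- withr::with_seed(5, sample(nrow(feats)))
  cl_p <- cluster_kidera(feats[perm, ], k = 3)
  a <- tidy(cl); b <- tidy(cl_p)
  b <- b[match(a$antibody_id, b$antibody_id), ]
  expect_true(same_partition(a$cluster, b$cluster))
  ea <- enrichment(cl, set)
  eb <- enrichment(cl_p, set)
  expect_setequal(
    paste(ea$phenotype, ea$n, ea$pct_of_phenotype),
    paste(eb$phenotype, eb$n, eb$pct_of_phenotype))
})

test_that("enrichment percentages follow the cross-tabulation", {
  records <- tibble::tibble(
    id = sprintf("gf%d", 1:10),
    phenotype = rep(c("promiscuous", "non_promiscuous"), c(4, 6)))
  # perfect split
  asg <- tibble::tibble(antibody_id = records$id,
                        cluster = rep(c(1L, 2L), c(4, 6)))
  e <- enrichment(asg, records)
  expect_equal(e$pct_of_phenotype[e$cluster == 1 &
                                    e$phenotype == "promiscuous"], 100)
  expect_equal(e$pct_of_cluster[e$cluster == 1 &
                                  e$phenotype == "non_promiscuous"], 0)
  # per-phenotype percentages sum to 100 across clusters
  sums <- tapply(e$pct_of_phenotype, e$phenotype, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # a cluster holding 4 of 6 non-promiscuous captures 66.7% of them,
  # one holding 3 of 4 promiscuous captures 75%
  asg2 <- tibble::tibble(
    antibody_id = records$id,
    cluster = c(2L, 3L, 3L, 3L, 1L, 1L, 1L, 1L, 2L, 2L))
  e2 <- enrichment(asg2, records)
  expect_equal(e2$pct_of_phenotype[e2$cluster == 1 &
                                     e2$phenotype == "non_promiscuous"], 66.7)
  expect_equal(e2$pct_of_phenotype[e2$cluster == 1 &
                                     e2$phenotype == "promiscuous"], 0)
  expect_equal(e2$pct_of_phenotype[e2$cluster == 3 &
                                     e2$phenotype == "promiscuous"], 75)
  # unknown labels flag the report
  records$phenotype[1] <- "unknown"
  expect_warning(ef <- enrichment(asg, records), "flagged")
  expect_true(attr(ef, "flagged"))
})

test_that("duplicate ids are rejected and Newick export parses", {
  m <- matrix(rnorm(8), 4, 2)
  f <- fake_features(m, ids = c("a", "a", "b", "c"))
  expect_error(cluster_kidera(f), class = "abloopr_input_error")
  cl <- cluster_kidera(fake_features(m))
  nw <- cluster_newick(cl)
  phy <- ape::read.tree(text = nw)
  expect_setequal(phy$tip.label, sprintf("ab%d", 1:4))
})
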