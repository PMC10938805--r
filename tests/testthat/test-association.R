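test_that("pearson_r matches hand values and the two-pass oracle", {
  expect_equal(pearson_r(1:11, 2 * (1:11) + 3)$r, 1, tolerance = 1e-12)
  ex <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ex$r, 0.8, tolerance = 1e-12)
  expect_true(is.na(pearson_r(rep(2, 11), 1:11)$r))
  expect_error(pearson_r(1:4, 1:5), "length mismatch")
  expect_error(pearson_r(1:2, 1:2), "at least 3")

  set.seed(99)
  for (i in 1:300) {
    x <- rnorm(11); y <- rnorm(11)
    got <- pearson_r(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    # cross-check p against cor.test
    expect_equal(got$p, cor.test(x, y)$p.value, tolerance = 1e-9)
  }
})

test_that("association edges apply the |r| and FDR gates", {
  set.seed(4)
  base <- zscore_series(rnorm(11))
  src <- rbind(exact = 2 * base + 5,
               weak = as.numeric(0.5 * base +
                                   sqrt(0.75) * zscore_series(rnorm(11))),
               flat = rep(3, 11))
  tgt <- rbind(m1 = as.numeric(3 * base + 10),
               m2 = as.numeric(zscore_series(rnorm(11)) + 5))
  colnames(src) <- colnames(tgt) <- paste0("S", 1:11)
  e <- build_association_edges(src, tgt)
  key <- paste(e$source_id, e$target_id)
  expect_true("exact m1" %in% key)
  expect_identical(e$sign[key == "exact m1"], "+")
  expect_equal(e$r[key == "exact m1"], 1, tolerance = 1e-12)
  expect_false("weak m1" %in% key)          # |r| gate
  expect_identical(attr(e, "skipped"), "flat")  # zero variance excluded
  expect_true(all(abs(e$r) > 0.85 & e$q_value < 0.05))
})

test_that("null pairs are almost never retained", {
  set.seed(17)
  src <- matrix(rnorm(400 * 11), 400, dimnames = list(paste0("g", 1:400)))
  tgt <- matrix(rnorm(60 * 11), 60, dimnames = list(paste0("m", 1:60)))
  e <- build_association_edges(src, tgt)
  expect_lte(nrow(e) / (400 * 60), 0.001)
})

test_that("the consistency filter removes exactly the sign-discordant pairs", {
  te <- data.frame(source_id = c("g1", "g2", "g3"),
                   target_id = c("m1", "m1", "m2"),
                   layer = "transcript-metabolite",
                   r = c(0.9, 0.9, -0.95), p_value = 1e-6, q_value = 1e-5,
                   sign = c("+", "+", "-"), stringsAsFactors = FALSE)
  pe <- data.frame(source_id = c("p1", "p2"),
                   target_id = c("m1", "m1"),
                   layer = "protein-metabolite",
                   r = c(-0.9, 0.88), p_value = 1e-6, q_value = 1e-5,
                   sign = c("-", "+"), stringsAsFactors = FALSE)
  p2g <- c(p1 = "g1", p2 = "g2")
  db <- consistency_filter(te, pe, p2g)
  # g1-m1 discordant (+ vs -): both its edges removed
  expect_identical(db$removed_pairs$gene_id, "g1")
  expect_false(any(db$edges$gene_id == "g1" & db$edges$target_id == "m1"))
  # concordant g2-m1 kept in both layers; g3 (no protein) passes through
  expect_identical(sum(db$edges$gene_id == "g2"), 2L)
  expect_true("g3" %in% db$edges$gene_id)
  expect_error(consistency_filter(te, data.frame(
    source_id = "pX", target_id = "m1", layer = "protein-metabolite",
    r = 1, p_value = 0, q_value = 0, sign = "+"), p2g), "pX")
})

test_that("database closure: removing a metabolite removes all its edges", {
  sim <- small_sim()
  mm <- stage_means(sim$metabolome)
  em <- stage_means(sim$transcriptome)
  dams <- significant_features(differential_all_pairs(sim$metabolome))
  degs <- significant_features(differential_all_pairs(sim$transcriptome))
  te <- build_association_edges(em[degs, , drop = FALSE],
                                mm[dams, , drop = FALSE])
  expect_true(all(te$source_id %in% rownames(em)))
  expect_true(all(te$target_id %in% rownames(mm)))
  drop <- te$target_id[1]
  te2 <- te[te$target_id != drop, ]
  expect_false(drop %in% te2$target_id)
})

test_that("methylation-expression coupling reports both signs with FDR", {
  set.seed(6)
  stages <- paste0("S", 1:11)
  meth <- matrix(runif(55, 0.1, 0.9), 5,
                 dimnames = list(paste0("g", 1:5), stages))
  expr <- meth * 100                      # identical series -> r = 1
  expr["g2", ] <- 100 - meth["g2", ] * 50 # mirrored -> r = -1
  meth["g3", ] <- 0.5                     # constant -> skipped
  meth["g4", 3] <- NA                     # undefined stage -> skipped
  me <- methylation_expression_edges(meth, expr)
  expect_identical(sort(attr(me, "skipped")), c("g3", "g4"))
  expect_equal(me$r[me$gene_id == "g1"], 1, tolerance = 1e-12)
  expect_identical(me$sign[me$gene_id == "g2"], "-")
  expect_true(all(me$is_significant[me$gene_id %in% c("g1", "g2", "g5")]))
})

test_that("genome methylation correlates with trend clusters as expected", {
  rising <- seq(0.2, 0.4, length.out = 11)
  names(rising) <- paste0("S", 1:11)
  A <- make_archetypes(11)
  mets <- rbind(up = as.numeric(3 + A["V", ]),
                down = as.numeric(3 + A["I", ]))
  colnames(mets) <- names(rising)
  clusters <- data.frame(feature_id = c("up", "down"),
                         cluster_label = c("V", "I"),
                         centroid_distance = 0)
  gm <- genome_methylation_dam_correlation(rising, mets, clusters)
  expect_gt(gm$edges$r[gm$edges$metabolite_id == "up"], 0)
  expect_lt(gm$edges$r[gm$edges$metabolite_id == "down"], 0)
  expect_identical(nrow(gm$cluster_summary), 2L)
  expect_gt(gm$cluster_summary$median_r[gm$cluster_summary$cluster_label ==
                                          "V"], 0)
})
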