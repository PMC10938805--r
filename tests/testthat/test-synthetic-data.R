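test_that("archetypes have the documented shapes and standardization", {
  A <- make_archetypes(11)
  expect_identical(rownames(A), archetype_labels())
  # z-standardized rows
  expect_equal(unname(rowMeans(A)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(A, 1, sd)), rep(1, 8), tolerance = 1e-12)
  # I strictly decreasing; V maximal at S10/S11; peaks at S7 and S6
  expect_true(all(diff(A["I", ]) < 0))
  expect_true(which.max(A["V", ]) %in% 10:11)
  expect_identical(unname(which.max(A["VII", ])), 7L)
  expect_identical(unname(which.max(A["VIII", ])), 6L)
  # early-high clusters are high early; late-high clusters high late
  for (k in c("I", "II", "IV"))
    expect_gt(mean(A[k, 1:3]), mean(A[k, 9:11]))
  for (k in c("III", "V", "VI"))
    expect_lt(mean(A[k, 1:3]), mean(A[k, 9:11]))
  expect_error(make_archetypes(2), "at least 3")
})

test_that("the generator is deterministic and validates its config", {
  cfg <- simulation_config(seed = 5, n_metabolites = 20, n_genes = 50,
                           n_proteins = 20, n_planted_edges = 5,
                           n_planted_dmrs = 5, n_background_sirna = 50)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a$metabolome$values, b$metabolome$values)
  expect_identical(a$transcript_counts, b$transcript_counts)
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth, b$truth)

  expect_error(simulation_config(n_planted_edges = 100, n_genes = 50),
               "exceeds")
  expect_error(simulation_config(frac_dam = 1.5), "fractions")
  expect_error(simulation_config(chh_start = -0.1), "levels")
  # no partner pool left for couplings
  expect_error(simulate_multiomics(
    simulation_config(frac_dam = 1, n_metabolites = 20, n_genes = 50,
                      n_proteins = 10, n_planted_edges = 5,
                      n_planted_dmrs = 0)),
    "no metabolites left")
})

test_that("planted structure meets the generator contracts", {
  sim <- small_sim()
  tr <- sim$truth
  # every planted object references an existing feature
  expect_true(all(tr$true_edges$gene_id %in% feature_ids(sim$transcriptome)))
  expect_true(all(tr$true_edges$metabolite_id %in%
                    feature_ids(sim$metabolome)))
  expect_true(all(tr$coupled_promoters$gene_id %in% sim$genes$gene_id))
  expect_true(all(tr$discordant_genes %in% sim$protein_to_gene))

  # planted-edge empirical r on stage means: >= 0.9 in at least 95% of edges
  mm <- stage_means(sim$metabolome)
  em <- stage_means(sim$transcriptome)
  rr <- vapply(seq_len(nrow(tr$true_edges)), function(i)
    cor(em[tr$true_edges$gene_id[i], ],
        mm[tr$true_edges$metabolite_id[i], ]), numeric(1))
  expect_gte(mean(rr >= 0.9), 0.95)

  # methylation-coupled genes stay below the fold-change gate
  fc <- apply(em[tr$coupled_promoters$gene_id, , drop = FALSE], 1,
              function(x) max(x) / min(x))
  expect_true(all(fc < 2))
})

test_that("population methylation trends follow the stage drifts", {
  sim <- small_sim()
  chh <- global_methylation_series(sim$sites, sim$design, "CHH")
  cg <- global_methylation_series(sim$sites, sim$design, "CG")
  chg <- global_methylation_series(sim$sites, sim$design, "CHG")
  expect_true(all(diff(chh) > 0))  # gradually increasing
  expect_true(all(diff(cg) < 0))   # gradually decreasing
  expect_lt(max(chg) - min(chg), 0.02)  # flat within tolerance
  # whole-genome pooled level rises (CHH dominates the site mix)
  allc <- global_methylation_series(sim$sites, sim$design)
  expect_gt(allc["S11"], allc["S1"])
})

test_that("a null configuration plants nothing", {
  sim0 <- simulate_multiomics(simulation_config(
    seed = 3, n_metabolites = 30, n_genes = 60, n_proteins = 20,
    frac_dam = 0, n_planted_edges = 0, n_planted_dmrs = 0,
    n_background_sirna = 20))
  expect_true(all(is.na(sim0$truth$trend_of)))
  expect_null(sim0$truth$true_edges)
  expect_identical(nrow(sim0$truth$true_dmrs), 0L)
  # flat expected series: stage means vary only by replicate noise
  mm <- stage_means(sim0$metabolome)
  expect_lt(max(apply(mm / rowMeans(mm), 1, sd)), 0.3)
})

test_that("negative-binomial counts track the abundance series", {
  sim <- small_sim()
  counts <- sim$transcript_counts
  expect_true(all(counts >= 0))
  expect_identical(dim(counts), dim(sim$transcriptome$values))
  # planted genes: count stage means correlate with abundance stage means
  g <- sim$truth$true_edges$gene_id[1:10]
  ctab <- feature_table(counts, "transcriptome", sim$design)
  cm <- stage_means(ctab)[g, ]
  am <- stage_means(sim$transcriptome)[g, ]
  rr <- vapply(seq_len(nrow(cm)), function(i) cor(cm[i, ], am[i, ]),
               numeric(1))
  expect_true(all(rr > 0.8))
})
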