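test_that("region methylation level is the count-pooled ratio", {
  s <- toy_sites(c(10, 20), c(3, 7), c(7, 3))
  expect_equal(region_methylation_level(toy_sites(10, 5, 15), "ChrSim",
                                        0, 100), 0.25)
  expect_equal(region_methylation_level(s, "ChrSim", 0, 100), 0.5)
  # empty interval and zero-coverage sites give NA, not 0
  expect_true(is.na(region_methylation_level(s, "ChrSim", 500, 600)))
  expect_true(is.na(region_methylation_level(toy_sites(10, 0, 0), "ChrSim",
                                             0, 100)))
  # context filter
  s2 <- rbind(toy_sites(10, 10, 0, context = "CG"),
              toy_sites(20, 0, 10, context = "CHH"))
  expect_equal(region_methylation_level(s2, "ChrSim", 0, 100, "CG"), 1)
  expect_equal(region_methylation_level(s2, "ChrSim", 0, 100, "CHH"), 0)
})

test_that("pooling invariance: union level equals count-pooled part levels", {
  set.seed(8)
  s <- toy_sites(sample(1000, 50), rbinom(50, 30, 0.3),
                 rbinom(50, 30, 0.7))
  whole <- region_methylation_level(s, "ChrSim", 0, 1000)
  m <- sum(s$meth[s$pos0 < 500]) + sum(s$meth[s$pos0 >= 500])
  tot <- sum(s$meth) + sum(s$unmeth)
  expect_equal(whole, m / tot)
})

test_that("metagene bins pool hand-placed sites correctly", {
  genes <- data.frame(gene_id = "g1", chrom = "ChrSim", start = 1000L,
                      end = 2000L, strand = "+", stringsAsFactors = FALSE)
  design <- stage_design(2, 1)
  # 4 sites: one per upstream bin, 1 in body, 1 downstream
  s <- rbind(toy_sites(c(910, 975), c(2, 4), c(8, 6), stage = "S1"),
             toy_sites(1500, 5, 5, stage = "S1"),
             toy_sites(2025, 9, 1, stage = "S1"))
  prof <- metagene_profile(s, genes, design, n_body_bins = 10,
                           flank_bp = 100, flank_bin_bp = 50)
  p1 <- prof[prof$stage == "S1" & prof$context == "CHH", ]
  # upstream has 2 bins; sites at rel -90 and -25 land in bins 1 and 2
  expect_equal(p1$level[p1$bin == 1], 2 / 10)
  expect_equal(p1$level[p1$bin == 2], 4 / 10)
  # body site at rel 500/1000 -> body bin 6 (bins 3..12)
  expect_equal(p1$level[p1$bin == 2 + 6], 0.5)
  # downstream site at rel 1050 -> first downstream bin (bin 13)
  expect_equal(p1$level[p1$bin == 13], 0.9)
  expect_true(all(is.na(p1$level[!p1$bin %in% c(1, 2, 8, 13)])))
})

test_that("minus-strand genes are reversed so upstream is 5prime", {
  design <- stage_design(2, 1)
  gplus <- data.frame(gene_id = "g", chrom = "ChrSim", start = 1000L,
                      end = 2000L, strand = "+", stringsAsFactors = FALSE)
  gminus <- transform(gplus, strand = "-")
  s_up_plus <- toy_sites(950, 8, 2, stage = "S1")     # upstream of + gene
  s_up_minus <- toy_sites(2049, 8, 2, stage = "S1")   # upstream of - gene
  p1 <- metagene_profile(s_up_plus, gplus, design, n_body_bins = 10,
                         flank_bp = 100, flank_bin_bp = 50)
  p2 <- metagene_profile(s_up_minus, gminus, design, n_body_bins = 10,
                         flank_bp = 100, flank_bin_bp = 50)
  b1 <- p1[p1$stage == "S1" & !is.na(p1$level), "bin"]
  b2 <- p2[p2$stage == "S1" & !is.na(p2$level), "bin"]
  expect_identical(b1, b2)  # same 5' flank bin after reversal
  expect_true(all(b1 <= 2))
})

test_that("uniform methylation yields a flat metagene profile", {
  sim <- small_sim()
  genes <- sim$genes[1:20, ]
  s <- toy_sites(rep(seq(genes$start[1] - 1500, genes$end[20] + 1500, 40)),
                 10, 10, stage = "S1")
  prof <- metagene_profile(s, genes, stage_design(2, 1))
  lev <- prof$level[prof$stage == "S1" & !is.na(prof$level)]
  expect_true(all(abs(lev - 0.5) < 1e-12))
})

test_that("call_dmrs finds a planted window and respects its gates", {
  # 10 CHH sites, depth 30: level 0.1 (stage a) vs 0.6 (stage b)
  set.seed(33)
  pos <- 100 + seq(0, 90, 10)
  a <- toy_sites(pos, rbinom(10, 30, 0.1), 0, stage = "S1")
  a$unmeth <- 30L - a$meth
  b <- toy_sites(pos, rbinom(10, 30, 0.6), 0, stage = "S2")
  b$unmeth <- 30L - b$meth
  d <- call_dmrs(a, b)
  expect_identical(nrow(d), 1L)
  expect_equal(d$delta, 0.5, tolerance = 0.12)
  expect_identical(d$context, "CHH")
  expect_true(d$start <= 100 && d$end >= 190)
  # Fisher engine agrees with an independent hypergeometric oracle
  ma <- sum(a$meth); ua <- sum(a$unmeth)
  mb <- sum(b$meth); ub <- sum(b$unmeth)
  expect_equal(stageomics:::fisher_p(ma, ua, mb, ub),
               fisher_oracle(ma, ua, mb, ub), tolerance = 1e-9)

  # identical methylation -> no DMRs
  d0 <- call_dmrs(a, transform(a, stage = "S2"))
  expect_identical(nrow(d0), 0L)

  # windows under min_sites are skipped however large the difference
  a3 <- a[1:3, ]; b3 <- b[1:3, ]
  b3$meth <- 30L; b3$unmeth <- 0L
  d3 <- call_dmrs(a3, b3)
  expect_identical(nrow(d3), 0L)
  expect_gt(attr(d3, "n_windows_skipped"), 0)

  # delta gate: significant but small shifts are not reported
  a2 <- toy_sites(pos, 300, 700, stage = "S1")
  b2 <- toy_sites(pos, 360, 640, stage = "S2")
  d2 <- call_dmrs(a2, b2, delta_min = 0.1)
  expect_identical(nrow(d2), 0L)
  expect_error(call_dmrs(rbind(a, b), b), "exactly one stage")
})

test_that("adjacent significant windows merge into one DMR", {
  set.seed(12)
  pos <- 100 + seq(0, 290, 15)  # 20 sites over 300 bp -> several windows
  a <- toy_sites(pos, rbinom(20, 30, 0.1), 0, stage = "S1")
  a$unmeth <- 30L - a$meth
  b <- toy_sites(pos, rbinom(20, 30, 0.7), 0, stage = "S2")
  b$unmeth <- 30L - b$meth
  d <- call_dmrs(a, b)
  expect_identical(nrow(d), 1L)
  expect_gte(d$n_sites, 18L)
})

test_that("promoter-DMR overlap uses half-open intervals and context flags", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "ChrSim",
                      start = c(10000L, 30000L), end = c(12000L, 32000L),
                      strand = "+", stringsAsFactors = FALSE)
  dmrs <- data.frame(chrom = "ChrSim",
                     start = c(8100L, 10000L, 8200L),
                     end = c(8200L, 10100L, 8300L),
                     context = c("CHH", "CG", "CG"),
                     stringsAsFactors = FALSE)
  ov <- promoter_dmr_genes(dmrs, genes, 2000)
  g1 <- ov$by_gene[ov$by_gene$gene_id == "g1", ]
  # promoter of g1 = [8000,10000): DMR 2 starting at 10000 does NOT overlap
  expect_identical(g1$n_dmrs, 2L)
  expect_identical(g1$contexts, "CG,CHH")
  expect_false("g2" %in% ov$by_gene$gene_id)
  empty <- promoter_dmr_genes(dmrs[0, ], genes, 2000)
  expect_identical(nrow(empty$by_gene), 0L)
})

test_that("siRNA RPM uses the midpoint rule and the clean-read denominator", {
  design <- stage_design(2, 1)
  counts <- matrix(c(50, 100, 30, 60), 2, 2,
                   dimnames = list(c("c1", "c2"), design$sample_ids))
  clusters <- list(
    intervals = data.frame(cluster_id = c("c1", "c2"), chrom = "ChrSim",
                           # c1 midpoint 150 inside region; c2 straddles the
                           # boundary with midpoint 1090 inside region 2
                           start = c(100L, 990L), end = c(200L, 1190L)),
    counts = counts)
  regions <- data.frame(region_id = c("r1", "r2", "r3"), chrom = "ChrSim",
                        start = c(0L, 1000L, 5000L),
                        end = c(500L, 1500L, 6000L))
  rpm <- sirna_rpm_in_regions(clusters, regions,
                              setNames(c(1e6, 2e6), design$sample_ids))
  expect_equal(rpm["r1", ], c(S1_R1 = 50, S2_R1 = 15))
  expect_equal(unname(rpm["r2", 1]), 100)  # straddling cluster counted once
  expect_equal(unname(rpm["r3", ]), c(0, 0))
  expect_error(sirna_rpm_in_regions(clusters, regions, c(0, 1e6)),
               "positive")
})

test_that("global and promoter series pool replicates within stage", {
  s <- rbind(toy_sites(10, 2, 8, stage = "S1", rep = 1),
             toy_sites(10, 6, 4, stage = "S1", rep = 2),
             toy_sites(10, 9, 1, stage = "S2", rep = 1),
             toy_sites(10, 9, 1, stage = "S2", rep = 2))
  g <- global_methylation_series(s, stage_design(2, 2))
  expect_equal(unname(g), c(0.4, 0.9))
  prom <- data.frame(gene_id = "g1", chrom = "ChrSim", start = 0L,
                     end = 100L, strand = "+")
  pm <- promoter_methylation_series(s, prom, stage_design(2, 2))
  expect_equal(unname(pm["g1", ]), c(0.4, 0.9))
})
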