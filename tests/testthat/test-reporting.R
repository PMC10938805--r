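make_db <- function() {
  edges <- data.frame(
    source_id = c("g1", "g2", "g2"), gene_id = c("g1", "g2", "g2"),
    target_id = c("m1", "m1", "m2"), layer = "transcript-metabolite",
    r = c(0.9, -0.88, 0.95), p_value = 1e-6, q_value = 1e-5,
    sign = c("+", "-", "+"), stringsAsFactors = FALSE)
  structure(list(
    edges = edges, removed_pairs = data.frame(),
    metabolite_clusters = data.frame(feature_id = c("m1", "m2"),
                                     cluster_label = c("I", "V"),
                                     centroid_distance = 0),
    class_of = c(m1 = "Amino acid", m2 = "Flavone")),
    class = "gene_metabolite_database")
}

test_that("network export partitions by cluster and round-trips TSV", {
  db <- make_db()
  out <- withr::local_tempdir()
  files <- export_network(db, "cluster", "tsv", out)
  expect_identical(length(files), 8L)  # one file per cluster I..VIII
  expect_true(all(file.exists(files)))
  back <- read_network_tsv(files[["I"]])
  expect_identical(nrow(back), 2L)
  expect_setequal(back$source_id, c("g1", "g2"))
  # empty group -> valid empty edge list
  expect_identical(nrow(read_network_tsv(files[["VII"]])), 0L)
  # graphml written and parseable by igraph
  gfiles <- export_network(db, "cluster", "graphml", out)
  g <- igraph::read_graph(gfiles[["I"]], format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_error(export_network(db, "cluster", "pdf", out))
})

test_that("chromosome class counts count distinct genes once per class", {
  db <- make_db()
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("Chr1", "Chr2"),
                      start = 0L, end = 10L, strand = "+",
                      stringsAsFactors = FALSE)
  cc <- chromosome_class_counts(db, genes)
  expect_identical(cc["Amino acid", "Chr1"], 1L)
  expect_identical(cc["Amino acid", "Chr2"], 1L)
  expect_identical(cc["Flavone", "Chr2"], 1L)
  # unannotated gene lands in the Others chromosome bucket
  db$edges$gene_id[1] <- "gX"; db$edges$source_id[1] <- "gX"
  cc2 <- chromosome_class_counts(db, genes)
  expect_identical(cc2["Amino acid", "Others"], 1L)
})

test_that("run_pipeline produces a complete, reproducible output bundle", {
  cfg <- simulation_config(seed = 42, n_metabolites = 40, n_genes = 120,
                           n_proteins = 60, n_planted_edges = 16,
                           n_planted_dmrs = 12, n_background_sirna = 100)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  man1 <- run_pipeline(cfg, out1)
  man2 <- run_pipeline(cfg, out2)

  # manifest record counts equal actual file row counts
  for (f in names(man1$record_counts)) {
    n <- nrow(data.table::fread(file.path(out1, "results", f)))
    expect_identical(n, as.integer(man1$record_counts[[f]]), info = f)
  }
  # determinism: byte-identical outputs over the whole bundle
  files <- list.files(out1, recursive = TRUE)
  expect_identical(files, list.files(out2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(out1, files))
  h2 <- tools::md5sum(file.path(out2, files))
  expect_identical(unname(h1), unname(h2))

  # file mode reproduces the synthetic-mode analysis from written inputs
  crep <- data.frame(
    path = list.files(file.path(out1, "inputs", "methylation"),
                      full.names = TRUE), stringsAsFactors = FALSE)
  crep$stage <- sub("_R.*", "", basename(crep$path))
  crep$rep <- as.integer(sub(".*_R([0-9]+).*", "\\1", basename(crep$path)))
  file_cfg <- list(
    metabolome = file.path(out1, "inputs", "metabolome.tsv"),
    proteome = file.path(out1, "inputs", "proteome.tsv"),
    transcriptome = file.path(out1, "inputs", "transcriptome.tsv"),
    genes = file.path(out1, "inputs", "genes.bed"),
    sirna = file.path(out1, "inputs", "sirna_clusters.tsv"),
    cytosine_reports = crep,
    protein_to_gene = file.path(out1, "inputs", "protein_to_gene.tsv"),
    total_clean_reads = file.path(out1, "inputs", "total_clean_reads.tsv"),
    seed = 42)
  out3 <- withr::local_tempdir()
  man3 <- run_pipeline(file_cfg, out3)
  expect_identical(man3$n_dams, man1$n_dams)
  expect_identical(man3$n_dmrs, man1$n_dmrs)
  d1 <- data.table::fread(file.path(out1, "results", "database_edges.tsv"))
  d3 <- data.table::fread(file.path(out3, "results", "database_edges.tsv"))
  expect_equal(d1, d3, tolerance = 1e-9)

  # missing input file -> error naming the path
  file_cfg$genes <- file.path(out1, "inputs", "nope.bed")
  expect_error(run_pipeline(file_cfg, withr::local_tempdir()), "nope.bed")
})

test_that("pipeline config files read as key-value maps", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "n_metabolites: 50", "out_dir: results"), path)
  cfg <- read_pipeline_config(path)
  expect_identical(cfg$seed, 7L)
  expect_identical(cfg$n_metabolites, 50L)
})
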