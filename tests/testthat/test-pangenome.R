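test_that("MCL separates disconnected cliques and keeps single edges together", {
  e1 <- t(utils::combn(c("a1", "a2", "a3"), 2))
  e2 <- t(utils::combn(c("b1", "b2", "b3"), 2))
  edges <- data.frame(from = c(e1[, 1], e2[, 1]), to = c(e1[, 2], e2[, 2]),
                      weight = 1)
  m <- mcl_cluster(edges, inflation = 1.5)
  expect_equal(length(unique(m)), 2L)
  expect_length(unique(m[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(m[c("b1", "b2", "b3")]), 1L)
  m2 <- mcl_cluster(data.frame(from = "x", to = "y", weight = 1), inflation = 1.5)
  expect_equal(length(unique(m2)), 1L)
})

test_that("MCL matches the exhaustive modularity oracle on two-block graphs", {
  for (s in 1:15) {
    g <- two_block_graph(700 + s)
    m <- mcl_cluster(g$edges, inflation = 1.5)
    expect_true(same_partition(split(names(m), m), modularity_oracle(g$edges)),
                info = paste("seed", 700 + s))
  }
})

test_that("MCL never merges disconnected components", {
  set.seed(41)
  for (rep in 1:5) {
    g1 <- two_block_graph(800 + rep)$edges
    g2 <- two_block_graph(900 + rep)$edges
    g2$from <- paste0("z", g2$from); g2$to <- paste0("z", g2$to)
    m <- mcl_cluster(rbind(g1, g2), inflation = 1.5)
    cl_of <- split(names(m), m)
    for (cl in cl_of) {
      expect_true(all(startsWith(cl, "z")) || !any(startsWith(cl, "z")))
    }
  }
})

test_that("clustering output partitions the gene set and venn counts add up", {
  cfg <- small_config(seed = 51)
  sim <- simulate_strains(cfg)
  hits <- homology_search(sim$genes, "protein")
  cl <- cluster_genes(hits, sim$genes, mode = "evalue", inflation = 1.5)
  covered <- c(cl$clusters$gene_id, cl$singletons$gene_id)
  expect_setequal(covered, sim$genes$gene_id)
  expect_equal(length(covered), nrow(sim$genes))      # no double assignment
  summ <- venn_partition(cl)
  expect_equal(sum(summ$venn$n_clusters), summ$total_clusters)
  expect_true(all(table(cl$clusters$cluster_id) >= 2))
})

test_that("no-event panels give one single-copy pan cluster per ancestral gene", {
  cfg <- small_config(seed = 52, gain_rate = 0, loss_rate = 0, dup_rate = 0,
                      planted_block_size = 0)
  sim <- simulate_strains(cfg)
  hits <- homology_search(sim$genes, "protein")
  cl <- cluster_genes(hits, sim$genes)
  scp <- single_copy_pan(cl)
  expect_equal(length(unique(scp$cluster_id)), cfg$n_ancestor_genes)
})

test_that("single-copy pan excludes clusters with duplicated members", {
  cl <- structure(list(
    clusters = data.frame(
      cluster_id = c("c1", "c1", "c1", "c1", "c2", "c2", "c2", "c2", "c2"),
      gene_id = paste0("g", 1:9),
      genome_id = c("A", "B", "C", "D", "A", "A", "B", "C", "D")),
    singletons = data.frame(gene_id = character(0), genome_id = character(0)),
    genomes = c("A", "B", "C", "D")), class = "pangenome_clusters")
  scp <- single_copy_pan(cl)
  expect_equal(unique(scp$cluster_id), "c1")
})

test_that("single-copy pan recovery matches the event-log oracle", {
  cfg <- small_config(seed = 53)
  sim <- simulate_strains(cfg)
  hits <- homology_search(sim$genes, "protein")
  scp <- single_copy_pan(cluster_genes(hits, sim$genes))
  fam_of <- stats::setNames(sim$genes$family, sim$genes$gene_id)
  recovered <- unique(unname(fam_of[scp$gene_id]))
  ## oracle: ancestral families with exactly one copy in each genome
  tab <- table(sim$genes$family, sim$genes$genome_id)
  oracle <- rownames(tab)[apply(tab == 1, 1, all)]
  oracle <- setdiff(oracle, sim$truth$planted)  # planted are not pan
  expect_setequal(recovered, oracle)
})

test_that("clade-specific scan recovers exactly the ground-truth exclusive set", {
  cfg <- small_config(seed = 54)
  sim <- simulate_strains(cfg)
  hits <- homology_search(sim$genes, "protein")
  cs <- clade_specific_single_copy(hits, sim$genes,
                                   clade = c("A", "B"), others = c("C", "D"))
  fam_of <- stats::setNames(sim$genes$family, sim$genes$gene_id)
  rec <- unique(vapply(cs$families, function(f) unname(fam_of[f[1]]), ""))
  truth <- true_clade_exclusive(sim, c("A", "B"))
  expect_setequal(rec, truth)
  expect_error(clade_specific_single_copy(hits, sim$genes,
                                          clade = c("A", "B"), others = c("B")),
               "overlap")
})

test_that("an ortholog in the contrast set disqualifies a clade family", {
  ## empty contrast set keeps all clade single-copy families
  cfg <- small_config(seed = 55)
  sim <- simulate_strains(cfg)
  clade_genes <- sim$genes[sim$genes$genome_id %in% c("A", "B"), ]
  hits <- homology_search(clade_genes, "protein")
  cs_all <- clade_specific_single_copy(hits, clade_genes,
                                       clade = c("A", "B"), others = character(0))
  expect_gt(length(cs_all$families), cfg$planted_block_size)
  ## give one planted gene an ortholog in a third genome: family excluded
  planted_fam <- sim$truth$planted[1]
  pg <- clade_genes[clade_genes$family == planted_fam, ][1, ]
  intruder <- pg; intruder$gene_id <- "X_intruder"; intruder$genome_id <- "X"
  genes2 <- rbind(clade_genes, intruder)
  hits2 <- homology_search(genes2, "protein")
  cs2 <- clade_specific_single_copy(hits2, genes2,
                                    clade = c("A", "B"), others = "X")
  fam_of <- stats::setNames(genes2$family, genes2$gene_id)
  rec2 <- vapply(cs2$families, function(f) unname(fam_of[f[1]]), "")
  expect_false(planted_fam %in% rec2)
})
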