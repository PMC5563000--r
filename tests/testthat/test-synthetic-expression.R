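make_counts <- function(seed = 1, ...) {
  cfg <- small_config(seed = seed, ...)
  sim <- simulate_strains(cfg)
  genes <- sim$genes[sim$genes$genome_id == "A", ]
  list(cfg = cfg, genes = genes, cs = simulate_counts(cfg, genes))
}

test_that("zero dispersion and unit folds give Poisson-level replicate agreement", {
  cfg <- small_config(seed = 5, dispersion = 0,
                      library_sizes = c(control = 1e6, salt = 1e6, osmotic = 1e6),
                      spike_table = data.frame(gene_id = character(0),
                                               salt_fold = numeric(0),
                                               osmotic_fold = numeric(0)))
  sim <- simulate_strains(cfg)
  genes <- sim$genes[sim$genes$genome_id == "A", ]
  cs <- simulate_counts(cfg, genes)
  m <- cs$counts$counts
  ## same expected proportion across all six samples: replicate differences
  ## within Poisson range (6 sd of the difference of two Poissons)
  mu <- rowMeans(m)
  for (j in 2:ncol(m)) {
    expect_true(all(abs(m[, j] - m[, 1]) <= 6 * sqrt(2 * mu + 1)))
  }
  expect_equal(nrow(cs$truth), 0L)
})

test_that("library size scaling changes counts, not proportions", {
  ## Poisson noise so the expectation dominates
  r1 <- make_counts(seed = 7, dispersion = 0,
                    library_sizes = c(control = 1e5, salt = 1e5, osmotic = 1e5))
  r2 <- make_counts(seed = 7, dispersion = 0,
                    library_sizes = c(control = 2e5, salt = 2e5, osmotic = 2e5))
  m1 <- colSums(r1$cs$counts$counts); m2 <- colSums(r2$cs$counts$counts)
  expect_true(all(abs(m2 / m1 - 2) < 0.05))
  p1 <- colSums(normalize_counts(r1$cs$counts))
  p2 <- colSums(normalize_counts(r2$cs$counts))
  expect_true(all(abs(p1 - p2) < 0.01))
})

test_that("a spiked salt fold is recovered by the normalized mean ratio", {
  ## Monte-Carlo over seeds: mean recovered ratio close to the planted 4
  ratios <- vapply(1:30, function(s) {
    cfg <- small_config(seed = 100 + s)
    sim <- simulate_strains(cfg)
    genes <- sim$genes[sim$genes$genome_id == "A", ]
    cs <- simulate_counts(cfg, genes)
    g <- cs$truth$gene_id[cs$truth$salt_fold == 4][1]
    np <- normalize_counts(cs$counts)
    cond <- cs$counts$condition
    mean(np[g, cond == "salt"]) / mean(np[g, cond == "control"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.5)
})

test_that("reads are exact substrings without errors and errors average out", {
  cfg <- small_config(seed = 2, error_rate = 0, read_length = 50L)
  sim <- simulate_strains(cfg)
  genes <- sim$genes[sim$genes$genome_id == "A", ]
  reads <- simulate_reads(genes, cfg, n_reads = 300)
  meta <- strsplit(names(reads), "|", fixed = TRUE)
  cds <- stats::setNames(genes$cds_seq, genes$gene_id)
  for (i in seq_along(reads)) {
    src <- cds[[meta[[i]][2]]]
    st <- as.integer(meta[[i]][3])
    expect_identical(substr(src, st, st + 49L), unname(reads[i]))
  }
  ## 1% errors on 100-mers: about one mismatch per read
  cfg2 <- small_config(seed = 2, error_rate = 0.01, read_length = 100L)
  reads2 <- simulate_reads(genes, cfg2, n_reads = 2000)
  meta2 <- strsplit(names(reads2), "|", fixed = TRUE)
  mm <- vapply(seq_along(reads2), function(i) {
    src <- cds[[meta2[[i]][2]]]
    st <- as.integer(meta2[[i]][3])
    sum(strsplit(substr(src, st, st + 99L), "")[[1]] !=
          strsplit(reads2[[i]], "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(mm) - 1), 0.15)
})

test_that("noise-free Ct tables reproduce count ratios exactly through ddCt", {
  r <- make_counts(seed = 9)
  norm <- r$genes$gene_id[which.max(rowSums(r$cs$counts$counts))]
  g <- setdiff(r$cs$truth$gene_id[r$cs$truth$salt_fold == 4],
               norm)[1]
  ctab <- simulate_ct(r$cs$counts, normalizer = norm, genes = g,
                      ct_sd = 0, seed = 1)
  res <- ddct_fold(ctab, g, "salt", "control")
  np <- normalize_counts(r$cs$counts)
  cond <- r$cs$counts$condition
  dct <- function(cc) mean(log2(np[norm, cond == cc]) - log2(np[g, cond == cc]))
  expected <- 2^-(dct("salt") - dct("control"))
  expect_equal(unname(res$fold), unname(signed_fold(expected)), tolerance = 1e-10)
})

test_that("doubling expression lowers Ct by one cycle; normalizer spikes shift folds", {
  counts <- matrix(c(100, 100, 200, 200, 400, 400), nrow = 1,
                   dimnames = list("g1", paste0(rep(c("control", "salt", "osmotic"), each = 2),
                                                "_", 1:2)))
  counts <- rbind(counts, n0 = 1000)
  ct <- count_table(counts, lib_sizes = rep(1e5, 6),
                    condition = rep(c("control", "salt", "osmotic"), each = 2),
                    replicate = rep(1:2, 3))
  tab <- simulate_ct(ct, normalizer = "n0", genes = "g1", ct_sd = 0, seed = 1)
  m <- stats::aggregate(ct ~ condition + gene, tab, mean)
  g1 <- m[m$gene == "g1", ]
  expect_equal(g1$ct[g1$condition == "control"] - g1$ct[g1$condition == "salt"], 1)
  expect_equal(g1$ct[g1$condition == "control"] - g1$ct[g1$condition == "osmotic"], 2)
  ## spiking the normalizer 2x under salt shifts the reported fold 2x down
  counts2 <- counts; counts2["n0", 3:4] <- 2000
  ct2 <- count_table(counts2, rep(1e5, 6),
                     rep(c("control", "salt", "osmotic"), each = 2), rep(1:2, 3))
  tab2 <- simulate_ct(ct2, "n0", genes = "g1", ct_sd = 0, seed = 1)
  f1 <- ddct_fold(tab, "g1", "salt", "control")$fold
  f2 <- ddct_fold(tab2, "g1", "salt", "control")$fold
  expect_equal(f1, 2)
  expect_equal(f2, 1)
})

test_that("growth curves hold yield0 to MTC, hit zero at MIC, and are reproducible", {
  cfg <- small_config(seed = 11, concentrations = c(0, 250, 500, 750, 1000))
  cfg$growth_params <- data.frame(strain = c("A", "B", "C", "D"),
                                  mic_true = 1000, mtc_true = 250,
                                  yield0 = 100, replicate_sd = 5)
  g <- simulate_growth(cfg, noise_sd = 0)
  a <- g[g$strain == "A" & g$replicate == 1, ]
  expect_equal(a$yield[a$concentration <= 250], c(100, 100))
  expect_equal(a$yield[a$concentration == 1000], 0)
  mid <- a$yield[a$concentration %in% c(250, 500, 750, 1000)]
  expect_true(all(diff(mid) < 0))
  ## same config: identical means, noise differs across replicates
  g2 <- simulate_growth(cfg)
  expect_identical(g2, simulate_growth(cfg))
  expect_false(identical(g2$yield[g2$replicate == 1], g2$yield[g2$replicate == 2]))
  expect_error(simulate_growth(small_config(concentrations = c(-5, 0, 10))),
               "negative")
})
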