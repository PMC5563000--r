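test_that("mapper honors the placement contract", {
  cfg <- small_config(seed = 81, error_rate = 0)
  sim <- simulate_strains(cfg)
  genes <- sim$genes[sim$genes$genome_id == "A", ]
  reads <- simulate_reads(genes, cfg, n_reads = 500)
  pl <- map_reads(reads, genes, seed = 1)
  src <- vapply(strsplit(names(reads), "|", fixed = TRUE), `[`, "", 2)
  uq <- pl$status == "unique"
  ## error-free reads from unique loci map uniquely to their source
  expect_true(all(pl$gene_id[uq] == src[uq]))
  expect_true(all(pl$mismatches[uq] == 0))
  ## conservation: every read has exactly one status
  expect_equal(sum(table(pl$status)), length(reads))
  ## determinism under a fixed seed
  expect_identical(pl, map_reads(reads, genes, seed = 1))
})

test_that("mismatch and multi-hit rules match the policy", {
  cfg <- small_config(seed = 82, error_rate = 0)
  sim <- simulate_strains(cfg)
  genes <- sim$genes[sim$genes$genome_id == "A", ][1:20, ]
  reads <- simulate_reads(genes, cfg, n_reads = 60)
  ## plant exactly 3 mismatches: unmapped
  set.seed(5)
  r3 <- vapply(reads, function(x) {
    ch <- strsplit(x, "")[[1]]
    i <- sample(length(ch), 3)
    ch[i] <- vapply(ch[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }, "")
  names(r3) <- paste0("mm3_", seq_along(r3))
  expect_true(all(map_reads(r3, genes, seed = 1)$status == "unmapped"))
  ## 2 mismatches: still mapped
  r2 <- vapply(reads, function(x) {
    ch <- strsplit(x, "")[[1]]
    i <- sample(length(ch), 2)
    ch[i] <- vapply(ch[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }, "")
  names(r2) <- paste0("mm2_", seq_along(r2))
  pl2 <- map_reads(r2, genes, seed = 1)
  expect_true(all(pl2$status != "unmapped"))
  ## 12 identical copies: more than 10 places, unmapped; 5 copies: multi
  base_gene <- genes$cds_seq[1]
  rd <- stats::setNames(substr(base_gene, 11, 110), "probe")
  ref12 <- stats::setNames(rep(base_gene, 12), paste0("c", 1:12))
  expect_equal(map_reads(rd, ref12, seed = 1)$status, "unmapped")
  ref5 <- ref12[1:5]
  pl5 <- map_reads(rd, ref5, seed = 1)
  expect_equal(pl5$status, "multi")
  expect_equal(pl5$n_places, 5L)
  ## random assignment is counted only in with_random_assignment mode
  cnt_u <- count_reads(pl5, names(ref5), mapping_policy())
  cnt_r <- count_reads(pl5, names(ref5),
                       mapping_policy(count_mode = "with_random_assignment"))
  expect_equal(sum(cnt_u), 0L)
  expect_equal(sum(cnt_r), 1L)
})

test_that("normalization is count over library total", {
  ct <- count_table(matrix(c(100L, 50L), 1, 2,
                           dimnames = list("g", c("s1", "s2"))),
                    lib_sizes = c(1e5, 5e4),
                    condition = c("control", "salt"), replicate = c(1L, 1L))
  np <- normalize_counts(ct)
  expect_equal(unname(np[1, ]), c(1e-3, 1e-3))
})

test_that("baggerley test is exact on trivial cases and symmetric", {
  ## identical groups: statistic 0, p 1
  ca <- matrix(c(40L, 60L, 50L, 55L), 2, 2)
  bt <- baggerley_test(ca, c(1e4, 1e4), ca, c(1e4, 1e4))
  expect_equal(bt$statistic, c(0, 0))
  expect_equal(bt$p_value, c(1, 1))
  ## group swap: p unchanged, statistic and fold flip
  cb <- matrix(c(400L, 380L, 45L, 52L), 2, 2)
  b1 <- baggerley_test(ca, c(1e4, 1e4), cb, c(1e4, 1e4))
  b2 <- baggerley_test(cb, c(1e4, 1e4), ca, c(1e4, 1e4))
  expect_equal(b1$p_value, b2$p_value)
  expect_equal(b1$statistic, -b2$statistic)
  expect_equal(sign(b1$fold), -sign(b2$fold))
  expect_error(baggerley_test(ca, c(0, 0), ca, c(1, 1)), "all-zero")
})

test_that("baggerley ranks agree with an independent two-proportion oracle", {
  set.seed(83)
  ng <- 100
  base <- stats::rgamma(ng, 2) / 50
  base <- base / sum(base) * 0.5
  tots <- rep(1e5, 2)
  fold <- sample(c(1, 1, 1, 4, 0.25), ng, TRUE)
  ca <- sapply(tots, function(t) stats::rpois(ng, t * base * fold))
  cb <- sapply(tots, function(t) stats::rpois(ng, t * base))
  bt <- baggerley_test(ca, tots, cb, tots)
  ## oracle: pooled two-proportion z-test on summed counts
  pa <- rowSums(ca) / sum(tots); pb <- rowSums(cb) / sum(tots)
  pp <- (rowSums(ca) + rowSums(cb)) / (2 * sum(tots))
  z <- (pa - pb) / sqrt(pp * (1 - pp) * (2 / sum(tots)))
  keep <- is.finite(z) & rowSums(ca + cb) > 0
  expect_true(all(sign(bt$statistic[keep]) == sign(z[keep]) |
                    bt$statistic[keep] == 0 | z[keep] == 0))
  expect_gt(stats::cor(abs(bt$statistic[keep]), abs(z[keep]),
                       method = "spearman"), 0.9)
})

test_that("rejection probability grows with the spiked fold", {
  set.seed(84)
  ng <- 200; tots <- rep(1e5, 2); disp <- 0.05
  base <- rep(2e-4, ng)
  rates <- vapply(c(1.5, 3, 6), function(f) {
    ca <- sapply(tots, function(t) stats::rnbinom(ng, mu = t * base * f, size = 1 / disp))
    cb <- sapply(tots, function(t) stats::rnbinom(ng, mu = t * base, size = 1 / disp))
    mean(baggerley_test(ca, tots, cb, tots)$p_value <= 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("de calling recovers spiked genes and builds consistent venns", {
  cfg <- small_config(seed = 85, n_ancestor_genes = 120,
                      library_sizes = c(control = 2e6, salt = 2e6, osmotic = 2e6))
  sim <- simulate_strains(cfg)
  genes <- sim$genes[sim$genes$genome_id == "A", ]
  cs <- simulate_counts(cfg, genes)
  de <- de_analysis(cs$counts)
  calls <- call_de(de)
  truth <- cs$truth
  t_salt_up <- truth$gene_id[truth$salt_fold > 1]
  rec <- mean(t_salt_up %in% calls$up$salt)
  expect_gt(rec, 0.8)
  ## venn cells partition each direction's union
  v <- calls$venn
  for (dir in c("up", "down")) {
    cells <- v$n[v$direction == dir]
    expect_equal(sum(cells),
                 length(union(calls[[dir]]$salt, calls[[dir]]$osmotic)))
  }
  ## empty results give empty sets
  de0 <- de[0, ]
  c0 <- call_de(de0)
  expect_equal(sum(c0$venn$n), 0L)
})

test_that("cog summary percentages sum to 100 and dual labels count once", {
  ann <- data.frame(gene_id = paste0("g", 1:10),
                    cog_category = c("C", "C", "EC", NA, "K", "K", "M", NA, "R", "T"))
  calls <- structure(list(up = list(salt = paste0("g", 1:6),
                                    osmotic = paste0("g", 4:8)),
                          down = list(salt = character(0), osmotic = character(0)),
                          contrasts = c("salt", "osmotic")),
                     class = "de_calls")
  cs <- cog_summary(calls, ann)
  up <- cs[cs$direction == "up", ]
  expect_equal(sum(up$percent), 100)
  expect_true("EC" %in% up$category)
  expect_true("unassigned" %in% up$category)
  expect_equal(sum(up$n), 8)
})
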