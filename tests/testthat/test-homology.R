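test_that("local alignment agrees with an independent DP oracle", {
  sch <- scoring_scheme("protein")
  ## classic toy pair plus random short pairs
  toy <- align_local("HEAGAWGHEE", "PAWHEAE", sch)
  expect_equal(toy$raw_score,
               sw_oracle_score("HEAGAWGHEE", "PAWHEAE", sch$matrix,
                               sch$gap_open, sch$gap_extend))
  set.seed(21)
  aa <- rownames(sch$matrix)[1:20]
  for (i in 1:25) {
    a <- paste(sample(aa, sample(8:25, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(8:25, 1), TRUE), collapse = "")
    expect_equal(align_local(a, b, sch)$raw_score,
                 sw_oracle_score(a, b, sch$matrix, sch$gap_open, sch$gap_extend))
  }
})

test_that("self-alignment is perfect and score is symmetric", {
  sch <- scoring_scheme("protein")
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  h <- align_local(s, s, sch)
  expect_equal(h$identity_fraction, 1)
  expect_equal(h$query_cov, 1)
  expect_equal(h$subject_cov, 1)
  set.seed(22)
  aa <- rownames(sch$matrix)[1:20]
  for (i in 1:10) {
    a <- paste(sample(aa, 30, TRUE), collapse = "")
    b <- paste(sample(aa, 30, TRUE), collapse = "")
    expect_equal(align_local(a, b, sch)$raw_score,
                 align_local(b, a, sch)$raw_score)
  }
})

test_that("bit scores and E-values follow the Karlin-Altschul formulas", {
  sch <- scoring_scheme("protein", lambda = 0.267, K = 0.041)
  be <- bit_and_evalue(100, sch, search_space = 1e6)
  expect_equal(be$bit_score, (0.267 * 100 - log(0.041)) / log(2), tolerance = 1e-12)
  expect_equal(round(be$bit_score, 1), 43.1)
  ## linear in search space
  be2 <- bit_and_evalue(100, sch, search_space = 2e6)
  expect_equal(be2$e_value, 2 * be$e_value)
  ## raw 0 is the finite floor
  be0 <- bit_and_evalue(0, sch, search_space = 1e6)
  expect_equal(be0$bit_score, -log(0.041) / log(2))
  ## monotonic: bits increase with raw, e-values decrease
  raws <- seq(0, 500, by = 25)
  bes <- bit_and_evalue(raws, sch, search_space = 1e6)
  expect_true(all(diff(bes$bit_score) > 0))
  expect_true(all(diff(bes$e_value) < 0))
})

test_that("bsr is 1 on self, symmetric, and low for unrelated proteins", {
  cfg <- small_config(seed = 31)
  sim <- simulate_strains(cfg)
  hits <- homology_search(sim$genes, "protein")
  g <- sim$genes$gene_id
  expect_equal(bsr(hits, g[1], g[1]), 1)
  cross <- hits[hits$query_id != hits$subject_id, ][1:20, ]
  for (r in seq_len(nrow(cross))) {
    expect_equal(bsr(hits, cross$query_id[r], cross$subject_id[r]),
                 bsr(hits, cross$subject_id[r], cross$query_id[r]))
  }
  ## unrelated random proteins: bsr below the homology cutoff
  set.seed(32)
  sch <- scoring_scheme("protein")
  aa <- rownames(sch$matrix)[1:20]
  rnd <- stats::setNames(replicate(30, paste(sample(aa, 120, TRUE), collapse = "")),
                         paste0("r", 1:30))
  rhits <- homology_search(rnd, "protein", prefilter = FALSE)
  rb <- rhits$bsr[rhits$query_id != rhits$subject_id]
  expect_lt(stats::quantile(rb, 0.99), 0.3)
})

test_that("homology edges honor the inclusive 0.30 bsr rule and planted cliques", {
  hits <- data.frame(query_id = c("a", "b", "c", "a", "a", "b"),
                     subject_id = c("a", "b", "c", "b", "c", "c"),
                     raw_score = 1, bit_score = c(100, 100, 100, 30, 29.9, 30.1),
                     e_value = c(0, 0, 0, 1e-10, 1e-3, 1e-12),
                     identity_fraction = 1, hsp_length = 10,
                     query_cov = 1, subject_cov = 1,
                     bsr = c(1, 1, 1, 0.30, 0.299, 0.301))
  e <- homology_edges(hits, mode = "bsr")
  expect_setequal(paste(e$from, e$to), c("a b", "b c"))  # 0.30 kept, 0.299 dropped
  ## a planted family across 4 strains forms the full 6-edge clique
  cfg <- small_config(seed = 33)
  sim <- simulate_strains(cfg)
  phits <- homology_search(sim$genes, "protein")
  pedges <- homology_edges(phits, mode = "bsr")
  fam <- sim$truth$families$family[sim$truth$families$origin == "ancestor"][1]
  members <- sim$genes$gene_id[sim$genes$family == fam]
  if (length(members) == 4) {
    within <- pedges$from %in% members & pedges$to %in% members
    expect_equal(sum(within), 6L)
  }
  ## gained genes private to one strain (true singletons) have no edges;
  ## gains on internal branches are inherited by several tips and may
  ## legitimately form small families
  gain_fams <- table(sim$genes$family[startsWith(sim$genes$family, "gain")])
  singles <- sim$genes$gene_id[sim$genes$family %in%
                                 names(gain_fams)[gain_fams == 1]]
  expect_false(any(pedges$from %in% singles | pedges$to %in% singles))
})

test_that("within-family identity exceeds between-family identity", {
  ## among homology-grade hits (at least half the query aligned), family
  ## members are always more similar than non-members
  seps <- vapply(1:5, function(s) {
    sim <- simulate_strains(small_config(seed = 500 + s))
    hits <- homology_search(sim$genes, "protein")
    fam <- stats::setNames(sim$genes$family, sim$genes$gene_id)
    cross <- hits[hits$query_id != hits$subject_id &
                    hits$query_cov >= 0.5, ]
    same <- fam[cross$query_id] == fam[cross$subject_id]
    if (!any(same) || all(same)) return(1)
    min(cross$identity_fraction[same]) > max(cross$identity_fraction[!same])
  }, numeric(1))
  expect_true(all(seps == 1))
})
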