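## Independent oracles and small fixtures used across the suite.

## compact 4-strain config for fast unit tests
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_ancestor_genes = 60,
               gene_length_range = c(60L, 120L),
               strain_tree = "((A:0.02,B:0.02):0.03,(C:0.03,D:0.02):0.02);",
               planted_clade = c("A", "B"), planted_block_size = 5)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

## brute-force affine-gap Smith-Waterman score (slow reference DP,
## independent of the package's C++ kernel)
sw_oracle_score <- function(a, b, mat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  open1 <- gap_open + gap_extend
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - open1, E[i, j - 1] - gap_extend)
    F[i, j] <- max(H[i - 1, j] - open1, F[i - 1, j] - gap_extend)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]], E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

## exhaustive small-parsimony: minimum changes over all internal labelings
fitch_oracle <- function(tree, col, states = c("A", "C", "G", "T")) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  n <- length(tree$tip.label)
  internal <- (n + 1):max(tree$edge)
  grid <- expand.grid(rep(list(states), length(internal)),
                      stringsAsFactors = FALSE)
  best <- Inf
  tipstate <- col[tree$tip.label]
  for (r in seq_len(nrow(grid))) {
    lab <- c(tipstate, stats::setNames(unlist(grid[r, ]), internal))
    names(lab)[1:n] <- as.character(1:n)
    ch <- sum(lab[as.character(tree$edge[, 1])] != lab[as.character(tree$edge[, 2])])
    best <- min(best, ch)
  }
  best
}

## random two-block graph: two cliques joined by one weak bridge
two_block_graph <- function(seed) {
  set.seed(seed)
  n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
  v1 <- paste0("a", seq_len(n1)); v2 <- paste0("b", seq_len(n2))
  e1 <- t(utils::combn(v1, 2)); e2 <- t(utils::combn(v2, 2))
  edges <- data.frame(from = c(e1[, 1], e2[, 1], sample(v1, 1)),
                      to = c(e1[, 2], e2[, 2], sample(v2, 1)),
                      stringsAsFactors = FALSE)
  edges$weight <- c(stats::runif(nrow(e1) + nrow(e2), 0.8, 1.2),
                    stats::runif(1, 0.05, 0.2))
  list(edges = edges, blocks = list(v1, v2))
}

## exhaustive best 2-partition by weighted modularity
modularity_oracle <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  best_q <- -Inf; best_side <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {
    side <- as.integer(intToBits(mask))[1:n] + 1L
    q <- igraph::modularity(g, side, weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best_side <- side }
  }
  split(nodes, best_side)
}

## partition equality as sets of sets
same_partition <- function(p1, p2) {
  s1 <- sort(unname(vapply(p1, function(x) paste(sort(x), collapse = ","), "")))
  s2 <- sort(unname(vapply(p2, function(x) paste(sort(x), collapse = ","), "")))
  identical(s1, s2)
}

## expected pairwise sequence identity after total JC divergence t
jc_expected_identity <- function(t) 0.25 + 0.75 * exp(-4 * t / 3)
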