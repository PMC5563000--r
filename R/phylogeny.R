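## Concatenated maximum-parsimony phylogeny from single-copy pan-ortholog
## families: center-star per-family alignment, a vectorized Fitch small-
## parsimony engine, exhaustive/heuristic topology search, and per-branch
## support from gene-tree bipartition concordance.

#' Build a concatenated character matrix from single-copy families
#'
#' Each family (exactly one sequence per taxon) is aligned and the aligned
#' blocks are concatenated in family-id order. Families whose sequences
#' share one length are stacked directly; unequal lengths go through a
#' center-star multiple alignment (the center is the sequence minimizing
#' the summed pairwise alignment distance; others are aligned to it by
#' global alignment and merged by the usual once-a-gap-always-a-gap rule).
#'
#' @param families Named list; each element a named character vector of
#'   sequences (names = taxon names, identical across families).
#' @param type `"protein"` or `"dna"`.
#' @return A list of class `char_matrix`: `taxa`, `mat` (character matrix,
#'   taxa x columns), `blocks` (`data.frame` `family`, `start`, `end`).
#' @export
build_matrix <- function(families, type = c("protein", "dna")) {
  type <- match.arg(type)
  stopifnot(length(families) >= 1)
  families <- families[order(names(families))]
  taxa <- sort(names(families[[1]]))
  for (f in names(families)) {
    if (!setequal(names(families[[f]]), taxa)) {
      stop("family ", f, " is missing a taxon")
    }
  }
  blocks <- list(); mats <- list(); pos <- 0L
  for (f in names(families)) {
    seqs <- families[[f]][taxa]
    aligned <- if (length(unique(nchar(seqs))) == 1L) seqs else
      center_star_align(seqs, type)
    w <- unique(nchar(aligned))
    stopifnot(length(w) == 1L)
    mats[[f]] <- do.call(rbind, strsplit(aligned, ""))
    blocks[[f]] <- data.frame(family = f, start = pos + 1L, end = pos + w,
                              stringsAsFactors = FALSE)
    pos <- pos + w
  }
  mat <- do.call(cbind, mats)
  rownames(mat) <- taxa
  structure(list(taxa = taxa, mat = mat, blocks = do.call(rbind, blocks)),
            class = "char_matrix")
}

#' Center-star multiple alignment
#'
#' Classic 2-approximation: pick the center sequence minimizing the summed
#' pairwise global-alignment cost, align every other sequence to it, and
#' merge the pairwise alignments, propagating center gaps to all rows.
#'
#' @param seqs Named character vector of sequences.
#' @param type `"protein"` or `"dna"`.
#' @return Named character vector of gap-padded aligned sequences.
#' @export
center_star_align <- function(seqs, type = c("protein", "dna")) {
  type <- match.arg(type)
  n <- length(seqs)
  if (n == 1L) return(seqs)
  xs <- if (type == "protein") Biostrings::AAStringSet else Biostrings::DNAStringSet
  sub <- if (type == "protein") .blosum62() else
    Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = TRUE)
  pairs <- utils::combn(n, 2)
  sc <- matrix(0, n, n)
  aln_score <- Biostrings::pairwiseAlignment(
    xs(unname(seqs[pairs[1, ]])), xs(unname(seqs[pairs[2, ]])),
    type = "global", substitutionMatrix = sub,
    gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
  for (k in seq_len(ncol(pairs))) {
    sc[pairs[1, k], pairs[2, k]] <- sc[pairs[2, k], pairs[1, k]] <- aln_score[k]
  }
  center <- which.max(rowSums(sc))
  others <- setdiff(seq_len(n), center)
  aln <- Biostrings::pairwiseAlignment(
    xs(unname(seqs[others])), xs(unname(seqs[center]))[rep(1, length(others))],
    type = "global", substitutionMatrix = sub,
    gapOpening = 10, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")
  cen <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")
  ## merged center coordinates: for each pairwise alignment, map columns to
  ## (center position, insert rank); build the union gap structure
  keys <- lapply(cen, function(cc) {
    cpos <- cumsum(cc != "-")
    ins <- stats::ave(seq_along(cc), cpos, FUN = function(ix) {
      g <- cc[ix] == "-"
      cumsum(g)
    })
    ins[cc != "-"] <- 0L
    paste0(cpos, ".", ins)
  })
  ## max inserts after each center position across alignments
  cen_len <- nchar(seqs[center])
  max_ins <- integer(cen_len + 1L)
  for (kk in seq_along(keys)) {
    cc <- cen[[kk]]
    cpos <- cumsum(cc != "-")
    runs <- rle(paste0(cpos, "_", cc == "-"))
    gaps <- cc == "-"
    if (any(gaps)) {
      tab <- tapply(gaps, cpos, sum)
      for (p in as.integer(names(tab))) {
        max_ins[p + 1L] <- max(max_ins[p + 1L], tab[as.character(p)])
      }
    }
  }
  ## global column layout: for center pos p (0..len), max_ins[p+1] insert
  ## columns after it (p=0 -> leading inserts), then the residue column
  total_cols <- cen_len + sum(max_ins)
  col_of <- function(cpos, ins) {
    ## column index for key (cpos, ins); ins = 0 means the residue column
    base <- cpos + sum(max_ins[seq_len(cpos + 1L)]) - max_ins[cpos + 1L]
    if (ins == 0L) base else base + ins
  }
  out <- matrix("-", n, total_cols)
  ## center row
  ccols <- vapply(seq_len(cen_len), function(p) col_of(p, 0L), 0)
  out[center, ccols] <- strsplit(seqs[center], "")[[1]]
  for (kk in seq_along(others)) {
    cc <- cen[[kk]]; pp <- pat[[kk]]
    cpos <- cumsum(cc != "-")
    ins <- integer(length(cc))
    run <- 0L; last <- -1L
    for (z in seq_along(cc)) {
      if (cc[z] == "-") { run <- run + 1L; ins[z] <- run } else { run <- 0L; ins[z] <- 0L }
    }
    cols <- vapply(seq_along(cc), function(z) col_of(cpos[z], ins[z]), 0)
    out[others[kk], cols] <- pp
  }
  res <- apply(out, 1, paste, collapse = "")
  names(res) <- names(seqs)
  res
}

## ---- Fitch engine ----------------------------------------------------

## Encode a character matrix column-wise into integer bitmasks per state;
## gaps and unknowns get the full state set (missing data).
.encode_states <- function(mat) {
  states <- sort(setdiff(unique(as.vector(mat)), c("-", "?", "X", "N")))
  if (length(states) > 30L) stop("alphabet too large for bitmask encoding")
  full <- bitwShiftL(1L, length(states)) - 1L
  code <- stats::setNames(bitwShiftL(1L, seq_along(states) - 1L), states)
  enc <- matrix(full, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  known <- mat %in% names(code)
  enc[known] <- code[mat[known]]
  enc
}

## Collapse identical site patterns; returns list(enc = taxa x npattern,
## weight = counts).
.compress_patterns <- function(enc) {
  key <- apply(enc, 2, paste, collapse = ",")
  u <- !duplicated(key)
  w <- as.vector(table(key)[key[u]])
  list(enc = enc[, u, drop = FALSE], weight = w)
}

#' Fitch parsimony score of a tree
#'
#' Bottom-up Fitch count of the minimum number of state changes implied by
#' the tree, summed over columns. Tip gaps/unknowns carry the full state
#' set (missing data), so they never force a change. The score is
#' invariant under re-rooting, so unrooted trees are scored via an
#' arbitrary rooting.
#'
#' @param tree An `ape` `phylo` over the matrix's taxa (binary; the basal
#'   trifurcation of unrooted trees is handled).
#' @param cm A [build_matrix()] result (or a plain character matrix with
#'   taxa as rownames).
#' @return Integer: total state changes.
#' @export
fitch_score <- function(tree, cm) {
  mat <- if (inherits(cm, "char_matrix")) cm$mat else cm
  if (!setequal(tree$tip.label, rownames(mat))) stop("taxon mismatch")
  enc <- .compress_patterns(.encode_states(mat))
  .fitch_on_encoded(tree, enc$enc, enc$weight)
}

.fitch_on_encoded <- function(tree, enc, weight) {
  tree <- ape::reorder.phylo(tree, "postorder")
  np <- ncol(enc)
  nnode <- max(tree$edge)
  sets <- matrix(0L, nnode, np)
  sets[seq_along(tree$tip.label), ] <- enc[tree$tip.label, , drop = FALSE]
  changes <- numeric(np)
  done <- logical(nnode)
  done[seq_along(tree$tip.label)] <- TRUE
  ## postorder edges: combine children into parents pairwise
  parents <- unique(tree$edge[, 1])
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    if (!done[par]) {
      sets[par, ] <- sets[chl, ]
      done[par] <- TRUE
    } else {
      inter <- bitwAnd(sets[par, ], sets[chl, ])
      zero <- inter == 0L
      changes[zero] <- changes[zero] + 1
      inter[zero] <- bitwOr(sets[par, zero], sets[chl, zero])
      sets[par, ] <- inter
    }
  }
  as.integer(sum(changes * weight))
}

## canonical newick string of an unrooted topology (sorted clades) used
## for deterministic tie-breaks
.canonical_newick <- function(tree) {
  tree <- ape::unroot(tree)
  lab <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) return(tree$tip.label[node])
    parts <- sort(vapply(kids, lab, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  paste0(lab(root), ";")
}

#' Maximum-parsimony tree search
#'
#' Exhaustive enumeration of unrooted topologies for up to
#' `exhaustive_max` taxa (the optimum is certain); above that, stepwise
#' addition followed by nearest-neighbor-interchange hill climbing with
#' `n_restarts` seeded random addition orders. Score ties are broken by
#' the lexicographically smallest canonical newick, so the result is
#' deterministic.
#'
#' @param cm A [build_matrix()] result or character matrix.
#' @param exhaustive_max Largest taxon count searched exhaustively.
#' @param n_restarts Random addition orders for the heuristic phase.
#' @param seed Seed for the restart orders.
#' @return A list of class `mp_tree`: `tree` (unrooted `phylo`), `score`,
#'   `method`.
#' @export
search_tree <- function(cm, exhaustive_max = 8L, n_restarts = 5L, seed = 1L) {
  mat <- if (inherits(cm, "char_matrix")) cm$mat else cm
  taxa <- rownames(mat)
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  enc <- .compress_patterns(.encode_states(mat))
  score_fn <- function(tr) .fitch_on_encoded(tr, enc$enc, enc$weight)
  if (n <= exhaustive_max) {
    cand <- .all_topologies(taxa)
    scores <- vapply(cand, score_fn, 0L)
    best <- which(scores == min(scores))
    if (length(best) > 1L) {
      nks <- vapply(cand[best], .canonical_newick, "")
      best <- best[order(nks)][1L]
    }
    out <- list(tree = cand[[best]], score = min(scores), method = "exhaustive")
  } else {
    set.seed(seed)
    best_tree <- NULL; best_score <- Inf
    for (r in seq_len(n_restarts)) {
      ord <- sample(taxa)
      tr <- .stepwise_addition(ord, score_fn)
      tr <- .nni_climb(tr, score_fn)
      sc <- score_fn(tr)
      if (sc < best_score ||
          (sc == best_score && .canonical_newick(tr) < .canonical_newick(best_tree))) {
        best_tree <- tr; best_score <- sc
      }
    }
    out <- list(tree = best_tree, score = best_score, method = "stepwise+NNI")
  }
  out$tree$edge.length <- NULL
  class(out) <- "mp_tree"
  out
}

#' @export
print.mp_tree <- function(x, ...) {
  cat("mp_tree (", x$method, "): parsimony score", x$score, "\n")
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

## all unrooted binary topologies over the taxa (recursive edge insertion)
.all_topologies <- function(taxa) {
  n <- length(taxa)
  base <- ape::read.tree(text = paste0("(", taxa[1], ",", taxa[2], ",", taxa[3], ");"))
  base$edge.length <- rep(1, nrow(base$edge))
  trees <- list(base)
  for (k in seq(4L, n)) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        nxt[[length(nxt) + 1L]] <- ape::bind.tree(
          tr, ape::read.tree(text = paste0("(", taxa[k], ":1);")),
          where = tr$edge[e, 2], position = 0.5)
      }
    }
    trees <- lapply(nxt, function(t) { t$edge.length <- rep(1, nrow(t$edge)); t })
  }
  lapply(trees, function(t) { t$edge.length <- NULL; t })
}

.stepwise_addition <- function(ord, score_fn) {
  tr <- ape::read.tree(text = paste0("(", ord[1], ",", ord[2], ",", ord[3], ");"))
  tr$edge.length <- rep(1, nrow(tr$edge))
  if (length(ord) < 4L) return(tr)
  for (k in seq(4L, length(ord))) {
    cand <- lapply(seq_len(nrow(tr$edge)), function(e)
      ape::bind.tree(tr, ape::read.tree(text = paste0("(", ord[k], ":1);")),
                     where = tr$edge[e, 2], position = 0.5))
    cand <- lapply(cand, function(t) { t$edge.length <- rep(1, nrow(t$edge)); t })
    sc <- vapply(cand, score_fn, 0L)
    tr <- cand[[which.min(sc)]]
  }
  tr
}

.nni_climb <- function(tr, score_fn, max_rounds = 50L) {
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    return(tr)  # heuristic refinement unavailable; stepwise tree returned
  }
  cur <- tr; cur_score <- score_fn(cur)
  for (round in seq_len(max_rounds)) {
    nb <- phangorn::nni(cur)
    sc <- vapply(nb, function(t) {
      t$edge.length <- NULL
      score_fn(t)
    }, 0L)
    if (min(sc) >= cur_score) break
    cur <- nb[[which.min(sc)]]
    cur$edge.length <- rep(1, nrow(cur$edge))
    cur_score <- min(sc)
  }
  cur
}

## ---- branch support --------------------------------------------------

## nontrivial bipartitions of an unrooted tree as canonical strings
.bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  all_t <- sort(tree$tip.label)
  intern <- setdiff(unique(tree$edge[, 1]), seq_len(n))
  out <- character(0)
  for (node in setdiff(intern, setdiff(tree$edge[, 1], tree$edge[, 2]))) {
    tips <- sort(tree$tip.label[.descendant_tips(tree, node)])
    if (length(tips) >= 2L && length(tips) <= n - 2L) {
      other <- setdiff(all_t, tips)
      side <- if (length(tips) < length(other) ||
                  (length(tips) == length(other) && tips[1] < other[1])) tips else other
      out <- c(out, paste(side, collapse = "|"))
    }
  }
  unique(out)
}

.descendant_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    acc <- c(acc, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  acc
}

#' Gene-tree concordance support for a species tree
#'
#' For every internal branch of the species tree, the percentage of gene
#' trees whose bipartition set contains that branch's bipartition. This is
#' the package's reading of per-branch "percent confidence": agreement
#' among the single-gene maximum-parsimony trees summarized on the
#' concatenated topology.
#'
#' @param species_tree `phylo` or [search_tree()] result.
#' @param gene_trees List of `phylo` (or `mp_tree`) over the same taxa.
#' @return A list of class `branch_support`: `tree` (species tree with
#'   support as node labels), `support` (`data.frame` `bipartition`,
#'   `percent`).
#' @export
branch_support <- function(species_tree, gene_trees) {
  sp <- if (inherits(species_tree, "mp_tree")) species_tree$tree else species_tree
  gts <- lapply(gene_trees, function(g) if (inherits(g, "mp_tree")) g$tree else g)
  if (!length(gts)) stop("need at least one gene tree")
  for (g in gts) {
    if (!setequal(g$tip.label, sp$tip.label)) stop("gene tree over different taxa")
  }
  sp_bi <- .bipartitions(sp)
  gt_bi <- lapply(gts, .bipartitions)
  pct <- vapply(sp_bi, function(b)
    100 * mean(vapply(gt_bi, function(s) b %in% s, logical(1))), 0)
  support <- data.frame(bipartition = sp_bi, percent = unname(pct),
                        stringsAsFactors = FALSE)
  ## annotate node labels on a copy of the tree
  sp2 <- ape::unroot(sp)
  n <- length(sp2$tip.label)
  lab <- rep("", sp2$Nnode)
  for (node in unique(sp2$edge[, 1])) {
    if (node <= n) next
    tips <- sort(sp2$tip.label[.descendant_tips(sp2, node)])
    all_t <- sort(sp2$tip.label)
    if (length(tips) >= 2L && length(tips) <= n - 2L) {
      other <- setdiff(all_t, tips)
      side <- if (length(tips) < length(other) ||
                  (length(tips) == length(other) && tips[1] < other[1])) tips else other
      key <- paste(side, collapse = "|")
      hit <- match(key, support$bipartition)
      if (!is.na(hit)) lab[node - n] <- sprintf("%.0f", support$percent[hit])
    }
  }
  sp2$node.label <- lab
  structure(list(tree = sp2, support = support), class = "branch_support")
}

#' @export
print.branch_support <- function(x, ...) {
  cat("branch_support:\n")
  print(x$support)
  invisible(x)
}

#' Single-copy families as per-taxon sequence lists
#'
#' Reshapes a [single_copy_pan()] table plus the gene records into the
#' per-family named sequence vectors [build_matrix()] consumes.
#'
#' @param scp [single_copy_pan()] output.
#' @param genes Gene records.
#' @param type `"protein"` or `"dna"` sequences.
#' @return Named list of named character vectors.
#' @export
family_sequences <- function(scp, genes, type = c("protein", "dna")) {
  type <- match.arg(type)
  col <- if (type == "protein") "protein_seq" else "cds_seq"
  seq_of <- stats::setNames(genes[[col]], genes$gene_id)
  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)
  lapply(split(scp$gene_id, scp$cluster_id), function(gid)
    stats::setNames(seq_of[gid], genome_of[gid]))
}
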