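## Ortholog clustering by Markov clustering of the homology graph, Venn
## partitioning of clusters by genome membership, singleton detection, and
## clade-specific single-copy gene discovery.

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Standard MCL: self-loops are added (weight equal to the node's maximum
#' incident weight), columns are normalized to stochastic, and expansion
#' (matrix squaring) alternates with inflation (elementwise power `r`,
#' renormalize) until the maximum entrywise change drops below `tol` or
#' `max_iter` is reached (non-convergence is an error; no partial result is
#' returned). Nodes are then assigned to attractor-based clusters; the
#' result is a partition. Disconnected components are clustered
#' independently (expansion never crosses components), which also keeps the
#' matrices small.
#'
#' @param edges `data.frame` with `from`, `to`, `weight` (nonnegative).
#' @param inflation Inflation exponent, > 1. The study value is 1.5.
#' @param nodes Optional full node set (isolated nodes become singleton
#'   groups of size one, reported separately by the pangenome wrappers).
#' @param tol,max_iter Convergence controls.
#' @param prune Entries below this are zeroed each iteration to preserve
#'   sparsity.
#' @return Named integer vector: cluster id per node.
#' @export
mcl_cluster <- function(edges, inflation = 1.5, nodes = NULL,
                        tol = 1e-8, max_iter = 200L, prune = 1e-12) {
  stopifnot(inflation > 1, all(edges$weight >= 0))
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to", "weight")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  membership <- integer(length(nodes))
  names(membership) <- nodes
  next_id <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    if (length(vs) == 1L) {
      next_id <- next_id + 1L
      membership[vs] <- next_id
      next
    }
    sub <- edges[edges$from %in% vs & edges$to %in% vs, , drop = FALSE]
    part <- .mcl_component(vs, sub, inflation, tol, max_iter, prune)
    membership[vs] <- part + next_id
    next_id <- next_id + max(part)
  }
  membership
}

.mcl_component <- function(vs, edges, inflation, tol, max_iter, prune) {
  n <- length(vs)
  i <- match(edges$from, vs); j <- match(edges$to, vs)
  w <- pmax(edges$weight, 1e-10)  # zero-weight edges still connect
  M <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  M <- M + Matrix::Diagonal(n, loop)
  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    M %*% Matrix::Diagonal(n, 1 / cs)
  }
  M <- normalize(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2@x <- M2@x^inflation             # inflation
    M2 <- Matrix::drop0(M2, tol = prune)
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
    if (it == max_iter) stop("MCL did not converge in ", max_iter, " iterations")
  }
  ## attractors: nodes with positive return probability; a node joins the
  ## attractor carrying most of its column mass; overlapping attractor rows
  ## are merged via connected components of the limit structure
  M <- as(M, "CsparseMatrix")
  att <- which(Matrix::diag(M) > 1e-6)
  if (!length(att)) att <- seq_len(n)  # degenerate; treat all as attractors
  assign_to <- integer(n)
  for (v in seq_len(n)) {
    col <- M[, v]
    cand <- intersect(which(col > 1e-9), att)
    if (!length(cand)) cand <- which.max(col)
    assign_to[v] <- cand[which.max(col[cand])]
  }
  ## merge attractor systems that share nodes' support
  ag <- igraph::graph_from_edgelist(cbind(assign_to, seq_len(n)), directed = FALSE)
  cl <- igraph::components(ag)$membership[seq_len(n)]
  as.integer(factor(cl))
}

#' Cluster a panel's genes into ortholog groups
#'
#' Builds the homology graph from a hit table under the chosen criterion
#' and Markov-clusters it at the given inflation. Groups of size one are
#' singletons, not clusters.
#'
#' @param hits Hit table from [homology_search()].
#' @param genes Gene records `data.frame` (`gene_id`, `genome_id`).
#' @param mode,threshold Edge criterion, see [homology_edges()].
#' @param inflation MCL inflation (study value 1.5).
#' @return A list of class `pangenome_clusters`: `clusters` (`data.frame`
#'   `cluster_id`, `gene_id`, `genome_id`), `singletons` (`data.frame`
#'   `gene_id`, `genome_id`), `genomes`.
#' @export
cluster_genes <- function(hits, genes, mode = c("evalue", "bsr"),
                          threshold = NULL, inflation = 1.5) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene_id", "genome_id") %in% names(genes)))
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), genes$gene_id)
  if (length(unknown)) stop("hits reference unknown genes: ", unknown[1])
  edges <- homology_edges(hits, mode = mode, threshold = threshold)
  membership <- mcl_cluster(edges, inflation = inflation, nodes = genes$gene_id)
  tab <- data.frame(gene_id = names(membership),
                    cluster = unname(membership),
                    genome_id = genes$genome_id[match(names(membership), genes$gene_id)],
                    stringsAsFactors = FALSE)
  sizes <- table(tab$cluster)
  single <- tab$cluster %in% as.integer(names(sizes)[sizes == 1L])
  singletons <- tab[single, c("gene_id", "genome_id")]
  clusters <- tab[!single, , drop = FALSE]
  ## stable, size-independent cluster ids
  if (nrow(clusters)) {
    remap <- stats::setNames(seq_along(unique(clusters$cluster)), unique(clusters$cluster))
    clusters$cluster_id <- sprintf("clu%05d", remap[as.character(clusters$cluster)])
  } else {
    clusters$cluster_id <- character(0)
  }
  clusters <- clusters[order(clusters$cluster_id, clusters$gene_id),
                       c("cluster_id", "gene_id", "genome_id")]
  rownames(clusters) <- rownames(singletons) <- NULL
  structure(list(clusters = clusters, singletons = singletons,
                 genomes = sort(unique(genes$genome_id))),
            class = "pangenome_clusters")
}

#' @export
print.pangenome_clusters <- function(x, ...) {
  cat("pangenome_clusters:", length(unique(x$clusters$cluster_id)),
      "clusters,", nrow(x$singletons), "singletons across",
      length(x$genomes), "genomes\n")
  invisible(x)
}

#' Venn partition and summary of a pangenome clustering
#'
#' Assigns every cluster to the subset of genomes it contains members of
#' (presence/absence; paralog copy counts are recorded but do not change
#' the subset), tabulates the Venn cells, counts per-genome singletons, and
#' flags single-copy pan clusters (exactly one member in every genome).
#'
#' @param clustering A [cluster_genes()] result.
#' @param genomes Genome set (default: all genomes seen).
#' @return A list of class `pangenome_summary`: `venn` (`data.frame`
#'   `subset`, `n_clusters`), `singletons` (per-genome counts),
#'   `total_clusters`, `single_copy_pan` (cluster ids), `copy_counts`
#'   (cluster x genome matrix).
#' @export
venn_partition <- function(clustering, genomes = NULL) {
  stopifnot(inherits(clustering, "pangenome_clusters"))
  genomes <- genomes %||% clustering$genomes
  cl <- clustering$clusters
  if (!all(cl$genome_id %in% genomes)) {
    stop("gene with unknown genome: ",
         cl$genome_id[!cl$genome_id %in% genomes][1])
  }
  copy <- table(cl$cluster_id, factor(cl$genome_id, levels = genomes))
  copy <- matrix(copy, nrow = nrow(copy),
                 dimnames = list(rownames(copy), genomes))
  subset_of <- apply(copy > 0, 1, function(z) paste(genomes[z], collapse = "&"))
  venn <- as.data.frame(table(subset = subset_of), stringsAsFactors = FALSE)
  names(venn) <- c("subset", "n_clusters")
  sing <- table(factor(clustering$singletons$genome_id, levels = genomes))
  scp <- rownames(copy)[apply(copy == 1, 1, all)]
  structure(list(venn = venn,
                 singletons = stats::setNames(as.integer(sing), genomes),
                 total_clusters = nrow(copy),
                 single_copy_pan = scp,
                 copy_counts = copy),
            class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat("pangenome_summary:", x$total_clusters, "clusters;",
      length(x$single_copy_pan), "single-copy pan clusters;",
      sum(x$singletons), "singletons\n")
  invisible(x)
}

#' Single-copy pan-ortholog clusters
#'
#' Clusters with exactly one member in every genome: the input for the
#' concatenated phylogeny, which excludes duplicated genes to avoid
#' paralogy artefacts.
#'
#' @param clustering A [cluster_genes()] result.
#' @param genomes Genome set (default: all genomes seen).
#' @return `data.frame` (`cluster_id`, `gene_id`, `genome_id`) restricted
#'   to single-copy pan clusters.
#' @export
single_copy_pan <- function(clustering, genomes = NULL) {
  summ <- venn_partition(clustering, genomes)
  out <- clustering$clusters[clustering$clusters$cluster_id %in% summ$single_copy_pan, ]
  rownames(out) <- NULL
  out
}

#' Clade-exclusive single-copy gene families
#'
#' Finds gene families private to a clade: connected components of the
#' BSR-homology graph restricted to the clade's genes that (i) contain
#' exactly one gene from every clade genome and (ii) have no homology edge
#' (BSR at or above the threshold) from any member to any gene of the
#' contrasting genomes. This is the criterion behind a shared tolerant-only
#' gene set.
#'
#' @param hits Hit table over the union of both genome sets
#'   ([homology_search()] output with self-hits).
#' @param genes Gene records (`gene_id`, `genome_id`).
#' @param clade,others Disjoint genome sets.
#' @param threshold BSR homology cutoff (default 0.30, inclusive).
#' @return A list of class `clade_specific`: `families` (list of gene-id
#'   vectors), `table` (`data.frame` `family`, `gene_id`, `genome_id`).
#' @export
clade_specific_single_copy <- function(hits, genes, clade, others,
                                       threshold = 0.30) {
  if (length(intersect(clade, others))) stop("clade and others overlap")
  stopifnot(all(c(clade, others) %in% genes$genome_id))
  edges <- homology_edges(hits, mode = "bsr", threshold = threshold)
  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)
  clade_genes <- genes$gene_id[genes$genome_id %in% clade]
  other_genes <- genes$gene_id[genes$genome_id %in% others]
  in_clade <- edges$from %in% clade_genes & edges$to %in% clade_genes
  g <- igraph::graph_from_data_frame(edges[in_clade, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = clade_genes))
  comp <- igraph::components(g)$membership
  ## genes with any homology into the contrast set are disqualified
  crosses <- unique(c(edges$from[edges$from %in% clade_genes &
                                   edges$to %in% other_genes],
                      edges$to[edges$to %in% clade_genes &
                                 edges$from %in% other_genes]))
  fams <- split(names(comp), comp)
  keep <- vapply(fams, function(members) {
    gm <- genome_of[members]
    length(members) == length(clade) &&
      setequal(gm, clade) && !anyDuplicated(gm) &&
      !any(members %in% crosses)
  }, logical(1))
  fams <- unname(fams[keep])
  tab <- if (length(fams)) {
    data.frame(family = rep(sprintf("cs%04d", seq_along(fams)), lengths(fams)),
               gene_id = unlist(fams),
               genome_id = unname(genome_of[unlist(fams)]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(0), gene_id = character(0),
               genome_id = character(0))
  }
  structure(list(families = fams, table = tab), class = "clade_specific")
}

#' @export
print.clade_specific <- function(x, ...) {
  cat("clade_specific:", length(x$families), "clade-exclusive single-copy families\n")
  invisible(x)
}
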