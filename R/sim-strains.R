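## Strain-panel simulator: ancestral CDSs evolved along a tree under
## Jukes-Cantor with per-branch gene gain, loss and duplication, plus a
## planted block of single-copy genes private to a designated clade.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

## one random sense codon stream of n codons (no stops by construction)
.random_cds <- function(n_codons) {
  codons <- character(n_codons)
  need <- seq_len(n_codons)
  while (length(need)) {
    cand <- paste0(sample(.BASES, length(need), replace = TRUE),
                   sample(.BASES, length(need), replace = TRUE),
                   sample(.BASES, length(need), replace = TRUE))
    codons[need] <- cand
    need <- need[cand %in% .STOPS]
  }
  unlist(strsplit(codons, ""), use.names = FALSE)
}

## Jukes-Cantor substitution over a branch of length t (expected subs/site).
## Mutations that create an in-frame stop codon are resampled.
.mutate_jc <- function(seq, t) {
  if (t <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  n <- length(seq)
  hit <- which(stats::runif(n) < p)
  if (!length(hit)) return(seq)
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  orig <- seq[hit]
  seq[hit] <- alt[cbind(match(orig, .BASES), sample.int(3L, length(hit), replace = TRUE))]
  ## resample mutated positions whose codon became an in-frame stop
  repeat {
    cod_of_hit <- (hit - 1L) %/% 3L
    starts <- unique(cod_of_hit) * 3L + 1L
    cods <- paste0(seq[starts], seq[starts + 1L], seq[starts + 2L])
    bad_cod <- unique(cod_of_hit)[cods %in% .STOPS]
    if (!length(bad_cod)) break
    redo <- cod_of_hit %in% bad_cod
    seq[hit[redo]] <- alt[cbind(match(orig[redo], .BASES),
                                sample.int(3L, sum(redo), replace = TRUE))]
    hit <- hit[redo]
    orig <- orig[redo]
  }
  seq
}

## optional short in-frame indel (insertion or deletion of 1-3 codons)
.maybe_indel <- function(seq, rate) {
  if (rate <= 0 || stats::runif(1) >= rate) return(seq)
  n_cod <- length(seq) %/% 3L
  k <- sample(1:3, 1L)
  if (stats::runif(1) < 0.5 && n_cod - k >= 10L) {       # deletion
    at <- sample.int(n_cod - k + 1L, 1L)
    drop <- ((at - 1L) * 3L + 1L):((at + k - 1L) * 3L)
    seq[-drop]
  } else {                                               # insertion
    at <- sample.int(n_cod + 1L, 1L)
    ins <- .random_cds(k)
    append(seq, ins, after = (at - 1L) * 3L)
  }
}

.translate_cds <- function(cds_strings) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds_strings)))
}

.COG_LETTERS <- c("C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M", "N",
                  "O", "P", "Q", "R", "S", "T", "U", "V")

#' Simulate a panel of bacterial strain gene sets with known ground truth
#'
#' Ancestral CDSs are generated from random sense codons, then evolved along
#' the config's rooted strain tree under a Jukes-Cantor nucleotide model
#' (mutations creating in-frame stop codons are resampled). On each branch
#' every gene is independently lost or duplicated at the configured
#' per-gene rates, and fresh random genes are gained (these become future
#' singletons). A block of `planted_block_size` genes is created at the
#' most recent common ancestor of `planted_clade` and deposited, one copy
#' per clade member, in those tips only: the clade-exclusive single-copy
#' signal every downstream stage is asked to recover.
#'
#' @param config A [sim_config()].
#' @return A list of class `strain_sim` with
#'   \describe{
#'     \item{genes}{`data.frame` of gene records: `gene_id`, `genome_id`,
#'       `family`, `protein_seq`, `cds_seq`, `product`, `cog_category`.}
#'     \item{truth}{ground truth: `families` (per-family origin), `events`
#'       (per-branch gain/loss/dup log), `planted` (planted family ids),
#'       `tree` (the generating topology), `growth` (true MIC/MTC table).}
#'   }
#' @export
simulate_strains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$strain_tree
  ntip <- length(tree$tip.label)

  ## ancestral gene pool
  len_aa <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                   config$n_ancestor_genes, replace = TRUE)
  fam_ids <- sprintf("fam%04d", seq_len(config$n_ancestor_genes))
  pool <- lapply(seq_len(config$n_ancestor_genes),
                 function(i) list(fam = fam_ids[i], seq = .random_cds(len_aa[i])))

  ## family-level annotation (shared by all members of a family)
  .annotate <- function(fams) {
    has_cog <- stats::runif(length(fams)) < 0.65
    cog <- ifelse(has_cog, sample(.COG_LETTERS, length(fams), replace = TRUE),
                  NA_character_)
    dual <- has_cog & stats::runif(length(fams)) < 0.1
    cog[dual] <- paste0(cog[dual], sample(.COG_LETTERS, sum(dual), replace = TRUE))
    stats::setNames(cog, fams)
  }
  fam_cog <- .annotate(fam_ids)

  gain_counter <- 0L
  events <- list()
  log_event <- function(branch_to, type, fam) {
    events[[length(events) + 1L]] <<- data.frame(
      branch_to = branch_to, event = type, family = fam, stringsAsFactors = FALSE)
  }

  ## preorder walk; node labels: tips 1..ntip, root ntip+1
  edge <- tree$edge
  elen <- tree$edge.length
  node_pool <- vector("list", max(edge))
  root <- ntip + 1L
  node_pool[[root]] <- pool
  node_name <- function(v) if (v <= ntip) tree$tip.label[v] else paste0("node", v)

  ## process edges whose parent pool is ready (preorder)
  pending <- seq_len(nrow(edge))
  while (length(pending)) {
    ready <- pending[vapply(pending, function(e) !is.null(node_pool[[edge[e, 1]]]), TRUE)]
    for (e in ready) {
      par <- edge[e, 1]; chl <- edge[e, 2]; t <- elen[e]
      genes <- node_pool[[par]]
      n <- length(genes)
      ## loss
      lost <- which(stats::runif(n) < config$loss_rate)
      if (length(lost)) {
        for (i in lost) log_event(node_name(chl), "loss", genes[[i]]$fam)
        if (length(lost)) genes <- genes[-lost]
      }
      ## duplication
      ndup <- length(genes)
      dup <- which(stats::runif(ndup) < config$dup_rate)
      for (i in dup) {
        log_event(node_name(chl), "dup", genes[[i]]$fam)
        genes[[length(genes) + 1L]] <- genes[[i]]
      }
      ## gain
      n_gain <- stats::rpois(1L, config$gain_rate * length(genes))
      if (n_gain > 0) {
        for (k in seq_len(n_gain)) {
          gain_counter <- gain_counter + 1L
          gfam <- sprintf("gain%04d", gain_counter)
          glen <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]), 1L)
          genes[[length(genes) + 1L]] <- list(fam = gfam, seq = .random_cds(glen))
          log_event(node_name(chl), "gain", gfam)
        }
      }
      ## substitution (and optional indels)
      genes <- lapply(genes, function(g) {
        g$seq <- .mutate_jc(g$seq, t)
        if (config$indel_rate > 0) g$seq <- .maybe_indel(g$seq, config$indel_rate)
        g
      })
      node_pool[[chl]] <- genes
    }
    pending <- setdiff(pending, ready)
    if (!length(ready)) stop("tree edge table is not traversable")
  }

  ## planted clade-exclusive block, evolved from the clade MRCA
  planted_fams <- character(0)
  planted_seqs <- list()
  if (config$planted_block_size > 0 && length(config$planted_clade)) {
    planted_fams <- sprintf("planted%03d", seq_len(config$planted_block_size))
    plen <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                   config$planted_block_size, replace = TRUE)
    block0 <- lapply(plen, .random_cds)
    mrca <- if (length(config$planted_clade) > 1L) {
      ape::getMRCA(tree, config$planted_clade)
    } else {
      match(config$planted_clade, tree$tip.label)
    }
    for (tip_name in config$planted_clade) {
      tip <- match(tip_name, tree$tip.label)
      ## total path length MRCA -> tip
      path_t <- 0
      v <- tip
      while (v != mrca) {
        e <- which(edge[, 2] == v)
        path_t <- path_t + elen[e]
        v <- edge[e, 1]
      }
      planted_seqs[[tip_name]] <- lapply(block0, .mutate_jc, t = path_t)
    }
    fam_cog <- c(fam_cog, .annotate(planted_fams))
  }
  if (gain_counter > 0) {
    fam_cog <- c(fam_cog, .annotate(sprintf("gain%04d", seq_len(gain_counter))))
  }

  ## assemble tip gene tables
  rows <- list()
  for (tip in seq_len(ntip)) {
    nm <- tree$tip.label[tip]
    genes <- node_pool[[tip]]
    if (nm %in% config$planted_clade) {
      genes <- c(genes, lapply(seq_along(planted_fams), function(i)
        list(fam = planted_fams[i], seq = planted_seqs[[nm]][[i]])))
    }
    if (!length(genes)) next
    fam <- vapply(genes, `[[`, "", "fam")
    cds <- vapply(genes, function(g) paste(g$seq, collapse = ""), "")
    gid <- make.unique(paste0(nm, "_", fam), sep = ".")
    rows[[nm]] <- data.frame(
      gene_id = gid, genome_id = nm, family = fam,
      cds_seq = cds, stringsAsFactors = FALSE)
  }
  genes_df <- do.call(rbind, rows)
  rownames(genes_df) <- NULL
  genes_df$protein_seq <- .translate_cds(genes_df$cds_seq)
  genes_df$product <- ifelse(is.na(fam_cog[genes_df$family]),
                             "hypothetical protein",
                             paste("predicted protein, COG", fam_cog[genes_df$family]))
  genes_df$cog_category <- unname(fam_cog[genes_df$family])
  genes_df <- genes_df[, c("gene_id", "genome_id", "family", "protein_seq",
                           "cds_seq", "product", "cog_category")]

  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(branch_to = character(0), event = character(0), family = character(0))
  families <- data.frame(
    family = c(fam_ids, planted_fams,
               if (gain_counter > 0) sprintf("gain%04d", seq_len(gain_counter)) else character(0)),
    origin = c(rep("ancestor", length(fam_ids)),
               rep("planted", length(planted_fams)),
               rep("gain", gain_counter)),
    stringsAsFactors = FALSE)

  out <- list(genes = genes_df,
              truth = list(families = families,
                           events = events_df,
                           planted = planted_fams,
                           tree = tree,
                           growth = config$growth_params))
  class(out) <- "strain_sim"
  out
}

#' @export
print.strain_sim <- function(x, ...) {
  cat("strain_sim:", nrow(x$genes), "genes across",
      length(unique(x$genes$genome_id)), "strains;",
      length(x$truth$planted), "planted clade-exclusive families\n")
  invisible(x)
}

#' True clade-exclusive single-copy families of a simulated panel
#'
#' Derives, from the generator's family labels, the families present in
#' exactly one copy in every clade genome and absent from all other
#' genomes. Besides the planted block this includes families gained on the
#' clade's stem branch or lost everywhere else — the full ground truth a
#' clade-specific scan should recover.
#'
#' @param sim A [simulate_strains()] result.
#' @param clade Genome names forming the clade.
#' @return Character vector of family ids.
#' @export
true_clade_exclusive <- function(sim, clade) {
  stopifnot(inherits(sim, "strain_sim"))
  g <- sim$genes
  in_clade <- g$genome_id %in% clade
  tab <- table(g$family, factor(in_clade, levels = c(FALSE, TRUE)))
  per_genome <- table(g$family[in_clade], g$genome_id[in_clade])
  ok_inside <- rownames(per_genome)[ncol(per_genome) == length(clade) &
                                      apply(per_genome == 1, 1, all)]
  if (ncol(per_genome) < length(clade)) ok_inside <- character(0)
  absent_outside <- rownames(tab)[tab[, "FALSE"] == 0]
  intersect(ok_inside, absent_outside)
}

#' Write per-strain FASTA files and the ground-truth event log
#'
#' One protein and one CDS FASTA per strain plus tab-separated gene
#' annotation and event-log tables, the on-disk form downstream runs read.
#'
#' @param sim A [simulate_strains()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_strain_fasta <- function(sim, dir) {
  stopifnot(inherits(sim, "strain_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (g in unique(sim$genes$genome_id)) {
    sub <- sim$genes[sim$genes$genome_id == g, ]
    aa <- Biostrings::AAStringSet(stats::setNames(sub$protein_seq, sub$gene_id))
    nt <- Biostrings::DNAStringSet(stats::setNames(sub$cds_seq, sub$gene_id))
    fa <- file.path(dir, paste0(g, ".faa")); fn <- file.path(dir, paste0(g, ".fna"))
    Biostrings::writeXStringSet(aa, fa)
    Biostrings::writeXStringSet(nt, fn)
    files <- c(files, fa, fn)
  }
  ann <- file.path(dir, "annotations.tsv")
  utils::write.table(sim$genes[, c("gene_id", "genome_id", "family", "product", "cog_category")],
                     ann, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- file.path(dir, "events.tsv")
  utils::write.table(sim$truth$events, ev, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, ann, ev))
}
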