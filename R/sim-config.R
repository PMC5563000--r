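#' Simulation configuration for a strain panel
#'
#' Bundles every knob of the synthetic-data generators: the strain tree along
#' which ancestral genes evolve, per-branch gene gain/loss/duplication rates,
#' a planted block of single-copy genes exclusive to a designated tolerant
#' clade, read/count library parameters, and per-strain dose-response
#' parameters. The defaults describe the study conditions the package is
#' exercised under: six strains diverged from a common ancestor, 300 ancestral
#' genes, a 10-gene block private to the two tolerant strains, two-replicate
#' count libraries of unequal depth under control/salt/osmotic conditions,
#' and sigmoidal growth-yield declines between a strain's maximum tolerable
#' (MTC) and minimum inhibitory (MIC) concentrations.
#'
#' @param seed Integer seed; the same config (including seed) reproduces every
#'   generator output exactly.
#' @param n_ancestor_genes Number of genes in the common ancestor.
#' @param gene_length_range Amino-acid length interval genes are drawn from.
#' @param strain_tree Rooted tree with branch lengths in expected nucleotide
#'   substitutions per site; a newick string or an [ape] `phylo` object.
#' @param gain_rate,loss_rate,dup_rate Expected events per gene per branch.
#' @param indel_rate Per-gene per-branch probability of a short in-frame
#'   indel. Off (0) by default so family alignments stay trivial.
#' @param planted_clade Tip names receiving the planted tolerant-exclusive
#'   gene block (one copy each, absent elsewhere).
#' @param planted_block_size Number of planted clade-exclusive genes.
#' @param read_length,error_rate Read simulator: fixed read length (nt) and
#'   per-base substitution error probability.
#' @param library_sizes Named numeric, total reads per condition (per
#'   replicate). Deliberately unequal across conditions.
#' @param n_replicates Biological replicates per condition for count data.
#' @param spike_table Optional `data.frame(gene_id, salt_fold, osmotic_fold)`
#'   of expression fold changes to plant; `NULL` lets [simulate_counts()]
#'   plant its default 20 salt-only / 20 osmotic-only / 10 shared spikes.
#' @param dispersion Negative-binomial overdispersion of replicate counts
#'   (variance `mu + dispersion * mu^2`); 0 gives Poisson replicates.
#' @param growth_params `data.frame(strain, mic_true, mtc_true, yield0,
#'   replicate_sd)`; one row per tip. Yields in protein microgram/ml,
#'   concentrations in mM.
#' @param concentrations Solute concentration grid (mM) for growth assays.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_ancestor_genes = 300L,
                       gene_length_range = c(80L, 250L),
                       strain_tree = "((S1:0.02,S2:0.02):0.04,((S3:0.03,S4:0.03):0.03,(S5:0.04,S6:0.04):0.02):0.01);",
                       gain_rate = 0.02,
                       loss_rate = 0.02,
                       dup_rate = 0.01,
                       indel_rate = 0,
                       planted_clade = c("S1", "S2"),
                       planted_block_size = 10L,
                       read_length = 100L,
                       error_rate = 0.01,
                       library_sizes = c(control = 2.14e6, salt = 0.85e6, osmotic = 2.5e6),
                       n_replicates = 2L,
                       spike_table = NULL,
                       dispersion = 0.05,
                       growth_params = NULL,
                       concentrations = seq(0, 1000, by = 125)) {
  if (is.character(strain_tree)) {
    strain_tree <- ape::read.tree(text = strain_tree)
  }
  stopifnot(inherits(strain_tree, "phylo"), !is.null(strain_tree$edge.length))
  if (length(strain_tree$tip.label) < 2L) {
    stop("strain_tree must have at least 2 tips")
  }
  if (!all(planted_clade %in% strain_tree$tip.label)) {
    stop("planted_clade contains names that are not tips of strain_tree")
  }
  for (r in c(gain_rate, loss_rate, dup_rate, indel_rate, error_rate, dispersion)) {
    if (!is.numeric(r) || any(r < 0)) stop("rates must be nonnegative")
  }
  stopifnot(length(gene_length_range) == 2L,
            gene_length_range[1] >= 10L,
            gene_length_range[2] >= gene_length_range[1],
            all(library_sizes > 0),
            n_replicates >= 1L,
            read_length >= 20L)
  if (is.null(growth_params)) {
    tips <- strain_tree$tip.label
    mic <- rep(750, length(tips))
    mtc <- rep(250, length(tips))
    mic[match(planted_clade, tips)] <- 1000   # tolerant clade
    if (length(tips) >= 1L) {                 # last tip plays the sensitive strain
      sens <- setdiff(tips, planted_clade)
      if (length(sens)) {
        mic[match(sens[length(sens)], tips)] <- 500
        mtc[match(sens[length(sens)], tips)] <- 125
      }
    }
    growth_params <- data.frame(strain = tips, mic_true = mic, mtc_true = mtc,
                                yield0 = 100, replicate_sd = 5,
                                stringsAsFactors = FALSE)
  }
  stopifnot(all(growth_params$mtc_true < growth_params$mic_true))
  cfg <- list(seed = as.integer(seed),
              n_ancestor_genes = as.integer(n_ancestor_genes),
              gene_length_range = as.integer(gene_length_range),
              strain_tree = strain_tree,
              gain_rate = gain_rate, loss_rate = loss_rate, dup_rate = dup_rate,
              indel_rate = indel_rate,
              planted_clade = planted_clade,
              planted_block_size = as.integer(planted_block_size),
              read_length = as.integer(read_length),
              error_rate = error_rate,
              library_sizes = library_sizes,
              n_replicates = as.integer(n_replicates),
              spike_table = spike_table,
              dispersion = dispersion,
              growth_params = growth_params,
              concentrations = as.numeric(concentrations))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$strain_tree$tip.label), "strains,",
      x$n_ancestor_genes, "ancestral genes, seed", x$seed, "\n")
  cat("  planted clade:", paste(x$planted_clade, collapse = ","),
      "(block of", x$planted_block_size, "genes)\n")
  cat("  rates (gain/loss/dup per gene per branch):",
      x$gain_rate, "/", x$loss_rate, "/", x$dup_rate, "\n")
  invisible(x)
}
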