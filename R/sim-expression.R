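## Count, read, Ct and growth-yield simulators. All are seeded from the
## config seed plus a fixed per-generator offset so the same config
## reproduces every output exactly while the generators stay decoupled.

.seed_off <- c(counts = 101L, reads = 202L, ct = 303L, growth = 404L)

#' Simulate two-condition, replicated RNA-seq count libraries
#'
#' Draws per-gene baseline abundances (gamma), multiplies in the planted
#' condition fold changes, and samples replicate counts from a
#' gamma-Poisson (negative binomial) with the configured overdispersion:
#' `Var = mu + dispersion * mu^2`. Library totals are the configured
#' per-condition depths (deliberately unequal); gene counts sum to roughly
#' 80% of each total, the remainder standing in for reads that map outside
#' annotated CDSs. Conditions are control, salt and osmotic with
#' `n_replicates` biological replicates each.
#'
#' If `config$spike_table` is `NULL`, 50 spiked genes are planted: 20
#' salt-only, 20 osmotic-only and 10 responsive to both, half up (fold 4)
#' and half down (fold 1/4) within each group.
#'
#' @param config A [sim_config()].
#' @param genes `data.frame` of gene records (e.g. one genome's rows of
#'   [simulate_strains()]`$genes`), or a character vector of gene ids.
#' @return A list of class `count_sim`: `counts` (a `count_table`), and
#'   `truth` (`data.frame` of spiked genes with their true folds).
#' @export
simulate_counts <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  stopifnot(length(gene_ids) >= 10L, !anyDuplicated(gene_ids))
  set.seed(config$seed + .seed_off[["counts"]])
  ng <- length(gene_ids)

  base <- stats::rgamma(ng, shape = 0.6, rate = 1)
  base <- 0.8 * base / sum(base)
  names(base) <- gene_ids

  spikes <- config$spike_table
  if (is.null(spikes)) {
    n_need <- 50L
    if (ng >= n_need) {
      pick <- sample(gene_ids, n_need)
      updown <- function(k) rep(c(4, 0.25), length.out = k)
      spikes <- data.frame(gene_id = pick,
                           salt_fold = 1, osmotic_fold = 1,
                           stringsAsFactors = FALSE)
      spikes$salt_fold[1:20] <- updown(20)
      spikes$osmotic_fold[21:40] <- updown(20)
      both <- updown(10)
      spikes$salt_fold[41:50] <- both
      spikes$osmotic_fold[41:50] <- both
    } else {
      spikes <- data.frame(gene_id = character(0), salt_fold = numeric(0),
                           osmotic_fold = numeric(0))
    }
  }
  stopifnot(all(spikes$gene_id %in% gene_ids),
            all(spikes$salt_fold > 0), all(spikes$osmotic_fold > 0))
  if (config$dispersion < 0) stop("dispersion must be >= 0")

  fold <- matrix(1, ng, 3, dimnames = list(gene_ids, c("control", "salt", "osmotic")))
  fold[spikes$gene_id, "salt"] <- spikes$salt_fold
  fold[spikes$gene_id, "osmotic"] <- spikes$osmotic_fold

  conds <- rep(c("control", "salt", "osmotic"), each = config$n_replicates)
  reps <- rep(seq_len(config$n_replicates), times = 3)
  samples <- paste0(conds, "_", reps)
  libs <- stats::setNames(config$library_sizes[conds], samples)

  counts <- matrix(0L, ng, length(samples), dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    mu <- libs[j] * base * fold[, conds[j]]
    counts[, j] <- if (config$dispersion == 0) {
      stats::rpois(ng, mu)
    } else {
      stats::rnbinom(ng, mu = mu, size = 1 / config$dispersion)
    }
  }
  ct <- count_table(counts, lib_sizes = libs, condition = conds, replicate = reps)

  truth <- spikes[spikes$salt_fold != 1 | spikes$osmotic_fold != 1, , drop = FALSE]
  out <- list(counts = ct, truth = truth, baseline = base)
  class(out) <- "count_sim"
  out
}

#' Gene-by-sample count container
#'
#' @param counts Integer matrix, genes in rows, samples in columns.
#' @param lib_sizes Per-sample total library sizes (may exceed the column
#'   sums: totals count all reads, not only those assigned to genes).
#' @param condition,replicate Per-sample condition labels and replicate ids.
#' @return A `count_table` object.
#' @export
count_table <- function(counts, lib_sizes, condition, replicate) {
  stopifnot(is.matrix(counts), length(lib_sizes) == ncol(counts),
            length(condition) == ncol(counts), all(lib_sizes > 0),
            all(counts >= 0))
  structure(list(counts = counts, lib_sizes = as.numeric(lib_sizes),
                 condition = as.character(condition),
                 replicate = as.integer(replicate)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      paste(unique(x$condition), collapse = "/"), ")\n")
  invisible(x)
}

#' Simulate single-end reads from gene CDSs
#'
#' Reads of fixed length are sampled uniformly over all valid start
#' positions (so genes contribute in proportion to length), then corrupted
#' with independent per-base substitution errors. The source gene and start
#' are retained in the read identifier (`r000001|gene|start`).
#'
#' @param genes Gene records `data.frame` (needs `gene_id`, `cds_seq`) or a
#'   named character vector of CDS sequences.
#' @param config A [sim_config()] supplying `read_length` and `error_rate`.
#' @param n_reads Number of reads to draw.
#' @return Named character vector of reads.
#' @export
simulate_reads <- function(genes, config, n_reads = 10000L) {
  stopifnot(inherits(config, "sim_config"))
  cds <- if (is.data.frame(genes)) stats::setNames(genes$cds_seq, genes$gene_id) else genes
  if (!length(cds)) stop("empty gene set")
  L <- config$read_length
  lens <- nchar(cds)
  if (L > min(lens)) stop("read_length exceeds the shortest gene")
  set.seed(config$seed + .seed_off[["reads"]])
  nstart <- lens - L + 1L
  gene_pick <- sample.int(length(cds), n_reads, replace = TRUE, prob = nstart)
  start <- 1L + floor(stats::runif(n_reads) * nstart[gene_pick])
  reads <- substr(cds[gene_pick], start, start + L - 1L)
  if (config$error_rate > 0) {
    mat <- matrix(unlist(strsplit(reads, ""), use.names = FALSE), nrow = L)
    err <- which(matrix(stats::runif(L * n_reads) < config$error_rate, nrow = L))
    if (length(err)) {
      alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
      mat[err] <- alt[cbind(match(mat[err], .BASES),
                            sample.int(3L, length(err), replace = TRUE))]
    }
    reads <- apply(mat, 2, paste, collapse = "")
  }
  stats::setNames(as.character(reads), sprintf("r%06d|%s|%d", seq_len(n_reads),
                                               names(cds)[gene_pick], start))
}

#' Simulate a qPCR Ct table consistent with a count table
#'
#' Models Ct as `offset - log2(count / library total)` plus Gaussian
#' technical noise, in technical triplicate per sample. With zero noise the
#' delta-delta-Ct fold recovered from the table equals the counts'
#' normalized expression ratio exactly.
#'
#' @param counts A `count_table`.
#' @param normalizer Gene id used as the reference gene.
#' @param genes Genes to measure (default: the normalizer plus up to 20
#'   highest-count genes). All requested genes must have nonzero counts in
#'   every sample.
#' @param offset Ct intercept (cycles).
#' @param ct_sd Technical noise standard deviation (cycles).
#' @param n_tech Technical replicates per reaction.
#' @param seed Integer seed.
#' @return A `data.frame` of class `ct_table`: `sample`, `condition`,
#'   `replicate`, `gene`, `tech_rep`, `ct`; the normalizer id is kept in
#'   `attr(, "normalizer")`.
#' @export
simulate_ct <- function(counts, normalizer, genes = NULL,
                        offset = 12, ct_sd = 0.15, n_tech = 3L, seed = 1L) {
  stopifnot(inherits(counts, "count_table"))
  cm <- counts$counts
  if (!normalizer %in% rownames(cm)) stop("normalizer not in count table")
  if (any(cm[normalizer, ] == 0)) stop("normalizer has zero expression in some sample")
  if (is.null(genes)) {
    cand <- setdiff(rownames(cm)[order(-rowSums(cm))], normalizer)
    cand <- cand[apply(cm[cand, , drop = FALSE] > 0, 1, all)]
    genes <- utils::head(cand, 20L)
  }
  bad <- genes[apply(cm[genes, , drop = FALSE] == 0, 1, any)]
  if (length(bad)) stop("zero expression for requested gene(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed + .seed_off[["ct"]])
  all_genes <- unique(c(normalizer, genes))
  samples <- colnames(cm)
  grid <- expand.grid(gene = all_genes, sample = samples,
                      tech_rep = seq_len(n_tech),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- cm[cbind(grid$gene, grid$sample)] / counts$lib_sizes[match(grid$sample, samples)]
  grid$ct <- offset - log2(p) + stats::rnorm(nrow(grid), 0, ct_sd)
  grid$condition <- counts$condition[match(grid$sample, samples)]
  grid$replicate <- counts$replicate[match(grid$sample, samples)]
  out <- grid[, c("sample", "condition", "replicate", "gene", "tech_rep", "ct")]
  attr(out, "normalizer") <- normalizer
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Simulate dose-response growth-yield tables
#'
#' Mean yield is `yield0` up to the strain's true MTC, declines smoothly
#' (cubic smoothstep, i.e. sigmoidal) to 0 at the true MIC, and stays 0
#' beyond; Gaussian replicate noise is added. Yields may dip below zero
#' after noise, as inoculum-subtracted measurements do.
#'
#' @param config A [sim_config()] supplying `growth_params` and
#'   `concentrations`.
#' @param n_rep Replicates per concentration.
#' @param noise_sd Override of the per-strain replicate standard deviation
#'   (`NULL` uses `growth_params$replicate_sd`).
#' @return `data.frame`: `strain`, `concentration`, `replicate`, `yield`.
#' @export
simulate_growth <- function(config, n_rep = 3L, noise_sd = NULL) {
  stopifnot(inherits(config, "sim_config"))
  conc <- config$concentrations
  if (any(conc < 0)) stop("negative concentrations")
  set.seed(config$seed + .seed_off[["growth"]])
  gp <- config$growth_params
  out <- list()
  for (i in seq_len(nrow(gp))) {
    mtc <- gp$mtc_true[i]; mic <- gp$mic_true[i]
    x <- pmin(pmax((conc - mtc) / (mic - mtc), 0), 1)
    mean_y <- gp$yield0[i] * (1 - (3 * x^2 - 2 * x^3))
    sd_i <- if (is.null(noise_sd)) gp$replicate_sd[i] else noise_sd
    for (r in seq_len(n_rep)) {
      out[[length(out) + 1L]] <- data.frame(
        strain = gp$strain[i], concentration = conc, replicate = r,
        yield = mean_y + stats::rnorm(length(conc), 0, sd_i),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
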