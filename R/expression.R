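## RNA-seq arm: parameterized read mapping against a gene reference,
## unique-read counting, total-count normalization, Baggerley's weighted
## proportions test, DE calling with a two-condition Venn, and COG
## category summaries.

#' Read-mapping policy
#'
#' The mapping rules of the study's pipeline, as configurable defaults: at
#' most 2 mismatches, at least 50% of the read aligned, at least 80%
#' identity, reads matching more than 10 distinct places unmapped, reads
#' matching 2-10 places randomly assigned to one of them (seeded).
#'
#' @param max_mismatches,min_length_fraction,min_identity,max_hits Policy
#'   thresholds.
#' @param count_mode `"unique_only"` (default: only uniquely placed reads
#'   are counted) or `"with_random_assignment"` (randomly assigned
#'   multireads count too).
#' @return A `mapping_policy` object.
#' @export
mapping_policy <- function(max_mismatches = 2L, min_length_fraction = 0.5,
                           min_identity = 0.8, max_hits = 10L,
                           count_mode = c("unique_only", "with_random_assignment")) {
  count_mode <- match.arg(count_mode)
  stopifnot(max_mismatches >= 0, min_length_fraction > 0, min_length_fraction <= 1,
            min_identity > 0, min_identity <= 1, max_hits >= 1)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 min_length_fraction = min_length_fraction,
                 min_identity = min_identity,
                 max_hits = as.integer(max_hits),
                 count_mode = count_mode),
            class = "mapping_policy")
}

#' Map reads to a gene reference
#'
#' Ungapped end-to-end placement of each read against every gene: a
#' placement is valid when the whole read lies inside the gene with at
#' most `max_mismatches` mismatches (which also satisfies the identity and
#' length-fraction floors for the default policy and read lengths of 10+).
#' Candidate placements are found with a pigeonhole seed index (a read
#' with at most k mismatches has one of its k+1 segments exact) and
#' verified by Hamming distance, so the scan is exact. A read with one
#' valid placement is `unique`; 2..`max_hits` placements draw one at
#' random (seeded); more than `max_hits` distinct placements leaves the
#' read `unmapped`.
#'
#' @param reads Named character vector (names = read ids).
#' @param reference Named character vector of gene CDSs, or gene records
#'   `data.frame`.
#' @param policy A [mapping_policy()].
#' @param seed Seed for random assignment of multireads.
#' @return `data.frame` of class `read_placements`: `read_id`, `status`
#'   (`unique` / `multi` / `unmapped`), `n_places`, `gene_id`, `start`,
#'   `mismatches` (NA for unmapped).
#' @export
map_reads <- function(reads, reference, policy = mapping_policy(), seed = 1L) {
  ref <- if (is.data.frame(reference)) {
    stats::setNames(reference$cds_seq, reference$gene_id)
  } else reference
  stopifnot(length(ref) > 0, length(reads) > 0, !is.null(names(reads)))
  L <- unique(nchar(reads))
  if (length(L) != 1L) stop("reads must have a single fixed length")
  if (L > max(nchar(ref))) stop("reads longer than every reference gene")
  k <- policy$max_mismatches
  ## identity of a full-length ungapped placement is (L-k)/L; refuse
  ## policies the ungapped contract cannot honor
  if ((L - k) / L < policy$min_identity) {
    stop("max_mismatches incompatible with min_identity for this read length")
  }
  nseg <- k + 1L
  seg_bounds <- floor(seq(0L, L, length.out = nseg + 1L))
  ## concatenated reference with '+' separators (never matches ACGT)
  sep <- strrep("+", L)
  cat_ref <- paste(ref, collapse = sep)
  offsets <- cumsum(c(1L, nchar(ref)[-length(ref)] + nchar(sep)))  # gene start in cat_ref
  names(offsets) <- names(ref)

  cand_read <- integer(0); cand_pos <- integer(0)
  for (s in seq_len(nseg)) {
    a <- seg_bounds[s] + 1L; b <- seg_bounds[s + 1L]
    segs <- substr(reads, a, b)
    dict <- Biostrings::PDict(Biostrings::DNAStringSet(segs))
    m <- Biostrings::matchPDict(dict, Biostrings::DNAString(cat_ref))
    st <- Biostrings::startIndex(m)
    hit_n <- lengths(st)
    if (!sum(hit_n)) next
    rd <- rep(seq_along(reads), hit_n)
    pos <- unlist(st, use.names = FALSE) - (a - 1L)   # implied read start
    cand_read <- c(cand_read, rd)
    cand_pos <- c(cand_pos, pos)
  }
  keep <- cand_pos >= 1L & cand_pos + L - 1L <= nchar(cat_ref)
  cand_read <- cand_read[keep]; cand_pos <- cand_pos[keep]
  dup <- duplicated(paste0(cand_read, "_", cand_pos))
  cand_read <- cand_read[!dup]; cand_pos <- cand_pos[!dup]
  ## verify by Hamming distance on the full read
  win <- substr(rep(cat_ref, length(cand_pos)), cand_pos, cand_pos + L - 1L)
  mm <- .hamming_batch(unname(reads[cand_read]), win)
  ok <- mm <= k & !grepl("+", win, fixed = TRUE)   # windows crossing genes are invalid
  cand_read <- cand_read[ok]; cand_pos <- cand_pos[ok]; mm <- mm[ok]
  ## map concatenated positions back to genes
  gidx <- findInterval(cand_pos, offsets)
  gstart <- cand_pos - offsets[gidx] + 1L

  set.seed(seed)
  n_places <- tabulate(cand_read, nbins = length(reads))
  status <- rep("unmapped", length(reads))
  status[n_places == 1L] <- "unique"
  status[n_places >= 2L & n_places <= policy$max_hits] <- "multi"
  pick_gene <- rep(NA_character_, length(reads))
  pick_start <- rep(NA_integer_, length(reads))
  pick_mm <- rep(NA_integer_, length(reads))
  ord <- order(cand_read, gidx, gstart)
  cr <- cand_read[ord]; gi <- gidx[ord]; gs <- gstart[ord]; mmo <- mm[ord]
  first_of <- match(seq_along(reads), cr)
  uq <- which(status == "unique")
  pick_gene[uq] <- names(ref)[gi[first_of[uq]]]
  pick_start[uq] <- gs[first_of[uq]]
  pick_mm[uq] <- mmo[first_of[uq]]
  for (r in which(status == "multi")) {
    ix <- which(cr == r)
    j <- ix[sample.int(length(ix), 1L)]
    pick_gene[r] <- names(ref)[gi[j]]
    pick_start[r] <- gs[j]
    pick_mm[r] <- mmo[j]
  }
  out <- data.frame(read_id = names(reads), status = status,
                    n_places = n_places, gene_id = pick_gene,
                    start = pick_start, mismatches = pick_mm,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_placements", "data.frame")
  out
}

#' Tabulate per-gene read counts from placements
#'
#' @param placements A [map_reads()] result.
#' @param gene_ids Reference gene ids (rows of the output).
#' @param policy A [mapping_policy()]; `count_mode` decides whether
#'   randomly assigned multireads are counted on top of unique reads.
#' @return Named integer vector of per-gene counts.
#' @export
count_reads <- function(placements, gene_ids, policy = mapping_policy()) {
  use <- placements$status == "unique"
  if (policy$count_mode == "with_random_assignment") {
    use <- use | placements$status == "multi"
  }
  tab <- table(factor(placements$gene_id[use], levels = gene_ids))
  stats::setNames(as.integer(tab), gene_ids)
}

#' Normalize a count table to per-library proportions
#'
#' Each count is divided by its sample's total library size.
#'
#' @param ct A [count_table()].
#' @return Matrix of proportions with the count table's dimensions.
#' @export
normalize_counts <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  if (any(ct$lib_sizes <= 0)) stop("zero library total")
  sweep(ct$counts, 2, ct$lib_sizes, "/")
}

#' Baggerley's weighted proportions test for replicated count libraries
#'
#' Two-sample test on per-gene proportions that models between-replicate
#' overdispersion beta-binomially. Within each group the proportion is
#' estimated as a variance-minimizing weighted mean of the replicate
#' proportions (weights `1/(1/n_i + theta)`, iterated with a moment
#' estimate of the overdispersion `theta`); the statistic is
#' `(pA - pB) / sqrt(Var(pA) + Var(pB))`, referred to the standard normal
#' (two-sided). The signed fold change is the ratio of normalized group
#' means under the convention: ratio `r >= 1` reported as `r`, `r < 1` as
#' `-1/r` (a 0.5 pseudo-count enters the fold's group mean counts only,
#' never the test).
#'
#' @param counts_a,counts_b Matrices (genes x replicates) of counts for
#'   the two groups (vectors are treated as single genes).
#' @param totals_a,totals_b Per-replicate library totals.
#' @return `data.frame`: `statistic`, `p_value`, `fold` (signed),
#'   `prop_a`, `prop_b`.
#' @export
baggerley_test <- function(counts_a, totals_a, counts_b, totals_b) {
  if (is.vector(counts_a)) counts_a <- matrix(counts_a, nrow = 1)
  if (is.vector(counts_b)) counts_b <- matrix(counts_b, nrow = 1)
  stopifnot(ncol(counts_a) == length(totals_a),
            ncol(counts_b) == length(totals_b),
            nrow(counts_a) == nrow(counts_b))
  if (all(totals_a <= 0) || all(totals_b <= 0)) stop("group with all-zero totals")
  ga <- .bag_group(counts_a, totals_a)
  gb <- .bag_group(counts_b, totals_b)
  se <- sqrt(ga$var + gb$var)
  stat <- ifelse(se > 0, (ga$p - gb$p) / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  ## signed fold from normalized mean counts with 0.5 pseudo-count
  ma <- (rowMeans(counts_a) + 0.5) / mean(totals_a)
  mb <- (rowMeans(counts_b) + 0.5) / mean(totals_b)
  ratio <- ma / mb
  fold <- ifelse(ratio >= 1, ratio, -1 / ratio)
  data.frame(statistic = stat, p_value = p, fold = fold,
             prop_a = ga$p, prop_b = gb$p)
}

## weighted per-group proportion estimate with beta-binomial moment
## overdispersion (vectorized over genes)
.bag_group <- function(counts, totals, n_iter = 10L) {
  ngene <- nrow(counts); nrep <- ncol(counts)
  n <- matrix(totals, ngene, nrep, byrow = TRUE)
  pi_hat <- counts / n
  theta <- numeric(ngene)
  for (it in seq_len(n_iter)) {
    vw <- 1 / sweep(1 / n, 1, theta, "+")    # inverse variance factors
    w <- vw / rowSums(vw)
    p <- rowSums(w * pi_hat)
    ## moment re-estimate: E[ sum w_i (p_i - p)^2 ] =
    ##   p(1-p) * sum w_i (1-w_i) (1/n_i + theta)
    Q <- rowSums(w * (pi_hat - p)^2)
    a <- rowSums(w * (1 - w) / n)
    b <- rowSums(w * (1 - w))
    pq <- p * (1 - p)
    theta_new <- ifelse(pq > 0 & b > 0, pmax(0, (Q / pq - a) / b), 0)
    if (max(abs(theta_new - theta)) < 1e-12) { theta <- theta_new; break }
    theta <- theta_new
  }
  vw <- 1 / sweep(1 / n, 1, theta, "+")
  w <- vw / rowSums(vw)
  p <- rowSums(w * pi_hat)
  v <- p * (1 - p) * rowSums(w^2 * sweep(1 / n, 1, theta, "+"))
  list(p = p, var = v, theta = theta)
}

#' Differential expression over a count table's contrasts
#'
#' Runs [baggerley_test()] for `salt` vs `control` and `osmotic` vs
#' `control`. A gene is `expressed` when it has at least one read in some
#' sample. No multiple-testing correction is applied by default;
#' Benjamini-Hochberg adjusted p-values are added when `fdr = TRUE`.
#'
#' @param ct A [count_table()] with control/salt/osmotic conditions.
#' @param contrasts Conditions to compare against control.
#' @param fdr Add BH-adjusted p-values per contrast.
#' @return `data.frame` of class `de_result`: `gene_id`, `expressed`, then
#'   per contrast `fold_<c>`, `p_<c>` (and `padj_<c>` with `fdr`).
#' @export
de_analysis <- function(ct, contrasts = c("salt", "osmotic"), fdr = FALSE) {
  stopifnot(inherits(ct, "count_table"))
  ctrl <- ct$condition == "control"
  if (!any(ctrl)) stop("no control samples")
  out <- data.frame(gene_id = rownames(ct$counts),
                    expressed = rowSums(ct$counts) > 0,
                    stringsAsFactors = FALSE)
  for (cond in contrasts) {
    sel <- ct$condition == cond
    if (!any(sel)) stop("no samples for condition ", cond)
    bt <- baggerley_test(ct$counts[, sel, drop = FALSE], ct$lib_sizes[sel],
                         ct$counts[, ctrl, drop = FALSE], ct$lib_sizes[ctrl])
    out[[paste0("fold_", cond)]] <- bt$fold
    out[[paste0("p_", cond)]] <- bt$p_value
    if (fdr) out[[paste0("padj_", cond)]] <- stats::p.adjust(bt$p_value, "BH")
  }
  class(out) <- c("de_result", "data.frame")
  out
}

#' Call up/down gene sets and the two-condition Venn
#'
#' A gene is called per contrast when it is expressed, its p-value is at
#' most `p_cut` and its signed fold is at least `fold_cut` in magnitude.
#' The Venn is computed separately for up- and down-regulated sets:
#' condition-only cells and the shared cell.
#'
#' @param de A [de_analysis()] result.
#' @param p_cut,fold_cut Thresholds (defaults 0.05 and 2).
#' @param contrasts The two contrasts to intersect.
#' @return A list of class `de_calls`: `up`, `down` (lists of gene-id
#'   vectors per contrast), `venn` (`data.frame` `direction`, `cell`,
#'   `n`).
#' @export
call_de <- function(de, p_cut = 0.05, fold_cut = 2,
                    contrasts = c("salt", "osmotic")) {
  sets <- list(up = list(), down = list())
  for (cond in contrasts) {
    f <- de[[paste0("fold_", cond)]]
    p <- de[[paste0("p_", cond)]]
    ok <- de$expressed & !is.na(p) & p <= p_cut
    sets$up[[cond]] <- de$gene_id[ok & f >= fold_cut]
    sets$down[[cond]] <- de$gene_id[ok & f <= -fold_cut]
  }
  venn <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    a <- sets[[dir]][[contrasts[1]]]; b <- sets[[dir]][[contrasts[2]]]
    data.frame(direction = dir,
               cell = c(paste0(contrasts[1], "_only"),
                        paste0(contrasts[2], "_only"), "shared"),
               n = c(length(setdiff(a, b)), length(setdiff(b, a)),
                     length(intersect(a, b))),
               stringsAsFactors = FALSE)
  }))
  structure(list(up = sets$up, down = sets$down, venn = venn,
                 contrasts = contrasts),
            class = "de_calls")
}

#' @export
print.de_calls <- function(x, ...) {
  cat("de_calls (p/fold thresholds applied):\n")
  print(x$venn)
  invisible(x)
}

#' COG category composition of DE gene sets
#'
#' Expresses, per direction, the number of called genes in each COG
#' category as a percentage of all called genes in that direction, split
#' by condition specificity (first-condition-only / second-only / shared).
#' Dual-letter categories count once under the dual label; genes without a
#' category fall into `unassigned`. Percentages over categories (including
#' `unassigned`) sum to 100 within a direction.
#'
#' @param calls A [call_de()] result.
#' @param annotations Gene records with `gene_id` and `cog_category`.
#' @return `data.frame`: `direction`, `category`, `specificity`, `n`,
#'   `percent` (of the direction's total).
#' @export
cog_summary <- function(calls, annotations) {
  stopifnot(inherits(calls, "de_calls"))
  cog_of <- stats::setNames(annotations$cog_category, annotations$gene_id)
  out <- list()
  for (dir in c("up", "down")) {
    a <- calls[[dir]][[calls$contrasts[1]]]
    b <- calls[[dir]][[calls$contrasts[2]]]
    total <- length(union(a, b))
    if (!total) next
    spec <- c(stats::setNames(rep(paste0(calls$contrasts[1], "_only"),
                                  length(setdiff(a, b))), setdiff(a, b)),
              stats::setNames(rep(paste0(calls$contrasts[2], "_only"),
                                  length(setdiff(b, a))), setdiff(b, a)),
              stats::setNames(rep("shared", length(intersect(a, b))),
                              intersect(a, b)))
    cats <- cog_of[names(spec)]
    cats[is.na(cats)] <- "unassigned"
    tab <- as.data.frame(table(category = cats, specificity = spec),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, ]
    out[[dir]] <- data.frame(direction = dir, category = tab$category,
                             specificity = tab$specificity, n = tab$Freq,
                             percent = 100 * tab$Freq / total,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
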