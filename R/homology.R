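## All-vs-all similarity search: Smith-Waterman local alignment (affine
## gaps, via Biostrings), Karlin-Altschul bit scores and E-values, and the
## bit-score-ratio (BSR) homology criterion.

#' Alignment scoring scheme with Karlin-Altschul statistics
#'
#' Packages the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw alignment scores into bit
#' scores and E-values. Defaults are the standard gapped BLOSUM62 set for
#' proteins (lambda = 0.267, K = 0.041, gap open 11 / extend 1) and a
#' +2/-3 match/mismatch scheme with gap open 5 / extend 2 for nucleotides
#' (lambda = 0.625, K = 0.41). All values are configurable.
#'
#' @param type `"protein"` or `"dna"`.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length g
#'   costs `gap_open + g * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters (`lambda > 0`, `K > 0`).
#' @param match,mismatch Nucleotide match reward / mismatch penalty
#'   (ignored for proteins, which use BLOSUM62).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(type = c("protein", "dna"),
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL,
                           match = 2, mismatch = -3) {
  type <- match.arg(type)
  if (type == "protein") {
    mat <- .blosum62()
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    lambda <- lambda %||% 0.267
    K <- K %||% 0.041
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = TRUE)
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
    lambda <- lambda %||% 0.625
    K <- K %||% 0.41
  }
  stopifnot(lambda > 0, K > 0, gap_open > 0, gap_extend > 0)
  structure(list(type = type, matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gap penalties under the
#' given scoring scheme. The traceback is deterministic, so repeated calls
#' return identical alignments.
#'
#' @param a,b Sequences (plain strings) over the scheme's alphabet.
#' @param scheme A [scoring_scheme()].
#' @param search_space Effective search space m*n used for the E-value;
#'   defaults to `nchar(a) * nchar(b)`.
#' @return One-row `data.frame` with the hit fields: `query_id`,
#'   `subject_id` (names of `a`/`b` if set), `raw_score`, `bit_score`,
#'   `e_value`, `identity_fraction`, `hsp_length`, `query_cov`,
#'   `subject_cov`.
#' @export
align_local <- function(a, b, scheme = scoring_scheme("protein"),
                        search_space = NULL) {
  hits <- align_local_many(stats::setNames(as.character(a), names(a) %||% "query"),
                           stats::setNames(as.character(b), names(b) %||% "subject"),
                           scheme, search_space = search_space)
  hits
}

## Vectorized pairwise local alignment: patterns[i] vs subjects[i].
align_local_many <- function(patterns, subjects, scheme,
                             search_space = NULL) {
  stopifnot(length(patterns) == length(subjects))
  if (any(nchar(patterns) == 0) || any(nchar(subjects) == 0)) {
    stop("empty sequence")
  }
  alpha <- rownames(scheme$matrix)
  res <- .sw_batch(unname(as.character(patterns)), unname(as.character(subjects)),
                   scheme$matrix, alpha, scheme$gap_open, scheme$gap_extend)
  ss <- search_space %||% (nchar(patterns) * nchar(subjects))
  be <- bit_and_evalue(res$raw_score, scheme, search_space = ss)
  empty <- res$raw_score <= 0
  out <- data.frame(
    query_id = names(patterns) %||% as.character(seq_along(patterns)),
    subject_id = names(subjects) %||% as.character(seq_along(subjects)),
    raw_score = res$raw_score,
    bit_score = be$bit_score,
    e_value = be$e_value,
    identity_fraction = ifelse(res$hsp_length > 0, res$nmatch / res$hsp_length, 0),
    hsp_length = res$hsp_length,
    query_cov = ifelse(empty, 0, (res$q_end - res$q_start + 1) / nchar(patterns)),
    subject_cov = ifelse(empty, 0, (res$s_end - res$s_start + 1) / nchar(subjects)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Convert a raw alignment score to a bit score and E-value
#'
#' `bit = (lambda * raw - ln K) / ln 2`; `E = search_space * 2^(-bit)`.
#' A raw score of 0 maps to the finite floor `-ln(K)/ln(2)` bits.
#'
#' @param raw_score Nonnegative raw score(s).
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @param search_space Effective search space m*n.
#' @return `list(bit_score =, e_value =)`, vectorized over `raw_score`.
#' @export
bit_and_evalue <- function(raw_score, scheme, search_space) {
  stopifnot(all(raw_score >= 0), all(search_space > 0))
  bits <- (scheme$lambda * raw_score - log(scheme$K)) / log(2)
  list(bit_score = bits, e_value = search_space * 2^(-bits))
}

## Raw self-alignment score: every residue aligned to itself (diagonal
## substitution scores are the maxima, so no gaps ever help).
.self_raw <- function(seqs, scheme) {
  mat <- scheme$matrix
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(mat[cbind(ch, ch)])
  }, numeric(1))
}

## Shared-k-mer prefilter: candidate pairs (i < j) sharing >= min_shared
## distinct k-mers. Hyper-common k-mers (in > max_group seqs) are skipped.
.kmer_candidates <- function(seqs, k, min_shared, max_group = 200L) {
  n <- length(seqs)
  L <- nchar(seqs)
  nk <- pmax(L - k + 1L, 0L)
  g <- rep.int(seq_len(n), nk)
  starts <- sequence(nk)
  dt <- data.table::data.table(
    kmer = substring(rep.int(unname(seqs), nk), starts, starts + k - 1L), g = g)
  dt <- unique(dt)                      # distinct k-mers per sequence
  data.table::setkey(dt, kmer)
  sz <- dt[, list(n = .N), by = "kmer"]
  keep <- sz[sz$n >= 2L & sz$n <= max_group, ][["kmer"]]
  dt <- dt[data.table::data.table(kmer = keep), on = "kmer"]
  if (!nrow(dt)) return(data.table::data.table(i = integer(0), j = integer(0)))
  j <- dt[dt, on = "kmer", allow.cartesian = TRUE]
  j <- j[j$g < j$i.g, ]
  pairs <- j[, list(nsh = .N), by = c("g", "i.g")]
  pairs <- pairs[pairs$nsh >= min_shared, ]
  data.table::data.table(i = pairs$g, j = pairs[["i.g"]])
}

#' All-vs-all similarity search over a panel's gene set
#'
#' Computes local alignments for every candidate gene pair (after an
#' optional shared-k-mer prefilter), with bit scores, E-values against the
#' whole-pool search space, and the bit-score ratio
#' `bsr = bit(a,b) / max(bit(a,a), bit(b,b))`. Self-hits are included, so
#' the table is a complete input for [homology_edges()] and the pangenome
#' stage.
#'
#' @param genes Gene records `data.frame` (`gene_id`, `protein_seq`,
#'   `cds_seq`) or a named character vector of sequences.
#' @param type `"protein"` or `"dna"` (selects the sequence column and the
#'   default scheme).
#' @param scheme Optional [scoring_scheme()] override.
#' @param prefilter Use the shared-k-mer prefilter (`k` = 4 for proteins,
#'   12 for DNA; pairs sharing fewer than `min_shared` k-mers are skipped).
#'   Disable to force full all-vs-all dynamic programming.
#' @param k,min_shared Prefilter parameters.
#' @param chunk Alignment batch size.
#' @return `data.frame` of hits (one row per unordered pair with a
#'   positive-scoring alignment, plus one self-hit row per gene):
#'   `query_id`, `subject_id`, `raw_score`, `bit_score`, `e_value`,
#'   `identity_fraction`, `hsp_length`, `query_cov`, `subject_cov`, `bsr`.
#'   E-values use search space `length(query) * total database residues`.
#' @export
homology_search <- function(genes, type = c("protein", "dna"),
                            scheme = NULL, prefilter = TRUE,
                            k = NULL, min_shared = 5L, chunk = 5000L) {
  type <- match.arg(type)
  seqs <- if (is.data.frame(genes)) {
    stats::setNames(if (type == "protein") genes$protein_seq else genes$cds_seq,
                    genes$gene_id)
  } else genes
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  scheme <- scheme %||% scoring_scheme(type)
  k <- k %||% if (type == "protein") 4L else 12L
  n <- length(seqs)
  n_total <- sum(nchar(seqs))

  self_raw <- .self_raw(seqs, scheme)
  self_be <- bit_and_evalue(self_raw, scheme, search_space = nchar(seqs) * n_total)
  self_hits <- data.frame(
    query_id = names(seqs), subject_id = names(seqs),
    raw_score = self_raw, bit_score = self_be$bit_score,
    e_value = self_be$e_value, identity_fraction = 1,
    hsp_length = nchar(seqs), query_cov = 1, subject_cov = 1,
    stringsAsFactors = FALSE)

  cand <- if (prefilter) {
    .kmer_candidates(seqs, k = k, min_shared = min_shared)
  } else {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    data.table::data.table(i = idx[, "row"], j = idx[, "col"])
  }
  cross <- NULL
  if (nrow(cand)) {
    parts <- split(seq_len(nrow(cand)), (seq_len(nrow(cand)) - 1L) %/% chunk)
    cross <- do.call(rbind, lapply(parts, function(ix) {
      a <- seqs[cand$i[ix]]; b <- seqs[cand$j[ix]]
      align_local_many(a, b, scheme, search_space = nchar(a) * n_total)
    }))
    cross <- cross[cross$raw_score > 0, , drop = FALSE]
  }
  hits <- rbind(self_hits, cross)
  rownames(hits) <- NULL
  self_bits <- stats::setNames(self_be$bit_score, names(seqs))
  hits$bsr <- hits$bit_score /
    pmax(self_bits[hits$query_id], self_bits[hits$subject_id])
  hits
}

#' Bit-score ratio between two genes from a hit table
#'
#' `bsr(a, b) = bit(a, b) / max(bit(a, a), bit(b, b))`. Using the larger of
#' the two self scores as the denominator makes the ratio symmetric in its
#' arguments; `bsr(a, a) = 1`.
#'
#' @param hits Hit table from [homology_search()] (self-hits required).
#' @param a,b Gene ids.
#' @return The ratio in `[0, 1]`, or 0 if the pair has no hit.
#' @export
bsr <- function(hits, a, b) {
  selfs <- hits[hits$query_id == hits$subject_id, ]
  sa <- selfs$bit_score[match(a, selfs$query_id)]
  sb <- selfs$bit_score[match(b, selfs$query_id)]
  if (is.na(sa) || is.na(sb)) stop("missing self-hit for ", if (is.na(sa)) a else b)
  if (a == b) return(1)
  row <- hits[(hits$query_id == a & hits$subject_id == b) |
              (hits$query_id == b & hits$subject_id == a), ]
  if (!nrow(row)) return(0)
  max(row$bit_score) / max(sa, sb)
}

#' Homology edges from a hit table
#'
#' Filters the all-vs-all hit table down to an undirected homology edge
#' list under one of the study's two criteria: E-value at most `1e-5`, or
#' bit-score ratio of at least 0.30 ("equal to or higher", so a pair
#' exactly at the threshold is kept). Edge weights for downstream Markov
#' clustering are `-log10(E)` capped at 200 (raw bit score available via
#' `weight_by`).
#'
#' @param hits Hit table from [homology_search()].
#' @param mode `"bsr"` or `"evalue"`.
#' @param threshold Cutoff; defaults 0.30 (bsr) / 1e-5 (evalue).
#' @param weight_by `"neglog_evalue"` (default) or `"bit_score"`.
#' @return `data.frame`: `from`, `to`, `weight`, `bsr`, `e_value`.
#' @export
homology_edges <- function(hits, mode = c("bsr", "evalue"), threshold = NULL,
                           weight_by = c("neglog_evalue", "bit_score")) {
  mode <- match.arg(mode)
  weight_by <- match.arg(weight_by)
  threshold <- threshold %||% if (mode == "bsr") 0.30 else 1e-5
  cross <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  keep <- if (mode == "bsr") cross$bsr >= threshold else cross$e_value <= threshold
  cross <- cross[keep, , drop = FALSE]
  w <- if (weight_by == "bit_score") cross$bit_score else
    pmin(-log10(pmax(cross$e_value, 1e-200)), 200)
  out <- data.frame(from = cross$query_id, to = cross$subject_id,
                    weight = w, bsr = cross$bsr, e_value = cross$e_value,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
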