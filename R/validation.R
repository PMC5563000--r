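## qPCR delta-delta-Ct validation, qPCR vs RNA-seq fold-change agreement,
## MIC/MTC phenotype calling from dose-response growth tables, and
## per-vesicle nitrogenase activity normalization.

#' Signed fold-change convention shared by RNA-seq and qPCR results
#'
#' Expression ratios at or above 1 are reported as-is; ratios below 1 as
#' the negative reciprocal (`0.25 -> -4`).
#'
#' @param ratio Positive expression ratio(s).
#' @return Signed fold(s).
#' @export
signed_fold <- function(ratio) {
  stopifnot(all(ratio > 0))
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

## inverse of the convention: signed fold -> plain ratio. Printed values
## with magnitude below 1 (nonstandard but they occur) are taken as
## already being ratios.
.fold_to_ratio <- function(s) {
  ifelse(s >= 1, s, ifelse(s <= -1, -1 / s, abs(s)))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = mean Ct(target) - mean Ct(normalizer)` over
#' technical replicates; `ddCt = mean dCt(treated) - mean dCt(control)`
#' over biological replicates; fold `= 2^(-ddCt)` reported under the
#' signed convention. Significance is a two-sided two-sample t-test on the
#' per-replicate dCt values. A global Ct shift in any sample cancels in
#' dCt, so the fold is unaffected.
#'
#' @param ct A `ct_table` ([simulate_ct()] layout: `sample`, `condition`,
#'   `replicate`, `gene`, `tech_rep`, `ct`) or any data.frame with those
#'   columns.
#' @param target Gene id to quantify.
#' @param treated,control Condition labels.
#' @param normalizer Reference gene id (defaults to the table's
#'   `normalizer` attribute).
#' @return One-row `data.frame`: `target`, `ddct`, `fold` (signed),
#'   `p_value`, `n_treated`, `n_control`.
#' @export
ddct_fold <- function(ct, target, treated, control,
                      normalizer = attr(ct, "normalizer")) {
  if (is.null(normalizer)) stop("normalizer not specified")
  stopifnot(all(c("sample", "condition", "gene", "ct") %in% names(ct)))
  for (g in c(target, normalizer)) {
    for (cond in c(treated, control)) {
      if (!any(ct$gene == g & ct$condition == cond)) {
        stop(g, " not measured under condition ", cond)
      }
    }
  }
  mean_ct <- stats::aggregate(ct ~ sample + condition + gene,
                              data = ct[ct$gene %in% c(target, normalizer), ],
                              FUN = mean)
  dct <- merge(mean_ct[mean_ct$gene == target, c("sample", "condition", "ct")],
               mean_ct[mean_ct$gene == normalizer, c("sample", "ct")],
               by = "sample", suffixes = c("_t", "_n"))
  dct$dct <- dct$ct_t - dct$ct_n
  tr <- dct$dct[dct$condition == treated]
  co <- dct$dct[dct$condition == control]
  ddct <- mean(tr) - mean(co)
  fold <- signed_fold(2^(-ddct))
  p <- if (length(tr) >= 2 && length(co) >= 2) {
    tryCatch(stats::t.test(tr, co)$p.value,
             error = function(e) if (isTRUE(all.equal(mean(tr), mean(co)))) 1 else NA_real_)
  } else {
    NA_real_
  }
  data.frame(target = target, ddct = ddct, fold = fold, p_value = p,
             n_treated = length(tr), n_control = length(co),
             stringsAsFactors = FALSE)
}

#' Correlation between qPCR and RNA-seq fold changes
#'
#' Pearson correlation over paired fold-change estimates of the same
#' genes/contrasts by the two platforms. Signed folds are a discontinuous
#' encoding (the interval (-1, 1) is unreachable), so by default both
#' vectors are mapped back to plain expression ratios before correlating
#' (`transform = "ratio"`); `"signed"` correlates the folds exactly as
#' given and `"log2"` correlates log2 ratios.
#'
#' @param qpcr_folds,rnaseq_folds Numeric vectors of signed folds, same
#'   length and order (at least 3 pairs).
#' @param transform `"ratio"` (default), `"signed"` or `"log2"`.
#' @return Pearson correlation coefficient.
#' @export
fold_correlation <- function(qpcr_folds, rnaseq_folds,
                             transform = c("ratio", "signed", "log2")) {
  transform <- match.arg(transform)
  stopifnot(length(qpcr_folds) == length(rnaseq_folds),
            length(qpcr_folds) >= 3)
  x <- switch(transform,
              ratio = .fold_to_ratio(qpcr_folds),
              signed = qpcr_folds,
              log2 = log2(.fold_to_ratio(qpcr_folds)))
  y <- switch(transform,
              ratio = .fold_to_ratio(rnaseq_folds),
              signed = rnaseq_folds,
              log2 = log2(.fold_to_ratio(rnaseq_folds)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in fold vector")
  stats::cor(x, y)
}

#' Call MTC and MIC from a dose-response growth table
#'
#' MTC (maximum tolerable concentration) is the highest concentration
#' whose mean yield is not significantly below the 0-mM control (one-sided
#' two-sample t-test at `alpha`). MIC (minimum inhibitory concentration)
#' is the lowest concentration whose mean yield is at most
#' `mic_fraction` of the control mean; if none qualifies the MIC is
#' reported as `Inf` (above the tested range). Both are members of the
#' tested grid; MTC is capped at MIC. Scaling all yields by a positive
#' constant leaves the calls unchanged.
#'
#' @param growth `data.frame` with `strain`, `concentration`, `replicate`,
#'   `yield` ([simulate_growth()] layout).
#' @param alpha MTC test level.
#' @param mic_fraction Fraction of control mean at or below which growth
#'   counts as inhibited.
#' @return `data.frame`: `strain`, `mtc`, `mic` (`Inf` = above range).
#' @export
call_tolerance <- function(growth, alpha = 0.05, mic_fraction = 0.05) {
  stopifnot(all(c("strain", "concentration", "yield") %in% names(growth)))
  if (any(growth$concentration < 0)) stop("negative concentrations")
  out <- list()
  for (s in unique(growth$strain)) {
    g <- growth[growth$strain == s, ]
    conc <- sort(unique(g$concentration))
    if (conc[1] != 0) stop("no 0-mM control for strain ", s)
    ctrl <- g$yield[g$concentration == 0]
    if (length(ctrl) < 2) stop("control needs >= 2 replicates")
    if (mean(ctrl) <= 0) stop("control mean yield <= 0 for strain ", s)
    higher <- conc[-1]
    not_affected <- vapply(higher, function(cc) {
      y <- g$yield[g$concentration == cc]
      if (stats::sd(y) == 0 && stats::sd(ctrl) == 0) return(mean(y) >= mean(ctrl))
      stats::t.test(y, ctrl, alternative = "less")$p.value >= alpha
    }, logical(1))
    mtc <- if (any(not_affected)) max(higher[not_affected]) else 0
    inhibited <- vapply(higher, function(cc)
      mean(g$yield[g$concentration == cc]) <= mic_fraction * mean(ctrl),
      logical(1))
    mic <- if (any(inhibited)) min(higher[inhibited]) else Inf
    out[[s]] <- data.frame(strain = s, mtc = min(mtc, mic), mic = mic,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Nitrogenase activity per vesicle
#'
#' @param activity Activity (e.g. nmol ethylene per time unit).
#' @param vesicles Vesicle count (per mg protein); must be positive.
#' @return Activity per vesicle, vectorized.
#' @export
per_vesicle_activity <- function(activity, vesicles) {
  if (any(vesicles <= 0)) stop("vesicle count must be positive")
  activity / vesicles
}
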