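## Readers and writers for the package's on-disk formats: FASTA gene sets
## (via Biostrings) and the tab-separated tables every stage emits.

#' Read a panel's gene records from per-strain FASTA files
#'
#' Expects the layout written by [write_strain_fasta()]: `<strain>.faa`
#' (protein) and `<strain>.fna` (CDS) per strain, and optionally
#' `annotations.tsv` with `gene_id`, `product`, `cog_category`.
#'
#' @param dir Directory of FASTA files.
#' @return Gene records `data.frame` (`gene_id`, `genome_id`,
#'   `protein_seq`, `cds_seq`, `product`, `cog_category`).
#' @export
read_gene_records <- function(dir) {
  faa <- list.files(dir, pattern = "\\.faa$", full.names = TRUE)
  if (!length(faa)) stop("no .faa files in ", dir)
  rows <- lapply(faa, function(f) {
    strain <- sub("\\.faa$", "", basename(f))
    aa <- Biostrings::readAAStringSet(f)
    fn <- file.path(dir, paste0(strain, ".fna"))
    nt <- if (file.exists(fn)) Biostrings::readDNAStringSet(fn) else NULL
    data.frame(gene_id = names(aa), genome_id = strain,
               protein_seq = as.character(aa),
               cds_seq = if (!is.null(nt)) as.character(nt)[match(names(aa), names(nt))]
                         else NA_character_,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  ann_file <- file.path(dir, "annotations.tsv")
  if (file.exists(ann_file)) {
    ann <- utils::read.delim(ann_file, stringsAsFactors = FALSE)
    genes$product <- ann$product[match(genes$gene_id, ann$gene_id)]
    genes$cog_category <- ann$cog_category[match(genes$gene_id, ann$gene_id)]
  } else {
    genes$product <- NA_character_
    genes$cog_category <- NA_character_
  }
  rownames(genes) <- NULL
  genes
}

#' Write a hit table, cluster table, or any stage table as TSV
#'
#' Plain tab-separated output with a header row and no quoting, the format
#' all of the package's tables use on disk.
#'
#' @param x A `data.frame`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the square identity matrices as TSVs
#'
#' One file per metric (`ani.tsv`, `aai.tsv`, `ggd.tsv`) with genome names
#' as row and column headers; GGD additionally as `ggd_x1000.tsv` on the
#' display scale.
#'
#' @param im An [identity_matrix()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_identity_matrices <- function(im, dir) {
  stopifnot(inherits(im, "identity_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(ani = "ani.tsv", aai = "aai.tsv", ggd = "ggd.tsv")
  out <- character(0)
  for (m in names(files)) {
    p <- file.path(dir, files[[m]])
    utils::write.table(im[[m]], p, sep = "\t", quote = FALSE, col.names = NA)
    out <- c(out, p)
  }
  p <- file.path(dir, "ggd_x1000.tsv")
  utils::write.table(im$ggd * 1000, p, sep = "\t", quote = FALSE, col.names = NA)
  invisible(c(out, p))
}

#' Bundled qPCR-vs-RNA-seq fold-change validation table
#'
#' The published 11-gene validation panel of a salt-stressed *Frankia*
#' strain: signed fold changes (treatment vs control) measured by qRT-PCR
#' and by RNA-seq for the salt and osmotic contrasts, 22 pairs in total.
#' Used to reproduce the platform-agreement correlation.
#'
#' @return `data.frame`: `locus_tag`, `contrast`, `qpcr_fold`,
#'   `rnaseq_fold`.
#' @export
qpcr_validation_folds <- function() {
  path <- system.file("extdata", "qpcr_rnaseq_folds.tsv", package = "panstress")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
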