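#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide codes -> allowed bases. N deliberately matches nothing
## in the scanner (ambiguous promoter bases are never counted as hits), so
## it is excluded here and handled explicitly.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G")
)

#' Reverse-complement a DNA string (IUPAC-aware)
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  vapply(x, function(s) {
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(b), names(comp))
    if (length(bad)) stop("invalid nucleotide code(s): ", paste(bad, collapse = ","))
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Deterministic per-stage seed derived from one root seed. Keeps every
## stage's randomness reproducible and independent of execution order.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100000L) * 20011L + (h %% 19997L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a gene x sample count matrix from TSV
#'
#' Expects gene identifiers in the first column and one column per sample.
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("negative counts in ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  m
}

#' Write a gene x sample matrix as TSV
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Columns: sample, condition (C/T), day, replicate.
#' @param path TSV file path.
#' @return a validated sample design data.frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(df)
}

#' Validate a sample design
#'
#' The layout mirrors a shared-baseline two-arm time course: day 0 exists
#' only under the control condition, and every (condition, day) cell carries
#' at least two replicates.
#' @param design data.frame with columns sample, condition, day, replicate.
#' @return the design, invisibly classed as `sample_design`.
#' @export
validate_design <- function(design) {
  need <- c("sample", "condition", "day", "replicate")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (!all(design$condition %in% c("C", "T")))
    stop("condition must be 'C' or 'T'")
  if (any(design$day == 0 & design$condition == "T"))
    stop("day 0 exists only under condition C (shared baseline)")
  tab <- table(paste(design$condition, design$day))
  if (any(tab < 2)) stop("each (condition, day) cell needs >= 2 replicates")
  if (anyDuplicated(design$sample)) stop("duplicate sample ids")
  class(design) <- c("sample_design", "data.frame")
  design
}

#' Read a gene-length table (gene TAB length)
#' @param path TSV file path.
#' @return named numeric vector of lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  len <- df[[2]]
  names(len) <- df[[1]]
  if (any(len <= 0)) stop("gene lengths must be positive")
  len
}

#' Read promoter sequences from FASTA
#' @param path FASTA path; one record per gene, sequence 5'->3' ending
#'   immediately before the ATG.
#' @return named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write promoter sequences to FASTA
#' @param promoters named character vector.
#' @param path output path.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters)
  names(ss) <- names(promoters)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gene annotation table
#' @param path TSV with columns gene, term and optionally namespace.
#' @return data.frame(gene, term, namespace).
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"namespace" %in% names(df)) df$namespace <- "default"
  df[, c("gene", "term", "namespace")]
}
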