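#' Read sequences from a FASTA file
#'
#' Parses a FASTA file into the package's sequence tibble. Record ids are the
#' header token before the first whitespace; residues are upper-cased.
#' Ambiguity symbols (N and other IUPAC codes; X/B/Z/U in protein) are kept —
#' they are excluded later, at k-mer counting.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @return A tibble with columns `id`, `seq` (see [seq_tbl()]).
#' @export
read_fasta <- function(path, alphabet = c("DNA", "PROTEIN")) {
  alphabet <- match_alphabet(match.arg(alphabet))
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  seq_tbl(ids, as.character(set), alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a sequence tibble (columns `id`, `seq`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract promoter windows upstream of annotated genes
#'
#' Returns the strand-aware sequence window immediately upstream of each gene
#' feature's 5' end: for a `+` strand gene the `window` bases ending just
#' before the gene start; for a `-` strand gene the reverse complement of the
#' `window` bases starting just after the gene end. Windows are clipped at
#' chromosome boundaries and may be shorter than `window`; genes whose window
#' is empty after clipping, or whose chromosome is absent from the genome, are
#' skipped with a warning. GFF3 coordinates are 1-based, fully closed.
#'
#' @param genome path to a genome FASTA file.
#' @param annotation path to a GFF3 file; features with `type == "gene"` are
#'   used (all features if none is typed `gene`).
#' @param window upstream window size in bp (default 5000, the 5 kb promoter
#'   region used throughout the package).
#' @return A DNA sequence tibble, one record per extracted promoter, named by
#'   the gene's `ID` attribute (or Name, or a seqid:start-end fallback).
#' @export
extract_promoters <- function(genome, annotation, window = 5000L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) abort("`window` must be a positive integer")
  chrom <- Biostrings::readDNAStringSet(genome)
  names(chrom) <- sub("\\s.*$", "", names(chrom))
  gr <- rtracklayer::import(annotation, format = "gff3")
  if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene")) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  if (length(gr) == 0) abort("no gene features in annotation")
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids <- ifelse(is.na(ids) | !nzchar(ids),
                paste0(GenomeInfoDb::seqnames(gr), ":",
                       GenomicRanges::start(gr), "-", GenomicRanges::end(gr)),
                ids)

  out_id <- character(0)
  out_seq <- character(0)
  for (i in seq_along(gr)) {
    sid <- as.character(GenomeInfoDb::seqnames(gr)[i])
    if (!sid %in% names(chrom)) {
      warn(paste0("gene ", ids[i], ": seqid '", sid, "' absent from genome; skipped"))
      next
    }
    len <- length(chrom[[sid]])
    strand <- as.character(BiocGenerics::strand(gr)[i])
    if (strand == "-") {
      lo <- GenomicRanges::end(gr)[i] + 1L
      hi <- min(GenomicRanges::end(gr)[i] + window, len)
    } else {
      # unstranded features treated as '+'
      lo <- max(GenomicRanges::start(gr)[i] - window, 1L)
      hi <- GenomicRanges::start(gr)[i] - 1L
    }
    if (lo > hi || hi < 1L || lo > len) {
      warn(paste0("gene ", ids[i], ": empty promoter window after clipping; skipped"))
      next
    }
    s <- as.character(Biostrings::subseq(chrom[[sid]], start = lo, end = hi))
    if (strand == "-") s <- revcomp(s)
    out_id <- c(out_id, ids[i])
    out_seq <- c(out_seq, s)
  }
  if (length(out_id) == 0) abort("no promoters could be extracted")
  seq_tbl(out_id, out_seq, "DNA")
}

#' Read a gene-by-tissue expression table
#'
#' Reads a tab-delimited table whose header row names the tissues and whose
#' first column holds gene ids; empty cells or `NA` denote missing values.
#' The result is a long tibble — one row per (gene, tissue) cell — with `NA`
#' in `value` marking missing measurements, the layout every labeling and
#' feature-building function in the package consumes.
#'
#' @param path path to the tab-delimited file.
#' @return A tibble with columns `gene`, `tissue`, `value`.
#' @export
read_expression <- function(path) {
  wide <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            na.strings = c("NA", ""), colClasses = "character")
  if (ncol(wide) < 2) abort("expression table needs a gene column and at least one tissue")
  names(wide)[1] <- "gene"
  vals <- suppressWarnings(
    as.data.frame(lapply(wide[-1], as.numeric), check.names = FALSE, optional = TRUE)
  )
  bad <- which(vapply(seq_along(vals), function(j)
    any(is.na(vals[[j]]) & !is.na(wide[[j + 1]])), logical(1)))
  if (length(bad)) abort(paste0("non-numeric expression values in column '",
                                names(wide)[bad[1] + 1], "'"))
  expr <- dplyr::bind_cols(tibble(gene = as.character(wide$gene)), as_tibble(vals)) |>
    tidyr::pivot_longer(-"gene", names_to = "tissue", values_to = "value")
  validate_expression(expr)
}

#' @rdname read_expression
#' @param expr a long expression tibble (`gene`, `tissue`, `value`).
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  wide <- tidyr::pivot_wider(expr, names_from = "tissue", values_from = "value")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Validate a long expression tibble
#'
#' Enforces the matrix invariants: unique (gene, tissue) cells, unique tissue
#' names, all present values non-negative, and at least one present value per
#' gene.
#'
#' @param expr a tibble with columns `gene`, `tissue`, `value`.
#' @return `expr`, with `gene` and `tissue` coerced to character.
#' @export
validate_expression <- function(expr) {
  need <- c("gene", "tissue", "value")
  if (!all(need %in% names(expr))) {
    abort("expression table must have columns gene, tissue, value")
  }
  expr <- as_tibble(expr)
  expr$gene <- as.character(expr$gene)
  expr$tissue <- as.character(expr$tissue)
  expr$value <- as.numeric(expr$value)
  if (anyDuplicated(expr[c("gene", "tissue")])) {
    abort("duplicate gene ids within a tissue")
  }
  if (any(expr$value < 0, na.rm = TRUE)) abort("negative expression value")
  present <- tapply(!is.na(expr$value), expr$gene, any)
  if (!all(present)) {
    abort(paste0("gene(s) with no present value in any tissue: ",
                 paste(head(names(present)[!present], 3), collapse = ", ")))
  }
  expr
}
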