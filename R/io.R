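#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and every character outside `{A, C, G, T, N}`
#' (including IUPAC ambiguity codes) is mapped to `N`. Record order is
#' preserved.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- names(set)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA identifier: ", dup[1])
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Accepts BED3/BED4 (tab-separated); an optional fourth column becomes the
#' interval label. Coordinates are kept 0-based half-open exactly as stored.
#'
#' @param path Path to the BED file.
#' @return A `genomic_interval` data frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file must have >= 3 tab-separated columns")
  start <- suppressWarnings(as.numeric(tab[[2]]))
  end <- suppressWarnings(as.numeric(tab[[3]]))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad) > 0L)
    stop("non-integer BED coordinates on line ", bad[1])
  bad <- which(start >= end)
  if (length(bad) > 0L)
    stop("BED start >= end on line ", bad[1])
  label <- if (ncol(tab) >= 4L) tab[[4]] else NA_character_
  genomic_interval(tab[[1]], start, end, label)
}

#' Write intervals to BED
#'
#' @param intervals A `genomic_interval` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, c("chrom", "start", "end")]
  cols$start <- format(cols$start, scientific = FALSE, trim = TRUE)
  cols$end <- format(cols$end, scientific = FALSE, trim = TRUE)
  if ("label" %in% names(intervals) && !all(is.na(intervals$label)))
    cols$label <- intervals$label
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNVs from a VCF file
#'
#' Only biallelic single-nucleotide substitutions are retained: records with
#' indel alleles, multiallelic ALT fields, symbolic alleles, or ambiguous
#' bases are skipped, and the skipped count is reported with a message and
#' attached as attribute `skipped`.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @return Data frame with columns `chrom`, `pos` (1-based, as stored),
#'   `ref`, `alt`; attribute `skipped` holds the number of excluded records.
#' @export
read_snvs <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  if (any(is.na(pos)))
    stop("malformed VCF record (non-numeric POS) at data line ",
         which(is.na(pos))[1])
  keep <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T") &
    ref != alt
  skipped <- sum(!keep)
  if (skipped > 0L)
    message("read_snvs: skipped ", skipped,
            " non-biallelic-SNV record(s) in ", basename(path))
  out <- data.frame(chrom = chrom[keep], pos = pos[keep],
                    ref = ref[keep], alt = alt[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write SNVs as a minimal sorted VCF
#'
#' @param snps Data frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path, contigs = NULL) {
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=fragilescan", con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contigs), as.integer(contigs)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(snps) > 0L)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       snps$chrom, as.integer(snps$pos),
                       snps$ref, snps$alt), con)
  invisible(path)
}
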