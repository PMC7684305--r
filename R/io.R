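# Readers and writers for the on-disk formats: paired FASTQ (Phred+33),
# taxonomy-annotated reference FASTA, OTU/census TSV tables, metadata TSV.

#' Read a pair of positionally paired FASTQ files
#'
#' Qualities are Phred+33 (no autodetection). Records are paired by position;
#' a record-count mismatch is an error.
#'
#' @param path_fwd,path_rev FASTQ files (optionally gzipped).
#' @return object of class `fastq_pairs`: list with `id`, `fwd_seq`,
#'   `fwd_qual`, `rev_seq`, `rev_qual` (qualities as Phred+33 strings; decode
#'   with [decode_phred()]).
#' @export
read_fastq_pairs <- function(path_fwd, path_rev) {
  fwd <- read_fastq_one(path_fwd)
  rev <- read_fastq_one(path_rev)
  if (length(fwd$seq) != length(rev$seq))
    stop("pairing error: ", length(fwd$seq), " forward vs ",
         length(rev$seq), " reverse records")
  structure(list(id = fwd$id,
                 fwd_seq = fwd$seq, fwd_qual = fwd$qual,
                 rev_seq = rev$seq, rev_qual = rev$qual),
            class = "fastq_pairs")
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) diagnose_fastq(path, conditionMessage(e)))
  list(id = names(x),
       seq = unname(as.character(x)),
       qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

# Locate the offending record when the fast parser fails.
diagnose_fastq <- function(path, msg) {
  lines <- readLines(path)
  n <- length(lines)
  rec <- 0L
  i <- 1L
  while (i <= n) {
    rec <- rec + 1L
    if (i + 3L > n)
      stop("parse error in ", path, " at record ", rec,
           ": truncated record")
    if (!startsWith(lines[i], "@") || !startsWith(lines[i + 2L], "+") ||
        nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      stop("parse error in ", path, " at record ", rec, ": malformed record")
    i <- i + 4L
  }
  stop("parse error in ", path, ": ", msg)
}

#' Write a FASTQ file
#'
#' @param path output path (`.gz` suffix triggers compression).
#' @param id record identifiers.
#' @param seq sequences.
#' @param qual Phred+33 quality strings of matching lengths.
#' @export
write_fastq <- function(path, id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual),
            all(nchar(seq) == nchar(qual)))
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Reference database -----------------------------------------------------

#' Read a taxonomy-annotated reference barcode FASTA
#'
#' Headers carry `id|level1;...;level6|habitat` with exactly six
#' semicolon-separated taxonomy levels and habitat `planktonic` or `benthic`.
#' Sequences outside the marker length window (default 68-196 nt, the 37f
#' hypervariable region) are dropped with a warning.
#'
#' @param path FASTA file.
#' @param length_window numeric length 2; allowed sequence length range.
#' @return a `ref_db` data.frame with columns `id`, `seq`, `taxonomy`
#'   (semicolon path), `habitat`.
#' @export
read_reference_fasta <- function(path, length_window = c(68, 196)) {
  x <- Biostrings::readDNAStringSet(path)
  ref_db(names(x), as.character(x), length_window = length_window)
}

ref_db <- function(headers, seqs, length_window = c(68, 196)) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("format error: header without id|taxonomy|habitat at record ",
         bad[1])
  id <- vapply(parts, `[`, character(1), 1)
  taxonomy <- vapply(parts, `[`, character(1), 2)
  habitat <- vapply(parts, `[`, character(1), 3)
  nlev <- lengths(strsplit(taxonomy, ";", fixed = TRUE))
  if (any(nlev != 6))
    stop("format error: taxonomy path with ", nlev[nlev != 6][1],
         " levels (6 required) in record '", id[nlev != 6][1], "'")
  if (anyDuplicated(id))
    stop("format error: duplicate record identifier '",
         id[duplicated(id)][1], "'")
  if (!all(habitat %in% c("planktonic", "benthic")))
    stop("format error: habitat must be 'planktonic' or 'benthic'")
  keep <- nchar(seqs) >= length_window[1] & nchar(seqs) <= length_window[2]
  if (any(!keep))
    warning(sum(!keep), " reference record(s) outside the length window [",
            length_window[1], ", ", length_window[2], "] dropped")
  structure(data.frame(id = unname(id[keep]),
                       seq = unname(toupper(seqs[keep])),
                       taxonomy = unname(taxonomy[keep]),
                       habitat = unname(habitat[keep]),
                       stringsAsFactors = FALSE),
            class = c("ref_db", "data.frame"))
}

#' Write a reference database as annotated FASTA
#'
#' @param db a `ref_db` data.frame.
#' @param path output path.
#' @export
write_reference_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$seq)
  names(x) <- paste(db$id, db$taxonomy, db$habitat, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Split a 6-level taxonomy path string into a character matrix.
taxonomy_levels <- function(taxonomy) {
  do.call(rbind, strsplit(taxonomy, ";", fixed = TRUE))
}

# OTU table ---------------------------------------------------------------

#' Write / read an OTU table as TSV
#'
#' OTUs are rows and samples are columns; `taxonomy` and `habitat` trail as
#' annotation columns. Counts are raw integers.
#'
#' @param table list with `counts` (integer matrix, OTUs x samples) and
#'   `annotation` (data.frame with rownames matching `counts`, columns
#'   `taxonomy` and `habitat`), as produced by [otu_table()].
#' @param path file path.
#' @return `read_otu_table` returns the same structure.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(is.matrix(table$counts),
            identical(rownames(table$counts), rownames(table$annotation)))
  ptax <- table$annotation$planktonic_taxon
  if (is.null(ptax)) ptax <- ""
  df <- data.frame(otu_id = rownames(table$counts),
                   table$counts,
                   taxonomy = table$annotation$taxonomy,
                   habitat = table$annotation$habitat,
                   planktonic_taxon = ptax,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  ann_cols <- intersect(c("taxonomy", "habitat", "planktonic_taxon"),
                        names(df))
  sample_cols <- setdiff(names(df), c("otu_id", ann_cols))
  counts_chr <- as.matrix(df[, sample_cols, drop = FALSE])
  suppressWarnings(counts_num <- matrix(as.numeric(counts_chr),
                                        nrow = nrow(counts_chr)))
  if (anyNA(counts_num) || any(counts_num != floor(counts_num)))
    stop("format error: non-integer count cell in ", path)
  counts <- matrix(as.integer(counts_num), nrow = nrow(df),
                   dimnames = list(df$otu_id, sample_cols))
  annotation <- data.frame(df[, ann_cols, drop = FALSE],
                           row.names = df$otu_id, stringsAsFactors = FALSE)
  list(counts = counts, annotation = annotation)
}

# Metadata and census tables ----------------------------------------------

#' Read sample metadata
#'
#' Requires columns `sample`, `site`, `depth_cm_top`, `depth_cm_bottom`,
#' `zone` (one of `LC`, `transition`, `NAC`).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "site", "depth_cm_top", "depth_cm_bottom", "zone")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(md$zone %in% c("LC", "transition", "NAC")))
    stop("zone must be one of LC, transition, NAC")
  md
}

#' Write a generic TSV table
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a census-count table
#'
#' Samples as rows (column `sample`), taxa as the remaining integer columns.
#'
#' @param path TSV file.
#' @return list with `counts` (samples x taxa integer matrix).
#' @export
read_census_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("census table lacks 'sample' column")
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  if (any(m != floor(m))) stop("format error: non-integer census count")
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  list(counts = m)
}
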