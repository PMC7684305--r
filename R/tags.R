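# Latin-square tagged-primer scheme used for inline demultiplexing.

#' Build a Latin-square tag scheme
#'
#' Every sample unit (a PCR replicate) receives a unique combination of an
#' 8-nt forward tag and an 8-nt reverse tag attached to the amplification
#' primers. Tag pairs are assigned on a cyclic Latin square over `k` forward
#' and `k` reverse tags (`k = ceiling(sqrt(n))`), so each forward tag meets
#' each reverse tag at most once. Tags within each pool are drawn with a
#' minimum pairwise Hamming distance (default 5) so that demultiplexing with
#' up to 2 construct mismatches can never be ambiguous.
#'
#' @param sample_ids character vector of unique sample-unit identifiers.
#' @param fwd_primer,rev_primer primer sequences appended 3' of the tags.
#' @param tag_length tag length in nt (default 8).
#' @param min_tag_dist minimum pairwise Hamming distance within a tag pool.
#' @param seed integer seed for tag drawing.
#' @return object of class `tag_scheme`: a list with `samples` (data.frame of
#'   sample, fwd_tag, rev_tag), `fwd_tags`, `rev_tags`, and the primers.
#' @export
tag_scheme <- function(sample_ids, fwd_primer, rev_primer,
                       tag_length = 8, min_tag_dist = 5, seed = 1) {
  if (anyDuplicated(sample_ids)) stop("sample identifiers must be unique")
  n <- length(sample_ids)
  if (n < 1) stop("need at least one sample")
  k <- ceiling(sqrt(n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fwd_tags <- draw_tag_pool(k, tag_length, min_tag_dist)
  rev_tags <- draw_tag_pool(k, tag_length, min_tag_dist)
  i <- seq_len(n) - 1L
  f <- (i %% k) + 1L
  r <- (((i %/% k) + (i %% k)) %% k) + 1L
  samples <- data.frame(sample = sample_ids,
                        fwd_tag = fwd_tags[f],
                        rev_tag = rev_tags[r],
                        stringsAsFactors = FALSE)
  scheme <- structure(list(samples = samples,
                           fwd_tags = fwd_tags, rev_tags = rev_tags,
                           fwd_primer = toupper(fwd_primer),
                           rev_primer = toupper(rev_primer)),
                      class = "tag_scheme")
  validate_tag_scheme(scheme)
  scheme
}

draw_tag_pool <- function(k, tag_length, min_dist) {
  pool <- character(0)
  tries <- 0L
  while (length(pool) < k) {
    cand <- random_dna(1, tag_length)
    ok <- TRUE
    if (length(pool) > 0) {
      d <- hamming_cross_cpp(cand, pool)
      ok <- all(d >= min_dist)
    }
    if (ok) pool <- c(pool, cand)
    tries <- tries + 1L
    if (tries > 20000L)
      stop("could not draw ", k, " tags at Hamming distance >= ", min_dist)
  }
  pool
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat("tag_scheme:", nrow(x$samples), "sample units,",
      length(x$fwd_tags), "fwd x", length(x$rev_tags), "rev tags\n")
  invisible(x)
}

validate_tag_scheme <- function(x) {
  s <- x$samples
  tags <- c(x$fwd_tags, x$rev_tags, s$fwd_tag, s$rev_tag)
  if (!all(grepl("^[ACGT]+$", tags))) stop("tags must be over {A,C,G,T}")
  if (length(unique(nchar(tags))) != 1) stop("tags must share one length")
  if (anyDuplicated(paste(s$fwd_tag, s$rev_tag)))
    stop("tag pair combinations must be unique")
  invisible(x)
}

#' Write / read a tag scheme as TSV
#'
#' The file stores the per-sample tag assignment with the primers in a header
#' comment so a scheme file is self-contained.
#'
#' @param scheme a [tag_scheme()] object.
#' @param path file path.
#' @return `read_tag_scheme` returns a `tag_scheme`.
#' @export
write_tag_scheme <- function(scheme, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# fwd_primer=", scheme$fwd_primer),
               paste0("# rev_primer=", scheme$rev_primer)), con)
  write.table(scheme$samples, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_scheme
#' @export
read_tag_scheme <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fp <- sub("^# fwd_primer=", "", grep("fwd_primer=", hdr, value = TRUE))
  rp <- sub("^# rev_primer=", "", grep("rev_primer=", hdr, value = TRUE))
  if (length(fp) != 1 || length(rp) != 1)
    stop("tag scheme file lacks primer header lines")
  tab <- read.delim(text = lines[!grepl("^#", lines)],
                    stringsAsFactors = FALSE)
  scheme <- structure(list(samples = tab,
                           fwd_tags = unique(tab$fwd_tag),
                           rev_tags = unique(tab$rev_tag),
                           fwd_primer = fp, rev_primer = rp),
                      class = "tag_scheme")
  validate_tag_scheme(scheme)
  scheme
}

# Save/restore the global RNG state so seeded constructors do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
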