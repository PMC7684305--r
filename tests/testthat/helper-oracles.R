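# Independent oracles used to cross-check the implementation.

# Global-alignment oracle: memoised top-down recursion over prefixes, with a
# traceback applying the documented tie preference (diagonal, then gap in
# the second sequence, then gap in the first). Implemented independently of
# the package's iterative dynamic program.
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  m <- length(ca)
  n <- length(cb)
  memo <- matrix(NA_real_, m + 1, n + 1)
  S <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    val <- if (i == 0 && j == 0) {
      0
    } else {
      cand <- -Inf
      if (i > 0 && j > 0)
        cand <- max(cand,
                    S(i - 1, j - 1) + if (ca[i] == cb[j]) match else mismatch)
      if (i > 0) cand <- max(cand, S(i - 1, j) + gap)
      if (j > 0) cand <- max(cand, S(i, j - 1) + gap)
      cand
    }
    memo[i + 1, j + 1] <<- val
    val
  }
  score <- S(m, n)
  i <- m; j <- n; matches <- 0L; columns <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S(i, j) == S(i - 1, j - 1) +
          (if (ca[i] == cb[j]) match else mismatch)) {
      if (ca[i] == cb[j]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    columns <- columns + 1L
  }
  list(score = score, matches = matches, columns = columns,
       identity = matches / columns)
}

# All-shift overlap scan: largest k >= min_overlap whose forward suffix
# equals the reverse-complement prefix, testing every shift explicitly.
overlap_oracle <- function(fwd, rev_rc, min_overlap) {
  kmax <- min(nchar(fwd), nchar(rev_rc))
  best <- 0L
  for (k in seq_len(kmax)) {
    if (substr(fwd, nchar(fwd) - k + 1, nchar(fwd)) ==
        substr(rev_rc, 1, k) && k >= min_overlap) {
      best <- k
    }
  }
  best
}

# Exhaustive two-parent breakpoint search (no parent pruning): is any splice
# of two sufficiently abundant sequences at least `min_id` identical to the
# query and closer than its best single parent?
chimera_oracle <- function(seqs, totals, ratio = 2, min_id = 0.99) {
  n <- length(seqs)
  flags <- logical(n)
  for (q in seq_len(n)) {
    par <- which(totals >= ratio * totals[q] & seq_len(n) != q)
    if (length(par) < 2) next
    best_single <- max(vapply(par, function(p)
      nw_identity(seqs[q], seqs[p]), numeric(1)))
    if (best_single == 1) next
    found <- FALSE
    for (a in par) for (b in setdiff(par, a)) {
      A <- seqs[a]; B <- seqs[b]
      for (k in seq_len(min(nchar(A), nchar(B)) - 1L)) {
        model <- paste0(substr(A, 1, k), substr(B, k + 1, nchar(B)))
        id <- nw_identity(seqs[q], model)
        if (id >= min_id && id > best_single) { found <- TRUE; break }
      }
      if (found) break
    }
    flags[q] <- found
  }
  flags
}

# Random DNA helper for fixtures.
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Substitute specific positions to a different base, deterministically.
sub_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# Minimal reference database object for unit fixtures.
make_refdb <- function(id, seq, habitat,
                       taxonomy = paste("Foraminifera", "Globothalamea",
                                        "OrderX", "FamilyX", "GenusX", id,
                                        sep = ";")) {
  data.frame(id = id, seq = seq, taxonomy = taxonomy, habitat = habitat,
             stringsAsFactors = FALSE)
}

# Write a fastq pair from a reads data.frame (as simulate_reads returns).
write_pair_files <- function(reads, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  f1 <- file.path(dir, "r1.fastq")
  f2 <- file.path(dir, "r2.fastq")
  write_fastq(f1, reads$id, reads$fwd_seq, reads$fwd_qual)
  write_fastq(f2, reads$id, reads$rev_seq, reads$rev_qual)
  list(fwd = f1, rev = f2)
}
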