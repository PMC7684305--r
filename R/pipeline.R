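# The amplicon-processing chain: quality filter -> exact-overlap merge ->
# tagged-primer demultiplex -> chimera removal -> dereplication to ISUs ->
# NW taxonomic assignment -> 5'-signature pre-clustering -> average-linkage
# OTU delineation -> planktonic/benthic classification -> occupancy filter.

#' Per-mate mean-quality filter
#'
#' A pair is kept iff the mean Phred score of each mate is strictly greater
#' than the threshold.
#'
#' @param fwd_qual,rev_qual Phred+33 quality strings.
#' @param mean_phred_min threshold (strict).
#' @return logical keep vector.
#' @export
quality_filter <- function(fwd_qual, rev_qual, mean_phred_min = 30) {
  phred_means(fwd_qual) > mean_phred_min &
    phred_means(rev_qual) > mean_phred_min
}

#' Merge read pairs by exact suffix/prefix overlap
#'
#' The reverse mate is reverse-complemented, then the largest exact overlap
#' between the forward suffix and the reverse-complement prefix of length at
#' least `min_overlap` is used; no mismatches are tolerated in the overlap.
#' Pairs without a qualifying overlap are rejected (`NA`).
#'
#' @param fwd_seq,rev_seq mate sequences.
#' @param min_overlap minimum exact overlap (default 12).
#' @return character vector of merged sequences, `NA` where rejected.
#' @export
merge_pairs <- function(fwd_seq, rev_seq, min_overlap = 12) {
  stopifnot(length(fwd_seq) == length(rev_seq), min_overlap >= 1)
  if (any(nchar(fwd_seq) == 0) || any(nchar(rev_seq) == 0))
    stop("mates must be non-empty")
  rc <- revcomp(rev_seq)
  k <- find_overlap_cpp(fwd_seq, rc, as.integer(min_overlap))
  out <- rep(NA_character_, length(fwd_seq))
  hit <- k > 0
  out[hit] <- paste0(fwd_seq[hit],
                     substr(rc[hit], k[hit] + 1, nchar(rc[hit])))
  out
}

#' Demultiplex merged reads on inline tagged primers
#'
#' Hamming distances are computed between the observed 5' block and every
#' sample's forward tag+primer construct, and between the observed 3' block
#' and every reverse-complemented reverse construct; the two distances are
#' summed. A read is assigned to the unique sample with the minimal summed
#' distance `<= max_mismatch`; ties and misses are never guessed
#' (`unassigned`). The constructs are stripped from the returned insert.
#'
#' @param merged merged read sequences.
#' @param scheme a [tag_scheme()] (carries the primers).
#' @param max_mismatch maximum summed construct mismatches (default 2).
#' @return data.frame with `sample` (`NA` if unassigned) and `insert`.
#' @export
demultiplex <- function(merged, scheme, max_mismatch = 2) {
  lf <- nchar(scheme$samples$fwd_tag[1]) + nchar(scheme$fwd_primer)
  lr <- nchar(scheme$samples$rev_tag[1]) + nchar(scheme$rev_primer)
  cons_f <- paste0(scheme$samples$fwd_tag, scheme$fwd_primer)
  cons_r <- revcomp(paste0(scheme$samples$rev_tag, scheme$rev_primer))
  u <- unique(merged)
  L <- nchar(u)
  long_enough <- L >= lf + lr + 1
  obs_f <- substr(u, 1, lf)
  obs_r <- substr(u, L - lr + 1, L)
  sample_u <- rep(NA_character_, length(u))
  if (any(long_enough)) {
    d <- hamming_cross_cpp(obs_f[long_enough], cons_f) +
      hamming_cross_cpp(obs_r[long_enough], cons_r)
    best <- apply(d, 1, min)
    nbest <- rowSums(d == best)
    hit <- best <= max_mismatch & nbest == 1
    idx <- apply(d, 1, which.min)
    sample_u[long_enough][hit] <- scheme$samples$sample[idx[hit]]
  }
  insert_u <- substr(u, lf + 1, L - lr)
  m <- match(merged, u)
  data.frame(sample = sample_u[m], insert = insert_u[m],
             stringsAsFactors = FALSE)
}

#' Dereplicate demultiplexed inserts into ISUs
#'
#' Identical full-length sequences collapse into one Individual Sequence
#' Unit with per-sample counts. ISUs are ordered by decreasing total
#' abundance, ties broken lexicographically on sequence.
#'
#' @param sample sample label per insert.
#' @param insert insert sequence per read.
#' @return list with `seq` (ISU sequences), `counts` (ISU x sample integer
#'   matrix), `total`.
#' @export
dereplicate <- function(sample, insert) {
  stopifnot(length(sample) == length(insert))
  keep <- !is.na(sample) & !is.na(insert) & nchar(insert) > 0
  sample <- sample[keep]; insert <- insert[keep]
  tab <- table(insert, sample)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  total <- rowSums(counts)
  o <- order(-total, rownames(counts))
  counts <- counts[o, , drop = FALSE]
  list(seq = rownames(counts), counts = counts,
       total = rowSums(counts))
}

#' Flag chimeric ISUs with a two-parent breakpoint model
#'
#' Simplified de novo detector: scanning ISUs in decreasing abundance, a
#' query is flagged when two unflagged, more abundant parents (each at least
#' `min_parent_ratio` times the query abundance) admit a single-breakpoint
#' splice whose identity to the query is at least `min_identity` and exceeds
#' the query's best single-parent identity. Only the `max_parents` parents
#' most similar to the query are combined.
#'
#' @param seqs ISU sequences, ordered by decreasing abundance.
#' @param totals ISU total abundances.
#' @param config a [pipeline_config()] (chimera settings and NW scoring).
#' @return logical flag vector.
#' @export
detect_chimeras <- function(seqs, totals, config = pipeline_config()) {
  n <- length(seqs)
  flags <- logical(n)
  if (n < 3 || !isTRUE(config$chimera$enabled)) return(flags)
  sc <- config$nw
  ratio <- config$chimera$min_parent_ratio
  min_id <- config$chimera$min_identity
  maxp <- config$chimera$max_parents
  o <- order(-totals, seqs)
  for (qi in o) {
    eligible <- which(!flags & totals >= ratio * totals[qi] &
                        seq_len(n) != qi)
    if (length(eligible) < 2) next
    ids <- nw_identity_cross_cpp(seqs[qi], seqs[eligible],
                                 sc$match, sc$mismatch, sc$gap)[1, ]
    best_single <- max(ids)
    if (best_single == 1) next
    par <- eligible[order(-ids)][seq_len(min(maxp, length(eligible)))]
    models <- character(0)
    for (a in par) for (b in setdiff(par, a)) {
      A <- seqs[a]; B <- seqs[b]
      ks <- seq_len(min(nchar(A), nchar(B)) - 1L)
      models <- c(models,
                  paste0(substring(A, 1, ks),
                         substring(B, ks + 1, nchar(B))))
    }
    models <- unique(models)
    mid <- nw_identity_cross_cpp(seqs[qi], models,
                                 sc$match, sc$mismatch, sc$gap)[1, ]
    if (max(mid) >= min_id && max(mid) > best_single) flags[qi] <- TRUE
  }
  flags
}

#' Assign ISUs to reference taxonomy by best NW identity
#'
#' Identity is computed against every reference; if the best identity is not
#' strictly above `identity_floor` the ISU is unassigned. Otherwise all
#' references tied (within `tie_tol`) with the best hit vote, and the
#' deepest taxonomy prefix shared by all of them is returned.
#'
#' @param seqs ISU sequences.
#' @param refdb a `ref_db` data.frame.
#' @param identity_floor assignment floor (strict, default 0.80).
#' @param config a [pipeline_config()] (NW scoring).
#' @param tie_tol identity tolerance for ties (default 0 = exact ties).
#' @return data.frame with `taxonomy` (possibly truncated path, `NA` if
#'   unassigned) and `best_identity`.
#' @export
assign_isus <- function(seqs, refdb, identity_floor = 0.80,
                        config = pipeline_config(), tie_tol = 0) {
  if (nrow(refdb) == 0) stop("reference database is empty")
  sc <- config$nw
  idm <- nw_identity_cross_cpp(seqs, refdb$seq, sc$match, sc$mismatch,
                               sc$gap)
  best <- apply(idm, 1, max)
  tax <- rep(NA_character_, length(seqs))
  for (i in seq_along(seqs)) {
    if (best[i] <= identity_floor) next
    hits <- which(idm[i, ] >= best[i] - tie_tol)
    tax[i] <- consensus_taxonomy(refdb$taxonomy[hits])
  }
  data.frame(taxonomy = tax, best_identity = best,
             stringsAsFactors = FALSE)
}

# Deepest shared prefix of semicolon taxonomy paths.
consensus_taxonomy <- function(paths) {
  lev <- strsplit(paths, ";", fixed = TRUE)
  depth <- min(lengths(lev))
  out <- character(0)
  for (k in seq_len(depth)) {
    vals <- unique(vapply(lev, `[`, character(1), k))
    if (length(vals) > 1) break
    out <- c(out, vals)
  }
  paste(out, collapse = ";")
}

#' Pre-cluster ISUs by their 5' hypervariable signature
#'
#' Groups ISUs by exact match of their first `signature_length` bases; an
#' ISU shorter than the signature uses its full length.
#'
#' @param seqs ISU sequences (primer-stripped, 5'-anchored).
#' @param signature_length prefix length (default 30).
#' @return integer group index per ISU.
#' @export
precluster <- function(seqs, signature_length = 30) {
  sig <- substr(seqs, 1, signature_length)
  match(sig, unique(sig))
}

#' Delineate OTUs by average-linkage clustering within pre-clusters
#'
#' Pairwise NW distances (1 - identity) within each pre-cluster feed an
#' agglomerative average-linkage dendrogram cut at the group's threshold
#' (cluster heights at or below the cut merge). The threshold defaults to
#' `cluster$default_threshold`; a pre-cluster whose member assignments share
#' a taxonomy prefix listed in `cluster$taxonomy_thresholds` uses that
#' override. ISUs within a group are processed in lexicographic order so
#' distance ties resolve deterministically.
#'
#' @param isus a dereplication result (see [dereplicate()]).
#' @param assignments assignment table from [assign_isus()].
#' @param config a [pipeline_config()].
#' @return list of OTUs; each has `members` (ISU indices), `representative`
#'   (most abundant member sequence, ties lexicographic), `counts`
#'   (per-sample), `taxonomy` (consensus prefix of member assignments).
#' @export
cluster_otus <- function(isus, assignments, config = pipeline_config()) {
  groups <- precluster(isus$seq, config$precluster_signature_length)
  sc <- config$nw
  otus <- list()
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    idx <- idx[order(isus$seq[idx])]
    thr <- group_threshold(assignments$taxonomy[idx], config)
    if (length(idx) == 1) {
      membership <- 1L
    } else {
      idm <- nw_identity_self_cpp(isus$seq[idx], sc$match, sc$mismatch,
                                  sc$gap)
      d <- as.dist(1 - idm)
      membership <- cutree(hclust(d, method = "average"), h = thr)
    }
    for (m in sort(unique(membership))) {
      mem <- idx[membership == m]
      otus[[length(otus) + 1]] <- build_otu(isus, assignments, mem)
    }
  }
  # stable order: decreasing abundance, ties by representative sequence
  tot <- vapply(otus, function(o) sum(o$counts), numeric(1))
  rep_ <- vapply(otus, `[[`, character(1), "representative")
  otus <- otus[order(-tot, rep_)]
  names(otus) <- sprintf("OTU_%04d", seq_along(otus))
  otus
}

group_threshold <- function(taxonomies, config) {
  thr <- config$cluster$default_threshold
  over <- config$cluster$taxonomy_thresholds
  if (length(over) == 0) return(thr)
  taxonomies <- taxonomies[!is.na(taxonomies)]
  if (length(taxonomies) == 0) return(thr)
  cons <- consensus_taxonomy(taxonomies)
  # deepest matching prefix key wins
  keys <- names(over)
  hit <- keys[startsWith(cons, keys)]
  if (length(hit) == 0) return(thr)
  over[[hit[which.max(nchar(hit))]]]
}

build_otu <- function(isus, assignments, mem) {
  tot <- isus$total[mem]
  rep_i <- mem[order(-tot, isus$seq[mem])][1]
  counts <- colSums(isus$counts[mem, , drop = FALSE])
  tax <- assignments$taxonomy[mem]
  tax <- if (all(is.na(tax))) NA_character_ else
    consensus_taxonomy(tax[!is.na(tax)])
  list(members = mem, representative = isus$seq[rep_i],
       counts = counts, taxonomy = tax)
}

#' Classify OTUs as planktonic or benthic
#'
#' The representative sequence is compared against the planktonic references
#' only; the OTU is planktonic (and labelled with the best planktonic
#' taxon's species) iff its best identity is at least `otu_assign_identity`
#' (inclusive boundary). Everything else is considered benthic by exclusion.
#'
#' @param otus OTU list from [cluster_otus()].
#' @param refdb a `ref_db`; its planktonic records are used.
#' @param otu_assign_identity classification identity (default 0.95).
#' @param config a [pipeline_config()] (NW scoring).
#' @return the OTU list with `habitat` and `planktonic_taxon` added.
#' @export
classify_otus <- function(otus, refdb, otu_assign_identity = 0.95,
                          config = pipeline_config()) {
  pl <- refdb[refdb$habitat == "planktonic", , drop = FALSE]
  if (nrow(pl) == 0) stop("no planktonic references")
  sc <- config$nw
  reps <- vapply(otus, `[[`, character(1), "representative")
  idm <- nw_identity_cross_cpp(reps, pl$seq, sc$match, sc$mismatch, sc$gap)
  for (i in seq_along(otus)) {
    best <- max(idm[i, ])
    if (best >= otu_assign_identity) {
      # ties broken lexicographically on reference id
      hits <- which(idm[i, ] == best)
      hit <- hits[order(pl$id[hits])][1]
      otus[[i]]$habitat <- "planktonic"
      otus[[i]]$planktonic_taxon <- pl$id[hit]
    } else {
      otus[[i]]$habitat <- "benthic"
      otus[[i]]$planktonic_taxon <- NA_character_
    }
  }
  otus
}

#' Occupancy filter for OTUs
#'
#' Retains OTUs with nonzero counts in strictly more than `min_samples`
#' samples.
#'
#' @param otus classified OTU list.
#' @param min_samples occupancy threshold (default 3; "more than three").
#' @return filtered OTU list.
#' @export
filter_otus <- function(otus, min_samples = 3) {
  occ <- vapply(otus, function(o) sum(o$counts > 0), integer(1))
  otus[occ > min_samples]
}

#' Merge planktonic OTUs assigned to the same species
#'
#' Optional reporting step collapsing intragenomic variants: planktonic OTUs
#' sharing an identical species-level assignment merge into one unit with
#' summed abundances.
#'
#' @param otus classified OTU list.
#' @param enabled if `FALSE`, returns the input unchanged.
#' @return OTU list.
#' @export
merge_variant_otus <- function(otus, enabled = TRUE) {
  if (!enabled || length(otus) == 0) return(otus)
  taxon <- vapply(otus, function(o)
    if (is.null(o$planktonic_taxon)) NA_character_ else o$planktonic_taxon,
    character(1))
  merged <- list()
  done <- logical(length(otus))
  for (i in seq_along(otus)) {
    if (done[i]) next
    if (is.na(taxon[i])) {
      merged[[length(merged) + 1]] <- otus[[i]]
      done[i] <- TRUE
      next
    }
    grp <- which(!done & !is.na(taxon) & taxon == taxon[i])
    o <- otus[[grp[1]]]
    if (length(grp) > 1) {
      for (j in grp[-1]) {
        o$members <- c(o$members, otus[[j]]$members)
        o$counts <- o$counts + otus[[j]]$counts
      }
    }
    merged[[length(merged) + 1]] <- o
    done[grp] <- TRUE
  }
  tot <- vapply(merged, function(o) sum(o$counts), numeric(1))
  rep_ <- vapply(merged, `[[`, character(1), "representative")
  merged <- merged[order(-tot, rep_)]
  names(merged) <- sprintf("OTU_%04d", seq_along(merged))
  merged
}

#' OTU table from a classified OTU list
#'
#' @param otus classified OTU list.
#' @return list with `counts` (OTU x sample integer matrix) and
#'   `annotation` (taxonomy, habitat, planktonic_taxon), suitable for
#'   [write_otu_table()].
#' @export
otu_table <- function(otus) {
  counts <- do.call(rbind, lapply(otus, `[[`, "counts"))
  storage.mode(counts) <- "integer"
  rownames(counts) <- names(otus)
  annotation <- data.frame(
    taxonomy = vapply(otus, function(o)
      if (is.na(o$taxonomy) || o$taxonomy == "") "unassigned" else
        o$taxonomy, character(1)),
    habitat = vapply(otus, `[[`, character(1), "habitat"),
    planktonic_taxon = vapply(otus, function(o)
      if (is.na(o$planktonic_taxon)) "" else o$planktonic_taxon,
      character(1)),
    row.names = names(otus), stringsAsFactors = FALSE)
  list(counts = counts, annotation = annotation)
}

#' Run the full processing chain on a pair of FASTQ files
#'
#' Chains every stage with read accounting: at each stage the number of
#' surviving reads and itemized drops are logged, so that
#' `assigned + unassigned + dropped = raw` end to end.
#'
#' @param path_fwd,path_rev paired FASTQ files.
#' @param scheme a [tag_scheme()].
#' @param refdb a `ref_db` reference database.
#' @param config a [pipeline_config()].
#' @param verbose print per-stage counts.
#' @return list with `otus` (classified, filtered OTU list), `table`
#'   ([otu_table()] of the retained OTUs), `isus`, `assignments`, and `log`
#'   (data.frame of stage counts).
#' @export
run_pipeline <- function(path_fwd, path_rev, scheme, refdb,
                         config = pipeline_config(), verbose = FALSE) {
  pairs <- read_fastq_pairs(path_fwd, path_rev)
  n_raw <- length(pairs$id)
  keep_q <- quality_filter(pairs$fwd_qual, pairs$rev_qual,
                           config$mean_phred_min)
  merged <- rep(NA_character_, n_raw)
  merged[keep_q] <- merge_pairs(pairs$fwd_seq[keep_q],
                                pairs$rev_seq[keep_q],
                                config$min_overlap)
  n_merged <- sum(!is.na(merged))
  dmx <- demultiplex(merged[!is.na(merged)], scheme,
                     config$tag_mismatch_max)
  n_demux <- sum(!is.na(dmx$sample))
  isus0 <- dereplicate(dmx$sample, dmx$insert)
  chim <- detect_chimeras(isus0$seq, isus0$total, config)
  n_chimeric_reads <- sum(isus0$total[chim])
  isus <- list(seq = isus0$seq[!chim],
               counts = isus0$counts[!chim, , drop = FALSE],
               total = isus0$total[!chim])
  assignments <- assign_isus(isus$seq, refdb, config$identity_floor, config)
  otus_all <- cluster_otus(isus, assignments, config)
  otus_all <- classify_otus(otus_all, refdb, config$otu_assign_identity,
                            config)
  otus <- filter_otus(otus_all, config$min_samples_per_otu)
  otus <- merge_variant_otus(otus, config$merge_variants)
  log <- data.frame(
    stage = c("raw", "quality_filtered", "merged", "demultiplexed",
              "non_chimeric", "otus_total", "otus_retained"),
    reads = c(n_raw, sum(keep_q), n_merged, n_demux,
              n_demux - n_chimeric_reads,
              sum(vapply(otus_all, function(o) sum(o$counts), numeric(1))),
              sum(vapply(otus, function(o) sum(o$counts), numeric(1)))),
    units = c(n_raw, sum(keep_q), n_merged, n_demux,
              length(isus$seq), length(otus_all), length(otus)))
  if (verbose) {
    for (i in seq_len(nrow(log)))
      message(sprintf("%-18s %10d reads %8d units", log$stage[i],
                      log$reads[i], log$units[i]))
  }
  list(otus = otus, table = otu_table(otus), otus_all = otus_all,
       isus = isus, assignments = assignments, log = log)
}
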