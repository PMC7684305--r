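# Pipeline configuration: every threshold of the processing chain in one
# place, serializable to a YAML config file.

#' Pipeline configuration
#'
#' Collects the thresholds of the amplicon-processing chain. Defaults follow
#' the study conditions: per-mate mean Phred strictly above 30, a minimum
#' exact overlap of 12 bases for pair merging, at most 2 mismatches against
#' the tagged-primer constructs, taxonomic assignment floor strictly above
#' 0.80 identity, planktonic classification at >= 0.95 identity, and OTUs
#' retained when present in strictly more than 3 samples.
#'
#' @param mean_phred_min per-mate mean quality threshold (strict).
#' @param min_overlap minimum exact suffix/prefix overlap for merging.
#' @param tag_mismatch_max maximum summed mismatches over both tagged-primer
#'   constructs during demultiplexing.
#' @param identity_floor assignment identity floor (strict; below or equal is
#'   unassigned).
#' @param otu_assign_identity planktonic classification identity (inclusive).
#' @param min_samples_per_otu OTUs must occur in strictly more samples.
#' @param chimera list: `enabled`, `min_parent_ratio` (parent abundance must
#'   be at least this multiple of the query), `min_identity` (splice-model
#'   identity needed to flag), `max_parents` (candidate parents scanned).
#' @param cluster list: `default_threshold` (average-linkage cut height on
#'   1 - identity) and `taxonomy_thresholds` (named overrides keyed by a
#'   taxonomy prefix).
#' @param precluster_signature_length 5'-prefix length for pre-clustering.
#' @param nw an [nw_scoring()] object (stored as a plain list).
#' @param merge_variants merge planktonic OTUs sharing a species-level
#'   assignment into one reporting unit.
#' @param seed random seed recorded with the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mean_phred_min = 30,
                            min_overlap = 12,
                            tag_mismatch_max = 2,
                            identity_floor = 0.80,
                            otu_assign_identity = 0.95,
                            min_samples_per_otu = 3,
                            chimera = list(enabled = TRUE,
                                           min_parent_ratio = 2,
                                           min_identity = 0.99,
                                           max_parents = 4),
                            cluster = list(default_threshold = 0.03,
                                           taxonomy_thresholds = list()),
                            precluster_signature_length = 30,
                            nw = list(match = 1, mismatch = -1, gap = -2),
                            merge_variants = FALSE,
                            seed = 1) {
  cfg <- structure(list(mean_phred_min = mean_phred_min,
                        min_overlap = as.integer(min_overlap),
                        tag_mismatch_max = as.integer(tag_mismatch_max),
                        identity_floor = identity_floor,
                        otu_assign_identity = otu_assign_identity,
                        min_samples_per_otu = as.integer(min_samples_per_otu),
                        chimera = chimera,
                        cluster = cluster,
                        precluster_signature_length =
                          as.integer(precluster_signature_length),
                        nw = nw,
                        merge_variants = isTRUE(merge_variants),
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$min_overlap >= 1,
            cfg$tag_mismatch_max >= 0,
            cfg$identity_floor > 0,
            cfg$identity_floor < cfg$otu_assign_identity,
            cfg$otu_assign_identity <= 1,
            cfg$min_samples_per_otu >= 0,
            cfg$cluster$default_threshold > 0,
            cfg$precluster_signature_length >= 1)
  cfg
}

config_scoring <- function(cfg) {
  nw_scoring(cfg$nw$match, cfg$nw$mismatch, cfg$nw$gap)
}

#' Write / read a pipeline configuration file
#'
#' YAML serialization; `read_config(write_config(cfg))` reproduces `cfg`.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns a validated `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$cluster$taxonomy_thresholds))
    raw$cluster$taxonomy_thresholds <- list()
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config: phred>", x$mean_phred_min,
      " overlap>=", x$min_overlap,
      " tag_mm<=", x$tag_mismatch_max,
      " assign>", x$identity_floor,
      " planktonic>=", x$otu_assign_identity,
      " otu_samples>", x$min_samples_per_otu, "\n", sep = "")
  invisible(x)
}
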