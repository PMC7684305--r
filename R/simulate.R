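# Synthetic sediment-core metabarcoding studies: reference barcodes, depth-
# and zone-structured communities, tagged paired-end reads with ground truth,
# and coupled microfossil census counts.

#' Default synthetic taxon roster
#'
#' Nine planktonic morphospecies emulating the regional assemblage of the
#' Newfoundland margin (a polar dominant, transitional and temperate species,
#' three microperforates, one warm-advected species, and the two spinose
#' species whose forward-primer mismatches prevent amplification) plus
#' `n_benthic` generic benthic taxa. Per-zone base abundances encode the
#' polar (`LC`) / `transition` / temperate (`NAC`) compositional gradient.
#' The temperate *G. inflata* analogue carries a copy-number multiplier of 5
#' (rDNA over-representation); the *G. uvula* analogue is flagged for surface
#' enrichment.
#'
#' @param n_benthic number of benthic taxa (default 20).
#' @return data.frame of taxon specifications, one row per taxon.
#' @export
default_taxa <- function(n_benthic = 20) {
  pl <- data.frame(
    name = c("Neogloboquadrina_pachyderma", "Neogloboquadrina_incompta",
             "Globigerina_bulloides", "Turborotalita_quinqueloba",
             "Globorotalia_inflata", "Globigerinita_glutinata",
             "Globigerinita_uvula", "Tenuitella_fleisheri",
             "Globorotalia_hirsuta"),
    habitat = "planktonic",
    thermal = c("polar", "transitional", "transitional", "polar",
                "temperate", "transitional", "transitional", "transitional",
                "warm"),
    spinose = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    fwd_primer_mismatches = c(0L, 0L, 2L, 1L, 0L, 0L, 0L, 0L, 0L),
    copy_number_multiplier = c(1, 1, 1, 1, 5, 1, 1, 1, 1),
    surface_boost = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                      FALSE),
    base_LC = c(0.66, 0.08, 0.10, 0.06, 0.02, 0.03, 0.02, 0.01, 0.02),
    base_transition = c(0.30, 0.20, 0.18, 0.08, 0.10, 0.06, 0.04, 0.02,
                        0.02),
    base_NAC = c(0.10, 0.18, 0.18, 0.04, 0.25, 0.09, 0.06, 0.04, 0.06),
    stringsAsFactors = FALSE)
  w <- 0.6 ^ (seq_len(n_benthic) %% 7 + 1)
  w <- w / sum(w)
  be <- data.frame(
    name = sprintf("Benthic_sp%02d", seq_len(n_benthic)),
    habitat = "benthic", thermal = "transitional", spinose = FALSE,
    fwd_primer_mismatches = 0L, copy_number_multiplier = 1,
    surface_boost = FALSE,
    base_LC = w, base_transition = w, base_NAC = w,
    stringsAsFactors = FALSE)
  rbind(pl, be)
}

#' Default site layout across the hydrographic gradient
#'
#' @param n_LC,n_transition,n_NAC number of sites per hydrographic zone.
#' @return data.frame with columns `site`, `zone`.
#' @export
default_sites <- function(n_LC = 4, n_transition = 3, n_NAC = 3) {
  zones <- c(rep("LC", n_LC), rep("transition", n_transition),
             rep("NAC", n_NAC))
  data.frame(site = sprintf("S%02d", seq_along(zones)), zone = zones,
             stringsAsFactors = FALSE)
}

#' Contiguous core layers
#'
#' @param bottom core bottom depth (cm).
#' @param step layer thickness (cm); cores are extruded in 2-3 cm steps.
#' @return data.frame with columns `top`, `bottom`.
#' @export
core_layers <- function(bottom = 30, step = 2) {
  tops <- seq(0, bottom - step, by = step)
  data.frame(top = tops, bottom = tops + step)
}

#' Synthetic study design
#'
#' Bundles everything needed to generate a complete synthetic study. The
#' defaults are the study conditions the analysis assumes: a 30-cm core grid
#' in 2-cm layers across ten sites in three hydrographic zones, two PCR
#' replicates per sample, spinose primer dropout, a 5x copy-number multiplier
#' for the temperate dominant, and a 10x surface enrichment of the
#' *G. uvula* analogue above 4 cm.
#'
#' @param taxa taxon roster, see [default_taxa()].
#' @param sites site/zone table, see [default_sites()].
#' @param layers layer table (`top`, `bottom`), non-overlapping, ordered and
#'   contiguous from 0.
#' @param decay a [decay_params()] object driving the planktonic:benthic
#'   read-mass split.
#' @param error_rate per-base substitution rate of simulated reads.
#' @param chimera_rate fraction of reads replaced by two-parent splices.
#' @param reads_per_sample read pairs generated per sample unit.
#' @param replicates PCR replicates per sample (default 2; units are named
#'   `sample.rep1`, `sample.rep2`, ...).
#' @param read_length read length of each mate.
#' @param barcode_length length of the simulated 37f barcode (must fall in
#'   the 68-196 nt marker window).
#' @param divergence per-site substitution fraction separating taxa in the
#'   synthetic reference database.
#' @param fwd_primer,rev_primer synthetic primer sequences.
#' @param boost_factor,boost_max_depth surface-enrichment multiplier applied
#'   to `surface_boost` taxa in layers with midpoints above this depth (cm).
#' @param census_tests foraminiferal tests per census count.
#' @param benthic_shell_ratio planktonic:benthic shell ratio in the census.
#' @param seed master seed for the study.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(taxa = default_taxa(),
                              sites = default_sites(),
                              layers = core_layers(),
                              decay = decay_params(),
                              error_rate = 0,
                              chimera_rate = 0,
                              reads_per_sample = 2000,
                              replicates = 2,
                              read_length = 130,
                              barcode_length = 115,
                              divergence = 0.2,
                              fwd_primer = "ACCACAAGGAACGCAGGG",
                              rev_primer = "CCGCGGTAATTCCAGCTC",
                              boost_factor = 10,
                              boost_max_depth = 4,
                              census_tests = 250,
                              benthic_shell_ratio = 100,
                              seed = 1) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            replicates >= 1, read_length > 0,
            barcode_length >= 68, barcode_length <= 196)
  if (any(taxa$spinose & taxa$fwd_primer_mismatches < 1))
    stop("spinose taxa must carry at least one forward-primer mismatch")
  if (any(taxa$copy_number_multiplier <= 0))
    stop("copy-number multipliers must be positive")
  if (any(taxa$base_LC < 0 | taxa$base_transition < 0 | taxa$base_NAC < 0))
    stop("base abundances must be non-negative")
  o <- order(layers$top)
  layers <- layers[o, , drop = FALSE]
  if (any(layers$bottom <= layers$top) ||
      layers$top[1] != 0 ||
      (nrow(layers) > 1 &&
       any(abs(layers$top[-1] - layers$bottom[-nrow(layers)]) > 1e-9)))
    stop("layers must be ordered, non-overlapping and cover 0 to the core ",
         "bottom")
  structure(list(taxa = taxa, sites = sites, layers = layers, decay = decay,
                 error_rate = error_rate, chimera_rate = chimera_rate,
                 reads_per_sample = as.integer(reads_per_sample),
                 replicates = as.integer(replicates),
                 read_length = as.integer(read_length),
                 barcode_length = as.integer(barcode_length),
                 divergence = divergence,
                 fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 boost_factor = boost_factor,
                 boost_max_depth = boost_max_depth,
                 census_tests = as.integer(census_tests),
                 benthic_shell_ratio = benthic_shell_ratio,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

layer_midpoints <- function(layers) (layers$top + layers$bottom) / 2

zone_base <- function(taxa, zone) {
  switch(zone, LC = taxa$base_LC, transition = taxa$base_transition,
         NAC = taxa$base_NAC, stop("unknown zone: ", zone))
}

#' Simulate a taxonomy-annotated reference barcode database
#'
#' All taxa descend from one random ancestor of the requested length; each
#' taxon substitutes a fraction `divergence` of its sites. The draw is
#' rejected and repeated until the minimum pairwise alignment distance
#' between distinct taxa exceeds `min_separation`, which guarantees that taxa
#' are separable both at the OTU clustering cut and at the planktonic
#' classification identity; if that cannot be achieved the parameters are a
#' design error.
#'
#' @param n_planktonic,n_benthic taxon counts (>= 1).
#' @param divergence per-site substitution fraction, in (0, 0.5).
#' @param seed integer seed.
#' @param barcode_length sequence length (inside the 68-196 nt window).
#' @param taxa optional taxon roster supplying names and habitats (its first
#'   `n_planktonic` planktonic and `n_benthic` benthic rows are used).
#' @param min_separation required minimum pairwise NW distance.
#' @return a `ref_db` data.frame (see [read_reference_fasta()]).
#' @export
simulate_reference_db <- function(n_planktonic = 9, n_benthic = 20,
                                  divergence = 0.2, seed = 1,
                                  barcode_length = 115, taxa = NULL,
                                  min_separation = 0.1) {
  if (n_planktonic < 1 || n_benthic < 1) stop("taxon counts must be >= 1")
  if (divergence <= 0 || divergence >= 0.5)
    stop("design error: divergence must lie in (0, 0.5)")
  n_sub <- max(1L, round(divergence * barcode_length))
  if (n_sub / barcode_length <= min_separation / 2)
    stop("design error: divergence too small for separable taxa")
  if (is.null(taxa)) {
    taxa <- data.frame(
      name = c(sprintf("Planktonic_sp%02d", seq_len(n_planktonic)),
               sprintf("Benthic_sp%02d", seq_len(n_benthic))),
      habitat = rep(c("planktonic", "benthic"), c(n_planktonic, n_benthic)),
      stringsAsFactors = FALSE)
  } else {
    pl <- taxa[taxa$habitat == "planktonic", , drop = FALSE]
    be <- taxa[taxa$habitat == "benthic", , drop = FALSE]
    if (nrow(pl) < n_planktonic || nrow(be) < n_benthic)
      stop("taxon roster smaller than requested counts")
    taxa <- rbind(pl[seq_len(n_planktonic), c("name", "habitat")],
                  be[seq_len(n_benthic), c("name", "habitat")])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(taxa)
  for (try in 1:20) {
    ancestor <- random_dna(1, barcode_length)
    seqs <- vapply(seq_len(n), function(i) {
      mutate_positions(ancestor, sample.int(barcode_length, n_sub))
    }, character(1))
    idm <- nw_identity_self_cpp(seqs, 1, -1, -2)
    if (min(1 - idm[upper.tri(idm)]) > min_separation) {
      tax <- synthetic_taxonomy(taxa$name, taxa$habitat)
      return(structure(data.frame(id = taxa$name, seq = seqs,
                                  taxonomy = tax, habitat = taxa$habitat,
                                  stringsAsFactors = FALSE),
                       class = c("ref_db", "data.frame")))
    }
  }
  stop("design error: could not separate taxa at divergence ", divergence)
}

# Six-level synthetic taxonomy path for a taxon name ("Genus_species").
synthetic_taxonomy <- function(name, habitat) {
  genus <- sub("_.*$", "", name)
  species <- name
  order_ <- ifelse(habitat == "planktonic", "Globigerinida", "Rotaliida")
  paste("Foraminifera", "Globothalamea", order_,
        paste0(genus, "idae"), genus, species, sep = ";")
}

#' Expected read proportions of a core layer
#'
#' The planktonic:benthic read-mass split follows the decay model at the
#' layer midpoint. Within the planktonic mass, zone-specific base abundances
#' are multiplied by the copy-number multipliers, the surface-enrichment
#' factor (for flagged taxa in layers whose midpoint lies above
#' `boost_max_depth`), and set to zero for taxa with forward-primer
#' mismatches; the result is renormalized. Benthic mass is shared among
#' benthic taxa by their base abundances.
#'
#' @param design a [simulation_design()].
#' @param site site identifier present in `design$sites`.
#' @param layer layer index into `design$layers`.
#' @return named numeric vector of expected read proportions (sums to 1).
#' @export
simulate_layer_community <- function(design, site, layer) {
  zi <- match(site, design$sites$site)
  if (is.na(zi)) stop("unknown site: ", site)
  if (layer < 1 || layer > nrow(design$layers))
    stop("layer outside the design")
  zone <- design$sites$zone[zi]
  z <- layer_midpoints(design$layers)[layer]
  f <- with(fraction_profile(z, design$decay), fraction)
  taxa <- design$taxa
  base <- zone_base(taxa, zone)
  ispl <- taxa$habitat == "planktonic"
  pw <- base * taxa$copy_number_multiplier
  pw[taxa$fwd_primer_mismatches >= 1] <- 0
  pw[taxa$surface_boost & z < design$boost_max_depth] <-
    pw[taxa$surface_boost & z < design$boost_max_depth] * design$boost_factor
  pw[!ispl] <- 0
  bw <- ifelse(ispl, 0, base)
  props <- numeric(nrow(taxa))
  if (sum(pw) > 0) props <- props + f * pw / sum(pw)
  if (sum(bw) > 0) props <- props + (1 - f) * bw / sum(bw)
  props <- props / sum(props)
  names(props) <- taxa$name
  props
}

#' Expected census composition of a hydrographic zone
#'
#' The microfossil census samples the living planktonic assemblage directly:
#' no primer dropout and no copy-number multipliers, so spinose taxa are
#' present.
#'
#' @param design a [simulation_design()].
#' @param zone one of `LC`, `transition`, `NAC`.
#' @return named vector of expected planktonic test proportions.
#' @export
expected_census_composition <- function(design, zone) {
  taxa <- design$taxa
  ispl <- taxa$habitat == "planktonic"
  w <- zone_base(taxa, zone)[ispl]
  names(w) <- taxa$name[ispl]
  w / sum(w)
}

#' Simulate a microfossil census count
#'
#' Draws `n_tests` planktonic tests from the zone assemblage (multinomial)
#' plus benthic tests at the configured planktonic:benthic shell ratio
#' (Poisson mean `n_tests / ratio`, shared among benthic taxa by base
#' abundance). Uses the current RNG stream.
#'
#' @param design a [simulation_design()].
#' @param site,layer location of the census (layer index).
#' @param n_tests planktonic tests counted.
#' @return named integer vector of counts over all design taxa.
#' @export
simulate_census <- function(design, site, layer,
                            n_tests = design$census_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  zi <- match(site, design$sites$site)
  if (is.na(zi)) stop("unknown site: ", site)
  zone <- design$sites$zone[zi]
  taxa <- design$taxa
  ispl <- taxa$habitat == "planktonic"
  counts <- integer(nrow(taxa))
  ppl <- zone_base(taxa, zone)[ispl]
  counts[ispl] <- as.integer(rmultinom(1, n_tests, ppl))
  nb <- rpois(1, n_tests / design$benthic_shell_ratio)
  if (nb > 0) {
    pbe <- zone_base(taxa, zone)[!ispl]
    counts[!ispl] <- as.integer(rmultinom(1, nb, pbe))
  }
  names(counts) <- taxa$name
  counts
}

# Sample-unit table: one row per site x layer x replicate.
sample_units <- function(design) {
  g <- expand.grid(layer = seq_len(nrow(design$layers)),
                   site = design$sites$site,
                   stringsAsFactors = FALSE)
  g$zone <- design$sites$zone[match(g$site, design$sites$site)]
  g$top <- design$layers$top[g$layer]
  g$bottom <- design$layers$bottom[g$layer]
  g$sample <- sprintf("%s_%02d_%02d", g$site, g$top, g$bottom)
  out <- g[rep(seq_len(nrow(g)), each = design$replicates), ]
  out$replicate <- rep(seq_len(design$replicates), nrow(g))
  out$unit <- paste0(out$sample, ".rep", out$replicate)
  rownames(out) <- NULL
  out
}

#' Simulate tagged paired-end reads with ground truth
#'
#' Each sample unit's reads are drawn multinomially from its expected layer
#' community; every read pair carries the unit's tagged primers inline; point
#' errors are placed at the design substitution rate; chimeras are two-parent
#' splices at a uniform breakpoint, with parents drawn abundance-weighted
#' within the unit. Mates overlap by construction so exact-overlap merging
#' can succeed. Uses the current RNG stream (orchestrate via
#' [simulate_study()] for seeded determinism).
#'
#' @param design a [simulation_design()].
#' @param refdb reference database from [simulate_reference_db()].
#' @param scheme a [tag_scheme()] covering every sample unit.
#' @return list with `reads` (data.frame: id, unit, fwd_seq, fwd_qual,
#'   rev_seq, rev_qual) and `truth` (data.frame: id, sample, replicate,
#'   taxon; chimeras labelled `chimera:parentA+parentB`).
#' @export
simulate_reads <- function(design, refdb, scheme) {
  if (design$reads_per_sample < 1) stop("design error: reads_per_sample = 0")
  units <- sample_units(design)
  if (!all(units$unit %in% scheme$samples$sample))
    stop("tag scheme does not cover every sample unit")
  inserts <- setNames(refdb$seq, refdb$id)
  qconst <- strrep(rawToChar(as.raw(37 + 33)), design$read_length)
  all_fwd <- all_rev <- all_id <- all_unit <- all_taxon <- list()
  for (u in seq_len(nrow(units))) {
    unit <- units$unit[u]
    props <- simulate_layer_community(design, units$site[u], units$layer[u])
    props <- props[names(props) %in% names(inserts)]
    props <- props / sum(props)
    counts <- as.integer(rmultinom(1, design$reads_per_sample, props))
    taxon <- rep(names(props), counts)
    ins <- unname(inserts[taxon])
    n <- length(ins)
    # chimeric replacements: two distinct parents, abundance-weighted
    if (design$chimera_rate > 0 && sum(props > 0) >= 2) {
      is_chim <- runif(n) < design$chimera_rate
      for (i in which(is_chim)) {
        par <- sample(names(props), 2, prob = props)
        a <- inserts[[par[1]]]; b <- inserts[[par[2]]]
        k <- sample.int(min(nchar(a), nchar(b)) - 1L, 1)
        ins[i] <- paste0(substr(a, 1, k), substr(b, k + 1, nchar(b)))
        taxon[i] <- paste0("chimera:", par[1], "+", par[2])
      }
    }
    row <- match(unit, scheme$samples$sample)
    fc <- paste0(scheme$samples$fwd_tag[row], scheme$fwd_primer)
    rc3 <- revcomp(paste0(scheme$samples$rev_tag[row], scheme$rev_primer))
    templates <- paste0(fc, ins, rc3)
    L <- nchar(templates)
    rl <- pmin(design$read_length, L)
    fwd <- substr(templates, 1, rl)
    rev3 <- substr(templates, L - rl + 1, L)
    rev <- revcomp(rev3)
    if (design$error_rate > 0) {
      fwd <- add_read_errors(fwd, design$error_rate)
      rev <- add_read_errors(rev, design$error_rate)
    }
    all_fwd[[u]] <- fwd
    all_rev[[u]] <- rev
    all_unit[[u]] <- rep(unit, n)
    all_taxon[[u]] <- taxon
    all_id[[u]] <- sprintf("%s_r%06d", unit, seq_len(n))
  }
  id <- unlist(all_id, use.names = FALSE)
  unit <- unlist(all_unit, use.names = FALSE)
  reads <- data.frame(id = id, unit = unit,
                      fwd_seq = unlist(all_fwd, use.names = FALSE),
                      rev_seq = unlist(all_rev, use.names = FALSE),
                      stringsAsFactors = FALSE)
  reads$fwd_qual <- substr(qconst, 1, nchar(reads$fwd_seq))
  reads$rev_qual <- substr(qconst, 1, nchar(reads$rev_seq))
  truth <- data.frame(id = id,
                      sample = sub("\\.rep[0-9]+$", "", unit),
                      replicate = as.integer(sub("^.*\\.rep", "", unit)),
                      unit = unit,
                      taxon = unlist(all_taxon, use.names = FALSE),
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

add_read_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    pos <- which(runif(nchar(s)) < rate)
    if (length(pos) == 0) s else mutate_positions(s, pos)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a complete synthetic study
#'
#' Seeds the RNG from the design, then generates the reference database, tag
#' scheme, paired reads with truth table, per-layer census counts and sample
#' metadata. With `dir` set, writes: `reference.fasta`, `tags.tsv`,
#' `reads_R1.fastq.gz` / `reads_R2.fastq.gz`, `truth.tsv`, `census.tsv`,
#' `metadata.tsv` and `config.yml`. Identical seeds give identical outputs.
#'
#' @param design a [simulation_design()].
#' @param dir optional output directory.
#' @param config optional [pipeline_config()] written alongside the data.
#' @return list with `refdb`, `scheme`, `reads`, `truth`, `census` (samples
#'   x taxa matrix), `metadata`, and `paths` when `dir` is given.
#' @export
simulate_study <- function(design, dir = NULL, config = pipeline_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)
  taxa <- design$taxa
  refdb <- simulate_reference_db(
    n_planktonic = sum(taxa$habitat == "planktonic"),
    n_benthic = sum(taxa$habitat == "benthic"),
    divergence = design$divergence, seed = design$seed,
    barcode_length = design$barcode_length, taxa = taxa)
  units <- sample_units(design)
  scheme <- tag_scheme(units$unit, design$fwd_primer, design$rev_primer,
                       seed = design$seed)
  sim <- simulate_reads(design, refdb, scheme)
  # one census per site x layer
  census_ids <- unique(units$sample)
  census <- t(vapply(census_ids, function(s) {
    i <- match(s, units$sample)
    simulate_census(design, units$site[i], units$layer[i])
  }, numeric(nrow(taxa))))
  storage.mode(census) <- "integer"
  metadata <- unique(units[, c("sample", "site", "top", "bottom", "zone")])
  names(metadata)[names(metadata) == "top"] <- "depth_cm_top"
  names(metadata)[names(metadata) == "bottom"] <- "depth_cm_bottom"
  rownames(metadata) <- NULL
  out <- list(refdb = refdb, scheme = scheme, reads = sim$reads,
              truth = sim$truth, census = census, metadata = metadata)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      reference = file.path(dir, "reference.fasta"),
      tags = file.path(dir, "tags.tsv"),
      fastq_fwd = file.path(dir, "reads_R1.fastq.gz"),
      fastq_rev = file.path(dir, "reads_R2.fastq.gz"),
      truth = file.path(dir, "truth.tsv"),
      census = file.path(dir, "census.tsv"),
      metadata = file.path(dir, "metadata.tsv"),
      config = file.path(dir, "config.yml"))
    write_reference_fasta(refdb, paths$reference)
    write_tag_scheme(scheme, paths$tags)
    write_fastq(paths$fastq_fwd, sim$reads$id, sim$reads$fwd_seq,
                sim$reads$fwd_qual)
    write_fastq(paths$fastq_rev, sim$reads$id, sim$reads$rev_seq,
                sim$reads$rev_qual)
    write_tsv(sim$truth, paths$truth)
    write_tsv(data.frame(sample = rownames(census), census,
                         check.names = FALSE), paths$census)
    write_tsv(metadata, paths$metadata)
    write_config(config, paths$config)
    out$paths <- paths
  }
  out
}
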