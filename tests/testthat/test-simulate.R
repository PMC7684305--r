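# The synthetic-study generator.

test_that("simulated reference database is deterministic and separable", {
  db1 <- simulate_reference_db(7, 5, divergence = 0.2, seed = 12)
  db2 <- simulate_reference_db(7, 5, divergence = 0.2, seed = 12)
  expect_identical(db1, db2)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_reference_fasta(db1, f1); write_reference_fasta(db2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical FASTA

  expect_equal(sum(db1$habitat == "planktonic"), 7)
  expect_true(all(nchar(db1$seq) >= 68 & nchar(db1$seq) <= 196))
  expect_true(all(lengths(strsplit(db1$taxonomy, ";")) == 6))
  # taxa separable beyond the OTU clustering threshold
  idm <- nw_identity_matrix(db1$seq)
  expect_gt(min(1 - idm[upper.tri(idm)]), 0.1)

  # indistinguishable taxa are a design error
  expect_error(simulate_reference_db(3, 3, divergence = 0), "design error")
})

test_that("layer communities follow the decay split, dropout and multipliers", {
  des <- simulation_design(seed = 2)
  # spinose taxa receive zero read mass in every layer
  spinose <- with(des$taxa, name[fwd_primer_mismatches >= 1])
  for (ly in c(1, 5, 10)) {
    pr <- simulate_layer_community(des, "S01", ly)
    expect_equal(sum(pr), 1)
    expect_true(all(pr[spinose] == 0))
  }
  # planktonic mass fraction equals the decay-model fraction at the midpoint
  pr1 <- simulate_layer_community(des, "S01", 1)   # layer 0-2 cm
  ispl <- des$taxa$habitat == "planktonic"
  expect_equal(unname(sum(pr1[ispl])),
               fraction_profile(1, des$decay)$fraction)

  # symmetric base abundances give symmetric proportions
  taxa <- default_taxa(4)
  taxa$base_LC[1:2] <- 0.3
  taxa$copy_number_multiplier[1:2] <- 1
  taxa$surface_boost[1:2] <- FALSE
  des2 <- simulation_design(taxa = taxa, seed = 2)
  pr <- simulate_layer_community(des2, "S01", 3)   # below the boost depth
  expect_equal(unname(pr[taxa$name[1]]), unname(pr[taxa$name[2]]))

  # surface enrichment boosts the flagged taxon only above 4 cm
  pr_top <- simulate_layer_community(des, "S01", 1)    # midpoint 1 cm
  pr_deep <- simulate_layer_community(des, "S01", 4)   # midpoint 7 cm
  uv <- "Globigerinita_uvula"; gl <- "Globigerinita_glutinata"
  expect_gt(pr_top[uv] / pr_top[gl], pr_deep[uv] / pr_deep[gl])
})

test_that("census counts sample the unbiased assemblage with benthic shells", {
  des <- simulation_design(seed = 8)
  set.seed(33)
  cc <- simulate_census(des, "S01", 2, n_tests = 250)
  ispl <- des$taxa$habitat == "planktonic"
  expect_equal(sum(cc[ispl]), 250)
  # spinose present in the census (no primer dropout there)
  expect_gt(sum(cc[c("Globigerina_bulloides", "Turborotalita_quinqueloba")]),
            0)

  # polar-zone N. pachyderma proportion within 3 binomial SE of its base
  base <- expected_census_composition(des, "LC")["Neogloboquadrina_pachyderma"]
  set.seed(34)
  reps <- replicate(40, {
    x <- simulate_census(des, "S01", 2, n_tests = 250)
    x["Neogloboquadrina_pachyderma"] / 250
  })
  se <- sqrt(base * (1 - base) / 250)
  expect_true(mean(abs(reps - base) <= 3 * se) > 0.9)

  # expected benthic shells ~ n_tests / ratio
  set.seed(35)
  nb <- replicate(300, sum(simulate_census(des, "S01", 2, 250)[!ispl]))
  expect_lt(abs(mean(nb) - 2.5), 3 * sqrt(2.5 / 300))
})

test_that("census and eDNA compositions coincide when biases are off", {
  taxa <- default_taxa(6)
  taxa$copy_number_multiplier[] <- 1
  taxa$surface_boost[] <- FALSE
  des <- simulation_design(taxa = taxa, seed = 3)
  spinose <- with(taxa, name[fwd_primer_mismatches >= 1])
  ispl <- taxa$habitat == "planktonic"
  census <- expected_census_composition(des, "transition")
  census <- census[!names(census) %in% spinose]
  census <- census / sum(census)
  edna <- simulate_layer_community(des, "S05", 8)[ispl]
  edna <- edna[!names(edna) %in% spinose]
  edna <- edna / sum(edna)
  # Bray-Curtis between the two expected compositions is 0 by construction
  expect_equal(sum(abs(census - edna[names(census)])), 0, tolerance = 1e-12)
})

test_that("read simulation is seed-deterministic with a faithful truth table", {
  des <- simulation_design(sites = default_sites(1, 0, 1),
                           layers = core_layers(bottom = 4, step = 2),
                           reads_per_sample = 100, seed = 5)
  st1 <- simulate_study(des)
  st2 <- simulate_study(des)
  expect_identical(st1$reads, st2$reads)
  expect_identical(st1$census, st2$census)

  # no-noise reads merge exactly back to their template inserts
  with_tags <- st1$reads
  merged <- merge_pairs(with_tags$fwd_seq, with_tags$rev_seq, 12)
  expect_false(anyNA(merged))
  dmx <- demultiplex(merged, st1$scheme, 2)
  expect_equal(dmx$sample, with_tags$unit)
  inserts <- setNames(st1$refdb$seq, st1$refdb$id)
  expect_equal(dmx$insert, unname(inserts[st1$truth$taxon]))

  # reads-per-sample must be positive
  expect_error(simulation_design(reads_per_sample = 0), NA)
  des0 <- des; des0$reads_per_sample <- 0L
  expect_error(simulate_reads(des0, st1$refdb, st1$scheme), "design error")
})

test_that("chimera rate 1 with two templates yields only recorded splices", {
  taxa <- default_taxa(2)[c(1, 2, 10, 11), ]
  taxa$base_LC <- c(0.5, 0.5, 0.5, 0.5)
  des <- simulation_design(taxa = taxa,
                           sites = default_sites(1, 0, 0),
                           layers = core_layers(bottom = 2, step = 2),
                           reads_per_sample = 50, replicates = 1,
                           chimera_rate = 1, seed = 6)
  st <- simulate_study(des)
  expect_true(all(grepl("^chimera:", st$truth$taxon)))
})

test_that("a 167-unit study demultiplexes back to all 167 labels", {
  des <- simulation_design(sites = default_sites(3, 3, 3),
                           layers = core_layers(bottom = 20, step = 2),
                           reads_per_sample = 40,
                           replicates = 1, seed = 44)
  units <- sprintf("u%03d.rep1", 1:167)
  scheme <- tag_scheme(units, des$fwd_primer, des$rev_primer, seed = 44)
  # reuse the design communities round-robin across the 167 units
  refdb <- simulate_reference_db(9, 20, divergence = 0.2, seed = 44,
                                 taxa = des$taxa)
  set.seed(44)
  reads <- lapply(seq_along(units), function(u) {
    row <- match(units[u], scheme$samples$sample)
    ins <- refdb$seq[sample.int(nrow(refdb), 5)]
    tmpl <- paste0(scheme$samples$fwd_tag[row], scheme$fwd_primer, ins,
                   revcomp(paste0(scheme$samples$rev_tag[row],
                                  scheme$rev_primer)))
    data.frame(unit = units[u], merged = tmpl)
  })
  reads <- do.call(rbind, reads)
  dmx <- demultiplex(reads$merged, scheme, 2)
  expect_equal(dmx$sample, reads$unit)
  expect_equal(length(unique(dmx$sample)), 167)
})
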