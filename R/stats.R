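# Community-comparison statistics: WARM aggregation, cumulative sum scaling,
# Bray-Curtis, principal coordinates, dispersion and permutation ANOVA
# tests, planktonic-fraction depth profiles and fossil/molecular congruence.

#' Warm-advected morphospecies grouped in census reporting
#'
#' Rare temperate/subtropical morphospecies advected into the region by the
#' Gulf Stream / North Atlantic Current, aggregated into one `WARM`
#' category.
#'
#' @format character vector of morphospecies names.
#' @export
warm_morphospecies <- c(
  "Globigerinoides_ruber_albus", "Globorotalia_hirsuta",
  "Globorotalia_menardii", "Globigerina_falconensis",
  "Pulleniatina_obliquiloculata", "Trilobatus_sacculifer",
  "Globigerinoides_conglobatus", "Globigerinoides_elongatus",
  "Globigerinella_calida", "Globorotalia_truncatulinoides",
  "Neogloboquadrina_dutertrei", "Dentigloborotalia_anfracta",
  "Globigerinoides_ruber_ruber", "Globigerinella_siphonifera")

#' Aggregate warm-advected taxa into a WARM column
#'
#' Columns listed in `warm_list` are summed into one `WARM` column; listed
#' taxa absent from the table contribute 0. Totals are conserved.
#'
#' @param counts samples x taxa matrix.
#' @param warm_list taxa to aggregate (default [warm_morphospecies]).
#' @return samples x taxa matrix with the listed columns replaced by `WARM`.
#' @export
aggregate_warm <- function(counts, warm_list = warm_morphospecies) {
  warm_cols <- intersect(colnames(counts), warm_list)
  if (length(warm_cols) == 0 && length(warm_list) == 0) return(counts)
  keep <- setdiff(colnames(counts), warm_cols)
  out <- counts[, keep, drop = FALSE]
  if (length(warm_cols) > 0) {
    out <- cbind(out,
                 WARM = rowSums(counts[, warm_cols, drop = FALSE]))
  }
  out
}

#' Cumulative sum scaling normalization
#'
#' For each sample the scaling factor is the sum of that sample's counts
#' that are less than or equal to the `percentile` quantile of its nonzero
#' counts; normalized values are `count / factor * scale`. Optionally the
#' percentile is selected adaptively as the smallest grid value at which the
#' across-sample instability of the (relative) factors drops below `bound`.
#'
#' @param counts samples x taxa non-negative matrix.
#' @param percentile quantile of the nonzero counts (default 0.5).
#' @param scale common scale of the normalized table (default 1000).
#' @param adaptive select the percentile adaptively.
#' @param grid candidate percentiles for adaptive selection.
#' @param bound instability bound for adaptive selection.
#' @return list with `normalized` (matrix), `factors` (per sample),
#'   `percentile` (the one used). Samples with all-zero counts are excluded
#'   with a warning.
#' @export
css_normalize <- function(counts, percentile = 0.5, scale = 1000,
                          adaptive = FALSE,
                          grid = seq(0.25, 0.95, by = 0.05),
                          bound = 0.1) {
  if (any(counts < 0)) stop("counts must be non-negative")
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) excluded from normalization")
    counts <- counts[!zero, , drop = FALSE]
  }
  if (adaptive) percentile <- css_select_percentile(counts, grid, bound)
  factors <- apply(counts, 1, css_factor, percentile = percentile)
  normalized <- sweep(counts, 1, factors, "/") * scale
  list(normalized = normalized, factors = factors, percentile = percentile)
}

css_factor <- function(x, percentile) {
  nz <- x[x > 0]
  q <- quantile(nz, percentile, names = FALSE)
  sum(x[x <= q])
}

# Smallest percentile at which the across-sample spread of relative scaling
# factors stabilizes: the median relative change of the factors between
# consecutive grid points falls below `bound`.
css_select_percentile <- function(counts, grid, bound) {
  fmat <- vapply(grid, function(p) apply(counts, 1, css_factor, p),
                 numeric(nrow(counts)))
  rel <- sweep(fmat, 1, apply(counts, 1, sum), "/")
  for (i in seq_along(grid)[-1]) {
    change <- stats::median(abs(rel[, i] - rel[, i - 1]) /
                              pmax(rel[, i - 1], .Machine$double.eps))
    if (change < bound) return(grid[i - 1])
  }
  grid[length(grid)]
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x - y| / sum (x + y)` on non-negative rows, via
#' [vegan::vegdist()]. Pairs of all-zero samples are undefined and flagged.
#'
#' @param counts samples x taxa non-negative matrix.
#' @return a `dist` object; an attribute `undefined_pairs` lists sample
#'   pairs with zero total.
#' @export
bray_curtis <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  zero <- rowSums(counts) == 0
  d <- vegan::vegdist(counts, method = "bray")
  und <- which(outer(zero, zero, "&"), arr.ind = TRUE)
  und <- und[und[, 1] < und[, 2], , drop = FALSE]
  if (nrow(und) > 0) {
    warning(nrow(und), " all-zero sample pair(s) have undefined ",
            "dissimilarity")
    attr(d, "undefined_pairs") <- und
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical scaling by double-centering and eigendecomposition (via
#' [stats::cmdscale()]). When negative eigenvalues exceed the tolerance, the
#' Cailliez additive correction is applied and recorded.
#'
#' @param d a `dist` object or symmetric zero-diagonal matrix.
#' @param k number of returned axes (default all informative ones).
#' @param tol negative-eigenvalue tolerance relative to the largest
#'   eigenvalue.
#' @return list of class `pcoa_ord`: `coordinates`, `eigenvalues`
#'   (descending), `prop_explained` (over positive eigenvalues),
#'   `corrected` flag.
#' @export
pcoa_ord <- function(d, k = NULL, tol = 1e-8) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    d <- as.dist(d)
  }
  n <- attr(d, "Size")
  if (is.null(k)) k <- n - 1
  fit <- suppressWarnings(cmdscale(d, k = k, eig = TRUE))
  corrected <- FALSE
  if (min(fit$eig) < -tol * max(abs(fit$eig))) {
    fit <- suppressWarnings(cmdscale(d, k = k, eig = TRUE, add = TRUE))
    corrected <- TRUE
  }
  if (ncol(fit$points) == 0) {
    # fully degenerate input: every sample coincides
    return(structure(list(coordinates = matrix(0, n, 1,
                                               dimnames = list(NULL,
                                                               "Axis1")),
                          eigenvalues = rep(0, n),
                          prop_explained = NA_real_,
                          corrected = corrected),
                     class = "pcoa_ord"))
  }
  pos <- fit$eig > tol * max(abs(fit$eig))
  keep <- seq_len(max(1, min(k, sum(pos), ncol(fit$points))))
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE),
                 prop_explained = sort(fit$eig[pos],
                                       decreasing = TRUE)[keep] /
                   sum(fit$eig[pos]),
                 corrected = corrected),
            class = "pcoa_ord")
}

# Raw double-centered embedding keeping negative-eigenvalue ("imaginary")
# axes, as used by the dispersion test.
embed_all_axes <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  A <- -0.5 * m^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values))
  pos <- e$values > tol
  neg <- e$values < -tol
  list(real = sweep(e$vectors[, pos, drop = FALSE], 2,
                    sqrt(e$values[pos]), "*"),
       imag = sweep(e$vectors[, neg, drop = FALSE], 2,
                    sqrt(-e$values[neg]), "*"))
}

# One-way ANOVA F on a numeric vector given integer group codes.
anova_F <- function(x, g) {
  N <- length(x)
  k <- length(unique(g))
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ns <- tabulate(g)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((x - means[g])^2)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' Multivariate dispersion test (permutation ANOVA on centroid distances)
#'
#' Samples are embedded by principal coordinates keeping negative axes; each
#' sample's distance to its group centroid is computed with the squared
#' contributions of negative-eigenvalue axes subtracted (truncated at zero
#' before the square root). A one-way ANOVA F on these distances is compared
#' against `n_perm` random permutations of the group labels;
#' `p = (#{F* >= F} + 1) / (n_perm + 1)`.
#'
#' @param d distance matrix (`dist` or symmetric matrix).
#' @param groups group labels, >= 2 groups with >= 2 samples each
#'   (singleton groups are excluded with a warning).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param pairwise also run the test for every group pair.
#' @return list of class `dispersion_test`: `statistic`, `p_value`,
#'   `distances`, `groups`, and `pairwise` (data.frame) if requested.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = 1,
                            pairwise = FALSE) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2)) {
    warning("singleton group(s) excluded: ",
            paste(names(tab)[tab < 2], collapse = ", "))
    keep <- groups %in% names(tab)[tab >= 2]
    m <- m[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least two non-singleton groups")
  dist_c <- centroid_distances(m, groups)
  g <- match(groups, unique(groups))
  F_obs <- anova_F(dist_c, g)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  F_perm <- vapply(seq_len(n_perm), function(i) {
    anova_F(dist_c, sample(g))
  }, numeric(1))
  p <- (sum(F_perm >= F_obs) + 1) / (n_perm + 1)
  out <- list(statistic = F_obs, p_value = p, distances = dist_c,
              groups = groups)
  if (pairwise) {
    gs <- unique(groups)
    prs <- utils::combn(gs, 2)
    out$pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      sel <- groups %in% prs[, j]
      sub <- dispersion_test(m[sel, sel, drop = FALSE], groups[sel],
                             n_perm = n_perm, seed = seed)
      data.frame(group1 = prs[1, j], group2 = prs[2, j],
                 F = sub$statistic, p_value = sub$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  class(out) <- "dispersion_test"
  out
}

centroid_distances <- function(m, groups) {
  emb <- embed_all_axes(m)
  d2 <- numeric(nrow(m))
  for (grp in unique(groups)) {
    sel <- groups == grp
    cr <- colMeans(emb$real[sel, , drop = FALSE])
    d2r <- rowSums(sweep(emb$real[sel, , drop = FALSE], 2, cr)^2)
    d2i <- 0
    if (ncol(emb$imag) > 0) {
      ci <- colMeans(emb$imag[sel, , drop = FALSE])
      d2i <- rowSums(sweep(emb$imag[sel, , drop = FALSE], 2, ci)^2)
    }
    d2[sel] <- pmax(d2r - d2i, 0)
  }
  sqrt(d2)
}

#' Permutational multivariate ANOVA (one factor)
#'
#' Partition of squared distances among and within groups:
#' `SST = sum(d^2)/N`, `SSW = sum_g sum_{i<j in g} d_ij^2 / n_g`, pseudo-F
#' `= (SSA/(k-1)) / (SSW/(N-k))`; the p-value uses `n_perm` label
#' permutations with the +1 correction.
#'
#' @inheritParams dispersion_test
#' @return list of class `permanova_test`: `statistic` (pseudo-F),
#'   `p_value`, `R2`.
#' @export
permanova_test <- function(d, groups, n_perm = 999, seed = 1) {
  m2 <- as.matrix(d)^2
  groups <- as.character(groups)
  g <- match(groups, unique(groups))
  k <- length(unique(g))
  if (k < 2) stop("need at least two groups")
  N <- length(g)
  sst <- sum(m2[upper.tri(m2)]) / N
  ssw_of <- function(g) {
    s <- 0
    for (grp in unique(g)) {
      sel <- g == grp
      s <- s + sum(m2[sel, sel][upper.tri(m2[sel, sel])]) / sum(sel)
    }
    s
  }
  pseudo_F <- function(g) {
    ssw <- ssw_of(g)
    ((sst - ssw) / (k - 1)) / (ssw / (N - k))
  }
  F_obs <- pseudo_F(g)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  F_perm <- vapply(seq_len(n_perm), function(i) pseudo_F(sample(g)),
                   numeric(1))
  ssw <- ssw_of(g)
  structure(list(statistic = F_obs,
                 p_value = (sum(F_perm >= F_obs) + 1) / (n_perm + 1),
                 R2 = (sst - ssw) / sst),
            class = "permanova_test")
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the lower triangles; the p-value permutes the
#' rows/columns of the second matrix jointly (one-sided, upper, +1
#' correction).
#'
#' @param d1,d2 distance matrices over the same samples.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return list with `statistic` and `p_value`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  stopifnot(identical(dim(m1), dim(m2)))
  lt <- lower.tri(m1)
  r_obs <- stats::cor(m1[lt], m2[lt])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(m1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(m1[lt], m2[p, p][lt])
  }, numeric(1))
  list(statistic = r_obs,
       p_value = (sum(r_perm >= r_obs) + 1) / (n_perm + 1))
}

#' Planktonic read-fraction profile
#'
#' Per-sample planktonic fraction (planktonic reads / total foraminiferal
#' reads) with depth-binned summaries: the mean fraction over samples whose
#' layer midpoint falls in [0,10), [10,20) and [20,30) cm. PCR replicates
#' (`sample.repN` columns) are summed before fractions by default.
#'
#' @param table an OTU table (list with `counts` OTU x sample and
#'   `annotation` with `habitat`).
#' @param metadata data.frame with `sample`, `depth_cm_top`,
#'   `depth_cm_bottom`.
#' @param bins bin edges in cm (default `c(0, 10, 20, 30)`).
#' @param combine_replicates sum `.repN` columns into their sample.
#' @return list with `samples` (data.frame: sample, depth_mid, planktonic,
#'   benthic, fraction) and `bins` (data.frame: bin, mean_fraction,
#'   n_samples). Zero-total samples are excluded with a warning.
#' @export
planktonic_fraction_profile <- function(table, metadata,
                                        bins = c(0, 10, 20, 30),
                                        combine_replicates = TRUE) {
  counts <- table$counts
  habitat <- table$annotation$habitat
  if (combine_replicates) {
    base <- sub("\\.rep[0-9]+$", "", colnames(counts))
    counts <- t(rowsum(t(counts), base))
  }
  pl <- colSums(counts[habitat == "planktonic", , drop = FALSE])
  be <- colSums(counts[habitat == "benthic", , drop = FALSE])
  tot <- pl + be
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total sample(s) excluded")
    keep <- tot > 0
    pl <- pl[keep]; be <- be[keep]; tot <- tot[keep]
  }
  md <- metadata[match(names(pl), metadata$sample), ]
  depth_mid <- (md$depth_cm_top + md$depth_cm_bottom) / 2
  samples <- data.frame(sample = names(pl), depth_mid = depth_mid,
                        planktonic = as.numeric(pl),
                        benthic = as.numeric(be),
                        fraction = as.numeric(pl / tot),
                        stringsAsFactors = FALSE)
  bin_id <- cut(depth_mid, bins, right = FALSE,
                labels = sprintf("[%g,%g)", bins[-length(bins)], bins[-1]))
  bstats <- aggregate(samples$fraction, list(bin = bin_id), mean)
  names(bstats)[2] <- "mean_fraction"
  nsamp <- aggregate(samples$fraction, list(bin = bin_id), length)
  bstats$n_samples <- as.integer(nsamp$x[match(bstats$bin, nsamp$bin)])
  list(samples = samples, bins = bstats)
}

#' Fossil vs metabarcode congruence report
#'
#' Restricts both tables to their shared samples, removes spinose taxa from
#' the fossil table (the known amplification dropout), converts both to
#' relative abundances, and reports per-source ordinations, dispersion and
#' permutation-ANOVA p-values by site and by zone, and the Mantel
#' correlation between the two Bray-Curtis matrices.
#'
#' @param fossil,molecular samples x taxa count matrices.
#' @param metadata data.frame with `sample`, `site`, `zone`.
#' @param spinose_taxa taxa removed from the fossil table.
#' @param n_perm permutations for all tests.
#' @param seed RNG seed.
#' @return nested list of class `congruence_report`.
#' @export
congruence_report <- function(fossil, molecular, metadata,
                              spinose_taxa = character(0),
                              n_perm = 999, seed = 1) {
  shared <- intersect(rownames(fossil), rownames(molecular))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  fossil <- fossil[shared, setdiff(colnames(fossil), spinose_taxa),
                   drop = FALSE]
  molecular <- molecular[shared, , drop = FALSE]
  md <- metadata[match(shared, metadata$sample), ]
  rel <- function(m) sweep(m, 1, pmax(rowSums(m), 1), "/")
  d_f <- bray_curtis(rel(fossil))
  d_m <- bray_curtis(rel(molecular))
  per_source <- function(d) {
    list(pcoa = pcoa_ord(d),
         by_site = list(
           dispersion = dispersion_test(d, md$site, n_perm, seed),
           permanova = permanova_test(d, md$site, n_perm, seed)),
         by_zone = list(
           dispersion = dispersion_test(d, md$zone, n_perm, seed,
                                        pairwise = TRUE),
           permanova = permanova_test(d, md$zone, n_perm, seed)))
  }
  structure(list(samples = shared,
                 fossil = per_source(d_f),
                 molecular = per_source(d_m),
                 mantel = mantel_test(d_f, d_m, n_perm, seed)),
            class = "congruence_report")
}
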