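test_that("aggregation sums shared labels and conserves per-sample totals", {
  counts <- rbind(a = c(3, 1), b = c(7, 2), c = c(5, 9))
  ft <- make_ft(counts,
                lineage = c("P1;c1;o1;f1;gX", "P1;c1;o1;f1;gX",
                            "P2;c2;o2;f2;gY"))
  agg <- aggregate_taxa(ft, "genus")
  expect_equal(agg$counts["gX", ], c(s01 = 10L, s02 = 3L))
  expect_true(all(abs(colSums(agg$rel_abund) - 1) < 1e-12))
  # zOTU rank is the identity
  expect_equal(aggregate_taxa(ft, "zotu")$counts, ft$counts)
  # totals invariant across every rank on a generated table
  gc <- gen_community("microcosm", n_taxa = 50, depth = 5000,
                      timepoints = 3, seed = 4)
  totals <- colSums(gc$table$counts)
  for (rk in gc$table$ranks) {
    expect_equal(colSums(aggregate_taxa(gc$table, rk)$counts), totals)
  }
})

test_that("Bray-Curtis matches hand computation and metric axioms hold", {
  m <- rbind(x = c(2, 2), y = c(1, 3), z = c(2, 2))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["x", "y"], 0.25)
  expect_equal(d["x", "z"], 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)
  expect_error(bray_curtis(rbind(a = c(1, 1), b = c(0, 0))), "all-zero")

  set.seed(9)
  rnd <- matrix(rpois(60, 5) + 1, nrow = 6,
                dimnames = list(paste0("s", 1:6), NULL))
  for (d in list(bray_curtis(rnd), jaccard(rnd))) {
    dm <- as.matrix(d)
    expect_true(isSymmetric(dm))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0 & dm <= 1))
  }
})

test_that("binary Bray-Curtis and Jaccard obey J = 2B/(1+B) on equal-total presence tables", {
  set.seed(2)
  pres <- matrix(0L, nrow = 5, ncol = 12,
                 dimnames = list(paste0("s", 1:5), NULL))
  for (i in 1:5) pres[i, sample(12, 6)] <- 1L   # equal totals
  b <- as.vector(bray_curtis(pres))
  j <- as.vector(jaccard(pres))
  expect_equal(j, 2 * b / (1 + b), tolerance = 1e-12)
})

test_that("PCoA recovers known geometries and round-trips Euclidean input", {
  # three equidistant samples: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(letters[1:3], letters[1:3])
  ord <- pcoa_ordination(eq)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # collinear points: a single positive eigenvalue carries all variance
  line <- stats::dist(c(p1 = 0, p2 = 1, p3 = 3, p4 = 7))
  ordl <- pcoa_ordination(line)
  expect_equal(sum(ordl$eigenvalues > 1e-9), 1)
  expect_equal(ordl$prop_explained[1], 1, tolerance = 1e-12)

  # coordinates reproduce a Euclidean distance matrix
  set.seed(11)
  pts <- matrix(rnorm(12), ncol = 2,
                dimnames = list(paste0("s", 1:6), NULL))
  d <- stats::dist(pts)
  ordr <- pcoa_ordination(d)
  coords <- as.matrix(ordr$coordinates[-1])
  expect_equal(as.vector(stats::dist(coords[, 1:2])), as.vector(d),
               tolerance = 1e-9)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA agrees with an independent eigendecomposition", {
  skip_if_not_installed("ape")
  gc <- gen_community("microcosm", n_taxa = 40, depth = 5000,
                      timepoints = 3, seed = 8)
  d <- bray_curtis(gc$table, rank = "order")
  ours <- pcoa_ordination(d)
  ref <- ape::pcoa(d)
  k <- ncol(ref$vectors)
  expect_equal(ours$eigenvalues[1:k], unname(ref$values$Eigenvalues[1:k]),
               tolerance = 1e-8)
  for (ax in 1:2) {
    expect_equal(abs(ours$coordinates[[paste0("axis", ax)]]),
                 abs(unname(ref$vectors[, ax])), tolerance = 1e-6)
  }
})

test_that("ANOSIM yields R = 1 for perfect separation and matches brute-force ranks", {
  sep <- rbind(a1 = c(10, 0, 0), a2 = c(9, 1, 0), a3 = c(10, 1, 0),
               a4 = c(9, 2, 0),
               b1 = c(0, 0, 10), b2 = c(0, 1, 9), b3 = c(1, 0, 10),
               b4 = c(0, 2, 9))
  g <- rep(c("a", "b"), each = 4)
  d <- bray_curtis(sep)
  res <- suppressMessages(anosim_test(d, g, n_perm = 199, seed = 1))
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.05)
  expect_equal(res$statistic, brute_anosim_r(d, g))

  # arbitrary structure: vegan-backed statistic equals the rank formula
  set.seed(21)
  rnd <- matrix(rpois(80, 8) + 1, nrow = 8,
                dimnames = list(paste0("s", 1:8), NULL))
  d2 <- bray_curtis(rnd)
  g2 <- rep(c("u", "v"), each = 4)
  res2 <- suppressMessages(anosim_test(d2, g2, n_perm = 99, seed = 2))
  expect_equal(res2$statistic, brute_anosim_r(d2, g2), tolerance = 1e-12)
})

test_that("PERMANOVA pseudo-F matches the sums-of-squared-distances formula", {
  gc <- gen_community("microcosm", n_taxa = 40, responders = 1:4,
                      fold_changes = 6, depth = 10000, timepoints = 3,
                      seed = 14)
  d <- bray_curtis(gc$table, rank = "order")
  g <- gc$table$samples$corrinoid
  res <- permanova_test(d, g, n_perm = 199, seed = 3)
  expect_equal(res$statistic, brute_pseudo_f(d, g), tolerance = 1e-9)
  expect_lte(res$p_value, 0.05)
  expect_gte(res$statistic, 0)
})

test_that("permutation p-values are super-uniform under the null", {
  # homogeneous cloud, labels carry no information
  pvals_a <- numeric(40)
  r_stats <- numeric(40)
  for (i in seq_len(40)) {
    gc <- gen_community("microcosm", n_taxa = 30, fold_changes = 1,
                        depth = 5000, timepoints = 3, n_reps = 2,
                        corrinoids = c("none", "Cbl", "Cbi"), seed = 300 + i)
    d <- bray_curtis(gc$table, rank = "zotu")
    res <- suppressMessages(
      anosim_test(d, gc$table$samples$corrinoid, n_perm = 199, seed = i))
    pvals_a[i] <- res$p_value
    r_stats[i] <- res$statistic
  }
  expect_lt(abs(mean(r_stats)), 0.15)           # R centred near zero
  for (alpha in c(0.05, 0.25, 0.5)) {
    expect_lte(mean(pvals_a <= alpha), alpha + 0.14)
  }
})

test_that("grouping preconditions are enforced", {
  d <- bray_curtis(rbind(a = c(1, 2), b = c(2, 1), c = c(1, 1)))
  expect_error(anosim_test(d, c("x", "x", "y"), seed = 1), "size 1")
  expect_error(permanova_test(d, c("x", "x", "x"), seed = 1), "2 groups")
  d4 <- bray_curtis(rbind(a = c(1, 2), b = c(2, 1), c = c(1, 1),
                          e = c(3, 1)))
  expect_warning(
    suppressMessages(anosim_test(d4, c("x", "x", "y", "y"), n_perm = 49,
                                 seed = 1)),
    "99"
  )
})

test_that("KW screen recovers the hand-ranked H statistic", {
  # taxon A relative abundances form ranks 1..9 in three groups of three:
  # {.1,.2,.3}, {.4,.5,.6}, {.7,.8,.9} -> H = 7.2, p ~ 0.027 (chi-sq, df 2)
  a <- c(10, 20, 30, 40, 50, 60, 70, 80, 90)
  counts <- rbind(a, b = 100 - a)
  ft <- make_ft(counts, corrinoid = rep(c("none", "Cbl", "Cbi"), each = 3))
  sc <- kw_screen(ft, rank = "zotu")
  row_a <- sc[sc$taxon == rownames(ft$counts)[1], ]
  expect_equal(row_a$statistic, 7.2)
  expect_equal(row_a$p_value, kruskal.test(a, rep(1:3, each = 3))$p.value)
  expect_true(row_a$significant)
  expect_true(all(c("p_adj") %in% names(sc)))
})

test_that("degenerate taxa are skipped, not tested", {
  counts <- rbind(a = c(5, 6, 7, 8, 9, 10),
                  only_g1 = c(3, 4, 0, 0, 0, 0),   # present in one group
                  flat = c(10, 10, 10, 10, 10, 10))
  ft <- make_ft(counts, corrinoid = rep(c("none", "Cbl"), each = 3))
  sc <- kw_screen(ft, rank = "zotu")
  expect_equal(sc$status[sc$taxon == "only_g1"], "skipped")
  expect_true(is.na(sc$p_value[sc$taxon == "only_g1"]))
  expect_equal(sc$status[sc$taxon == "a"], "tested")
})

test_that("screen attains the level of its matched continuous-null oracle", {
  # independent oracle: attained level of the chi-square KW p at the same
  # group structure (7 treatments x 5 replicates) on tie-free data
  set.seed(99)
  g <- factor(rep(1:7, each = 5))
  oracle <- mean(replicate(4000, kruskal.test(rnorm(35), g)$p.value) <= 0.05)

  gc <- gen_community("microcosm", n_taxa = 1000, fold_changes = 1,
                      depth = 5e4, timepoints = 3, seed = 31)
  sc <- kw_screen(gc$table, rank = "zotu", timepoints = 3)
  level <- mean(sc$p_value[sc$status == "tested"] <= 0.05)
  expect_lt(abs(level - oracle), 0.012)
})

test_that("screen power is monotone in the planted fold-change", {
  hit_rates <- vapply(c(1, 1.5, 3), function(fc) {
    hits <- vapply(1:12, function(s) {
      gc <- gen_community("microcosm", n_taxa = 100, responders = 1:4,
                          fold_changes = fc, depth = 2e4, timepoints = 3,
                          seed = 500 + s)
      sc <- kw_screen(gc$table, rank = "zotu", timepoints = 3)
      mean(sc$significant[sc$taxon %in% gc$truth$responders])
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(hit_rates) >= 0))
  expect_gt(hit_rates[3], hit_rates[1])
})

test_that("responsive fractions follow their two distinct definitions", {
  # taxon A responds strongly, B is flat filler
  a <- c(10, 11, 12, 60, 62, 61, 10, 12, 11)
  counts <- rbind(a, b = 100 - a)
  ft <- make_ft(counts, corrinoid = rep(c("none", "Cbl", "Cbi"), each = 3))
  sc <- kw_screen(ft, rank = "zotu")
  frac <- responsive_fraction_count(sc)
  expect_equal(frac$n_taxa, 2)
  expect_equal(frac$fraction, frac$n_responsive / 2)

  # all significant at one timepoint -> fraction 1; none -> 0
  sc_all <- sc; sc_all$significant <- TRUE
  expect_equal(responsive_fraction_count(sc_all)$fraction, 1)
  sc_none <- sc; sc_none$significant <- FALSE
  expect_equal(responsive_fraction_count(sc_none)$fraction, 0)
  ab_none <- responsive_fraction_abundance(sc_none, ft)
  expect_equal(ab_none$prop_community, 0)

  # abundance-based: a single significant taxon at 30% mean abundance
  counts2 <- rbind(sig = c(30, 30, 30, 30, 30, 30),
                   rest = c(70, 70, 70, 70, 70, 70))
  ft2 <- make_ft(counts2, corrinoid = rep(c("none", "Cbl"), each = 3))
  sc2 <- tibble::tibble(timepoint = 1, rank = "zotu", taxon = "sig",
                        status = "tested", n_groups = 2, statistic = 5,
                        df = 1, p_value = 0.01, p_adj = 0.01,
                        significant = TRUE)
  ab <- responsive_fraction_abundance(sc2, ft2)
  expect_equal(ab$prop_community, 0.30)
})

test_that("pairwise Mann-Whitney matches exact enumeration and is symmetric", {
  # fully separated 5 vs 5: minimal exact two-sided p = 2/choose(10,5)
  sep <- rbind(t1 = c(10, 11, 12, 13, 14, 50, 52, 54, 56, 58),
               t2 = c(90, 89, 88, 87, 86, 50, 48, 46, 44, 42))
  ft <- make_ft(sep, corrinoid = rep(c("none", "Cbl"), each = 5))
  mw <- pairwise_mw(ft, "t1", rank = "zotu")
  expect_equal(mw$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(mw$p_value, 0.007936508, tolerance = 1e-6)
  expect_true(mw$statistic %in% c(0, 25))

  # identical groups: maximal p
  same <- rbind(t1 = rep(c(10, 20, 30), 2), t2 = rep(c(90, 80, 70), 2))
  ft_same <- make_ft(same, corrinoid = rep(c("none", "Cbl"), 3))
  mw_same <- pairwise_mw(ft_same, "t1", rank = "zotu")
  expect_equal(mw_same$p_value, 1)

  # swapping group labels leaves the p-value unchanged
  ft_sw <- make_ft(ft$counts[, c(6:10, 1:5)],
                   corrinoid = rep(c("none", "Cbl"), each = 5))
  mw_sw <- pairwise_mw(ft_sw, "t1", rank = "zotu")
  expect_equal(mw_sw$p_value, mw$p_value)

  single <- make_ft(rbind(t1 = c(5, 6), t2 = c(7, 8)),
                    corrinoid = c("none", "Cbl"))
  expect_error(pairwise_mw(single, "t1", rank = "zotu"), "single replicate")
})

test_that("statistics are invariant to sample and taxon ordering", {
  gc <- gen_community("microcosm", n_taxa = 30, responders = 1:2,
                      fold_changes = 4, depth = 5000, timepoints = 3,
                      seed = 77)
  ft <- gc$table
  perm_s <- sample(ncol(ft$counts))
  perm_t <- sample(nrow(ft$counts))
  ft2 <- feature_table(ft$counts[perm_t, perm_s],
                       ft$samples[perm_s, ],
                       ft$taxonomy[perm_t, ])
  d1 <- as.matrix(bray_curtis(ft, rank = "order"))
  d2 <- as.matrix(bray_curtis(ft2, rank = "order"))
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
  s1 <- dplyr::arrange(kw_screen(ft, rank = "order"), taxon)
  s2 <- dplyr::arrange(kw_screen(ft2, rank = "order"), taxon)
  expect_equal(s1, s2)
})

test_that("uninoculated controls are excluded from screens but kept for ordination checks", {
  gc <- gen_community("enrichment", n_taxa = 40, depth = 5000,
                      timepoints = 1, media = "M9", seed = 6)
  ft <- gc$table
  expect_true(any(!ft$samples$inoculated))
  sc <- kw_screen(ft, rank = "zotu", timepoints = 1)
  # screened sample count excludes uninoculated wells
  d <- bray_curtis(ft, rank = "zotu")
  res <- permanova_test(d, ifelse(ft$samples$inoculated, "inoc", "ctrl"),
                        n_perm = 199, seed = 2)
  expect_lte(res$p_value, 0.05)  # contamination profile separates clearly
})
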