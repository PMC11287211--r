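test_that("role rule table covers all four marker combinations", {
  ann <- make_annotations(list(
    g_prod = c("K06042", "K00548"),   # biosynthesis + dependent -> producer
    g_dep  = "PF08471",               # dependent marker only
    g_pnu  = "K03394",                # biosynthesis only
    g_ind  = "K00001"                 # decoy only
  ))
  ra <- suppressWarnings(classify_roles(ann))
  got <- setNames(as.character(ra$role), ra$genome_id)
  expect_equal(got[["g_prod"]], "producer")
  expect_equal(got[["g_dep"]], "dependent")
  expect_equal(got[["g_pnu"]], "producer_non_user")
  expect_equal(got[["g_ind"]], "independent")
  expect_true(all(table(ra$role) >= 0))
  expect_equal(sum(table(ra$role)), nrow(ra))
  # producer/non-users carry the unverified flag and raise a warning
  expect_warning(classify_roles(ann), "producer_non_user")
  expect_true(ra$unverified[ra$genome_id == "g_pnu"])
  expect_false(any(ra$unverified[ra$genome_id != "g_pnu"]))
})

test_that("classification is order-independent, idempotent, and matches a brute-force reclassification", {
  gen <- gen_annotations(300, seed = 42)
  ra <- suppressWarnings(classify_roles(gen$annotations))

  # brute force: direct set intersections per genome, written independently
  cfg <- marker_config()
  dep_sets <- cfg$dependent
  split_ann <- split(gen$annotations$annotation_id, gen$annotations$genome_id)
  brute <- vapply(names(split_ann), function(g) {
    d <- unique(split_ann[[g]])
    nb <- length(intersect(d, cfg$biosynthesis))
    nd <- sum(vapply(dep_sets, function(s) length(intersect(s, d)) > 0,
                     logical(1)))
    if (nb > 0 && nd > 0) "producer"
    else if (nb > 0) "producer_non_user"
    else if (nd > 0) "dependent"
    else "independent"
  }, character(1))
  expect_equal(setNames(as.character(ra$role), ra$genome_id),
               brute[ra$genome_id])

  # shuffled input rows give identical assignments
  shuffled <- gen$annotations[sample(nrow(gen$annotations)), ]
  ra2 <- suppressWarnings(classify_roles(shuffled))
  expect_equal(dplyr::arrange(ra, genome_id), dplyr::arrange(ra2, genome_id))
})

test_that("generator truth is recovered and per-phylum counts marginalise", {
  all_dep <- gen_annotations(
    80, role_probs = c(dependent = 1, producer = 0, independent = 0,
                       producer_non_user = 0), seed = 3)
  ra <- classify_roles(all_dep$annotations)
  expect_true(all(ra$role == "dependent"))

  gen <- gen_annotations(400, seed = 7)
  ra <- suppressWarnings(classify_roles(gen$annotations))
  truth <- gen$truth[match(ra$genome_id, gen$truth$genome_id), ]
  expect_equal(as.character(ra$role), truth$role)

  overall <- role_summary(ra)
  by_phy <- role_summary(ra, by = "phylum")
  marg <- by_phy |>
    dplyr::group_by(role) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  expect_equal(
    setNames(marg$n[match(overall$role, marg$role)], NULL),
    overall$n
  )
  expect_equal(sum(overall$n), 400)
})

test_that("redundancy report partitions genomes with both denominators", {
  ann <- make_annotations(list(
    g1 = c("K00548", "K00549"),  # MetH + MetE -> both
    g2 = "K00548",               # dependent only
    g3 = "K00549",               # independent only
    g4 = "K00001"                # neither
  ))
  rep_ <- redundancy_report(ann, functions = "methionine_synthase")
  got <- setNames(rep_$n, rep_$category)
  expect_equal(got[["both"]], 1L)
  expect_equal(got[["dependent_only"]], 1L)
  expect_equal(got[["independent_only"]], 1L)
  expect_equal(got[["neither"]], 1L)
  expect_equal(sum(rep_$n), 4L)
  expect_equal(rep_$pct_all, c(25, 25, 25, 25))
  # detected-denominator excludes the "neither" genome
  expect_equal(rep_$pct_detected[rep_$category == "independent_only"], 100 / 3)
  expect_true(is.na(rep_$pct_detected[rep_$category == "neither"]))

  expect_error(redundancy_report(ann, functions = "nitrogenase"),
               "without a configured")
})

test_that("malformed inputs and configs are rejected with informative errors", {
  expect_error(
    classify_roles(tibble::tibble(genome_id = c("a", ""), domain = "bacteria",
                                  lineage = "P;c",
                                  annotation_id = c("K00001", "K00002"))),
    "empty genome_id"
  )
  expect_error(
    classify_roles(tibble::tibble(genome_id = "a", domain = "bacteria",
                                  lineage = "P;c", annotation_id = "K 0001")),
    "malformed annotation_id"
  )
  # same genome with two different lineages is ambiguous
  expect_error(
    classify_roles(tibble::tibble(genome_id = "a", domain = "bacteria",
                                  lineage = c("P;c", "Q;c"),
                                  annotation_id = c("K00001", "K00002"))),
    "conflicting"
  )
  # an identifier in both sides of one function is contradictory
  expect_error(
    marker_config(dependent = list(ribonucleotide_reductase = "PF08471",
                                   methionine_synthase = "K00548"),
                  independent = list(methionine_synthase = "K00548")),
    "both the dependent and"
  )
  expect_error(
    marker_config(dependent = list(ribonucleotide_reductase = c("PF08471",
                                                                "K00525"))),
    "K00525"
  )
})

test_that("missing taxonomy ranks become explicit unassigned labels", {
  lin <- parse_lineage(c("Actinobacteria;Actinomycetia", "Firmicutes", ""),
                       ranks = c("phylum", "class", "order"))
  expect_equal(lin$phylum, c("Actinobacteria", "Firmicutes",
                             "unassigned_phylum"))
  expect_equal(lin$class, c("Actinomycetia", "unassigned_class",
                            "unassigned_class"))
  expect_equal(lin$order[1], "unassigned_order")
  # greengenes-style prefixes are tolerated
  expect_equal(parse_lineage("p__Bacteroidetes", ranks = "phylum")$phylum,
               "Bacteroidetes")
})
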