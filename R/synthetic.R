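# Ground-truthed synthetic inputs for every analysis stage. Each generator
# returns both the dataset and a `truth` record (parameters, seed, planted
# effects); regeneration from the same (arguments, seed) is identical, and
# downstream recovery tests read the truth rather than re-deriving it.

default_phylum_profile <- function() {
  c(Proteobacteria = 0.31, Actinobacteria = 0.23, Acidobacteria = 0.10,
    Thermoproteota = 0.08, Bacteroidetes = 0.08, Verrucomicrobia = 0.07,
    Firmicutes = 0.05, Chloroflexi = 0.05, Gemmatimonadetes = 0.02,
    Planctomycetes = 0.01)
}

#' Generate a genome annotation table with known ecological roles
#'
#' Samples a corrinoid ecological role per genome and plants marker
#' identifiers that force that role under [classify_roles()]: producers get
#' biosynthesis and corrinoid-dependent markers, dependents only the latter,
#' producer/non-users only the former, independents neither. Every genome
#' additionally receives 1-3 non-marker decoy annotations (and occasionally
#' corrinoid-independent alternatives), so classification must ignore
#' irrelevant identifiers.
#'
#' @param n_genomes Number of genomes.
#' @param role_probs Named probabilities for
#'   `c(dependent, producer, independent, producer_non_user)`; must sum to 1.
#'   The default mirrors a grassland soil MAG set dominated by dependents.
#' @param phylum_profile Named phylum probabilities (`Thermoproteota` is
#'   treated as archaeal).
#' @param seed Integer RNG seed.
#' @param cfg A [marker_config()].
#' @return A list: `annotations` (long tibble), `truth` (tibble
#'   `genome_id`, `role`, plus parameters as attributes).
#' @export
gen_annotations <- function(n_genomes,
                            role_probs = c(dependent = 0.794,
                                           producer = 0.2,
                                           independent = 0.004,
                                           producer_non_user = 0.002),
                            phylum_profile = default_phylum_profile(),
                            seed = 1, cfg = marker_config()) {
  if (!setequal(names(role_probs), corrinoid_roles())) {
    abort("`role_probs` must be named with the four corrinoid roles.")
  }
  if (any(role_probs < 0) || abs(sum(role_probs) - 1) > 1e-8) {
    abort("`role_probs` must be non-negative and sum to 1.")
  }
  stopifnot(n_genomes >= 1)

  dep_ids <- unlist(cfg$dependent, use.names = FALSE)
  ind_ids <- unlist(cfg$independent, use.names = FALSE)
  decoys <- c("K00001", "K02335", "K01872", "K03043", "K02906")

  with_seed(seed, {
    roles <- sample(names(role_probs), n_genomes, replace = TRUE,
                    prob = role_probs)
    phyla <- sample(names(phylum_profile), n_genomes, replace = TRUE,
                    prob = phylum_profile)
    ids <- sprintf("mag_%04d", seq_len(n_genomes))

    rows <- purrr::map(seq_len(n_genomes), function(i) {
      ann <- sample(decoys, sample(1:3, 1))
      if (runif(1) < 0.3) ann <- c(ann, sample(ind_ids, 1))
      if (roles[i] %in% c("producer", "producer_non_user")) {
        ann <- c(ann, sample(cfg$biosynthesis, sample(1:3, 1)))
      }
      if (roles[i] %in% c("producer", "dependent")) {
        ann <- c(ann, sample(dep_ids, sample(1:3, 1)))
      }
      tibble::tibble(
        genome_id = ids[i],
        domain = if (phyla[i] == "Thermoproteota") "archaea" else "bacteria",
        lineage = paste0(phyla[i], ";", phyla[i], "_class"),
        annotation_id = unique(ann)
      )
    })
    truth <- tibble::tibble(genome_id = ids, role = roles, phylum = phyla)
    attr(truth, "params") <- list(n_genomes = n_genomes,
                                  role_probs = role_probs, seed = seed)
    list(annotations = dplyr::bind_rows(rows), truth = truth)
  })
}

#' Deterministic synthetic instantiation of the published MAG breakdown
#'
#' Builds a 503-genome annotation table that plants, exactly, the published
#' role and redundancy structure of the grassland-soil MAG study: 399
#' dependents (79%), 101 producers (20%), 2 independents, 1 archaeal
#' producer/non-user; 307/503 genomes (61%) with the corrinoid-dependent
#' epoxyqueuosine reductase; 45/503 (9%) with both RNR classes; and, of the
#' 400 RNR-carrying genomes, 220 (55%) with only the corrinoid-independent
#' class. This is a synthetic stand-in for the study's supplementary
#' annotation table — it exercises the rule engine and report arithmetic,
#' not the real annotations.
#'
#' @param cfg A [marker_config()].
#' @return A list: `annotations` (long tibble), `truth` (tibble of planted
#'   roles), `expected` (list of the planted percentages).
#' @export
gen_mag_study_table <- function(cfg = marker_config()) {
  n <- 503
  ids <- sprintf("mag_%04d", seq_len(n))
  # genomes 1-399 dependent, 400-500 producer, 501-502 independent, 503 pnu
  role <- c(rep("dependent", 399), rep("producer", 101),
            rep("independent", 2), "producer_non_user")

  ann <- vector("list", n)
  phyla <- c("Proteobacteria", "Actinobacteria", "Acidobacteria",
             "Bacteroidetes", "Verrucomicrobia", "Firmicutes", "Chloroflexi",
             "Gemmatimonadetes", "Planctomycetes")
  for (i in seq_len(n)) {
    a <- "K00001"                                  # decoy on every genome
    if (i <= 307) a <- c(a, cfg$dependent$epoxyqueuosine_reductase[1])
    if (i <= 180) a <- c(a, "PF08471")             # corrinoid-dependent RNR
    if (i <= 45 || (i >= 181 && i <= 397) || i >= 501) {
      a <- c(a, "K00526")                          # corrinoid-independent RNR
    }
    if (i >= 308 && i <= 500) {
      a <- c(a, cfg$dependent$methionine_synthase[1])
    }
    if (role[i] %in% c("producer", "producer_non_user")) {
      a <- c(a, cfg$biosynthesis[1 + (i %% length(cfg$biosynthesis))])
    }
    phylum <- if (i == 503) "Thermoproteota"
      else if (role[i] == "producer" && i <= 430) "Thermoproteota"
      else phyla[1 + (i %% length(phyla))]
    ann[[i]] <- tibble::tibble(
      genome_id = ids[i],
      domain = if (phylum == "Thermoproteota") "archaea" else "bacteria",
      lineage = paste0(phylum, ";", phylum, "_class"),
      annotation_id = a
    )
  }
  list(
    annotations = dplyr::bind_rows(ann),
    truth = tibble::tibble(genome_id = ids, role = role),
    expected = list(pct_dependent = 79, pct_producer = 20, n_independent = 2,
                    n_producer_non_user = 1, pct_queg_dependent = 61,
                    pct_rnr_both = 9, pct_rnr_independent_of_detected = 55)
  )
}

#' Generate a serial-extraction series from a known partition coefficient
#'
#' Forward-simulates equilibrium serial extraction: each round the soil pool
#' is diluted by `1 / (1 + K_d vol_aq / vol_soil)` and the aqueous phase
#' carries `K_d` times the post-round soil concentration. Observed aqueous
#' concentrations are the true values times multiplicative lognormal noise
#' with log-sd `noise_sd`. Mass is conserved exactly in the noiseless truth:
#' the initial pool equals the summed removals plus the residual.
#'
#' @param true_kd Partition coefficient (>= 0).
#' @param initial_pool_pmol_per_g Initial soil pool (pmol per g soil).
#'   Default 34, the scale measured for a corrinoid-rich grassland soil.
#' @param geometry An [extraction_geometry()].
#' @param n_rounds Number of extraction rounds (>= 1). Default 12.
#' @param noise_sd Lognormal log-sd of the measurement noise (>= 0).
#'   Default 0.05 (5%).
#' @param seed Integer RNG seed.
#' @return A list: `series` (tibble `round`, `aq_conc_nM`), `truth` (list
#'   with the parameters, the noiseless aqueous series, and the residual
#'   soil pool after the final round in pmol/g).
#' @export
gen_extraction_series <- function(true_kd,
                                  initial_pool_pmol_per_g = 34,
                                  geometry = extraction_geometry(),
                                  n_rounds = 12, noise_sd = 0.05, seed = 1) {
  assert_scalar_number(true_kd, "true_kd", nonneg = TRUE)
  assert_scalar_number(initial_pool_pmol_per_g, "initial_pool_pmol_per_g",
                       nonneg = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot(n_rounds >= 1)
  stopifnot(inherits(geometry, "extraction_geometry"))

  # soil-phase concentration in nM-equivalents
  soil_nM <- initial_pool_pmol_per_g * geometry$soil_mass /
    geometry$vol_soil / 1000
  ratio <- geometry$vol_aq / geometry$vol_soil
  aq_true <- numeric(n_rounds)
  for (k in seq_len(n_rounds)) {
    soil_nM <- soil_nM / (1 + true_kd * ratio)
    aq_true[k] <- true_kd * soil_nM
  }
  residual <- soil_nM * geometry$vol_soil * 1000 / geometry$soil_mass

  obs <- with_seed(seed, aq_true * rlnorm(n_rounds, 0, noise_sd))
  list(
    series = tibble::tibble(round = seq_len(n_rounds), aq_conc_nM = obs),
    truth = list(kd = true_kd,
                 initial_pool_pmol_per_g = initial_pool_pmol_per_g,
                 aq_true_nM = aq_true, residual_pmol_per_g = residual,
                 geometry = geometry, noise_sd = noise_sd, seed = seed)
  )
}

#' Generate bioassay calibration data from a known saturating curve
#'
#' Draws OD600 readings from a monotone saturating dose-response
#' `od(c) = od_blank + (od_max - od_blank) * c / (c + half_sat_nM)` with
#' multiplicative lognormal noise, plus blank wells.
#'
#' @param conc_nM Calibration concentrations (strictly increasing, > 0).
#' @param shape Named list: `od_blank`, `od_max`, `half_sat_nM`; must be
#'   monotone (`od_max > od_blank`, `half_sat_nM > 0`).
#' @param noise_sd Lognormal log-sd on ODs (>= 0).
#' @param n_reps Replicate wells per concentration.
#' @param n_blanks Number of blank wells.
#' @param seed Integer RNG seed.
#' @return A list: `calibration` (tibble `conc_nM`, `od600`), `blanks`
#'   (numeric), `truth` (parameters and the noiseless ODs).
#' @export
gen_standard_curve <- function(conc_nM = c(0.01, 0.03, 0.1, 0.3, 1),
                               shape = list(od_blank = 0.10, od_max = 0.95,
                                            half_sat_nM = 0.08),
                               noise_sd = 0, n_reps = 3, n_blanks = 6,
                               seed = 1) {
  if (any(diff(conc_nM) <= 0) || any(conc_nM <= 0)) {
    abort("`conc_nM` must be strictly increasing and positive.")
  }
  if (shape$od_max <= shape$od_blank || shape$half_sat_nM <= 0) {
    abort("non-monotone `shape`: need od_max > od_blank and half_sat_nM > 0.")
  }
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)

  od_true <- shape$od_blank + (shape$od_max - shape$od_blank) *
    conc_nM / (conc_nM + shape$half_sat_nM)
  n_conc <- length(conc_nM)
  with_seed(seed, {
    calibration <- tibble::tibble(
      conc_nM = rep(conc_nM, each = n_reps),
      od600 = rep(od_true, each = n_reps) *
        rlnorm(n_conc * n_reps, 0, noise_sd)
    )
    blanks <- shape$od_blank * rlnorm(n_blanks, 0, max(noise_sd, 1e-3))
    list(calibration = calibration, blanks = blanks,
         truth = list(shape = shape, od_true = od_true, conc_nM = conc_nM,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a treatment-structured zOTU feature table
#'
#' Emulates the two 16S study designs: `"enrichment"` (two basal media, six
#' replicates per corrinoid condition plus one uninoculated control, weekly
#' timepoints) and `"microcosm"` (intact soil, five replicates, day
#' timepoints). Seven corrinoid treatments are used throughout: no corrinoid,
#' cobalamin, cobinamide and four lower-ligand variants.
#'
#' Expected relative abundances are log-normal across zOTUs; designated
#' responder zOTUs are multiplied by a per-corrinoid fold-change (suppression
#' via fold-change < 1 is supported) before renormalisation, and per-sample
#' counts are drawn multinomially at the given depth (or
#' Dirichlet-multinomially when `overdispersion > 0`). Each responder is
#' planted in its own dedicated lineage so its signal propagates cleanly to
#' higher taxonomy ranks. Uninoculated controls receive a half-contaminant
#' profile at a tenth of the depth.
#'
#' @param design `"enrichment"` or `"microcosm"`.
#' @param n_taxa Number of zOTUs.
#' @param responders Integer indices (in `1:n_taxa`) of responder zOTUs.
#' @param fold_changes Either a single fold-change applied under every
#'   corrinoid except `"none"`, or a named vector by corrinoid (absent
#'   corrinoids get 1).
#' @param depth Sequencing depth per sample. Default 50000.
#' @param n_reps Replicates per condition; default 6 (enrichment) or 5
#'   (microcosm).
#' @param timepoints Default weeks `c(1, 2, 12, 14)` (enrichment) or days
#'   `c(0, 3, 10, 30, 50)` (microcosm).
#' @param media Default `c("M9", "R2")` (enrichment) or `"soil"` (microcosm).
#' @param corrinoids Treatment levels; the first is the no-corrinoid control.
#' @param baseline_sdlog Log-sd of the baseline abundance distribution.
#' @param overdispersion Dirichlet-multinomial overdispersion (0 = pure
#'   multinomial).
#' @param include_uninoculated Add one uninoculated control per
#'   medium x corrinoid x timepoint (enrichment default).
#' @param seed Integer RNG seed.
#' @return A list: `table` (a [feature_table()]) and `truth` (responder ids,
#'   fold-changes, baseline, parameters).
#' @export
gen_community <- function(design = c("enrichment", "microcosm"),
                          n_taxa = 200, responders = integer(0),
                          fold_changes = 1, depth = 50000,
                          n_reps = NULL, timepoints = NULL, media = NULL,
                          corrinoids = c("none", "Cbl", "Cbi", "AdeCba",
                                         "2MeAdeCba", "CreCba", "5OHBzaCba"),
                          baseline_sdlog = 1, overdispersion = 0,
                          include_uninoculated = NULL, seed = 1) {
  design <- match.arg(design)
  n_reps <- n_reps %||% switch(design, enrichment = 6, microcosm = 5)
  timepoints <- timepoints %||%
    switch(design, enrichment = c(1, 2, 12, 14), microcosm = c(0, 3, 10, 30, 50))
  media <- media %||% switch(design, enrichment = c("M9", "R2"),
                             microcosm = "soil")
  include_uninoculated <- include_uninoculated %||% (design == "enrichment")

  responders <- as.integer(responders)
  if (length(responders) > 0 &&
      (any(responders < 1) || any(responders > n_taxa))) {
    abort("`responders` must index taxa in 1:n_taxa.")
  }
  if (any(fold_changes <= 0)) abort("`fold_changes` must be > 0.")
  if (depth < n_taxa) {
    warn("sequencing depth below the number of taxa: expect many zero counts.")
  }

  fc <- if (is.null(names(fold_changes))) {
    stopifnot(length(fold_changes) == 1)
    setNames(c(1, rep(fold_changes, length(corrinoids) - 1)), corrinoids)
  } else {
    v <- setNames(rep(1, length(corrinoids)), corrinoids)
    v[names(fold_changes)] <- fold_changes
    v
  }

  with_seed(seed, {
    zotu_ids <- sprintf("zotu_%04d", seq_len(n_taxa))
    taxonomy <- synth_taxonomy(n_taxa, zotu_ids, responders)
    baseline <- rlnorm(n_taxa, 0, baseline_sdlog)
    baseline <- baseline / sum(baseline)
    contaminant <- (baseline + 1 / n_taxa) / 2

    grid <- tidyr::expand_grid(medium = media, corrinoid = corrinoids,
                               timepoint = timepoints,
                               replicate = seq_len(n_reps))
    grid$inoculated <- TRUE
    if (include_uninoculated) {
      uninoc <- tidyr::expand_grid(medium = media, corrinoid = corrinoids,
                                   timepoint = timepoints, replicate = 0L)
      uninoc$inoculated <- FALSE
      grid <- dplyr::bind_rows(grid, uninoc)
    }
    grid$sample_id <- sprintf("%s_%s_t%s_r%d", grid$medium, grid$corrinoid,
                              grid$timepoint, grid$replicate)

    counts <- vapply(seq_len(nrow(grid)), function(i) {
      if (grid$inoculated[i]) {
        p <- baseline
        p[responders] <- p[responders] * fc[[grid$corrinoid[i]]]
        p <- p / sum(p)
        dep <- depth
      } else {
        p <- contaminant
        dep <- max(round(depth / 10), n_taxa)
      }
      if (overdispersion > 0) {
        g <- stats::rgamma(n_taxa, shape = p / overdispersion)
        p <- if (sum(g) > 0) g / sum(g) else p
      }
      rmultinom(1, dep, p)[, 1]
    }, integer(n_taxa))
    dimnames(counts) <- list(zotu_ids, grid$sample_id)

    ft <- feature_table(counts, grid, taxonomy)
    list(
      table = ft,
      truth = list(design = design, responders = zotu_ids[responders],
                   responder_orders = unique(taxonomy$order[responders]),
                   fold_changes = fc, baseline = setNames(baseline, zotu_ids),
                   depth = depth, n_reps = n_reps, seed = seed)
    )
  })
}

# hierarchical taxonomy; responders get dedicated lineages so their signal
# propagates intact to higher ranks
synth_taxonomy <- function(n_taxa, zotu_ids, responders) {
  phyla <- names(default_phylum_profile())
  phylum <- sample(phyla, n_taxa, replace = TRUE,
                   prob = default_phylum_profile())
  class_ <- paste0(phylum, "_c", sample(1:2, n_taxa, replace = TRUE))
  order_ <- paste0(class_, "_o", sample(1:2, n_taxa, replace = TRUE))
  family <- paste0(order_, "_f", sample(1:2, n_taxa, replace = TRUE))
  genus <- paste0(family, "_g", sample(1:2, n_taxa, replace = TRUE))
  for (j in seq_along(responders)) {
    i <- responders[j]
    class_[i] <- paste0(phylum[i], "_cResp", j)
    order_[i] <- paste0(class_[i], "_oResp", j)
    family[i] <- paste0(order_[i], "_fResp", j)
    genus[i] <- paste0(family[i], "_gResp", j)
  }
  tibble::tibble(zotu_id = zotu_ids, phylum = phylum, class = class_,
                 order = order_, family = family, genus = genus)
}
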