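#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic cohort
#' generator. Defaults reproduce the structure of a European seed-GSL
#' survey: 797 accessions measured in 2 independent replicates with
#' randomized plate positions, a 23-compound panel (9 canonical
#' short-chain aliphatic compounds plus long-chain/indolic/aromatic
#' filler), chemotype mixture dominated by Allyl (47%) and
#' 2-OH-3-Butenyl (27%), median broad-sense heritability 0.83, and a
#' sharp C3/C4 longitudinal partition south of the
#' Pyrenees--Alps--Carpathians line.
#'
#' @param n_accessions number of accessions.
#' @param n_replicates independent replicates per accession (default 2).
#' @param n_plates number of plate positions measurements are randomized
#'   over (default 8).
#' @param dominance proportion in (0.5, 1] of the short-chain aliphatic
#'   mass carried, in expectation, by the chemotype's dominant compound
#'   (default 0.85).
#' @param heritability_target broad-sense heritability the generated
#'   profiles realize per compound, as a variance-component ratio, in
#'   (0, 1] (default 0.83).
#' @param chemotype_weights named mixture weights over the seven
#'   chemotypes; default 47% Allyl, 27% 2-OH-3-Butenyl, remainder
#'   spread evenly over the other five.
#' @param seed integer seed; fully determines all generator output.
#' @param clade_mutation_rate,tip_mutation_rate substitutions per site
#'   for clade ancestors (from the root) and tips (from their clade
#'   ancestor); both in (0, 0.5), tip rate below clade rate.
#' @param outgroup_rate_multiplier outgroup divergence as a multiple of
#'   `clade_mutation_rate` (at least 3; default 4).
#' @param sequence_length alignment length in bases (at least 100).
#' @param env_effect_sizes named numeric vector of slopes (per standard
#'   deviation of covariate) on the probability of the 2-OH-3-Butenyl
#'   chemotype within the Allyl / 2-OH-3-Butenyl pair; names among
#'   `bio5`, `bio6`, `bio13`, `bio14`, `coast_distance`. Default all 0.
#' @param env_effect_sizes_south optional overrides applied to southern
#'   accessions, to inject geography × environment interactions.
#' @param outgroup_id tip label of the outgroup sequence.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 797,
                       n_replicates = 2,
                       n_plates = 8,
                       dominance = 0.85,
                       heritability_target = 0.83,
                       chemotype_weights = NULL,
                       seed = 1L,
                       clade_mutation_rate = 0.02,
                       tip_mutation_rate = 0.002,
                       outgroup_rate_multiplier = 4,
                       sequence_length = 1200,
                       env_effect_sizes = NULL,
                       env_effect_sizes_south = NULL,
                       outgroup_id = "A_lyrata_outgroup") {
  if (is.null(chemotype_weights)) {
    rest <- (1 - 0.47 - 0.27) / 5
    chemotype_weights <- c("3MSO" = rest, "4MSO" = rest, "3OHP" = rest,
                           "4OHB" = rest, "Allyl" = 0.47,
                           "3-Butenyl" = rest, "2-OH-3-Butenyl" = 0.27)
  }
  cfg <- list(
    n_accessions = n_accessions, n_replicates = n_replicates,
    n_plates = n_plates, dominance = dominance,
    heritability_target = heritability_target,
    chemotype_weights = chemotype_weights, seed = as.integer(seed),
    clade_mutation_rate = clade_mutation_rate,
    tip_mutation_rate = tip_mutation_rate,
    outgroup_rate_multiplier = outgroup_rate_multiplier,
    sequence_length = sequence_length,
    env_effect_sizes = env_effect_sizes,
    env_effect_sizes_south = env_effect_sizes_south,
    outgroup_id = outgroup_id
  )
  .chk <- function(ok, field, msg) {
    if (!ok) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  .chk(is.numeric(n_accessions) && n_accessions >= 0 &&
         n_accessions == round(n_accessions), "n_accessions",
       "must be a non-negative integer")
  .chk(n_replicates >= 1, "n_replicates", "must be >= 1")
  .chk(n_plates >= 1, "n_plates", "must be >= 1")
  .chk(dominance > 0.5 && dominance <= 1, "dominance", "must be in (0.5, 1]")
  .chk(heritability_target > 0 && heritability_target <= 1,
       "heritability_target", "must be in (0, 1]")
  .chk(abs(sum(chemotype_weights) - 1) < 1e-9 && all(chemotype_weights >= 0),
       "chemotype_weights", "must be non-negative and sum to 1")
  .chk(all(sort(names(chemotype_weights)) == sort(chemotype_levels())),
       "chemotype_weights", "must be named by the seven chemotypes")
  .chk(is.finite(cfg$seed), "seed", "must be an integer")
  .chk(clade_mutation_rate > 0 && clade_mutation_rate < 0.5,
       "clade_mutation_rate", "must be in (0, 0.5)")
  .chk(tip_mutation_rate >= 0 && tip_mutation_rate < clade_mutation_rate,
       "tip_mutation_rate", "must be in [0, clade_mutation_rate)")
  .chk(outgroup_rate_multiplier >= 3, "outgroup_rate_multiplier",
       "must be >= 3")
  .chk(outgroup_rate_multiplier * clade_mutation_rate < 0.5,
       "outgroup_rate_multiplier",
       "outgroup rate must stay below 0.5 substitutions per site")
  .chk(sequence_length >= 100, "sequence_length", "must be >= 100")
  ok_env <- function(e) {
    is.null(e) || (is.numeric(e) && all(names(e) %in%
      c("bio5", "bio6", "bio13", "bio14", "coast_distance")))
  }
  .chk(ok_env(env_effect_sizes), "env_effect_sizes",
       "must be named by environmental covariates")
  .chk(ok_env(env_effect_sizes_south), "env_effect_sizes_south",
       "must be named by environmental covariates")
  class(cfg) <- "sim_config"
  cfg
}

# chemotype -> (mam_state, aop_state, expressed gsoh state or NA)
.chemotype_states <- function(chemotype) {
  map <- list(
    "3MSO" = c("MAM2", "AOP_null", NA),
    "4MSO" = c("MAM1", "AOP_null", NA),
    "3OHP" = c("MAM2", "AOP3", NA),
    "4OHB" = c("MAM1", "AOP3", NA),
    "Allyl" = c("MAM2", "AOP2", NA),
    "3-Butenyl" = c("MAM1", "AOP2", "nonfunctional"),
    "2-OH-3-Butenyl" = c("MAM1", "AOP2", "functional")
  )
  map[[chemotype]]
}

.C3_CLADES <- c(1L, 3L, 6L)
.C4_CLADES <- c(2L, 4L, 5L, 7L, 8L)
.AOP_STRUCTURES <- list(AOP2 = "A", AOP3 = c("B", "E"),
                        AOP_null = c("C", "D", "F"))
# latent GS-OH loss-of-function rate in backgrounds where the enzyme is
# phenotypically hidden (roughly the summed masked carrier frequency of
# the known lesion classes)
.MASKED_LOF_RATE <- 0.15

#' Simulate accessions with known ground-truth genotypes
#'
#' Draws a cohort of accessions: chemotype from the configured mixture,
#' enzyme states derived from the chemotype, a MAM haplotype clade (1-8;
#' clades 1, 3, 6 carry the C3/MAM2 state, the rest C4/MAM1), an AOP
#' genomic structure (A = AOP2 expressed; B, E = AOP3; C, D, F = AOP
#' null), a latent GS-OH allele for every accession (expressed only in
#' MAM1 + AOP2 backgrounds), and collection coordinates. Southern
#' accessions (below the mountain-chain boundary) are placed with a
#' sharp longitudinal partition between C4 (west) and C3 (east)
#' chemotypes; northern accessions mix all chemotypes. When
#' `n_accessions >= 50`, every clade and every AOP structure is
#' guaranteed at least one accession (a minimal number of accessions is
#' reassigned if a random draw misses a category).
#'
#' @param config a [sim_config()].
#' @return data.frame of class `gsl_truth`, one row per accession with
#'   columns `accession_id`, `chemotype_true`, `mam_state`, `mam_clade`,
#'   `aop_state`, `aop_structure`, `gsoh_state`, `latitude`, `longitude`,
#'   `region_true`.
#' @export
simulate_accessions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_accessions
  if (n == 0) {
    return(structure(data.frame(), class = c("gsl_truth", "data.frame")))
  }
  withr::with_seed(config$seed, {
    w <- config$chemotype_weights
    chem <- sample(names(w), n, replace = TRUE, prob = w)
    truth <- data.frame(
      accession_id = sprintf("acc%04d", seq_len(n)),
      chemotype_true = chem,
      stringsAsFactors = FALSE
    )
    st <- t(vapply(chem, .chemotype_states, character(3)))
    truth$mam_state <- st[, 1]
    truth$aop_state <- st[, 2]
    gsoh_expr <- st[, 3]
    latent <- ifelse(stats::runif(n) < .MASKED_LOF_RATE,
                     "nonfunctional", "functional")
    truth$gsoh_state <- ifelse(is.na(gsoh_expr), latent, gsoh_expr)
    truth$mam_clade <- ifelse(
      truth$mam_state == "MAM2",
      sample(.C3_CLADES, n, replace = TRUE),
      sample(.C4_CLADES, n, replace = TRUE)
    )
    pick_structure <- function(state) {
      s <- .AOP_STRUCTURES[[state]]
      if (length(s) == 1) s else sample(s, 1)
    }
    truth$aop_structure <- vapply(truth$aop_state, pick_structure, character(1))

    # geography: ~55% of accessions south of the mountain line, where the
    # two predominant chemotypes partition sharply by longitude (C4 to the
    # west of 5 degrees E, C3 to the east); the north mixes everything
    south <- stats::runif(n) < 0.55
    is_c4 <- truth$mam_state == "MAM1"
    lon <- numeric(n)
    lat <- numeric(n)
    lat[south] <- stats::runif(sum(south), 36, 42)
    lon[south & is_c4] <- stats::runif(sum(south & is_c4), -10, 5)
    lon[south & !is_c4] <- stats::runif(sum(south & !is_c4), 5, 25)
    lat[!south] <- stats::runif(sum(!south), 47.5, 60)
    lon[!south] <- stats::runif(sum(!south), -10, 25)
    truth$latitude <- lat
    truth$longitude <- lon
    truth$region_true <- ifelse(south, "south", "north")

    if (n >= 50) {
      truth <- .ensure_coverage(truth)
    }
    class(truth) <- c("gsl_truth", "data.frame")
    truth
  })
}

# guarantee every clade and AOP structure at least one accession.
# Donors are accessions whose current category is represented more than
# once, so an earlier assignment is never stolen; if a state has no
# spare donor, an Allyl accession (the most common class) is converted.
.ensure_coverage <- function(truth) {
  for (cl in c(.C3_CLADES, .C4_CLADES)) {
    if (!any(truth$mam_clade == cl)) {
      state <- if (cl %in% .C3_CLADES) "MAM2" else "MAM1"
      cand <- which(truth$mam_state == state)
      over <- cand[duplicated(truth$mam_clade[cand])]
      if (length(over) > 0) {
        truth$mam_clade[over[1]] <- cl
      }
    }
  }
  for (state in names(.AOP_STRUCTURES)) {
    for (s in .AOP_STRUCTURES[[state]]) {
      if (any(truth$aop_structure == s)) next
      cand <- which(truth$aop_state == state)
      over <- cand[duplicated(truth$aop_structure[cand])]
      if (length(over) > 0) {
        truth$aop_structure[over[1]] <- s
      } else {
        # convert a spare Allyl accession (structure A is duplicated)
        allyl <- which(truth$chemotype_true == "Allyl")
        donors <- allyl[duplicated(truth$aop_structure[allyl])]
        if (length(donors) == 0) next
        i <- donors[1]
        truth$aop_state[i] <- state
        truth$aop_structure[i] <- s
        truth$chemotype_true[i] <- classify_chemotype(
          truth$mam_state[i], state,
          if (state == "AOP2") truth$gsoh_state[i] else "masked")
      }
    }
  }
  truth
}

# expected per-compound seed amounts (µmol/g) for a chemotype: the
# dominant compound carries `dominance` of the short-chain total, the
# remainder is split evenly over the other eight short-chain compounds
.chemotype_means <- function(chemotype, dominance, total = 20) {
  short <- .canonical_compounds()
  mu <- stats::setNames(rep(total * (1 - dominance) / (length(short) - 1), length(short)),
                        short)
  mu[chemotype] <- total * dominance
  mu
}

# fixed expected amounts for the 14 filler compounds (chemotype-independent)
.filler_means <- function() {
  c("5MSO" = 1.2, "6MSO" = 0.6, "7MSO" = 2.5, "8MSO" = 3.5,
    "5MT" = 0.3, "6MT" = 0.2, "7MT" = 0.8, "8MT" = 1.5,
    "I3M" = 2.0, "4OHI3M" = 0.4, "4MOI3M" = 0.7, "1MOI3M" = 0.9,
    "Benzyl" = 0.3, "2PE" = 0.5)
}

#' Simulate replicated glucosinolate profiles
#'
#' Generates the measurement table for a cohort: per-accession genetic
#' expected amounts (log-normal around the chemotype-determined means,
#' so the dominant compound carries the configured `dominance` fraction
#' of the short-chain aliphatic total in expectation), multiplied by
#' log-normal replicate, plate and residual noise. Per compound, the
#' noise variance is calibrated against the realized spread of genetic
#' values so that the broad-sense heritability (accession variance over
#' total, on the measurement scale) matches `heritability_target`; with
#' `heritability_target = 1` replicate measurements are exactly
#' identical. The design is balanced: every
#' (accession, replicate, compound) cell is present, with plate
#' positions randomized across accession × replicate units.
#'
#' @param truth output of [simulate_accessions()].
#' @param config the same [sim_config()].
#' @return a `gsl_measurements` data.frame (see [read_measurements()]).
#' @export
simulate_profiles <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) == 0) {
    stop("`truth` must contain at least one accession")
  }
  n <- nrow(truth)
  h2 <- config$heritability_target
  v_alpha <- 0.04  # accession-level quantitative variation within chemotype
  compounds <- c(.canonical_compounds(), names(.filler_means()))
  withr::with_seed(config$seed + 2L, {
    # genetic expected amount per accession x compound
    G <- matrix(0, nrow = n, ncol = length(compounds),
                dimnames = list(truth$accession_id, compounds))
    fill <- .filler_means()
    for (i in seq_len(n)) {
      mu <- c(.chemotype_means(truth$chemotype_true[i], config$dominance), fill)
      G[i, ] <- mu[compounds]
    }
    # centre the log-normal accession deviate so E[G] stays at mu
    alpha <- matrix(stats::rnorm(n * length(compounds), -v_alpha / 2,
                                 sqrt(v_alpha)),
                    nrow = n)
    G <- G * exp(alpha)

    reps <- seq_len(config$n_replicates)
    design <- expand.grid(accession = truth$accession_id, replicate = reps,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design$plate <- sprintf("P%02d", sample.int(config$n_plates,
                                                nrow(design), replace = TRUE))
    # per-compound residual log-variance solving
    #   h2 = Var(G) / (Var(G) + E[G^2] (e^V - 1));
    # replicate and plate main effects are fitted out by the ANOVA, so
    # they sit outside the calibration and get small proportional shifts
    tab_list <- vector("list", length(compounds))
    rep_eff <- stats::rnorm(length(reps))
    plate_eff <- stats::rnorm(config$n_plates)
    for (j in seq_along(compounds)) {
      g <- G[, j]
      vG <- if (n < 2) 0 else stats::var(g) * (n - 1) / n
      V <- if (h2 >= 1 || vG == 0) 0 else log1p(vG * (1 - h2) / (h2 * mean(g^2)))
      sd_r <- sqrt(0.05 * V); sd_p <- sqrt(0.05 * V); sd_e <- sqrt(V)
      b <- rep_eff * sd_r - sd_r^2 / 2
      p <- plate_eff * sd_p - sd_p^2 / 2
      e <- stats::rnorm(nrow(design), -sd_e^2 / 2, sd_e)
      noise <- exp(b[match(design$replicate, reps)] +
                     p[as.integer(substring(design$plate, 2))] + e)
      tab_list[[j]] <- data.frame(
        accession = design$accession,
        replicate = design$replicate,
        plate = design$plate,
        compound = compounds[j],
        amount = g[match(design$accession, truth$accession_id)] * noise,
        stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, tab_list)
    rownames(tab) <- NULL
    class(tab) <- c("gsl_measurements", "data.frame")
    tab
  })
}

.BASES <- c("A", "C", "G", "T")

.mutate_seq <- function(x, rate) {
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit) > 0) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(.BASES, b), 1),
                     character(1))
  }
  x
}

#' Simulate clade-structured marker sequences with an outgroup
#'
#' Emulates a haplotype marker gene: a random root sequence, eight clade
#' ancestors mutated from the root at `clade_mutation_rate`, accession
#' tips mutated from their clade ancestor at the (smaller)
#' `tip_mutation_rate`, and an outgroup mutated from the root at
#' `outgroup_rate_multiplier` times the clade rate. The result is an
#' equal-length, gap-free alignment.
#'
#' @inheritParams simulate_profiles
#' @return named character vector of aligned sequences (one per
#'   accession plus the outgroup), attribute `outgroup` giving its id.
#' @export
simulate_sequences <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) == 0) {
    stop("`truth` must contain at least one accession")
  }
  L <- config$sequence_length
  withr::with_seed(config$seed + 3L, {
    root <- sample(.BASES, L, replace = TRUE)
    ancestors <- lapply(1:8, function(k) .mutate_seq(root, config$clade_mutation_rate))
    tips <- vapply(seq_len(nrow(truth)), function(i) {
      paste(.mutate_seq(ancestors[[truth$mam_clade[i]]],
                        config$tip_mutation_rate), collapse = "")
    }, character(1))
    names(tips) <- truth$accession_id
    out <- paste(.mutate_seq(root, config$outgroup_rate_multiplier *
                               config$clade_mutation_rate), collapse = "")
    seqs <- c(tips, stats::setNames(out, config$outgroup_id))
    attr(seqs, "outgroup") <- config$outgroup_id
    seqs
  })
}

#' Simulate environmental covariates and inject chemotype associations
#'
#' Generates the five environmental covariates as smooth functions of
#' latitude/longitude plus noise (maximal temperature of the warmest
#' month `bio5` and minimal temperature of the coldest month `bio6` in
#' °C, precipitation of the wettest/driest month `bio13`/`bio14` in mm,
#' distance to the coast in km), assigns a genomic group correlated
#' with region, and, if `env_effect_sizes` are configured, re-draws the
#' Allyl vs 2-OH-3-Butenyl chemotype of pair accessions with
#' probabilities shifted by the standardized covariates (so that
#' [fit_region_model()] can recover the injected effects). Enzyme
#' states, clade and AOP structure are updated consistently for flipped
#' accessions, and `region_true` is recomputed with [assign_region()].
#'
#' @inheritParams simulate_profiles
#' @return list with `meta` (an `AccessionMeta` data.frame:
#'   `accession_id`, coordinates, `genomic_group`, covariates, `region`)
#'   and `truth` (the possibly updated ground truth). Use the returned
#'   `truth` for any later profile or sequence simulation.
#' @export
simulate_environment <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) == 0) {
    stop("`truth` must contain at least one accession")
  }
  n <- nrow(truth)
  withr::with_seed(config$seed + 1L, {
    lat <- truth$latitude
    lon <- truth$longitude
    meta <- data.frame(
      accession_id = truth$accession_id,
      latitude = lat, longitude = lon,
      bio5 = 36 - 0.3 * (lat - 35) + 0.15 * lon + stats::rnorm(n, 0, 2.5),
      bio6 = 4 - 0.5 * (lat - 35) - 0.25 * lon + stats::rnorm(n, 0, 3),
      bio13 = 55 + 0.8 * (lat - 45) - 0.3 * lon + stats::rnorm(n, 0, 15),
      bio14 = pmax(0, 35 - 1.0 * (lat - 35) + stats::rnorm(n, 0, 10)),
      coast_distance = pmax(0, 120 + 5 * lon + stats::rnorm(n, 0, 80)),
      stringsAsFactors = FALSE
    )
    region <- assign_region(meta)
    meta$region <- region
    # genomic group: categorical demography proxy correlated with region
    grp_north <- c("admixed", "central_europe", "north_sweden", "germany")
    grp_south <- c("admixed", "iberia", "relict", "italy_balkan")
    meta$genomic_group <- ifelse(
      region == "north",
      sample(grp_north, n, replace = TRUE, prob = c(0.2, 0.4, 0.25, 0.15)),
      sample(grp_south, n, replace = TRUE, prob = c(0.2, 0.45, 0.1, 0.25))
    )

    eff <- config$env_effect_sizes
    if (!is.null(eff) || !is.null(config$env_effect_sizes_south)) {
      covars <- c("bio5", "bio6", "bio13", "bio14", "coast_distance")
      z <- scale(as.matrix(meta[, covars]))
      b <- stats::setNames(rep(0, length(covars)), covars)
      b[names(eff)] <- eff
      bs <- b
      if (!is.null(config$env_effect_sizes_south)) {
        bs[names(config$env_effect_sizes_south)] <- config$env_effect_sizes_south
      }
      pair <- truth$chemotype_true %in% c("Allyl", "2-OH-3-Butenyl")
      w <- config$chemotype_weights
      p0 <- w[["2-OH-3-Butenyl"]] / (w[["Allyl"]] + w[["2-OH-3-Butenyl"]])
      shift <- ifelse(region == "south", z %*% bs, z %*% b)
      p <- pmin(0.98, pmax(0.02, p0 + shift))
      new_chem <- ifelse(stats::runif(n) < p, "2-OH-3-Butenyl", "Allyl")
      flip <- pair & new_chem != truth$chemotype_true
      truth <- .apply_chemotype_flip(truth, which(flip), new_chem[flip])
    }
    truth$region_true <- region
    list(meta = meta, truth = truth)
  })
}

# switch accessions between the Allyl and 2-OH-3-Butenyl chemotypes,
# keeping genotype fields consistent (deterministic category choice)
.apply_chemotype_flip <- function(truth, idx, new_chem) {
  for (k in seq_along(idx)) {
    i <- idx[k]
    truth$chemotype_true[i] <- new_chem[k]
    st <- .chemotype_states(new_chem[k])
    truth$mam_state[i] <- st[1]
    truth$aop_state[i] <- st[2]
    if (!is.na(st[3])) truth$gsoh_state[i] <- st[3]
    pool <- if (st[1] == "MAM2") .C3_CLADES else .C4_CLADES
    if (!truth$mam_clade[i] %in% pool) {
      truth$mam_clade[i] <- pool[1 + (i %% length(pool))]
    }
  }
  truth
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [simulate_accessions()],
#' [simulate_environment()] (which may flip chemotypes of the
#' Allyl / 2-OH-3-Butenyl pair when environmental effects are
#' configured), [simulate_profiles()] and [simulate_sequences()] in the
#' consistent order.
#'
#' @param config a [sim_config()].
#' @param sequences logical; set `FALSE` to skip sequence simulation.
#' @return list with `truth`, `meta`, `measurements`, `sequences`
#'   and the `config`.
#' @export
simulate_cohort <- function(config, sequences = TRUE) {
  truth <- simulate_accessions(config)
  env <- simulate_environment(truth, config)
  truth <- env$truth
  list(
    truth = truth,
    meta = env$meta,
    measurements = simulate_profiles(truth, config),
    sequences = if (sequences) simulate_sequences(truth, config) else NULL,
    config = config
  )
}

#' Write the pieces of a simulated cohort to files
#'
#' Measurements, ground truth and metadata as TSV; sequences as FASTA.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    measurements = file.path(dir, "measurements.tsv"),
    truth = file.path(dir, "truth.tsv"),
    meta = file.path(dir, "meta.tsv"),
    sequences = file.path(dir, "sequences.fasta")
  )
  write_measurements(cohort$measurements, paths["measurements"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cohort$sequences)) {
    write_fasta(cohort$sequences, paths["sequences"])
  } else {
    paths <- paths[names(paths) != "sequences"]
  }
  invisible(paths)
}
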