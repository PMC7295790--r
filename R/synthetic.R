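#' Parameters for the synthetic incidence-matrix generator
#'
#' The generator draws every cell of a species-by-condition incidence
#' matrix as an independent Bernoulli trial whose probability is the
#' clipped product of a heavy-tailed per-species baseline detectability, a
#' per-condition effect, and multiplicative modifiers for the designated
#' dominant condition, rumen-fluid supplementation, alcohol pre-treatment
#' and the recovery of strict anaerobes under an aerobic atmosphere.
#' Defaults emulate the structure of a large stool culturomics survey:
#' ~500 species over ~58 conditions, one dominant condition recovering
#' about 62% of all species on its own, a long non-increasing tail of
#' marginal gains, anaerobic conditions jointly capturing ~99% of
#' species, two thirds of species strictly anaerobic, and a detectability
#' boost on rumen-supplemented media.
#'
#' @param n_species,n_conditions matrix dimensions (>= 1).
#' @param n_aerobic number of aerobic conditions (the rest anaerobic);
#'   defaults to the survey's share, round(18/58 * n_conditions).
#' @param seed integer seed; generation is deterministic given the seed.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-species baseline detection probability (heavy-tailed: a few
#'   ubiquitous species, many rare ones).
#' @param condition_meanlog,condition_sdlog log-normal parameters of the
#'   per-condition effect multiplier.
#' @param dominant_boost baseline multiplier for the designated dominant
#'   condition (replaces its random condition effect, so the dominant
#'   condition's expected richness is set by this value alone).
#' @param supplement_boost multiplier for conditions supplemented with
#'   rumen fluid.
#' @param aerobic_effect multiplier on the effect of aerobic conditions
#'   (aerobic media recover far fewer gut species).
#' @param alcohol_effect multiplier for alcohol pre-treated conditions
#'   (the pre-treatment is selective for spore-formers).
#' @param aerobic_penalty multiplier on a strict anaerobe's detection
#'   probability under an aerobic condition; 0 makes aerobic recovery of
#'   strict anaerobes impossible.
#' @param anaerobe_fraction proportion of species flagged strict
#'   anaerobes (the rest oxygen-tolerant).
#' @param rumen_rate probability that an unconstrained condition carries
#'   rumen fluid.
#' @param new_taxon_rate proportion of species flagged as new taxa.
#' @param max_retries redraw cap per species for the all-zero-row rule.
#' @return object of class `synthetic_params` (a validated list).
#' @export
synthetic_params <- function(n_species = 497,
                             n_conditions = 58,
                             n_aerobic = round(n_conditions * 18 / 58),
                             seed = 1,
                             baseline_meanlog = log(0.04),
                             baseline_sdlog = 0.85,
                             condition_meanlog = log(3.0),
                             condition_sdlog = 0.34,
                             dominant_boost = 14.3,
                             supplement_boost = 1.45,
                             aerobic_effect = 0.24,
                             alcohol_effect = 0.20,
                             aerobic_penalty = 0.12,
                             anaerobe_fraction = 0.67,
                             rumen_rate = 0.3,
                             new_taxon_rate = 19 / 497,
                             max_retries = 100) {
  p <- list(n_species = as.integer(n_species),
            n_conditions = as.integer(n_conditions),
            n_aerobic = as.integer(n_aerobic), seed = as.integer(seed),
            baseline_meanlog = baseline_meanlog,
            baseline_sdlog = baseline_sdlog,
            condition_meanlog = condition_meanlog,
            condition_sdlog = condition_sdlog,
            dominant_boost = dominant_boost,
            supplement_boost = supplement_boost,
            aerobic_effect = aerobic_effect,
            alcohol_effect = alcohol_effect,
            aerobic_penalty = aerobic_penalty,
            anaerobe_fraction = anaerobe_fraction,
            rumen_rate = rumen_rate,
            new_taxon_rate = new_taxon_rate,
            max_retries = as.integer(max_retries))
  if (p$n_species < 1L || p$n_conditions < 1L) {
    stop("n_species and n_conditions must be >= 1", call. = FALSE)
  }
  if (p$n_aerobic < 0L || p$n_aerobic > p$n_conditions) {
    stop("n_aerobic must lie in [0, n_conditions]", call. = FALSE)
  }
  mult <- c("dominant_boost", "supplement_boost", "aerobic_effect",
            "alcohol_effect")
  if (any(unlist(p[mult]) <= 0)) {
    stop("multipliers must be > 0", call. = FALSE)
  }
  frac <- c("anaerobe_fraction", "rumen_rate", "new_taxon_rate")
  if (any(unlist(p[frac]) < 0 | unlist(p[frac]) > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (p$aerobic_penalty < 0 || p$aerobic_penalty > 1) {
    stop("aerobic_penalty must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "synthetic_params")
}

default_synthetic_conditions <- function(p) {
  n <- p$n_conditions
  atmosphere <- rep(c("anaerobic", "aerobic"),
                    c(n - p$n_aerobic, p$n_aerobic))
  temperature <- ifelse(stats::runif(n) < 0.15, 28, 37)
  rumen <- stats::runif(n) < p$rumen_rate
  blood <- stats::runif(n) < 0.5
  supplements <- ifelse(rumen & blood, "rumen_fluid;sheep_blood",
                        ifelse(rumen, "rumen_fluid",
                               ifelse(blood, "sheep_blood", "none")))
  pretreatment <- sample(c("none", "alcohol", "thermic_shock",
                           "filtration_0_45um", "filtration_5um"),
                         n, replace = TRUE,
                         prob = c(0.70, 0.15, 0.05, 0.05, 0.05))
  # dominant condition: first anaerobic one, supplemented like a blood
  # culture bottle with rumen fluid and sheep blood
  supplements[1] <- "rumen_fluid;sheep_blood"
  pretreatment[1] <- "none"
  temperature[1] <- 37
  id <- sprintf("C%02d_%s_%d", seq_len(n),
                ifelse(atmosphere == "anaerobic", "Ana", "Ae"), temperature)
  data.frame(id = id, label = id, atmosphere = atmosphere,
             temperature_c = temperature, supplements = supplements,
             pretreatment = pretreatment, group = NA_character_,
             pair_id = NA_integer_, stringsAsFactors = FALSE)
}

has_rumen <- function(supplements) {
  vapply(strsplit(supplements, ";", fixed = TRUE),
         function(s) "rumen_fluid" %in% s, logical(1L))
}

#' Generate a synthetic culturomics incidence matrix
#'
#' Draws a seeded binary species-by-condition matrix under the
#' probability model described in [synthetic_params()]. Species whose row
#' comes out all-zero (never isolated anywhere — not a legal record) are
#' redrawn up to `max_retries` times; pathological parameter settings
#' that exhaust the cap raise a generation error naming the number of
#' offending species.
#'
#' @param params a [synthetic_params()] object.
#' @param conditions optional condition metadata data.frame (columns as
#'   in [incidence_matrix()] plus an optional integer `pair_id`:
#'   conditions sharing a `pair_id` share their base condition effect, so
#'   a rumen-supplemented member differs from its match only by the
#'   supplement boost). When omitted, metadata is drawn from the
#'   parameters. Row 1 is the designated dominant condition.
#' @return list with `matrix` (an `incidence_matrix`), `conditions` and
#'   `species` metadata data.frames.
#' @export
generate_incidence <- function(params = synthetic_params(),
                               conditions = NULL) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  with_local_seed(p$seed, {
    cond <- if (is.null(conditions)) default_synthetic_conditions(p) else conditions
    if (nrow(cond) != p$n_conditions) {
      stop("condition metadata rows must equal n_conditions", call. = FALSE)
    }
    if (!"pair_id" %in% names(cond)) cond$pair_id <- NA_integer_

    n <- p$n_species
    base <- pmin(stats::rlnorm(n, p$baseline_meanlog, p$baseline_sdlog), 1)
    effect <- stats::rlnorm(nrow(cond), p$condition_meanlog, p$condition_sdlog)
    for (pid in unique(cond$pair_id[!is.na(cond$pair_id)])) {
      idx <- which(cond$pair_id == pid)
      effect[idx] <- effect[idx[1L]]        # matched pairs share base effect
    }
    effect[cond$atmosphere == "aerobic"] <-
      effect[cond$atmosphere == "aerobic"] * p$aerobic_effect
    effect[cond$pretreatment == "alcohol"] <-
      effect[cond$pretreatment == "alcohol"] * p$alcohol_effect
    effect[has_rumen(cond$supplements)] <-
      effect[has_rumen(cond$supplements)] * p$supplement_boost

    phenotype <- ifelse(stats::runif(n) < p$anaerobe_fraction,
                        "strict_anaerobe", "oxygen_tolerant")

    prob <- outer(base, effect)
    prob[, 1L] <- base * p$dominant_boost   # dominant condition overrides
    aerobic_cols <- cond$atmosphere == "aerobic"
    prob[phenotype == "strict_anaerobe", aerobic_cols] <-
      prob[phenotype == "strict_anaerobe", aerobic_cols] * p$aerobic_penalty
    prob <- pmin(pmax(prob, 0), 1)

    m <- matrix(stats::rbinom(length(prob), 1L, prob), nrow = n)
    for (i in which(rowSums(m) == 0L)) {
      tries <- 0L
      while (sum(m[i, ]) == 0L) {
        tries <- tries + 1L
        if (tries > p$max_retries) {
          stop(sprintf(paste("synthetic generation failed: %d species still",
                             "undetected after %d redraw(s); detection",
                             "probabilities are too small"),
                       sum(rowSums(m) == 0L), p$max_retries), call. = FALSE)
        }
        m[i, ] <- stats::rbinom(ncol(m), 1L, prob[i, ])
      }
    }

    species <- data.frame(
      name = sprintf("Bacterium sp%04d", seq_len(n)),
      phylum = sample(c("Firmicutes", "Bacteroidetes", "Actinobacteria",
                        "Proteobacteria", "Fusobacteria", "Verrucomicrobia",
                        "Synergistetes"), n, replace = TRUE,
                      prob = c(0.55, 0.14, 0.13, 0.12, 0.03, 0.02, 0.01)),
      oxygen_phenotype = phenotype,
      is_new_taxon = stats::runif(n) < p$new_taxon_rate,
      accession = NA_character_,
      stringsAsFactors = FALSE)

    rownames(m) <- species$name
    colnames(m) <- cond$id
    meta_cols <- setdiff(names(cond), "pair_id")
    list(matrix = incidence_matrix(m, condition_meta = cond[meta_cols],
                                   species_meta = species),
         conditions = cond, species = species)
  })
}

study_shaped_conditions <- function() {
  rows <- list()
  add <- function(id, atm, temp, supp, pre, group, pair = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, label = id, atmosphere = atm, temperature_c = temp,
      supplements = supp, pretreatment = pre, group = group,
      pair_id = pair, stringsAsFactors = FALSE)
  }
  ## group "18_standard" (12 anaerobic / 6 aerobic), incl. the dominant
  ## rumen+blood bottle and three matched rumen pairs
  add("STD01_HRS_Ana_37", "anaerobic", 37, "rumen_fluid;sheep_blood", "none",
      "18_standard", 1L)
  add("STD02_HS_Ana_37", "anaerobic", 37, "sheep_blood", "none",
      "18_standard", 1L)
  add("STD03_HR_Ana_37", "anaerobic", 37, "rumen_fluid", "none",
      "18_standard", 2L)
  add("STD04_Hemoc_Ana_37", "anaerobic", 37, "none", "none",
      "18_standard", 2L)
  add("STD05_HRS_Ae_37", "aerobic", 37, "rumen_fluid;sheep_blood", "none",
      "18_standard", 3L)
  add("STD06_HS_Ae_37", "aerobic", 37, "sheep_blood", "none",
      "18_standard", 3L)
  for (i in 7:13) {
    add(sprintf("STD%02d_Ana_37", i), "anaerobic", 37,
        if (i %% 2 == 0) "sheep_blood" else "none", "none", "18_standard")
  }
  add("STD14_Ae_37", "aerobic", 37, "none", "none", "18_standard")
  add("STD15_TS_Ana_37", "anaerobic", 37, "none", "thermic_shock",
      "18_standard")
  add("STD16_Ae_37", "aerobic", 37, "none", "none", "18_standard")
  add("STD17_Ae_37", "aerobic", 37, "sheep_blood", "none", "18_standard")
  add("STD18_Ae_28", "aerobic", 28, "none", "none", "18_standard")

  ## group "18_new" (14 anaerobic / 4 aerobic), two matched rumen pairs
  add("NEW01_R_SARS_Ana_37", "anaerobic", 37,
      "rumen_fluid;sheep_blood;lamb_serum", "none", "18_new")
  add("NEW02_R_Ana_37", "anaerobic", 37, "rumen_fluid", "none", "18_new", 4L)
  add("NEW03_Ana_37", "anaerobic", 37, "none", "none", "18_new", 4L)
  add("NEW04_R_Ana_28", "anaerobic", 28, "rumen_fluid", "none", "18_new", 5L)
  add("NEW05_Ana_28", "anaerobic", 28, "none", "none", "18_new", 5L)
  add("NEW06_YCFA_Ana_37", "anaerobic", 37, "none", "none", "18_new")
  add("NEW07_Filt045_Ana_37", "anaerobic", 37, "none", "filtration_0_45um",
      "18_new")
  add("NEW08_Filt5_Ana_37", "anaerobic", 37, "none", "filtration_5um",
      "18_new")
  for (i in 9:14) {
    add(sprintf("NEW%02d_Ana_37", i), "anaerobic", 37,
        if (i %% 3 == 0) "rumen_fluid;sheep_blood" else "sheep_blood",
        "none", "18_new")
  }
  add("NEW15_Filt045_Ae_37", "aerobic", 37, "none", "filtration_0_45um",
      "18_new")
  add("NEW16_Ae_37", "aerobic", 37, "sheep_blood", "none", "18_new")
  add("NEW17_Ae_37", "aerobic", 37, "rumen_fluid", "none", "18_new")
  add("NEW18_Ae_28", "aerobic", 28, "none", "none", "18_new")

  ## group "22_alcohol" (14 anaerobic / 8 aerobic), alcohol pre-treated,
  ## two matched rumen pairs
  add("ALC01_HRS_Ana_37", "anaerobic", 37, "rumen_fluid;sheep_blood",
      "alcohol", "22_alcohol", 6L)
  add("ALC02_HS_Ana_37", "anaerobic", 37, "sheep_blood", "alcohol",
      "22_alcohol", 6L)
  add("ALC03_HR_Ae_28", "aerobic", 28, "rumen_fluid", "alcohol",
      "22_alcohol", 7L)
  add("ALC04_H_Ae_28", "aerobic", 28, "none", "alcohol", "22_alcohol", 7L)
  for (i in 5:16) {
    add(sprintf("ALC%02d_Ana_%d", i, if (i %% 4 == 0) 28 else 37),
        "anaerobic", if (i %% 4 == 0) 28 else 37,
        if (i %% 2 == 0) "sheep_blood" else "none", "alcohol", "22_alcohol")
  }
  for (i in 17:22) {
    add(sprintf("ALC%02d_Ae_%d", i, if (i %% 2 == 0) 28 else 37),
        "aerobic", if (i %% 2 == 0) 28 else 37,
        if (i %% 3 == 0) "rumen_fluid" else "none", "alcohol", "22_alcohol")
  }
  do.call(rbind, rows)
}

#' Study-shaped synthetic fixture
#'
#' Convenience preset mirroring the structure of the 58-condition, 8-stool
#' culturomics survey the package's methods were designed around: 497
#' species over 58 conditions (40 anaerobic / 18 aerobic), condition
#' groups tagged `18_standard`, `18_new` and `22_alcohol` (sizes
#' 18/18/22), 67% strict anaerobes, one dominant rumen-and-blood
#' anaerobic bottle, and seven rumen-supplemented conditions each matched
#' by the same condition without rumen (retrievable as the contrast
#' arms).
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_params()].
#' @return list with `matrix`, `conditions`, `species` as in
#'   [generate_incidence()], plus `arms`: list of condition-id vectors
#'   `rumen` and `matched`.
#' @examples
#' fx <- study_shaped_fixture(seed = 42)
#' fx$matrix
#' @export
study_shaped_fixture <- function(seed = 1, ...) {
  cond <- study_shaped_conditions()
  params <- synthetic_params(n_species = 497, n_conditions = nrow(cond),
                             n_aerobic = sum(cond$atmosphere == "aerobic"),
                             seed = seed, ...)
  out <- generate_incidence(params, conditions = cond)
  paired <- cond[!is.na(cond$pair_id), ]
  out$arms <- list(rumen = paired$id[has_rumen(paired$supplements)],
                   matched = paired$id[!has_rumen(paired$supplements)])
  out
}
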