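# fixed vocabulary of annotation region classes, ordered by distance to TSS
region_classes <- c("promoter", "5'UTR", "exon", "intron", "3'UTR",
                    "distal intergenic")

#' Describe one species' sampling design
#'
#' A species design couples the life-history constants a cross-species clock
#' needs (maximum lifespan, age of sexual maturity) with the tissue sampling
#' plan: how many samples per tissue and over which age range ages are drawn
#' uniformly.
#'
#' @param name Species name.
#' @param max_lifespan Maximum recorded lifespan, years.
#' @param maturity_age Age of sexual maturity, years.
#' @param tissues `data.frame` with columns `tissue`, `n`, `min_age`,
#'   `max_age` and optionally `n_female`.
#' @return A `species_design` list.
#' @export
species_design <- function(name, max_lifespan, maturity_age, tissues) {
  stopifnot(is.character(name), max_lifespan > 0, maturity_age > 0,
            is.data.frame(tissues),
            all(c("tissue", "n", "min_age", "max_age") %in% names(tissues)))
  if (any(tissues$n < 0)) stop("tissue sample counts must be >= 0")
  if (any(tissues$min_age < 0) || any(tissues$max_age > max_lifespan) ||
      any(tissues$min_age > tissues$max_age)) {
    stop("tissue age ranges must lie within [0, max_lifespan]")
  }
  if (is.null(tissues$n_female)) tissues$n_female <- NA_integer_
  structure(list(name = name, max_lifespan = max_lifespan,
                 maturity_age = maturity_age, tissues = tissues),
            class = "species_design")
}

#' Built-in study designs
#'
#' `macaque_design()` reproduces the rhesus macaque multi-tissue study
#' design: 281 samples over 8 tissues — blood (n = 199, ages 1.79–42 y),
#' skin (n = 51, 7.61–42 y) and six postmortem tissues with n <= 6 each —
#' with maximum lifespan 42 y. `human_design()` is a blood + skin human
#' cohort (ages 0–93 y, maximum lifespan 122.5 y), scaled by default to
#' n = 200 for desk-scale runtime. `vervet_design()` is a vervet-like
#' transfer species (blood, cortex, liver; maximum lifespan 30.8 y) used to
#' study cross-species application of a fitted clock.
#'
#' @param n_blood,n_skin Human samples per tissue.
#' @param n_per_tissue Vervet samples per tissue.
#' @return A [species_design()].
#' @export
macaque_design <- function() {
  tissues <- data.frame(
    tissue   = c("adipose", "blood", "cortex", "kidney", "liver", "lung",
                 "muscle", "skin"),
    n        = c(5L, 199L, 6L, 4L, 5L, 6L, 5L, 51L),
    n_female = c(2L, 71L, 3L, 1L, 4L, 3L, 2L, 13L),
    min_age  = c(23.5, 1.79, 17.2, 23.5, 17.2, 17.2, 17.2, 7.61),
    max_age  = c(42, 42, 42, 33.4, 42, 42, 42, 42)
  )
  species_design("macaque", max_lifespan = 42, maturity_age = 4, tissues)
}

#' @rdname macaque_design
#' @export
human_design <- function(n_blood = 140L, n_skin = 60L) {
  tissues <- data.frame(
    tissue  = c("blood", "skin"),
    n       = c(n_blood, n_skin),
    min_age = c(0, 0),
    max_age = c(93, 93)
  )
  species_design("human", max_lifespan = 122.5, maturity_age = 15, tissues)
}

#' @rdname macaque_design
#' @export
vervet_design <- function(n_per_tissue = c(blood = 20L, cortex = 10L,
                                           liver = 10L)) {
  tissues <- data.frame(
    tissue  = names(n_per_tissue),
    n       = as.integer(n_per_tissue),
    min_age = 1,
    max_age = 26
  )
  species_design("vervet", max_lifespan = 30.8, maturity_age = 4, tissues)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic methylation-array generator. The
#' generator plants, per tissue, a set of causal CpGs whose mean methylation
#' moves linearly *in relative age* on the logit scale, plus a shared set of
#' CpGs that are age-associated (with a common sign and effect) in at least
#' `shared_min_tissues` tissues and in every species — the conservation
#' structure that dual-species clocks exploit. All remaining CpGs are
#' age-independent. Observed beta values are
#' `inverse-logit(baseline + effect * age/max_lifespan + noise)` with
#' Gaussian logit-scale noise, clipped to `[1e-6, 1 - 1e-6]` (a logit-normal
#' model: betas stay in range with realistic shrinking variance near 0/1).
#'
#' @param species List of [species_design()]s; default the macaque design.
#' @param n_cpgs Number of CpGs on the simulated array.
#' @param n_causal_per_tissue Causal CpGs per tissue (shared CpGs count
#'   toward the tissues they are planted in; the remainder are
#'   tissue-exclusive).
#' @param shared_set_size Number of shared CpGs.
#' @param shared_min_tissues Minimum tissues a shared CpG is causal in.
#' @param frac_hyper Fraction of causal CpGs gaining methylation with age.
#' @param effect_scale Mean absolute effect, logit units per unit relative
#'   age; individual magnitudes are `effect_scale * U(0.5, 1.5)`.
#' @param noise_sd Logit-scale noise standard deviation.
#' @param baseline_sd SD of per-CpG baseline logit levels around 0.
#' @param region_props Named proportions over the six region classes used by
#'   [generate_annotation()].
#' @param promoter_bias Multiplier applied to the promoter and 5'UTR
#'   proportions when annotating *causal* CpGs (1 = unbiased).
#' @param motif_ids Motif names available to [generate_motifs()].
#' @param motif_bg_rate Background probability that a CpG matches a motif.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species = list(macaque_design()),
                       n_cpgs = 2000L,
                       n_causal_per_tissue = 100L,
                       shared_set_size = 20L,
                       shared_min_tissues = 4L,
                       frac_hyper = 0.5,
                       effect_scale = 3,
                       noise_sd = 0.5,
                       baseline_sd = 1.5,
                       region_props = c("promoter" = 0.15, "5'UTR" = 0.05,
                                        "exon" = 0.15, "intron" = 0.35,
                                        "3'UTR" = 0.05,
                                        "distal intergenic" = 0.25),
                       promoter_bias = 1,
                       motif_ids = c("ZIC1", "ZIC2", "TFAP2C",
                                     sprintf("TF%02d", 1:27)),
                       motif_bg_rate = 0.05,
                       seed = 1L) {
  if (inherits(species, "species_design")) species <- list(species)
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, TRUE, "species_design")))
  if (n_cpgs <= 0 || n_causal_per_tissue <= 0) stop("counts must be > 0")
  if (frac_hyper < 0 || frac_hyper > 1) stop("`frac_hyper` must be in [0,1]")
  if (noise_sd < 0 || effect_scale < 0) stop("scales must be >= 0")
  if (!setequal(names(region_props), region_classes)) {
    stop("`region_props` must name exactly the six region classes")
  }
  if (abs(sum(region_props) - 1) > 1e-8) {
    stop("`region_props` must sum to 1")
  }
  tissues <- unique(unlist(lapply(species, function(s) s$tissues$tissue)))
  n_shared_eff <- min(shared_set_size, n_cpgs)
  pool_needed <- n_shared_eff + length(tissues) * n_causal_per_tissue
  if (pool_needed > n_cpgs) {
    stop("n_cpgs too small for the requested causal structure (needs >= ",
         pool_needed, ")")
  }
  # designs with fewer tissues than the default minimum simply plant the
  # shared set in every tissue
  shared_min_tissues <- min(shared_min_tissues, length(tissues))
  structure(list(species = species, n_cpgs = as.integer(n_cpgs),
                 n_causal_per_tissue = as.integer(n_causal_per_tissue),
                 shared_set_size = as.integer(shared_set_size),
                 shared_min_tissues = as.integer(shared_min_tissues),
                 frac_hyper = frac_hyper, effect_scale = effect_scale,
                 noise_sd = noise_sd, baseline_sd = baseline_sd,
                 region_props = region_props[region_classes],
                 promoter_bias = promoter_bias,
                 motif_ids = motif_ids, motif_bg_rate = motif_bg_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic methylation dataset
#'
#' Draws sample sheets, planted age effects and beta values according to a
#' [sim_config()]. Deterministic given the config (and its seed); the
#' caller's RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{beta}{numeric matrix, samples x CpGs, values in `[0, 1]`.}
#'     \item{sheet}{sample sheet `data.frame` with columns `sample_id`,
#'       `species`, `tissue`, `age`, `sex`, `max_lifespan`, `maturity_age`.}
#'     \item{truth}{ground truth: per-tissue `causal` tables (cpg, effect),
#'       the `shared` CpG ids with their tissue lists, and per-CpG
#'       `baseline` logit levels — everything needed for recovery tests.}
#'   }
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- sum(vapply(config$species, function(s) sum(s$tissues$n), 0))
  if (n_total == 0) stop("config has zero samples in every tissue")

  with_stream_seed(config$seed, "dataset", {
    cpgs <- sprintf("cpg%05d", seq_len(config$n_cpgs))
    baseline <- stats::rnorm(config$n_cpgs, 0, config$baseline_sd)
    names(baseline) <- cpgs

    tissues <- unique(unlist(lapply(config$species,
                                    function(s) s$tissues$tissue)))
    n_shared <- min(config$shared_set_size, config$n_cpgs)

    # shared CpGs: one sign and magnitude each, planted in >= shared_min_tissues
    shared <- if (n_shared > 0) sample(cpgs, n_shared) else character(0)
    shared_eff <- ifelse(stats::runif(n_shared) < config$frac_hyper, 1, -1) *
      config$effect_scale * stats::runif(n_shared, 0.5, 1.5)
    names(shared_eff) <- shared
    shared_tissues <- lapply(seq_len(n_shared), function(i) {
      k_choices <- seq(config$shared_min_tissues, length(tissues))
      k <- k_choices[sample.int(length(k_choices), 1)]
      sample(tissues, k)
    })
    names(shared_tissues) <- shared

    # tissue-exclusive causal CpGs, drawn disjointly so that no non-shared
    # CpG is age-associated in more than one tissue
    pool <- setdiff(cpgs, shared)
    causal <- list()
    for (t in tissues) {
      in_t <- shared[vapply(shared_tissues, function(ts) t %in% ts, TRUE)]
      n_excl <- max(0L, config$n_causal_per_tissue - length(in_t))
      excl <- if (n_excl > 0) sample(pool, n_excl) else character(0)
      pool <- setdiff(pool, excl)
      eff_excl <- ifelse(stats::runif(n_excl) < config$frac_hyper, 1, -1) *
        config$effect_scale * stats::runif(n_excl, 0.5, 1.5)
      causal[[t]] <- data.frame(
        cpg = c(in_t, excl),
        effect = c(unname(shared_eff[in_t]), eff_excl),
        stringsAsFactors = FALSE
      )
    }

    # sample sheet
    sheets <- lapply(config$species, function(sp) {
      rows <- lapply(seq_len(nrow(sp$tissues)), function(i) {
        ti <- sp$tissues[i, ]
        if (ti$n == 0) return(NULL)
        age <- stats::runif(ti$n, ti$min_age, ti$max_age)
        sex <- if (!is.na(ti$n_female)) {
          sample(rep(c("F", "M"), c(min(ti$n_female, ti$n),
                                    max(0L, ti$n - ti$n_female))))
        } else {
          sample(c("F", "M"), ti$n, replace = TRUE)
        }
        data.frame(
          sample_id = sprintf("%s_%s_%03d", sp$name, ti$tissue, seq_len(ti$n)),
          species = sp$name, tissue = ti$tissue, age = age, sex = sex,
          max_lifespan = sp$max_lifespan, maturity_age = sp$maturity_age,
          stringsAsFactors = FALSE
        )
      })
      do.call(rbind, rows)
    })
    sheet <- do.call(rbind, sheets)
    rownames(sheet) <- NULL

    # means on the logit scale: baseline + effect * relative age for causal
    # CpGs of the sample's tissue; age effects are linear in relative age so
    # that the same planted CpG carries a conserved signal in every species
    mu <- matrix(baseline, nrow = nrow(sheet), ncol = config$n_cpgs,
                 byrow = TRUE, dimnames = list(sheet$sample_id, cpgs))
    relage <- sheet$age / sheet$max_lifespan
    for (t in tissues) {
      idx <- which(sheet$tissue == t)
      if (length(idx) == 0 || nrow(causal[[t]]) == 0) next
      j <- match(causal[[t]]$cpg, cpgs)
      mu[idx, j] <- mu[idx, j] +
        outer(relage[idx], causal[[t]]$effect)
    }
    noise <- matrix(stats::rnorm(length(mu), 0, config$noise_sd), nrow(mu))
    beta <- expit(mu + noise)
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)

    list(beta = beta, sheet = sheet,
         truth = list(causal = causal, shared = shared,
                      shared_tissues = shared_tissues,
                      shared_effects = shared_eff, baseline = baseline))
  })
}

#' Generate a CpG annotation table
#'
#' Assigns each CpG a nearest gene, a region class drawn from
#' `config$region_props`, a signed distance to the nearest transcription
#' start site, and BED-like coordinates on a synthetic genome. When ground
#' truth is supplied and `config$promoter_bias > 1`, causal CpGs are
#' re-drawn with the promoter and 5'UTR proportions inflated by that factor,
#' emulating the concentration of age-related methylation change in
#' regulatory regions.
#'
#' @param config A [sim_config()].
#' @param truth Optional ground truth from [generate_dataset()].
#' @return `data.frame` with columns `cpg_id`, `chr`, `start`, `end`,
#'   `gene`, `region`, `dist_to_tss`.
#' @export
generate_annotation <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cpgs <- sprintf("cpg%05d", seq_len(config$n_cpgs))
  if (config$n_cpgs == 0) cpgs <- character(0)
  with_stream_seed(config$seed, "annotation", {
    n <- length(cpgs)
    if (n == 0) {
      return(data.frame(cpg_id = character(0), chr = character(0),
                        start = integer(0), end = integer(0),
                        gene = character(0), region = character(0),
                        dist_to_tss = integer(0)))
    }
    genes <- sprintf("GENE%04d", seq_len(max(1L, ceiling(n / 5))))
    region <- sample(region_classes, n, replace = TRUE,
                     prob = config$region_props)
    if (!is.null(truth) && config$promoter_bias != 1) {
      causal_all <- unique(unlist(lapply(truth$causal, `[[`, "cpg")))
      props <- config$region_props
      props[c("promoter", "5'UTR")] <- props[c("promoter", "5'UTR")] *
        config$promoter_bias
      props <- props / sum(props)
      idx <- match(causal_all, cpgs)
      idx <- idx[!is.na(idx)]
      region[idx] <- sample(region_classes, length(idx), replace = TRUE,
                            prob = props)
    }
    # class-typical signed distances to the nearest TSS
    dist <- vapply(region, function(r) {
      switch(r,
        "promoter" = round(stats::runif(1, -2000, 200)),
        "5'UTR" = round(stats::runif(1, 0, 2000)),
        "exon" = round(stats::runif(1, 200, 5e4)),
        "intron" = round(stats::runif(1, 200, 5e4)),
        "3'UTR" = round(stats::runif(1, 1e3, 5e4)),
        "distal intergenic" = round(stats::runif(1, 5e4, 5e5)) *
          sample(c(-1, 1), 1))
    }, 0)
    chr <- sample(sprintf("chr%d", 1:20), n, replace = TRUE)
    start <- as.integer(stats::runif(n, 1, 1e8))
    data.frame(cpg_id = cpgs, chr = chr, start = start, end = start + 1L,
               gene = sample(genes, n, replace = TRUE), region = region,
               dist_to_tss = as.integer(dist), stringsAsFactors = FALSE)
  })
}

#' Generate a CpG-to-motif match table
#'
#' Emulates a precomputed transcription-factor motif scan: every (CpG,
#' motif) pair matches independently at the background rate, except that one
#' chosen motif can be planted on causal promoter/5'UTR CpGs at
#' `enrichment_factor` times the background rate, giving enrichment analyses
#' a known positive control.
#'
#' @param config A [sim_config()].
#' @param annotation From [generate_annotation()].
#' @param truth From [generate_dataset()].
#' @param enriched_motif Motif id to enrich, or `NULL` for none.
#' @param enrichment_factor Rate multiplier, `>= 1`.
#' @param enriched_direction Restrict the planted motif to causal CpGs that
#'   gain (`"hyper"`) or lose (`"hypo"`) methylation with age, or `"both"`.
#' @return `data.frame` with columns `cpg_id`, `motif_id`; unique pairs.
#' @export
generate_motifs <- function(config, annotation, truth,
                            enriched_motif = NULL, enrichment_factor = 1,
                            enriched_direction = c("both", "hyper", "hypo")) {
  stopifnot(inherits(config, "sim_config"))
  enriched_direction <- match.arg(enriched_direction)
  if (enrichment_factor < 1) stop("`enrichment_factor` must be >= 1")
  if (length(config$motif_ids) == 0) {
    return(data.frame(cpg_id = character(0), motif_id = character(0)))
  }
  with_stream_seed(config$seed, "motifs", {
    cpgs <- annotation$cpg_id
    n <- length(cpgs)
    rate <- config$motif_bg_rate

    target <- character(0)
    if (!is.null(enriched_motif)) {
      if (!enriched_motif %in% config$motif_ids) {
        stop("`enriched_motif` is not among config$motif_ids")
      }
      ct <- do.call(rbind, truth$causal)
      if (enriched_direction == "hyper") ct <- ct[ct$effect > 0, , drop = FALSE]
      if (enriched_direction == "hypo") ct <- ct[ct$effect < 0, , drop = FALSE]
      causal <- unique(ct$cpg)
      promo <- annotation$cpg_id[annotation$region %in% c("promoter", "5'UTR")]
      target <- intersect(causal, promo)
    }

    out <- lapply(config$motif_ids, function(m) {
      p <- rep(rate, n)
      if (!is.null(enriched_motif) && m == enriched_motif) {
        p[cpgs %in% target] <- min(1, enrichment_factor * rate)
      }
      hit <- stats::runif(n) < p
      if (!any(hit)) return(NULL)
      data.frame(cpg_id = cpgs[hit], motif_id = m, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
      out <- data.frame(cpg_id = character(0), motif_id = character(0))
    }
    rownames(out) <- NULL
    out
  })
}
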