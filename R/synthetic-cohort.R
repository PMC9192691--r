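# Synthetic two-timepoint VTE-like cohort with planted protein effects.
#
# The generator emulates the structure of an acute-event / 12-month follow-up
# thrombosis cohort profiled on targeted proteomics panels: an FXI coagulant
# activity (FXI:C, % of normal plasma) outcome driven by clinical covariates
# plus a small set of truly associated proteins (linear and nonlinear
# shapes), correlated protein blocks so that high-correlation partners
# (Spearman rho > 0.8) exist, lower FXI:C under DOAC use, an APTT inversely
# related to FXI:C, and an FXI antigen proxy with a prescribed rank
# correlation with FXI:C.  Ground truth (active sets, shapes, partners) is
# returned so downstream selection can be scored.

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set consumed by [generate_cohort()].
#' Defaults reproduce the dimensions of the motivating study sample: 549
#' acute-event observations, 187 follow-up observations all of which are
#' paired with an acute sample, and 444 proteins on a relative (NPX-like)
#' scale.
#'
#' @param n_acute,n_followup Number of observations at the acute event and at
#'   follow-up.
#' @param n_overlap Number of subjects measured at both timepoints; must not
#'   exceed `min(n_acute, n_followup)`.
#' @param n_proteins Number of protein analytes.
#' @param block_size,block_rho Proteins are simulated in consecutive blocks of
#'   `block_size` with exchangeable within-block correlation `block_rho`
#'   (Gaussian factor construction), so correlated partners exist.
#' @param active_acute,active_followup,active_shared Character vectors of
#'   protein identifiers truly associated with FXI:C at each timepoint;
#'   `active_shared` must be contained in the intersection.
#' @param effect_shapes Named character vector mapping each active protein to
#'   one of `"linear"`, `"log"`, `"reciprocal"`, `"quadratic"`.  Shapes are
#'   applied to the min-shifted positive value `x - min(x) + 1`, the same
#'   convention used by the fractional-polynomial basis.
#' @param signal_r2 Fraction of covariate-adjusted outcome variance explained
#'   by the planted protein effects, in (0, 1).
#' @param covariate_effects Named numeric vector of latent-scale coefficients
#'   for `age`, `sex`, `bmi`.
#' @param doac_shift Offset (in % FXI:C, negative) applied to DOAC users.
#' @param doac_frac_acute,doac_frac_followup Fraction of observations flagged
#'   as DOAC users at each timepoint.  Counts are exact
#'   (`round(frac * n)`), so the follow-up default 111/187 plants exactly 111
#'   DOAC observations.
#' @param aptt_slope Slope (s per % FXI:C, negative) of APTT on FXI:C.
#' @param ag_rho Target Spearman correlation of the FXI antigen proxy with
#'   FXI:C.
#' @param malignancy_frac Fraction of subjects flagged with active malignancy.
#' @param deficiency_frac Fraction of subjects forced to severe FXI deficiency
#'   (FXI:C < 20%).
#' @param partner_rho Pearson correlation between each active protein and its
#'   designated high-correlation partner column.
#' @param attenuation Correlation between a subject's acute and follow-up
#'   latent protein factors.
#' @param fxi_mean_acute,fxi_sd_acute,fxi_mean_followup,fxi_sd_followup
#'   Marginal moments of FXI:C (%) at the two timepoints.
#' @param noise_sd Baseline residual SD on the latent scale before the
#'   `signal_r2` calibration (retained for reference; the calibration fixes
#'   the effective value).
#' @param seed Integer seed; generation is bit-reproducible given the config.
#'
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_acute = 549L,
                              n_followup = 187L,
                              n_overlap = 187L,
                              n_proteins = 444L,
                              block_size = 8L,
                              block_rho = 0.5,
                              active_acute = c("P001", "P002", "P003",
                                               "P004", "P005", "P006"),
                              active_followup = c("P004", "P005", "P006",
                                                  "P007", "P008", "P009"),
                              active_shared = c("P004", "P005", "P006"),
                              effect_shapes = c(P001 = "linear",
                                                P002 = "log",
                                                P003 = "reciprocal",
                                                P004 = "linear",
                                                P005 = "quadratic",
                                                P006 = "log",
                                                P007 = "linear",
                                                P008 = "reciprocal",
                                                P009 = "quadratic"),
                              signal_r2 = 0.5,
                              covariate_effects = c(age = 0.2, sex = 0.15,
                                                    bmi = 0.2),
                              doac_shift = -25,
                              doac_frac_acute = 0.28,
                              doac_frac_followup = 111 / 187,
                              aptt_slope = -0.07,
                              ag_rho = 0.22,
                              malignancy_frac = 0.03,
                              deficiency_frac = 0.02,
                              partner_rho = 0.9,
                              attenuation = 0.7,
                              fxi_mean_acute = 120.8,
                              fxi_sd_acute = 33.79,
                              fxi_mean_followup = 87.2,
                              fxi_sd_followup = 34.3,
                              noise_sd = 1,
                              seed = 1L) {
  cfg <- list(n_acute = as.integer(n_acute),
              n_followup = as.integer(n_followup),
              n_overlap = as.integer(n_overlap),
              n_proteins = as.integer(n_proteins),
              block_size = as.integer(block_size),
              block_rho = block_rho,
              active_acute = as.character(active_acute),
              active_followup = as.character(active_followup),
              active_shared = as.character(active_shared),
              effect_shapes = effect_shapes,
              signal_r2 = signal_r2,
              covariate_effects = covariate_effects,
              doac_shift = doac_shift,
              doac_frac_acute = doac_frac_acute,
              doac_frac_followup = doac_frac_followup,
              aptt_slope = aptt_slope,
              ag_rho = ag_rho,
              malignancy_frac = malignancy_frac,
              deficiency_frac = deficiency_frac,
              partner_rho = partner_rho,
              attenuation = attenuation,
              fxi_mean_acute = fxi_mean_acute,
              fxi_sd_acute = fxi_sd_acute,
              fxi_mean_followup = fxi_mean_followup,
              fxi_sd_followup = fxi_sd_followup,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_overlap > min(cfg$n_acute, cfg$n_followup)) {
    stop_config("n_overlap (%d) exceeds min(n_acute, n_followup)",
                cfg$n_overlap)
  }
  if (!(cfg$signal_r2 > 0 && cfg$signal_r2 < 1)) {
    stop_config("signal_r2 must lie strictly in (0, 1)")
  }
  if (!(cfg$block_rho >= 0 && cfg$block_rho < 1)) {
    stop_config("block_rho must lie in [0, 1)")
  }
  ids <- protein_ids(cfg$n_proteins)
  actives <- unique(c(cfg$active_acute, cfg$active_followup))
  bad <- setdiff(actives, ids)
  if (length(bad)) {
    stop_config("active proteins not among the %d generated proteins: %s",
                cfg$n_proteins, paste(bad, collapse = ", "))
  }
  if (!all(cfg$active_shared %in% intersect(cfg$active_acute,
                                            cfg$active_followup))) {
    stop_config("active_shared must be a subset of both active sets")
  }
  missing_shape <- setdiff(actives, names(cfg$effect_shapes))
  if (length(missing_shape)) {
    stop_config("effect_shapes missing for: %s",
                paste(missing_shape, collapse = ", "))
  }
  ok_shapes <- c("linear", "log", "reciprocal", "quadratic")
  if (!all(cfg$effect_shapes %in% ok_shapes)) {
    stop_config("effect_shapes must be one of: %s",
                paste(ok_shapes, collapse = ", "))
  }
  invisible(cfg)
}

protein_ids <- function(n) sprintf("P%03d", seq_len(n))

# Effect shape on the min-shifted positive scale shared with the FP basis.
shape_effect <- function(x, shape) {
  xs <- x - min(x) + 1
  switch(shape,
         linear = xs,
         log = log(xs),
         reciprocal = 1 / xs,
         quadratic = xs^2,
         stop_config("unknown effect shape '%s'", shape))
}

# Latent protein z-scores for one timepoint: exchangeable correlated blocks.
simulate_latent <- function(n, cfg, base = NULL) {
  p <- cfg$n_proteins
  n_blocks <- ceiling(p / cfg$block_size)
  block_of <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(p)]
  if (is.null(base)) {
    fac <- matrix(rnorm(n * n_blocks), n, n_blocks)
    eps <- matrix(rnorm(n * p), n, p)
  } else {
    a <- cfg$attenuation
    fac <- a * base$fac + sqrt(1 - a^2) * matrix(rnorm(n * n_blocks),
                                                 n, n_blocks)
    eps <- a * base$eps + sqrt(1 - a^2) * matrix(rnorm(n * p), n, p)
  }
  r <- cfg$block_rho
  z <- sqrt(r) * fac[, block_of, drop = FALSE] + sqrt(1 - r) * eps
  colnames(z) <- protein_ids(p)
  list(z = z, fac = fac, eps = eps)
}

# Overwrite each active protein's designated partner column so an
# out-of-model high-correlation partner (Pearson ~ partner_rho) exists.
plant_partners <- function(z, actives, partner_map) {
  for (a in names(partner_map)) {
    pcol <- partner_map[[a]]
    rho <- attr(partner_map, "rho")
    z[, pcol] <- rho * z[, a] + sqrt(1 - rho^2) * rnorm(nrow(z))
  }
  z
}

# Rank-preserving antigen proxy with target Spearman correlation to fxi_c.
antigen_proxy <- function(fxi_c, ag_rho) {
  n <- length(fxi_c)
  z1 <- qnorm(rank(fxi_c, ties.method = "average") / (n + 1))
  rho_p <- 2 * sin(pi * ag_rho / 6)  # Spearman -> Pearson under normality
  5 + rho_p * z1 + sqrt(1 - rho_p^2) * rnorm(n)
}

simulate_timepoint <- function(cfg, n, subjects, timepoint, actives,
                               latent, npx_mu, npx_sd, fxi_mean, fxi_sd,
                               doac_frac) {
  p <- cfg$n_proteins
  ids <- protein_ids(p)
  npx <- sweep(sweep(latent$z, 2, npx_sd, "*"), 2, npx_mu, "+")
  colnames(npx) <- ids
  rownames(npx) <- paste0(subjects, "_", timepoint)

  # planted protein signal, unit variance overall
  if (length(actives)) {
    eff <- vapply(actives, function(a) {
      e <- shape_effect(npx[, a], cfg$effect_shapes[[a]])
      as.numeric(scale(e))
    }, numeric(n))
    S <- rowSums(eff)
    # unit-variance total signal so signal_r2 is the protein share of the
    # covariate-adjusted variance even when actives are correlated
    if (sd(S) > 0) S <- S / sd(S)
  } else {
    S <- numeric(n)
  }

  ce <- cfg$covariate_effects
  age <- pmin(pmax(rnorm(n, 60, 16), 18), 95)
  sex <- rbinom(n, 1, 0.45)            # 1 = female
  bmi <- pmin(pmax(rnorm(n, 28, 5), 16), 55)
  covariate_term <- ce[["age"]] * as.numeric(scale(age)) +
    ce[["sex"]] * (sex - mean(sex)) +
    ce[["bmi"]] * as.numeric(scale(bmi))

  # residual SD calibrated so proteins explain signal_r2 of the
  # covariate-adjusted variance: var(S) = 1, sigma^2 = (1 - r2) / r2
  sigma <- sqrt((1 - cfg$signal_r2) / cfg$signal_r2)
  latent_y <- covariate_term + S + rnorm(n, 0, sigma)
  fxi_c <- fxi_mean + fxi_sd * (latent_y - mean(latent_y)) / sd(latent_y)

  doac <- integer(n)
  n_doac <- round(doac_frac * n)
  if (n_doac > 0) doac[sample.int(n, n_doac)] <- 1L
  fxi_c <- fxi_c + cfg$doac_shift * doac
  fxi_c <- pmax(fxi_c, 21)  # keep strictly positive, above exclusion bound

  # planted exclusions: active malignancy and severe deficiency (< 20%)
  malig <- integer(n)
  n_malig <- round(cfg$malignancy_frac * n)
  if (n_malig > 0) malig[sample.int(n, n_malig)] <- 1L
  n_def <- round(cfg$deficiency_frac * n)
  if (n_def > 0) {
    idx <- sample.int(n, n_def)
    fxi_c[idx] <- runif(n_def, 5, 19.5)
  }

  aptt <- 33.5 + cfg$aptt_slope * (fxi_c - 110) + rnorm(n, 0, 2.5)
  cohort <- data.frame(
    obs_id = paste0(subjects, "_", timepoint),
    subject_id = subjects,
    timepoint = timepoint,
    sex = sex,
    age = age,
    bmi = bmi,
    recent_surgery = rbinom(n, 1, 0.06),
    recent_immobilization = rbinom(n, 1, 0.14),
    recent_travel = rbinom(n, 1, 0.08),
    active_malignancy = malig,
    chronic_liver_disease = rbinom(n, 1, 0.05),
    chronic_kidney_disease = rbinom(n, 1, 0.06),
    diabetes = rbinom(n, 1, 0.13),
    hypertension = rbinom(n, 1, 0.51),
    doac_user = doac,
    thrombin_inhibitor = rbinom(n, 1, 0.015),
    heparin = rbinom(n, 1, 0.55),
    vka = rbinom(n, 1, 0.06),
    fxi_c = fxi_c,
    fxi_ag = antigen_proxy(fxi_c, cfg$ag_rho),
    aptt = aptt,
    crp = exp(rnorm(n, log(15), 1)),
    platelets = pmax(rnorm(n, 240, 60), 30),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, proteins = npx)
}

#' Generate a synthetic two-timepoint cohort with planted protein effects
#'
#' Produces one clinical table and one protein matrix covering acute-event
#' and follow-up observations (overlapping subjects are paired), plus the
#' ground truth needed to score downstream selection.  Deterministic for a
#' fixed config.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"fxi_cohort"` with elements `cohort` (data frame,
#'   one row per observation), `proteins` (numeric matrix, observations x
#'   proteins, rownames matching `cohort$obs_id`), and `truth` (planted
#'   active sets, effect shapes, partner map, generator seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    ids <- protein_ids(cfg$n_proteins)
    npx_mu <- runif(cfg$n_proteins, -1, 8)
    npx_sd <- runif(cfg$n_proteins, 0.8, 1.2)

    actives <- unique(c(cfg$active_acute, cfg$active_followup))
    partner_pool <- setdiff(ids, actives)
    n_partners <- min(length(actives), length(partner_pool))
    if (n_partners < length(actives)) {
      warning(sprintf("only %d of %d active proteins receive a designated partner (protein pool too small)",
                      n_partners, length(actives)))
    }
    partner_map <- as.list(utils::tail(partner_pool, n_partners))
    names(partner_map) <- utils::head(actives, n_partners)
    attr(partner_map, "rho") <- cfg$partner_rho

    subj_acute <- sprintf("S%04d", seq_len(cfg$n_acute))
    overlap_idx <- seq_len(cfg$n_overlap)
    n_new <- cfg$n_followup - cfg$n_overlap
    subj_follow <- c(subj_acute[overlap_idx],
                     if (n_new > 0) sprintf("S%04d", cfg$n_acute + seq_len(n_new)))

    lat_acute <- simulate_latent(cfg$n_acute, cfg)
    lat_acute$z <- plant_partners(lat_acute$z, actives, partner_map)
    acute <- simulate_timepoint(cfg, cfg$n_acute, subj_acute, "acute",
                                cfg$active_acute, lat_acute, npx_mu, npx_sd,
                                cfg$fxi_mean_acute, cfg$fxi_sd_acute,
                                cfg$doac_frac_acute)

    base <- list(fac = lat_acute$fac[overlap_idx, , drop = FALSE],
                 eps = lat_acute$eps[overlap_idx, , drop = FALSE])
    if (n_new > 0) {
      fresh <- simulate_latent(n_new, cfg)
      base$fac <- rbind(base$fac, fresh$fac)
      base$eps <- rbind(base$eps, fresh$eps)
    }
    lat_follow <- simulate_latent(cfg$n_followup, cfg, base = base)
    lat_follow$z <- plant_partners(lat_follow$z, actives, partner_map)
    follow <- simulate_timepoint(cfg, cfg$n_followup, subj_follow, "followup",
                                 cfg$active_followup, lat_follow,
                                 npx_mu, npx_sd,
                                 cfg$fxi_mean_followup, cfg$fxi_sd_followup,
                                 cfg$doac_frac_followup)

    cohort <- rbind(acute$cohort, follow$cohort)
    proteins <- rbind(acute$proteins, follow$proteins)
    truth <- list(active_acute = cfg$active_acute,
                  active_followup = cfg$active_followup,
                  active_shared = cfg$active_shared,
                  effect_shapes = as.list(cfg$effect_shapes),
                  partners = if (length(partner_map)) {
                    setNames(as.character(unlist(partner_map)),
                             names(partner_map))
                  } else setNames(character(0), character(0)),
                  signal_r2 = cfg$signal_r2,
                  seed = cfg$seed)
    structure(list(cohort = cohort, proteins = proteins, truth = truth),
              class = "fxi_cohort")
  })
}

#' Write cohort fixtures to plain-text files
#'
#' Writes `cohort.csv`, `proteins.csv` and `truth.json` into `dir`; the CSV
#' files round-trip through [read_cohort()] / [read_protein_matrix()].
#'
#' @param x An `"fxi_cohort"` (or a list with `cohort`, `proteins`, and
#'   optionally `truth`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             proteins = file.path(dir, "proteins.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(x$cohort, paths[["cohort"]], row.names = FALSE)
  prot <- as.data.frame(x$proteins)
  prot <- cbind(obs_id = rownames(x$proteins), prot)
  utils::write.csv(prot, paths[["proteins"]], row.names = FALSE)
  if (!is.null(x$truth)) {
    jsonlite::write_json(x$truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
  } else {
    paths <- paths[c("cohort", "proteins")]
  }
  invisible(paths)
}

#' Read a cohort table written by [write_fixtures()]
#' @param path Path to `cohort.csv`.
#' @return Data frame with one row per observation.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_config("cohort file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a protein matrix written by [write_fixtures()]
#' @param path Path to `proteins.csv` (first column `obs_id`).
#' @return Numeric matrix with observation rownames.
#' @export
read_protein_matrix <- function(path) {
  if (!file.exists(path)) stop_config("protein file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Generate a synthetic gene-set database over the measured proteins
#'
#' Builds random gene sets plus one planted pathway concentrated on the
#' truly associated proteins and their high-correlation partners, so that
#' enrichment of a correct selection is detectable by construction.
#'
#' @param protein_ids_all Character vector of measured protein identifiers
#'   (the enrichment background).
#' @param truth Truth list from [generate_cohort()] (may be `NULL`).
#' @param n_sets Number of random decoy sets.
#' @param set_size Range of decoy set sizes.
#' @param seed Integer seed.
#' @return Named list of character vectors (a `GeneSetDB`).
#' @export
generate_genesets <- function(protein_ids_all, truth = NULL, n_sets = 20,
                              set_size = c(10, 40), seed = 1L) {
  with_seed(seed, {
    db <- lapply(seq_len(n_sets), function(i) {
      k <- sample(seq(set_size[1], set_size[2]), 1)
      sample(protein_ids_all, min(k, length(protein_ids_all)))
    })
    names(db) <- sprintf("RANDOM_SET_%02d", seq_len(n_sets))
    if (!is.null(truth)) {
      core <- unique(c(truth$active_acute, truth$active_followup,
                       unname(truth$partners)))
      pad <- sample(setdiff(protein_ids_all, core),
                    min(5, length(setdiff(protein_ids_all, core))))
      db$PLANTED_PATHWAY <- unique(c(core, pad))
    }
    db
  })
}

#' Generate a synthetic protein-protein interaction edge list
#'
#' Sparse random background edges plus a planted clique over the truly
#' associated proteins (and their partners), mimicking a curated
#' physical-interaction network in which the signal proteins form a dense
#' complex.
#'
#' @param protein_ids_all Character vector of node identifiers.
#' @param truth Truth list from [generate_cohort()] (may be `NULL`).
#' @param p_edge Background edge probability.
#' @param seed Integer seed.
#' @return Data frame with columns `node_a`, `node_b`, `weight`, `physical`.
#' @export
generate_ppi <- function(protein_ids_all, truth = NULL, p_edge = 0.01,
                         seed = 1L) {
  with_seed(seed, {
    n <- length(protein_ids_all)
    pairs <- utils::combn(protein_ids_all, 2)
    keep <- runif(ncol(pairs)) < p_edge
    edges <- data.frame(node_a = pairs[1, keep], node_b = pairs[2, keep],
                        stringsAsFactors = FALSE)
    if (!is.null(truth)) {
      core <- unique(c(truth$active_shared,
                       unname(truth$partners[truth$active_shared])))
      if (length(core) >= 2) {
        cl <- utils::combn(core, 2)
        edges <- rbind(edges, data.frame(node_a = cl[1, ], node_b = cl[2, ],
                                         stringsAsFactors = FALSE))
      }
    }
    edges <- edges[!duplicated(t(apply(edges[, 1:2], 1, sort))), ]
    edges$weight <- round(runif(nrow(edges), 0.4, 1), 3)
    edges$physical <- rbinom(nrow(edges), 1, 0.8) == 1
    rownames(edges) <- NULL
    edges
  })
}
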