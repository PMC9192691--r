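# End-to-end pipeline: simulate -> preprocess -> fit (two timepoints) ->
# sensitivity -> overlap -> enrichment -> network, with a reproducible
# manifest.

#' Default pipeline configuration
#'
#' Nested list consumed by [run_all()].  Sections: `simulate` (arguments to
#' [simulation_config()]), `covariates`, `fp` (powers), `cv` (folds),
#' `sensitivity` (`aptt_threshold`), `enrichment` (`gmt` path or `NULL` for
#' a synthetic database, `rho_threshold`), `network` (`edges` path or
#' `NULL`, `restrict_physical`, `inflation`, MCODE parameters), and `seed`.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       simulate = list(),
       covariates = default_covariates(),
       fp = list(powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)),
       cv = list(k = 10),
       sensitivity = list(aptt_threshold = 38),
       enrichment = list(gmt = NULL, rho_threshold = 0.80),
       network = list(edges = NULL, restrict_physical = TRUE,
                      inflation = 2, degree_cutoff = 2,
                      node_score_cutoff = 0.2, k_core = 2))
}

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  base <- default_pipeline_config(seed = config$seed %||% 1L)
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) base[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full discovery pipeline on one configuration
#'
#' Executes the stages in study order for the acute-event and follow-up
#' samples: cohort generation (or loading), exclusions, descriptive table,
#' paired FXI:C comparison, fractional-polynomial LASSO selection per
#' timepoint, both sensitivity analyses, timepoint overlap,
#' correlation-augmented pathway enrichment with shared/specific partition,
#' and network clustering (MCL) plus dense complex detection (MCODE) with
#' enrichment labels.  All outputs land in a timestamp-free layout under
#' `outdir` and are digested into a JSON manifest, so a rerun with the same
#' config is bit-identical.
#'
#' @param config A config list or path to a JSON config (see
#'   [default_pipeline_config()]).
#' @param outdir Output directory.
#' @return Invisibly, the manifest list (also written to
#'   `outdir/manifest.json`).
#' @export
run_all <- function(config = default_pipeline_config(), outdir) {
  cfg <- load_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  sim_cfg <- do.call(simulation_config,
                     c(cfg$simulate, list(seed = seed)))
  sim <- generate_cohort(sim_cfg)
  write_fixtures(sim, file.path(outdir, "data"))

  cohort <- apply_exclusions(sim$cohort)
  excl <- attr(cohort, "exclusions")
  acute <- cohort[cohort$timepoint == "acute", , drop = FALSE]
  follow <- cohort[cohort$timepoint == "followup", , drop = FALSE]

  tab <- baseline_table(acute)
  write_tsv(tab, file.path(outdir, "baseline_table.tsv"))
  paired <- paired_fxi_test(acute$fxi_c, follow$fxi_c,
                            pairing = list(acute = acute$subject_id,
                                           followup = follow$subject_id))

  fpcfg <- fp_config(powers = cfg$fp$powers)
  k <- cfg$cv$k
  fits <- list()
  sens <- list()
  for (tp in c("acute", "followup")) {
    co <- if (tp == "acute") acute else follow
    s_fit <- seed + if (tp == "acute") 101L else 102L
    fits[[tp]] <- fit_timepoint_model(co, sim$proteins,
                                      covariates = cfg$covariates,
                                      config = fpcfg, seed = s_fit, k = k)
    write_selection(fits[[tp]],
                    file.path(outdir, sprintf("selection_%s.tsv", tp)))
    sens[[paste0(tp, "_no_doac")]] <-
      sensitivity_no_doac(co, sim$proteins, covariates = cfg$covariates,
                          config = fpcfg, seed = s_fit + 10L, k = k)
    sens[[paste0(tp, "_aptt")]] <-
      sensitivity_aptt(co, sim$proteins, covariates = cfg$covariates,
                       config = fpcfg, seed = s_fit + 20L, k = k,
                       aptt_threshold = cfg$sensitivity$aptt_threshold)
    for (nm in paste0(tp, c("_no_doac", "_aptt"))) {
      write_selection(sens[[nm]],
                      file.path(outdir, sprintf("sensitivity_%s.tsv", nm)))
    }
  }

  ov <- overlap_selections(fits$acute, fits$followup)
  jsonlite::write_json(ov, file.path(outdir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)

  background <- colnames(sim$proteins)
  db <- if (is.null(cfg$enrichment$gmt)) {
    generate_genesets(background, sim$truth, seed = seed + 201L)
  } else read_gmt(cfg$enrichment$gmt)
  enr <- list()
  for (tp in c("acute", "followup")) {
    selset <- fits[[tp]]$protein[fits[[tp]]$selected]
    prot_tp <- sim$proteins[
      rownames(sim$proteins) %in%
        cohort$obs_id[cohort$timepoint == tp], , drop = FALSE]
    query <- if (length(selset)) {
      augment_query(selset, prot_tp, cfg$enrichment$rho_threshold)
    } else character(0)
    enr[[tp]] <- if (length(query)) {
      suppressWarnings(enrich(query, db, background))
    } else NULL
    if (!is.null(enr[[tp]])) {
      write_tsv(enr[[tp]], file.path(outdir, sprintf("enrichment_%s.tsv", tp)))
    }
  }
  pathway_partition <- if (!is.null(enr$acute) && !is.null(enr$followup)) {
    compare_timepoints(enr$acute, enr$followup)
  } else list(shared = character(0), a_only = character(0),
              b_only = character(0))
  jsonlite::write_json(pathway_partition,
                       file.path(outdir, "pathway_partition.json"),
                       auto_unbox = TRUE, digits = NA)

  edges <- if (is.null(cfg$network$edges)) {
    generate_ppi(background, sim$truth, seed = seed + 301L)
  } else utils::read.delim(cfg$network$edges, stringsAsFactors = FALSE)
  g <- suppressWarnings(
    build_graph(edges, restrict_physical = cfg$network$restrict_physical))
  clusters <- mcl_cluster(g, inflation = cfg$network$inflation)
  write_tsv(data.frame(node = names(clusters),
                       cluster = as.integer(clusters)),
            file.path(outdir, "mcl_clusters.tsv"))
  complexes <- mcode(g, degree_cutoff = cfg$network$degree_cutoff,
                     node_score_cutoff = cfg$network$node_score_cutoff,
                     k_core = cfg$network$k_core)
  complexes <- label_complexes(complexes, db, background)
  cx_df <- if (length(complexes)) {
    data.frame(complex = seq_along(complexes),
               seed_node = vapply(complexes, `[[`, character(1), "seed"),
               size = vapply(complexes, function(x) length(x$nodes),
                             integer(1)),
               score = vapply(complexes, `[[`, numeric(1), "score"),
               label = vapply(complexes, `[[`, character(1), "label"),
               nodes = vapply(complexes, function(x)
                 paste(x$nodes, collapse = ","), character(1)),
               stringsAsFactors = FALSE)
  } else data.frame(complex = integer(0), seed_node = character(0),
                    size = integer(0), score = numeric(0),
                    label = character(0), nodes = character(0))
  write_tsv(cx_df, file.path(outdir, "complexes.tsv"))

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outdir, "manifest.json"))
  digests <- tools::md5sum(sort(files))
  names(digests) <- substring(names(digests), nchar(outdir) + 2)
  manifest <- list(
    seed = seed,
    config_digest = unname(tools::md5sum({
      tmp <- tempfile(); jsonlite::write_json(cfg, tmp, auto_unbox = TRUE,
                                              digits = NA); tmp
    })),
    exclusions = as.list(excl),
    paired_test = paired[c("t", "p", "df", "mean_acute", "mean_followup",
                           "n_pairs")],
    selection_counts = list(
      acute = sum(fits$acute$selected),
      followup = sum(fits$followup$selected),
      shared = length(ov$shared)),
    cv_r2 = list(acute = attr(fits$acute, "cv_r2"),
                 followup = attr(fits$followup, "cv_r2")),
    sensitivity_excluded = lapply(sens, attr, "n_excluded"),
    shared_proteins = ov$shared,
    shared_pathways = pathway_partition$shared,
    n_complexes = length(complexes),
    files = as.list(digests))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
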