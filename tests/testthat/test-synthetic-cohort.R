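test_that("config invariants are enforced", {
  expect_error(simulation_config(n_overlap = 300, n_followup = 187,
                                 n_acute = 200),
               "n_overlap")
  expect_error(simulation_config(signal_r2 = 1.2), "signal_r2")
  expect_error(simulation_config(block_rho = 1), "block_rho")
  expect_error(simulation_config(active_acute = "P999", n_proteins = 10,
                                 active_followup = character(0),
                                 active_shared = character(0)),
               "not among")
  expect_error(simulation_config(active_shared = "P009"), "subset")
  expect_error(small_sim_config(n_proteins = 40)$nothing, NA)
})

test_that("generation is deterministic per seed and distinct across seeds", {
  a <- generate_cohort(small_sim_config(seed = 7))
  b <- generate_cohort(small_sim_config(seed = 7))
  c <- generate_cohort(small_sim_config(seed = 8))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$proteins, b$proteins)
  expect_false(identical(a$proteins, c$proteins))
})

test_that("generated cohort matches its stated world", {
  sim <- generate_cohort(simulation_config(seed = 3))
  co <- sim$cohort
  expect_equal(nrow(co), 549 + 187)
  expect_equal(ncol(sim$proteins), 444)
  expect_true(all(co$fxi_c > 0))
  expect_false(anyDuplicated(co$obs_id) > 0)
  acute <- co[co$timepoint == "acute", ]
  follow <- co[co$timepoint == "followup", ]
  # follow-up subjects are all paired with acute subjects (default overlap)
  expect_true(all(follow$subject_id %in% acute$subject_id))
  # DOAC users have lower FXI:C (forced by the negative shift)
  expect_lt(mean(acute$fxi_c[acute$doac_user == 1]),
            mean(acute$fxi_c[acute$doac_user == 0]))
  # exactly 111 planted DOAC observations at follow-up
  expect_equal(sum(follow$doac_user), 111L)
  # planted exclusions exist
  expect_gt(sum(co$active_malignancy), 0)
  expect_gt(sum(co$fxi_c < 20), 0)
  # APTT decreases with FXI:C
  expect_lt(cor(acute$aptt, acute$fxi_c), 0)
  # acute mean/SD near the configured marginal moments (clamps and planted
  # deficiency perturb them slightly)
  expect_equal(mean(acute$fxi_c[acute$doac_user == 0 & acute$fxi_c >= 20]),
               120.8, tolerance = 0.1)
})

test_that("antigen proxy achieves the target Spearman correlation", {
  sims <- lapply(1:5, function(s)
    generate_cohort(simulation_config(seed = s)))
  rhos <- vapply(sims, function(sim) {
    acute <- sim$cohort[sim$cohort$timepoint == "acute", ]
    cor(acute$fxi_ag, acute$fxi_c, method = "spearman")
  }, numeric(1))
  expect_true(all(abs(rhos - 0.22) < 0.08))
})

test_that("block correlation matches block_rho", {
  cfg <- simulation_config(n_acute = 600, n_followup = 50, n_overlap = 50,
                           n_proteins = 48, block_size = 8, block_rho = 0.5,
                           active_acute = character(0),
                           active_followup = character(0),
                           active_shared = character(0),
                           effect_shapes = character(0), seed = 11)
  sim <- generate_cohort(cfg)
  acute <- sim$proteins[grepl("_acute$", rownames(sim$proteins)), ]
  for (b in c(1, 3)) {
    block <- acute[, ((b - 1) * 8 + 1):(b * 8)]
    cc <- cor(block)
    expect_equal(mean(cc[upper.tri(cc)]), 0.5, tolerance = 0.05)
  }
})

test_that("planted-signal contract: oracle regression recovers signal_r2", {
  r2s <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_acute = 500, n_followup = 50, n_overlap = 50,
                             n_proteins = 30, seed = s,
                             active_acute = c("P001", "P002", "P003"),
                             active_followup = c("P001", "P002", "P003"),
                             active_shared = c("P001", "P002", "P003"),
                             effect_shapes = c(P001 = "linear", P002 = "log",
                                               P003 = "quadratic"),
                             signal_r2 = 0.5,
                             malignancy_frac = 0, deficiency_frac = 0)
    sim <- generate_cohort(cfg)
    ac <- sim$cohort[sim$cohort$timepoint == "acute", ]
    prot <- sim$proteins[match(ac$obs_id, rownames(sim$proteins)), ]
    # oracle: regress out covariates+DOAC, then R^2 of the true design
    base <- lm(fxi_c ~ age + sex + bmi + doac_user, data = ac)
    res <- resid(base)
    D <- vapply(cfg$active_acute, function(a) {
      x <- prot[, a]; xs <- x - min(x) + 1
      switch(cfg$effect_shapes[[a]], linear = xs, log = log(xs),
             quadratic = xs^2, reciprocal = 1 / xs)
    }, numeric(nrow(prot)))
    summary(lm(res ~ D))$r.squared
  }, numeric(1))
  expect_equal(mean(r2s), 0.5, tolerance = 0.1)
})

test_that("every active protein has a high-correlation partner", {
  sim <- generate_cohort(small_sim_config(seed = 2, n_acute = 300))
  acute <- sim$proteins[grepl("_acute$", rownames(sim$proteins)), ]
  partners <- sim$truth$partners
  for (a in names(partners)) {
    r <- cor(acute[, a], acute[, partners[[a]]], method = "spearman")
    expect_gt(abs(r), 0.8)
  }
})

test_that("fixtures round-trip through the readers", {
  sim <- suppressWarnings(                 # 3-protein toy has no partner pool
    generate_cohort(small_sim_config(seed = 4, n_acute = 30,
                                     n_followup = 10, n_proteins = 3)))
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sim, dir)
  co <- read_cohort(paths[["cohort"]])
  pr <- read_protein_matrix(paths[["proteins"]])
  expect_equal(co, sim$cohort, tolerance = 1e-12)
  expect_equal(pr, sim$proteins, tolerance = 1e-12)
  expect_equal(ncol(pr), 3)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$active_acute, sim$truth$active_acute)

  # degenerate: empty cohort writes header-only files that read back empty
  empty <- list(cohort = sim$cohort[0, ], proteins = sim$proteins[0, ,
                                                                  drop = FALSE])
  paths2 <- write_fixtures(empty, withr::local_tempdir())
  expect_equal(nrow(read_cohort(paths2[["cohort"]])), 0)
  expect_equal(nrow(read_protein_matrix(paths2[["proteins"]])), 0)
})
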