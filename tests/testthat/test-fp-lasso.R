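test_that("fp_expand computes the power basis and its bookkeeping", {
  x <- c(3, 0, 8, 15)                       # shift = -0+1 = 1 -> xs = x+1
  m <- cbind(A = x)
  b <- fp_expand(m, fp_config(standardize = FALSE))
  xs <- x + 1
  expect_equal(ncol(b$X), 8)
  expect_equal(b$map$power, c(-2, -1, -0.5, 0, 0.5, 1, 2, 3))
  # raw (pre-centering) values: undo centering and check analytic powers
  raw <- sweep(b$X, 2, b$centers, "+")
  expect_equal(unname(raw[, "A^0.5"]), sqrt(xs))
  expect_equal(unname(raw[, "A^0"]), log(xs))
  expect_equal(unname(raw[, "A^-1"]), 1 / xs)
  expect_equal(unname(raw[1, "A^0.5"]), 2)  # xs = 4, power 0.5
  expect_equal(unname(raw[1, "A^0"]), log(4))
  expect_equal(unname(raw[1, "A^-1"]), 0.25)

  # powers = (1,): basis equals the shifted standardized input
  m2 <- cbind(A = rnorm(20), B = rnorm(20))
  b2 <- fp_expand(m2, fp_config(powers = 1))
  expect_equal(ncol(b2$X), 2)
  expect_equal(unname(b2$X[, 1]), as.numeric(scale(m2[, 1])))

  # 3 proteins x 8 powers -> 24 features each mapped to its protein
  m3 <- matrix(rexp(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  b3 <- fp_expand(m3)
  expect_equal(ncol(b3$X), 24)
  expect_equal(as.integer(table(b3$map$protein_id)), rep(8L, 3))

  # constant column: all its features dropped with warning
  m4 <- cbind(A = rnorm(20), K = rep(1, 20))
  expect_warning(b4 <- fp_expand(m4), "zero-variance")
  expect_false(any(b4$map$protein_id == "K"))
  expect_equal(length(b4$dropped), 8)

  expect_error(fp_config(powers = c(2, 3)), "contain 1")
  expect_error(fp_expand(cbind(A = c(1, NA))), "non-finite")
})

test_that("orthogonal designs: entry lambdas equal the soft-threshold closed form", {
  n <- 60; p <- 20
  X <- orthonormal_design(n, p, seed = 1)
  set.seed(2)
  y <- X[, 1] * 0.9 + X[, 3] * 0.4 + rnorm(n)
  path <- lasso_path(as_basis(X), NULL, y, thresh = 1e-12)
  covs <- abs(crossprod(X, y - mean(y)) / n)[, 1]
  entered <- !is.na(path$entry_lambda)
  # features with |cov| above the grid floor must match the closed form
  floor_lam <- min(path$lambda_grid)
  expect_true(all(entered[covs > floor_lam * 1.1]))
  expect_lt(max(abs(path$entry_lambda[entered] - covs[entered])), 1e-6)
  # at lambda_max all penalized coefficients are zero
  expect_true(all(path$beta[, 1] == 0))
  # prescribed two-feature example: covariances 0.5 and 0.2
  y2 <- 0.5 * X[, 1] + 0.2 * X[, 2]     # orthonormal -> cov = coefficient
  path2 <- lasso_path(as_basis(X[, 1:2]), NULL, y2, thresh = 1e-12)
  expect_equal(unname(path2$entry_lambda), c(0.5, 0.2), tolerance = 1e-6)
  expect_equal(order(-path2$entry_lambda), c(1, 2))
})

test_that("entry lambdas agree with a dense-grid re-solve on random designs", {
  for (s in 1:3) {
    set.seed(s)
    n <- 60; p <- 20
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- sprintf("F%02d", 1:p)
    X <- scale(X)
    y <- X %*% c(1, -0.7, 0.5, rep(0, p - 3)) + rnorm(n)
    y <- as.numeric(y)
    path <- lasso_path(as_basis(X), NULL, y, thresh = 1e-12)
    # oracle: independent glmnet solve on a 10x denser grid, grid detection
    sdy <- sd(y); ys <- (y - mean(y)) / sdy
    Xc <- scale(X, scale = FALSE)
    lmax <- max(abs(crossprod(Xc, ys)) / n)
    dense <- lmax * exp(seq(0, log(1e-3), length.out = 1000))
    fit <- glmnet::glmnet(Xc, ys, lambda = dense, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-12)
    bd <- as.matrix(fit$beta)
    dense_entry <- apply(bd != 0, 1, function(z)
      if (any(z)) dense[which(z)[1]] else NA) * sdy
    step <- path$lambda_grid[1] / path$lambda_grid[2]  # one coarse grid step
    both <- !is.na(path$entry_lambda) & !is.na(dense_entry)
    ratio <- path$entry_lambda[both] / dense_entry[both]
    expect_true(all(ratio < step * 1.01 & ratio > 1 / (step * 1.01)))
  }
})

test_that("outcome homogeneity: scaling y scales every lambda exactly", {
  X <- orthonormal_design(50, 8, seed = 3)
  set.seed(4)
  y <- X[, 1] + rnorm(50)
  p1 <- lasso_path(as_basis(X), NULL, y)
  p2 <- lasso_path(as_basis(X), NULL, y * 10)
  expect_equal(p2$entry_lambda, p1$entry_lambda * 10, tolerance = 1e-10)
  expect_equal(p2$lambda_grid, p1$lambda_grid * 10, tolerance = 1e-12)
})

test_that("lambda-ratio scale invariance at tight tolerance", {
  set.seed(6)
  worst <- 0
  for (i in 1:3) {
    n <- 60
    X <- matrix(rnorm(n * 12), n, 12)
    colnames(X) <- sprintf("Q%02d", 1:12)
    y <- X[, 1] * 0.8 + X[, 2] * 0.4 + rnorm(n)
    basis <- fp_expand(X, fp_config(powers = c(0.5, 1, 2)))
    for (cc in c(3.7, 256)) {
      s1 <- suppressWarnings(select_and_rank(
        lasso_path(basis, NULL, y, thresh = 1e-12),
        cv_select_lambda(basis, NULL, y, k = 5, seed = 9, thresh = 1e-12),
        basis, X, y))
      s2 <- suppressWarnings(select_and_rank(
        lasso_path(basis, NULL, y * cc, thresh = 1e-12),
        cv_select_lambda(basis, NULL, y * cc, k = 5, seed = 9,
                         thresh = 1e-12),
        basis, X, y * cc))
      expect_identical(s1$selected, s2$selected)
      d <- abs(s1$lambda_ratio - s2$lambda_ratio)
      worst <- max(worst, max(d[is.finite(d)], 0))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("cross-validation selects lambda deterministically and sanely", {
  set.seed(8)
  X <- matrix(rnorm(200 * 10), 200, 10)
  colnames(X) <- sprintf("C%02d", 1:10)
  y <- X[, 1] * 2 + rnorm(200)
  basis <- fp_expand(X, fp_config(powers = 1))
  cv1 <- cv_select_lambda(basis, NULL, y, k = 10, seed = 5)
  cv2 <- cv_select_lambda(basis, NULL, y, k = 10, seed = 5)
  expect_identical(cv1$lambda_opt, cv2$lambda_opt)
  expect_identical(cv1$cv_mse_curve, cv2$cv_mse_curve)
  expect_equal(cv1$lambda_opt,
               cv1$lambda_grid[which.min(cv1$cv_mse_curve)])
  expect_lte(cv1$cv_r2, 1)
  expect_gt(cv1$cv_r2, 0.5)     # strong planted signal
  expect_error(cv_select_lambda(basis, NULL, y, k = 300, seed = 1),
               "folds exceeds")
  expect_error(cv_select_lambda(basis, NULL, y, k = 10), "seed")
})

test_that("select_and_rank aggregates features to proteins correctly", {
  X <- orthonormal_design(80, 6, seed = 10)
  set.seed(11)
  y <- 0.9 * X[, 1] + 0.5 * X[, 2] + rnorm(80, 0, 0.7)
  basis <- as_basis(X)
  path <- lasso_path(basis, NULL, y, thresh = 1e-12)
  cv <- cv_select_lambda(basis, NULL, y, k = 10, seed = 3, thresh = 1e-12)
  sel <- select_and_rank(path, cv, basis, X, y)
  expect_selection_sane(sel)
  # orthogonal single-power design: LR order equals |cov with y| order
  covs <- abs(crossprod(X, y - mean(y)) / 80)[, 1]
  sel_only <- sel[sel$selected, ]
  expect_equal(sel_only$protein,
               names(sort(covs[sel_only$protein], decreasing = TRUE)))
  # unselected proteins have no ratio
  expect_true(all(is.na(sel$lambda_ratio[!sel$selected])))
  # protein entry lambda is the max over its features
  one <- sel_only$protein[1]
  expect_equal(sel_only$entry_lambda[1],
               max(path$entry_lambda[basis$map$protein_id == one],
                   na.rm = TRUE))
})

test_that("covariate adjustment is exactly unpenalized (FWL equivalence)", {
  set.seed(12)
  n <- 120
  Z <- cbind(age = rnorm(n, 60, 10), sex = rbinom(n, 1, 0.5))
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("P%d", 1:6)))
  y <- 3 * Z[, "sex"] + 0.2 * Z[, "age"] + X[, 1] + rnorm(n)
  path <- lasso_path(as_basis(X), Z, y)
  # covariate coefficients at lambda_max equal plain OLS of y on Z
  ols <- coef(lm(y ~ Z))
  expect_equal(unname(path$gamma[, 1]), unname(ols), tolerance = 1e-8)
  # penalized block all zero at lambda_max
  expect_true(all(path$beta[, 1] == 0))
})

test_that("full timepoint fit recovers planted proteins and is deterministic", {
  sim <- generate_cohort(small_sim_config(seed = 21, n_acute = 250))
  co <- apply_exclusions(sim$cohort)
  ac <- co[co$timepoint == "acute", ]
  sel1 <- suppressWarnings(fit_timepoint_model(ac, sim$proteins, seed = 31))
  sel2 <- suppressWarnings(fit_timepoint_model(ac, sim$proteins, seed = 31))
  expect_equal(as.data.frame(sel1), as.data.frame(sel2), ignore_attr = TRUE)
  expect_selection_sane(sel1)
  # the two planted acute actives are found (strong signal, n = 250)
  expect_true(all(c("P001", "P002") %in% sel1$protein[sel1$selected]))
  prov <- attr(sel1, "provenance")
  expect_equal(prov$seed, 31)
  expect_true(all(c("sex", "age", "bmi") %in% prov$covariates))
})

test_that("sensitivity analyses filter as prescribed", {
  sim <- generate_cohort(small_sim_config(seed = 22, n_acute = 220))
  co <- apply_exclusions(sim$cohort)
  ac <- co[co$timepoint == "acute", ]

  s_doac <- suppressWarnings(sensitivity_no_doac(ac, sim$proteins, seed = 7))
  expect_equal(attr(s_doac, "n_excluded"), sum(ac$doac_user == 1))
  expect_equal(attr(s_doac, "provenance")$n, sum(ac$doac_user == 0))

  # zero DOAC users -> identical to the full model
  ac0 <- ac; ac0$doac_user <- 0
  full <- suppressWarnings(fit_timepoint_model(
    ac0, sim$proteins, covariates = setdiff(default_covariates(),
                                            "doac_user"), seed = 7))
  s0 <- suppressWarnings(sensitivity_no_doac(ac0, sim$proteins, seed = 7))
  expect_equal(as.data.frame(s0), as.data.frame(full), ignore_attr = TRUE)

  # APTT rule: low-FXI:C retained regardless of APTT, normal/high dropped
  s_aptt <- suppressWarnings(sensitivity_aptt(ac, sim$proteins, seed = 7,
                                              aptt_threshold = 38))
  drop_expected <- sum(ac$fxi_c >= 70 & ac$aptt > 38)
  expect_equal(attr(s_aptt, "n_excluded"), drop_expected)
  low_long <- ac[ac$fxi_c < 70 & ac$aptt > 38, ]
  expect_gt(nrow(low_long), 0)   # fixture exercises the retention rule
  expect_equal(attr(s_aptt, "provenance")$n, nrow(ac) - drop_expected)

  # no elongated APTT -> identity with full model
  ac1 <- ac; ac1$aptt <- 30
  full1 <- suppressWarnings(fit_timepoint_model(ac1, sim$proteins, seed = 7))
  s1 <- suppressWarnings(sensitivity_aptt(ac1, sim$proteins, seed = 7))
  expect_equal(as.data.frame(s1), as.data.frame(full1), ignore_attr = TRUE)

  # too-small subset errors with a sample-size message
  tiny <- ac[1:12, ]; tiny$doac_user <- c(rep(1, 8), rep(0, 4))
  expect_error(sensitivity_no_doac(tiny, sim$proteins, seed = 1, k = 10),
               "non-users")
})

test_that("overlap_selections partitions selections", {
  a <- data.frame(protein = c("P1", "P2", "P3"),
                  selected = c(TRUE, TRUE, FALSE))
  b <- data.frame(protein = c("P1", "P2", "P3"),
                  selected = c(TRUE, FALSE, TRUE))
  ov <- overlap_selections(a, b)
  expect_equal(ov$shared, "P1")
  expect_equal(ov$a_only, "P2")
  expect_equal(ov$b_only, "P3")
  expect_equal(unname(ov$counts), c(2, 2, 1))
  # identical -> all shared; disjoint -> none
  expect_equal(overlap_selections(a, a)$shared, c("P1", "P2"))
  expect_equal(overlap_selections(a, b[c(3, 3), ])$shared, character(0))
})
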