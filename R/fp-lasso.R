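# Fractional-polynomial LASSO with entry-lambda tracking and lambda-ratio
# ranking: the analytical core.
#
# Every protein is expanded into the conventional fractional-polynomial
# power basis x^p, p in {-2, -1, -0.5, 0, 0.5, 1, 2, 3} (p = 0 meaning
# ln x), applied to the min-shifted positive value x - min(x) + 1.  A
# covariate-adjusted LASSO is solved along a 100-point log-spaced lambda
# grid; clinical covariates enter unpenalized, which is implemented exactly
# by Frisch-Waugh-Lovell projection (residualize outcome and penalized
# features on the covariates, solve the penalized-only problem, recover
# covariate coefficients afterwards).  A protein's entry lambda is the
# largest lambda at which any of its basis features has a nonzero
# coefficient; the lambda ratio LR = entry lambda / CV-optimal lambda is
# scale-invariant and ranks selected proteins by robustness.

#' Fractional-polynomial basis configuration
#'
#' @param powers Ordered numeric vector of powers; `0` denotes the natural
#'   log.  Must contain 1 so a plain linear term is always available.
#' @param standardize Center and scale every basis feature to unit SD
#'   (default `TRUE`; required for the lambda grid to weight features
#'   comparably).
#' @return List of class `"fp_config"`.
#' @export
fp_config <- function(powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                      standardize = TRUE) {
  if (!length(powers)) stop_config("powers must be nonempty")
  if (!1 %in% powers) stop_config("powers must contain 1 (identity term)")
  structure(list(powers = powers, standardize = isTRUE(standardize)),
            class = "fp_config")
}

#' Expand a protein matrix into a fractional-polynomial feature basis
#'
#' Each protein column is shifted to a strictly positive scale
#' (`x - min(x) + 1`) and raised to every configured power (power 0 is the
#' natural log).  Features are centered, and scaled to unit SD when
#' `config$standardize` is on.  Zero-variance features are dropped with a
#' warning and recorded.
#'
#' @param matrix Numeric observations x proteins matrix with column names.
#' @param config An [fp_config()].
#' @return List of class `"fp_basis"`: `X` (feature matrix), `map` (data
#'   frame feature_id / protein_id / power), `shifts`, `centers`, `scales`,
#'   `dropped`.
#' @export
fp_expand <- function(matrix, config = fp_config()) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  if (any(!is.finite(matrix))) {
    stop_config("protein matrix contains non-finite values; impute first")
  }
  powers <- config$powers
  p <- ncol(matrix); n <- nrow(matrix)
  shifts <- apply(matrix, 2, function(x) -min(x) + 1)
  X <- matrix(0, n, p * length(powers))
  feature_id <- character(p * length(powers))
  protein_id <- character(p * length(powers))
  power <- numeric(p * length(powers))
  k <- 0L
  for (j in seq_len(p)) {
    xs <- matrix[, j] + shifts[j]
    for (pw in powers) {
      k <- k + 1L
      X[, k] <- if (pw == 0) log(xs) else xs^pw
      feature_id[k] <- paste0(colnames(matrix)[j], "^", pw)
      protein_id[k] <- colnames(matrix)[j]
      power[k] <- pw
    }
  }
  colnames(X) <- feature_id
  rownames(X) <- rownames(matrix)
  centers <- colMeans(X)
  X <- sweep(X, 2, centers)
  scales <- apply(X, 2, sd)
  zero <- scales < 1e-12
  if (config$standardize) {
    X[, !zero] <- sweep(X[, !zero, drop = FALSE], 2, scales[!zero], "/")
  }
  dropped <- feature_id[zero]
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(zero)))
    X <- X[, !zero, drop = FALSE]
  }
  map <- data.frame(feature_id = feature_id[!zero],
                    protein_id = protein_id[!zero],
                    power = power[!zero], stringsAsFactors = FALSE)
  structure(list(X = X, map = map, shifts = shifts,
                 centers = centers[!zero], scales = scales[!zero],
                 dropped = dropped, standardize = config$standardize),
            class = "fp_basis")
}

# Residualize y and the penalized block on [1, covariates] (exact
# unpenalized adjustment by Frisch-Waugh-Lovell).  Returns projected data
# plus the QR used to recover covariate coefficients.
project_covariates <- function(X, covariates, y) {
  n <- length(y)
  C <- if (is.null(covariates)) matrix(1, n, 1) else {
    cbind(`(Intercept)` = 1, as.matrix(covariates))
  }
  qrC <- qr(C)
  My <- qr.resid(qrC, y)
  MX <- qr.resid(qrC, X)
  list(MX = MX, My = My, qrC = qrC, C = C)
}

#' Solve the covariate-adjusted LASSO path and track entry lambdas
#'
#' The grid runs from `lambda_max` (the smallest lambda at which every
#' penalized coefficient is zero) down to `lambda_min_ratio * lambda_max` in
#' `nlambda` log-spaced points.  Covariates are unpenalized.  Per-feature
#' entry lambdas are located on the grid and then refined by extrapolating
#' the inactive-side KKT correlation line to its crossing with lambda; on an
#' orthogonal design this reproduces the soft-threshold closed form
#' `entry lambda = |cov(x_j, y)|` exactly.
#'
#' @param basis An [fp_expand()] result (or any list with elements `X`,
#'   `map`).
#' @param covariates Numeric matrix/data frame of unpenalized covariate
#'   columns, or `NULL`.
#' @param y Numeric outcome.
#' @param nlambda,lambda_min_ratio Grid resolution (defaults 100 points down
#'   to 1e-3 of `lambda_max`).
#' @param thresh Coordinate-descent convergence threshold passed to
#'   `glmnet` (relative to null deviance).  The default 1e-8 balances
#'   runtime against the precision of refined entry lambdas; tighten for
#'   small problems where high-precision entry lambdas are needed.
#' @return List of class `"path_result"`: `lambda_grid`, `beta` (penalized
#'   coefficients, features x grid), `gamma` (covariate coefficients incl.
#'   intercept x grid), `entry_lambda` (named; `NA` if a feature never
#'   enters), `map`.
#' @export
lasso_path <- function(basis, covariates, y, nlambda = 100,
                       lambda_min_ratio = 1e-3, thresh = 1e-8) {
  X <- basis$X
  n <- length(y)
  if (n < 2 || nrow(X) != n) stop_config("need n >= 2 with matching rows")
  if (var(y) < 1e-24) stop_config("outcome variance is degenerate")
  # The problem is solved on the unit-SD outcome and all lambdas rescaled
  # afterwards, so entry lambdas and lambda_opt are exactly homogeneous in
  # the outcome scale (the lambda ratio is scale-invariant by construction,
  # not merely up to solver tolerance).
  sdy <- sd(y)
  pr <- project_covariates(X, covariates, y / sdy)
  lambda_max <- max(abs(crossprod(pr$MX, pr$My)) / n)
  if (lambda_max <= 0) stop_config("all features orthogonal to outcome")
  grid <- lambda_max * exp(seq(0, log(lambda_min_ratio),
                               length.out = nlambda))
  fit <- glmnet::glmnet(pr$MX, pr$My, lambda = grid, standardize = FALSE,
                        intercept = FALSE, thresh = thresh, maxit = 1e6)
  beta <- as.matrix(fit$beta)
  if (ncol(beta) < length(grid)) {  # glmnet may stop early; pad with last fit
    pad <- length(grid) - ncol(beta)
    beta <- cbind(beta, beta[, rep(ncol(beta), pad), drop = FALSE])
  }
  entry <- entry_lambdas(pr$MX, pr$My, beta, grid)
  beta <- beta * sdy
  # recover covariate coefficients gamma(lambda) from the full model
  resid_pen <- y - X %*% beta
  gamma <- qr.coef(pr$qrC, resid_pen)
  gamma[!is.finite(gamma)] <- 0
  rownames(gamma) <- colnames(pr$C)
  structure(list(lambda_grid = grid * sdy, beta = beta, gamma = gamma,
                 entry_lambda = entry * sdy, map = basis$map,
                 lambda_max = lambda_max * sdy),
            class = "path_result")
}

# Refined entry lambda per feature.  Grid detection gives the first grid
# index k with a nonzero coefficient; the crossing of the KKT condition
# |x_j' r(lambda)| / n = lambda inside (grid[k], grid[k-1]) is located by
# extending the inactive-side line through the last two inactive grid
# points (the gradient is piecewise linear in lambda while the active set
# is fixed), clamped to the bracketing interval.  When the line runs
# nearly parallel to the threshold (a "grazing" entry, |s - b| small) the
# crossing is ill-conditioned and solver noise is amplified, so the
# refinement falls back to the grid-resolution value grid[k].
entry_lambdas <- function(MX, My, beta, grid) {
  n <- length(My)
  R <- My - MX %*% beta                      # residuals at each grid point
  Cmat <- crossprod(MX, R) / n               # KKT gradients, p x nlambda
  entry <- rep(NA_real_, nrow(beta))
  names(entry) <- rownames(beta)
  first_nz <- apply(beta != 0, 1, function(z) if (any(z)) which(z)[1] else NA)
  # Polish the gradients at the grid points the secant uses: for a fixed
  # active set A with sign vector s_A the lasso solution is linear,
  # X_A'X_A beta = X_A'y - n lambda s_A, so the solver's iterative error
  # can be removed exactly.  Columns where the polish fails (singular
  # system or sign flip) keep the solver values.
  needed <- sort(unique(c(first_nz - 1L, first_nz - 2L)))
  needed <- needed[!is.na(needed) & needed >= 1L]
  for (m in needed) {
    A <- which(beta[, m] != 0)
    if (!length(A)) {
      Rm <- My
    } else {
      sA <- sign(beta[A, m])
      XA <- MX[, A, drop = FALSE]
      bhat <- tryCatch(
        solve(crossprod(XA), crossprod(XA, My) - n * grid[m] * sA),
        error = function(e) NULL)
      if (is.null(bhat) || any(sign(bhat) != sA)) next
      Rm <- My - XA %*% bhat
    }
    Cmat[, m] <- crossprod(MX, Rm) / n
  }
  for (j in which(!is.na(first_nz))) {
    k <- first_nz[[j]]
    if (k == 1L) { entry[j] <- grid[1]; next }
    s <- sign(Cmat[j, k])
    if (s == 0) s <- 1
    l1 <- grid[k - 1]; c1 <- Cmat[j, k - 1]
    if (k >= 3L) {
      l0 <- grid[k - 2]; c0 <- Cmat[j, k - 2]
      b <- (c1 - c0) / (l1 - l0)
      a <- c1 - b * l1
    } else {
      a <- c1; b <- 0
    }
    if (abs(s - b) >= 0.5) {
      lam <- a / (s - b)
      entry[j] <- min(max(lam, grid[k]), l1)
    } else {
      entry[j] <- grid[k]
    }
  }
  entry
}

#' Select the regularization parameter by k-fold cross-validation
#'
#' Folds are assigned by a seeded random permutation; the lambda grid is
#' computed once on the full sample and shared across folds.  Out-of-fold
#' squared errors are pooled per grid point and the exact minimizer is
#' returned (no one-standard-error rule).  Covariates are refit unpenalized
#' within each training fold.
#'
#' @inheritParams lasso_path
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment (required, logged).
#' @return List of class `"cv_result"`: `lambda_opt`, `cv_mse_curve`,
#'   `cv_r2`, `lambda_grid`, `k`, `seed`, `fold_id`.
#' @export
cv_select_lambda <- function(basis, covariates, y, k = 10, seed,
                             nlambda = 100, lambda_min_ratio = 1e-3,
                             thresh = 1e-8) {
  n <- length(y)
  if (k > n) stop_config("k = %d folds exceeds n = %d observations", k, n)
  if (missing(seed)) stop_config("cv_select_lambda requires an explicit seed")
  X <- basis$X
  sdy <- sd(y)                 # normalized-outcome units, as in lasso_path
  ys <- y / sdy
  pr <- project_covariates(X, covariates, ys)
  lambda_max <- max(abs(crossprod(pr$MX, pr$My)) / n)
  grid <- lambda_max * exp(seq(0, log(lambda_min_ratio),
                               length.out = nlambda))
  fold_id <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  sq_err <- matrix(NA_real_, n, length(grid))
  Cfull <- if (is.null(covariates)) NULL else as.matrix(covariates)
  for (f in seq_len(k)) {
    tr <- fold_id != f; te <- !tr
    prf <- project_covariates(X[tr, , drop = FALSE],
                              if (is.null(Cfull)) NULL else
                                Cfull[tr, , drop = FALSE],
                              ys[tr])
    fit <- glmnet::glmnet(prf$MX, prf$My, lambda = grid,
                          standardize = FALSE, intercept = FALSE,
                          thresh = thresh, maxit = 1e6)
    beta <- as.matrix(fit$beta)
    if (ncol(beta) < length(grid)) {
      beta <- cbind(beta,
                    beta[, rep(ncol(beta), length(grid) - ncol(beta)),
                         drop = FALSE])
    }
    gamma <- qr.coef(prf$qrC, ys[tr] - X[tr, , drop = FALSE] %*% beta)
    gamma[!is.finite(gamma)] <- 0
    Cte <- if (is.null(Cfull)) matrix(1, sum(te), 1) else
      cbind(1, Cfull[te, , drop = FALSE])
    pred <- X[te, , drop = FALSE] %*% beta + Cte %*% gamma
    sq_err[te, ] <- (ys[te] - pred)^2
  }
  mse <- colMeans(sq_err)
  opt <- which.min(mse)
  cv_r2 <- 1 - mse[opt] / mean((ys - mean(ys))^2)
  structure(list(lambda_opt = grid[opt] * sdy, opt_index = opt,
                 cv_mse_curve = mse * sdy^2, cv_r2 = cv_r2,
                 lambda_grid = grid * sdy, k = k, seed = seed,
                 fold_id = fold_id),
            class = "cv_result")
}

#' Aggregate feature-level LASSO results to protein-level selection
#'
#' A protein is selected iff any of its fractional-polynomial features has a
#' nonzero coefficient at the CV-optimal lambda.  Its entry lambda is the
#' maximum over its features' entry lambdas; the lambda ratio is
#' `entry_lambda / lambda_opt` (>= 1 for every selected protein by
#' construction).  Direction of (possibly nonlinear) association is the
#' sign of the marginal Spearman correlation between the raw protein column
#' and the outcome.  Proteins are ranked by descending lambda ratio, ties
#' broken by protein identifier.
#'
#' @param path A [lasso_path()] result.
#' @param cv A [cv_select_lambda()] result on the same grid.
#' @param basis The [fp_expand()] basis shared by both.
#' @param raw Raw protein matrix (for the direction of association).
#' @param y Outcome vector.
#' @return Object of class `"protein_selection"`: a data frame (protein,
#'   selected, direction, entry_lambda, lambda_ratio, rank) with attributes
#'   `lambda_opt`, `cv_r2`, `n`.
#' @export
select_and_rank <- function(path, cv, basis, raw, y) {
  if (max(abs(path$lambda_grid - cv$lambda_grid)) >
      1e-8 * path$lambda_grid[1]) {
    stop_config("path and CV results use different lambda grids")
  }
  opt <- cv$opt_index
  map <- path$map
  proteins <- unique(map$protein_id)
  beta_opt <- path$beta[, opt]
  sel <- vapply(proteins, function(p) {
    any(beta_opt[map$protein_id == p] != 0)
  }, logical(1))
  entry <- vapply(proteins, function(p) {
    e <- path$entry_lambda[map$protein_id == p]
    if (all(is.na(e))) NA_real_ else max(e, na.rm = TRUE)
  }, numeric(1))
  ratio <- ifelse(sel, entry / cv$lambda_opt, NA_real_)
  direction <- vapply(proteins, function(p) {
    if (!p %in% colnames(raw)) return("+")
    r <- suppressWarnings(cor(raw[, p], y, method = "spearman"))
    if (!is.finite(r) || r >= 0) "+" else "-"
  }, character(1))
  df <- data.frame(protein = proteins, selected = sel, direction = direction,
                   entry_lambda = ifelse(sel, entry, NA_real_),
                   lambda_ratio = ratio, stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.na(df$lambda_ratio), -Inf, df$lambda_ratio),
               df$protein)
  df <- df[ord, , drop = FALSE]
  df$rank <- ifelse(df$selected, cumsum(df$selected), NA_integer_)
  rownames(df) <- NULL
  structure(df, class = c("protein_selection", "data.frame"),
            lambda_opt = cv$lambda_opt, cv_r2 = cv$cv_r2, n = length(y),
            seed = cv$seed)
}

#' @export
print.protein_selection <- function(x, ...) {
  cat(sprintf(
    "Protein selection: %d of %d proteins (lambda_opt = %.4g, CV R^2 = %.3f, n = %d)\n",
    sum(x$selected), nrow(x), attr(x, "lambda_opt"), attr(x, "cv_r2"),
    attr(x, "n")))
  sel <- x[x$selected, c("rank", "protein", "direction", "entry_lambda",
                         "lambda_ratio")]
  if (nrow(sel)) print.data.frame(utils::head(sel, 20), row.names = FALSE)
  invisible(x)
}

default_covariates <- function() {
  c("sex", "age", "bmi", "recent_surgery", "recent_immobilization",
    "recent_travel", "chronic_liver_disease", "chronic_kidney_disease",
    "diabetes", "hypertension", "doac_user", "thrombin_inhibitor",
    "heparin", "vka")
}

#' Fit the full protein-selection model for one timepoint
#'
#' Composes the stages for a single timepoint sample: align proteins to the
#' cohort, expand the fractional-polynomial basis on raw (shifted) NPX
#' values, solve the covariate-adjusted LASSO path, pick lambda by ten-fold
#' cross-validation, and aggregate to ranked protein selection.  The
#' normality transforms are descriptive-only and are not applied to the
#' regression inputs (the FP basis performs its own power transforms); the
#' transform log is attached as provenance.
#'
#' @param cohort Cohort data frame (already passed through
#'   [apply_exclusions()]), with `obs_id` and `fxi_c`.
#' @param proteins Protein matrix with rownames matching `cohort$obs_id`.
#' @param covariates Character vector of cohort columns to adjust for
#'   (unpenalized); defaults to the clinical set: sex, age, BMI, transient
#'   VTE risk factors, comorbidities and anticoagulant medication.
#' @param config An [fp_config()].
#' @param seed Integer seed for the CV fold assignment.
#' @param k,nlambda,lambda_min_ratio,thresh Passed through to the path / CV
#'   stages.
#' @return A `"protein_selection"` with a `provenance` attribute (seed, grid
#'   endpoints, covariates, transform log, n).
#' @export
fit_timepoint_model <- function(cohort, proteins,
                                covariates = default_covariates(),
                                config = fp_config(), seed, k = 10,
                                nlambda = 100, lambda_min_ratio = 1e-3,
                                thresh = 1e-8) {
  stopifnot(all(c("obs_id", "fxi_c") %in% names(cohort)))
  idx <- match(cohort$obs_id, rownames(proteins))
  if (any(is.na(idx))) {
    stop_config("%d cohort observation(s) missing from the protein matrix",
                sum(is.na(idx)))
  }
  mat <- impute_median(proteins[idx, , drop = FALSE])
  y <- cohort$fxi_c
  covariates <- intersect(covariates, names(cohort))
  Cmat <- if (length(covariates)) {
    mm <- stats::model.matrix(~ ., data = cohort[, covariates, drop = FALSE])
    mm[, -1, drop = FALSE]
  } else NULL
  tl <- suppressWarnings(normality_transform(mat))
  basis <- fp_expand(mat, config)
  path <- lasso_path(basis, Cmat, y, nlambda, lambda_min_ratio, thresh)
  cv <- cv_select_lambda(basis, Cmat, y, k = k, seed = seed,
                         nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio,
                         thresh = thresh)
  sel <- select_and_rank(path, cv, basis, mat, y)
  attr(sel, "provenance") <- list(seed = seed, k = k,
                                  lambda_max = path$lambda_max,
                                  lambda_min_ratio = lambda_min_ratio,
                                  nlambda = nlambda,
                                  powers = config$powers,
                                  covariates = covariates,
                                  transform_log = tl$log,
                                  n = length(y))
  sel
}

#' Sensitivity analysis restricted to DOAC non-users
#'
#' Reruns the full pipeline on the subset with `doac_user == 0` (direct
#' oral anticoagulants interfere with the APTT-based FXI:C assay).
#'
#' @inheritParams fit_timepoint_model
#' @return A `"protein_selection"` with attribute `n_excluded`.
#' @export
sensitivity_no_doac <- function(cohort, proteins,
                                covariates = default_covariates(),
                                config = fp_config(), seed, k = 10, ...) {
  stopifnot("doac_user" %in% names(cohort))
  keep <- !(cohort$doac_user %in% 1)
  n_excluded <- sum(!keep)
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) < k) {
    stop_config("only %d DOAC non-users; need at least %d for %d-fold CV",
                nrow(sub), k, k)
  }
  sel <- fit_timepoint_model(sub, proteins,
                             covariates = setdiff(covariates, "doac_user"),
                             config = config, seed = seed, k = k, ...)
  attr(sel, "n_excluded") <- n_excluded
  sel
}

#' Sensitivity analysis excluding APTT-discordant observations
#'
#' Removes observations with normal or high FXI:C (>= 70%) but an elongated
#' APTT (above `aptt_threshold` seconds, default 38 s) — discordance
#' suggesting anticoagulant interference with the clotting assay — and
#' reruns the pipeline.  Low-FXI:C observations are retained regardless of
#' APTT (a long APTT is expected there).
#'
#' @inheritParams fit_timepoint_model
#' @param aptt_threshold Upper reference bound for APTT in seconds.
#' @return A `"protein_selection"` with attribute `n_excluded`.
#' @export
sensitivity_aptt <- function(cohort, proteins,
                             covariates = default_covariates(),
                             config = fp_config(), seed, k = 10,
                             aptt_threshold = 38, ...) {
  stopifnot(all(c("aptt", "fxi_c") %in% names(cohort)))
  stratum <- stratify_fxi(cohort$fxi_c)
  drop <- stratum %in% c("normal", "high") & cohort$aptt > aptt_threshold
  n_excluded <- sum(drop)
  sub <- cohort[!drop, , drop = FALSE]
  if (nrow(sub) < k) {
    stop_config("only %d observations retained; need at least %d for %d-fold CV",
                nrow(sub), k, k)
  }
  sel <- fit_timepoint_model(sub, proteins, covariates = covariates,
                             config = config, seed = seed, k = k, ...)
  attr(sel, "n_excluded") <- n_excluded
  sel
}

#' Overlap of two protein selections
#'
#' @param a,b `"protein_selection"` objects (or data frames with `protein`
#'   and `selected` columns).
#' @return List with `shared`, `a_only`, `b_only` protein vectors and
#'   `counts`.
#' @export
overlap_selections <- function(a, b) {
  sa <- a$protein[a$selected]
  sb <- b$protein[b$selected]
  shared <- sort(intersect(sa, sb))
  list(shared = shared,
       a_only = sort(setdiff(sa, sb)),
       b_only = sort(setdiff(sb, sa)),
       counts = c(a = length(sa), b = length(sb), shared = length(shared)))
}

#' Write a protein selection to TSV with a JSON run manifest
#'
#' @param sel A `"protein_selection"`.
#' @param path Output TSV path; a `.json` manifest is written alongside.
#' @return Invisibly, the TSV path.
#' @export
write_selection <- function(sel, path) {
  utils::write.table(as.data.frame(sel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(lambda_opt = attr(sel, "lambda_opt"),
                   cv_r2 = attr(sel, "cv_r2"), n = attr(sel, "n"),
                   n_selected = sum(sel$selected),
                   n_excluded = attr(sel, "n_excluded"),
                   provenance = attr(sel, "provenance")["seed"])
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
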