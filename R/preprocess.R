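# Cohort preprocessing: exclusion rules, normality transforms, FXI:C
# strata, descriptive table, paired timepoint comparison.

#' Apply cohort exclusion rules
#'
#' Removes observations with active malignancy (the cancer-associated
#' proinflammatory protein profile would confound the analysis) and
#' observations with severe FXI deficiency, defined as FXI:C < 20%.
#' Observations missing FXI:C are dropped with a warning.
#'
#' @param cohort Cohort data frame with columns `active_malignancy` and
#'   `fxi_c`.
#' @return The filtered cohort, with an attribute `exclusions` giving counts
#'   by reason.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(all(c("active_malignancy", "fxi_c") %in% names(cohort)))
  n0 <- nrow(cohort)
  miss <- !is.finite(cohort$fxi_c)
  if (any(miss)) {
    warning(sprintf("dropping %d observation(s) with missing FXI:C",
                    sum(miss)))
    cohort <- cohort[!miss, , drop = FALSE]
  }
  malig <- cohort$active_malignancy %in% 1
  cohort <- cohort[!malig, , drop = FALSE]
  deficient <- cohort$fxi_c < 20
  cohort <- cohort[!deficient, , drop = FALSE]
  attr(cohort, "exclusions") <- c(missing_fxi_c = sum(miss),
                                  active_malignancy = sum(malig),
                                  severe_deficiency = sum(deficient),
                                  retained = nrow(cohort),
                                  input = n0)
  cohort
}

#' Transform protein columns toward normality
#'
#' For each protein, picks the transform among identity, square root and
#' natural log that minimizes the absolute moment skewness of the column.
#' Square root and log are applied to the min-shifted positive value
#' `x - min(x) + 1` (NPX values may be negative); the shift constant is
#' recorded.  Missing entries are median-imputed per protein first.
#'
#' @param matrix Numeric observations x proteins matrix.
#' @return A list with `matrix` (transformed) and `log`, a data frame with
#'   one row per protein: chosen `transform`, `shift`, and pre/post absolute
#'   skewness.
#' @export
normality_transform <- function(matrix) {
  stopifnot(is.matrix(matrix))
  m <- impute_median(matrix)
  out <- m
  tf <- character(ncol(m)); shift <- numeric(ncol(m))
  skew_pre <- numeric(ncol(m)); skew_post <- numeric(ncol(m))
  constant <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    skew_pre[j] <- abs(skewness(x))
    if (sd(x) < 1e-12) {
      tf[j] <- "identity"; shift[j] <- 0; skew_post[j] <- skew_pre[j]
      constant[j] <- TRUE
      next
    }
    s <- if (min(x) <= 0) -min(x) + 1 else 0
    xs <- x + s
    cand <- list(identity = x, sqrt = sqrt(xs), ln = log(xs))
    sk <- vapply(cand, function(z) abs(skewness(z)), numeric(1))
    pick <- names(sk)[which.min(sk)]
    tf[j] <- pick
    shift[j] <- if (pick == "identity") 0 else s
    skew_post[j] <- sk[[pick]]
    out[, j] <- cand[[pick]]
  }
  if (any(constant)) {
    warning(sprintf("%d constant protein column(s) left untransformed",
                    sum(constant)))
  }
  log_df <- data.frame(protein_id = colnames(m), transform = tf,
                       shift = shift, skew_pre = skew_pre,
                       skew_post = skew_post, stringsAsFactors = FALSE)
  list(matrix = out, log = log_df)
}

#' Stratify FXI:C values into activity categories
#'
#' Low activity is FXI:C < 70%, normal is 70-150% (bounds inclusive), high
#' is > 150%.
#'
#' @param values Numeric FXI:C values (% activity), all > 0.
#' @return Factor with levels `low`, `normal`, `high`.
#' @export
stratify_fxi <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_config("FXI:C values must be finite and positive (apply exclusions first)")
  }
  lab <- ifelse(values < 70, "low", ifelse(values <= 150, "normal", "high"))
  factor(lab, levels = c("low", "normal", "high"))
}

#' Descriptive baseline table stratified by FXI:C category
#'
#' Binary flags are summarized as `% (n)`; continuous variables as
#' `mean +/- SD` when approximately normal (absolute skewness <= 1) and as
#' `median (Q1/Q3)` otherwise.
#'
#' @param cohort Cohort data frame.
#' @param strata Factor of stratum labels, one per row of `cohort`
#'   (default: [stratify_fxi()] of `cohort$fxi_c`).
#' @param variables Character vector of columns to summarize (default: all
#'   numeric columns except identifiers).
#' @return Data frame with one row per variable and one column per stratum,
#'   plus a `summary_type` column.
#' @export
baseline_table <- function(cohort, strata = stratify_fxi(cohort$fxi_c),
                           variables = NULL) {
  stopifnot(length(strata) == nrow(cohort))
  if (is.null(variables)) {
    num <- vapply(cohort, is.numeric, logical(1))
    variables <- setdiff(names(cohort)[num], c("obs_id", "subject_id"))
  }
  levs <- levels(strata)
  empty <- setdiff(levs, unique(as.character(strata)))
  if (length(empty)) {
    warning(sprintf("empty stratum: %s", paste(empty, collapse = ", ")))
  }
  fmt_cell <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return("NA")
    vals <- unique(x)
    if (all(vals %in% c(0, 1))) {
      sprintf("%.1f%% (%d)", 100 * mean(x), sum(x))
    } else if (abs(skewness(x)) <= 1) {
      sprintf("%.1f ± %.2f", mean(x), sd(x))
    } else {
      q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.2f (%.2f/%.2f)", q[2], q[1], q[3])
    }
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    cells <- vapply(levs, function(s) fmt_cell(x[strata == s]), character(1))
    xx <- x[is.finite(x)]
    type <- if (length(xx) && all(unique(xx) %in% c(0, 1))) "percent_n"
            else if (length(xx) && abs(skewness(xx)) <= 1) "mean_sd"
            else "median_iqr"
    c(variable = v, cells, summary_type = type)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("variable", levs, "summary_type")
  out
}

#' Paired t-test of FXI:C between timepoints
#'
#' Classical paired t on per-subject differences (acute minus follow-up),
#' `df = n_pairs - 1`.  Subjects present in both vectors (matched by
#' `pairing`) are used; incomplete pairs are dropped.
#'
#' @param acute,followup Numeric FXI:C vectors.
#' @param pairing Optional list with `acute` and `followup` subject
#'   identifier vectors used to match pairs; by default vectors are assumed
#'   aligned.
#' @return List with `t`, `p`, `df`, `mean_acute`, `mean_followup`,
#'   `mean_difference`, `n_pairs`.
#' @export
paired_fxi_test <- function(acute, followup, pairing = NULL) {
  if (!is.null(pairing)) {
    shared <- intersect(pairing$acute, pairing$followup)
    acute <- acute[match(shared, pairing$acute)]
    followup <- followup[match(shared, pairing$followup)]
  }
  keep <- is.finite(acute) & is.finite(followup)
  acute <- acute[keep]; followup <- followup[keep]
  n <- length(acute)
  if (n < 2) stop_config("paired t-test needs at least 2 complete pairs")
  d <- acute - followup
  if (all(d == 0)) {
    return(list(t = 0, p = 1, df = n - 1, mean_acute = mean(acute),
                mean_followup = mean(followup), mean_difference = 0,
                n_pairs = n))
  }
  if (sd(d) < 1e-12) {
    stop_config("paired differences have zero variance; t statistic undefined")
  }
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, p = 2 * pt(abs(tt), df = n - 1, lower.tail = FALSE),
       df = n - 1, mean_acute = mean(acute), mean_followup = mean(followup),
       mean_difference = mean(d), n_pairs = n)
}
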