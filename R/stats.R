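# Statistical battery over per-class mean tissue signatures: one-way
# repeated-measures ANOVA with Greenhouse-Geisser correction, Tukey HSD
# pairwise contrasts on the pooled within-subject error, and
# baseline-vs-1-year paired t tests with Holm correction.

#' Per-class mean of a quantitative map
#'
#' Arithmetic mean of map values over each class mask, excluding
#' non-converged voxels. An empty (post-filter) class mask yields NA.
#'
#' @param map numeric array (one fitted parameter).
#' @param masks named list of logical volumes on the map's grid.
#' @param converged optional logical array of per-voxel fit convergence.
#' @return named numeric vector, one mean per class.
#' @export
class_means <- function(map, masks, converged = NULL) {
  vapply(masks, function(m) {
    if (!is.null(converged)) m <- m & converged
    v <- map[m]
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
}

#' Greenhouse-Geisser epsilon
#'
#' epsilon-hat = (sum lambda)^2 / ((k-1) sum lambda^2), with lambda the
#' eigenvalues of the double-centered sample covariance of the k
#' conditions; clipped to [1/(k-1), 1]. A zero covariance (no
#' subject-by-condition variability) is reported as epsilon = 1 with a
#' warning.
#'
#' @param data n x k matrix, one row per subject, one column per
#'   condition.
#' @return epsilon in [1/(k-1), 1].
#' @export
gg_epsilon <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  stopifnot(n >= 2, k >= 2)
  S <- cov(data)
  C <- diag(k) - matrix(1 / k, k, k)
  B <- C %*% S %*% C
  tr <- sum(diag(B))
  if (tr <= .Machine$double.eps * k) {
    warning("zero within-subject covariance; epsilon defined as 1")
    return(1)
  }
  eps <- tr^2 / ((k - 1) * sum(B * B))
  clamp(eps, 1 / (k - 1), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' F = MS_condition / MS_error from the subject x condition decomposition;
#' the p-value uses GG-corrected degrees of freedom
#' (epsilon*(k-1), epsilon*(k-1)*(n-1)).
#'
#' @param data n x k complete-case matrix.
#' @return list with \code{F}, \code{df1}, \code{df2} (corrected),
#'   \code{epsilon}, \code{p}, \code{ms_error}, \code{df_error}
#'   (uncorrected error df), \code{n}, \code{k}.
#' @export
rm_anova_gg <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2) stop("repeated-measures ANOVA needs >= 2 subjects")
  if (any(!is.finite(data))) stop("complete cases only")
  grand <- mean(data)
  cond_means <- colMeans(data)
  subj_means <- rowMeans(data)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- data -
    outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + grand
  ss_err <- sum(resid^2)
  df1u <- k - 1
  df2u <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1u
  ms_err <- ss_err / df2u
  Fstat <- if (ms_err > 0) ms_cond / ms_err else if (ss_cond > 0) Inf else 0
  eps <- suppressWarnings(gg_epsilon(data))
  p <- if (!is.finite(Fstat)) 0 else
    pf(Fstat, eps * df1u, eps * df2u, lower.tail = FALSE)
  if (Fstat == 0) p <- 1
  list(F = Fstat, df1 = eps * df1u, df2 = eps * df2u, epsilon = eps,
       p = p, ms_error = ms_err, df_error = df2u, n = n, k = k)
}

#' Tukey HSD pairwise contrasts for repeated measures
#'
#' For each condition pair: estimate = difference of condition means,
#' SE = sqrt(2 MS_error / n) with the pooled within-subject MS_error,
#' adjusted p from the studentized-range distribution with k groups and
#' (k-1)(n-1) error df at q = |estimate| sqrt(2) / SE, and simultaneous CI
#' estimate +/- q_crit SE / sqrt(2). \code{error = "pairwise"} instead
#' uses each pair's own paired-difference SE with n-1 df (sensitivity
#' analysis).
#'
#' @param data n x k complete-case matrix with condition names as
#'   colnames.
#' @param alpha familywise level for the CIs (default 0.05).
#' @param error \code{"pooled"} (default) or \code{"pairwise"}.
#' @return data frame: \code{comparison}, \code{estimate}, \code{ci_low},
#'   \code{ci_high}, \code{p_adj}.
#' @export
tukey_pairwise <- function(data, alpha = 0.05, error = c("pooled",
                                                         "pairwise")) {
  error <- match.arg(error)
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (is.null(colnames(data))) colnames(data) <- paste0("c", seq_len(k))
  a <- rm_anova_gg(data)
  cm <- colMeans(data)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est <- cm[i1] - cm[i2]
    if (error == "pooled") {
      se <- sqrt(2 * a$ms_error / n)
      df <- a$df_error
    } else {
      d <- data[, i1] - data[, i2]
      se <- sd(d) / sqrt(n) * sqrt(2)  # scaled so q = |est| sqrt(2)/se = t sqrt(2)
      df <- n - 1
    }
    if (se == 0) {
      p <- if (est == 0) 1 else 0
      qc <- 0
    } else {
      q <- abs(est) * sqrt(2) / se
      p <- ptukey(q, k, df, lower.tail = FALSE)
      qc <- qtukey(1 - alpha, k, df)
    }
    data.frame(comparison = paste(colnames(data)[i1], "-",
                                  colnames(data)[i2]),
               estimate = est, ci_low = est - qc * se / sqrt(2),
               ci_high = est + qc * se / sqrt(2), p_adj = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired t tests per tissue class (follow-up minus baseline)
#'
#' Classical paired t test per column: estimate = mean(fu - bl), CI from
#' the t distribution with n-1 df, two-sided p. Differences with zero
#' variance take the exact-equality fast path (p = 1 for a zero estimate,
#' p = 0 otherwise, degenerate CI).
#'
#' @param data_bl,data_fu n x k matrices with matching subjects and
#'   condition columns.
#' @param conf_level CI level (default 0.95).
#' @return data frame: \code{class}, \code{estimate}, \code{ci_low},
#'   \code{ci_high}, \code{p_raw}, \code{n}.
#' @export
paired_tests <- function(data_bl, data_fu, conf_level = 0.95) {
  data_bl <- as.matrix(data_bl); data_fu <- as.matrix(data_fu)
  stopifnot(identical(dim(data_bl), dim(data_fu)))
  k <- ncol(data_bl)
  cls <- colnames(data_bl) %||% paste0("c", seq_len(k))
  out <- lapply(seq_len(k), function(j) {
    d <- data_fu[, j] - data_bl[, j]
    d <- d[is.finite(d)]
    n <- length(d)
    est <- mean(d)
    if (n < 2 ||
        sd(d) < 10 * .Machine$double.eps * max(1, abs(est)) * sqrt(n)) {
      p <- if (isTRUE(all.equal(est, 0)) || n < 2) 1 else 0
      ci <- c(est, est)
    } else {
      tt <- t.test(d, conf.level = conf_level)
      p <- tt$p.value
      ci <- as.numeric(tt$conf.int)
      est <- as.numeric(tt$estimate)
    }
    data.frame(class = cls[j], estimate = est, ci_low = ci[1],
               ci_high = ci[2], p_raw = p, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Holm step-down multiple-comparison adjustment
#'
#' Sort ascending; adjusted_(i) = max over j <= i of
#' min(1, (m - j + 1) p_(j)); restore the original order. Adjusted values
#' are monotone in raw-p rank and never below the raw p.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Build wide matrices from a long cohort table
#'
#' Applies the complete-case rule: a subject enters the matrix for a given
#' parameter/timepoint only if all four class means exist.
#'
#' @param cohort long data frame with columns subject, parameter, class,
#'   timepoint, value.
#' @param parameter parameter name to extract.
#' @param timepoint timepoint code ("bl" or "fu").
#' @param classes column order.
#' @return n x 4 matrix with subject rownames (complete cases only).
#' @export
cohort_matrix <- function(cohort, parameter, timepoint,
                          classes = TISSUE_CLASSES) {
  sub <- cohort[cohort$parameter == parameter &
                  cohort$timepoint == timepoint, ]
  subjects <- sort(unique(sub$subject))
  m <- matrix(NA_real_, length(subjects), length(classes),
              dimnames = list(subjects, classes))
  for (i in seq_len(nrow(sub)))
    m[as.character(sub$subject[i]), sub$class[i]] <- sub$value[i]
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Run the full statistical battery on a cohort table
#'
#' Cross-sectional: per parameter and timepoint, repeated-measures ANOVA
#' with GG correction plus Tukey HSD contrasts across the four classes.
#' Longitudinal: per longitudinal parameter and class, paired t tests of
#' follow-up minus baseline, with a single Holm family spanning all
#' (parameter, class) rows, mirroring the 12-test family of the published
#' analysis.
#'
#' @param cohort long cohort table (subject, parameter, class, timepoint,
#'   value).
#' @param cross_params parameters analyzed cross-sectionally at both
#'   timepoints.
#' @param baseline_only_params parameters analyzed cross-sectionally at
#'   baseline only (e.g. NODDI outputs when no follow-up multishell data
#'   exist).
#' @param long_params parameters entering the paired longitudinal tests.
#' @return list with \code{anova} (data frame), \code{tukey} (data frame),
#'   \code{paired} (data frame with Holm-adjusted p).
#' @export
run_stats_battery <- function(cohort,
                              cross_params = c("FA", "MD", "T1"),
                              baseline_only_params = c("NDI", "ODI", "FWF"),
                              long_params = c("FA", "MD", "T1")) {
  anova_rows <- list(); tukey_rows <- list()
  for (p in c(cross_params, baseline_only_params)) {
    tps <- if (p %in% baseline_only_params) "bl" else c("bl", "fu")
    for (tp in tps) {
      m <- cohort_matrix(cohort, p, tp)
      if (nrow(m) < 2) next
      a <- rm_anova_gg(m)
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        parameter = p, timepoint = tp, F = a$F, df1 = a$df1, df2 = a$df2,
        epsilon = a$epsilon, p = a$p, n = a$n, stringsAsFactors = FALSE)
      tk <- tukey_pairwise(m)
      tukey_rows[[length(tukey_rows) + 1L]] <-
        cbind(parameter = p, timepoint = tp, tk)
    }
  }
  paired_rows <- list()
  for (p in long_params) {
    mb <- cohort_matrix(cohort, p, "bl")
    mf <- cohort_matrix(cohort, p, "fu")
    common <- intersect(rownames(mb), rownames(mf))
    if (length(common) < 2) next
    pt <- paired_tests(mb[common, , drop = FALSE],
                       mf[common, , drop = FALSE])
    paired_rows[[length(paired_rows) + 1L]] <- cbind(parameter = p, pt)
  }
  paired <- if (length(paired_rows)) do.call(rbind, paired_rows) else NULL
  if (!is.null(paired)) paired$p_holm <- holm_adjust(paired$p_raw)
  list(
    anova = if (length(anova_rows)) do.call(rbind, anova_rows) else NULL,
    tukey = if (length(tukey_rows)) do.call(rbind, tukey_rows) else NULL,
    paired = paired
  )
}

#' Sign-pattern summary of the longitudinal tests
#'
#' Compares each paired-test estimate against an expected direction table
#' (e.g. the ground-truth effect signs of a synthetic cohort). A row fails
#' if it is Holm-significant with the wrong sign, or if a clearly
#' programmed effect (|expected effect| at or above \code{floor}) is not
#' recovered as significant. Near-null effects ("little change" cells)
#' below the floor are only required not to produce a significant wrong
#' sign.
#'
#' @param paired paired-test data frame from \code{run_stats_battery}.
#' @param expected data frame with columns parameter, class,
#'   expected_effect.
#' @param alpha significance level on the Holm-adjusted p.
#' @param floor minimum |expected effect| (in the parameter's reported
#'   units) that must be detected.
#' @return data frame with per-row verdicts and an attribute
#'   \code{all_match}.
#' @export
sign_pattern_summary <- function(paired, expected, alpha = 0.05,
                                 floor = 0.01) {
  m <- merge(paired, expected, by = c("parameter", "class"))
  m$programmed <- abs(m$expected_effect) >= floor
  m$sign_match <- sign(m$estimate) == sign(m$expected_effect)
  m$significant <- m$p_holm < alpha
  sign_error <- m$significant & !m$sign_match
  m$ok <- !sign_error & (!m$programmed | m$significant)
  attr(m, "all_match") <- all(m$ok)
  m
}

#' Write the analysis tables to CSV files
#'
#' Emits the cross-sectional ANOVA and Tukey tables, the longitudinal
#' paired-test table (with Holm-adjusted p), per-subject class volumes and
#' the sign-pattern summary.
#'
#' @param results list from \code{run_cohort} (or a compatible list).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
report_tables <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$anova, "anova_gg.csv")
  wr(results$tukey, "tukey_pairwise.csv")
  wr(results$paired, "paired_holm.csv")
  wr(results$volumes, "class_volumes.csv")
  sp <- results$sign_summary
  if (!is.null(sp)) {
    attr(sp, "all_match") <- NULL
    wr(sp, "sign_pattern.csv")
  }
  invisible(paths)
}
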