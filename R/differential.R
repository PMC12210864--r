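#' Filter metabolite features by QC-sample coefficient of variation
#'
#' Retains features whose coefficient of variation (sd/mean) across the
#' designated pooled quality-control injections is strictly below the
#' threshold (default 30%), then drops the QC columns from the returned table.
#' Features with zero mean in the QC samples have an undefined CV and are
#' dropped with a warning.
#'
#' @param table metabolite intensity [abundance_table()] including QC columns.
#' @param qc_sample_ids ids of the QC columns (at least 2).
#' @param cv_threshold keep features with `CV < cv_threshold`.
#' @return Filtered [abundance_table()] without the QC columns.
#' @export
qc_filter_metabolites <- function(table, qc_sample_ids, cv_threshold = 0.30) {
  stopifnot(inherits(table, "abundance_table"))
  missing_qc <- setdiff(qc_sample_ids, ab_samples(table))
  if (length(missing_qc) > 0) {
    stop("QC sample(s) not in table: ", paste(missing_qc, collapse = ", "),
         call. = FALSE)
  }
  if (length(qc_sample_ids) < 2) {
    stop("at least 2 QC samples are required to estimate a CV", call. = FALSE)
  }
  v <- ab_values(table)
  qc <- v[, qc_sample_ids, drop = FALSE]
  mu <- rowMeans(qc)
  zero_mean <- mu == 0
  if (any(zero_mean)) {
    warning("dropping ", sum(zero_mean), " feature(s) with zero QC mean (undefined CV)",
            call. = FALSE)
  }
  cv <- rep(Inf, nrow(qc))
  cv[!zero_mean] <- apply(qc[!zero_mean, , drop = FALSE], 1L, stats::sd) / mu[!zero_mean]
  keep <- !zero_mean & cv < cv_threshold
  bio <- setdiff(ab_samples(table), qc_sample_ids)
  abundance_table(v[keep, bio, drop = FALSE], ab_kind(table))
}

#' Auto-scale (unit-variance scale) a feature table
#'
#' Centers each feature and divides by its sample standard deviation (n-1
#' denominator) — the normalization commonly applied before multivariate
#' discriminant modelling of metabolomic intensities. Zero-variance features
#' are set to 0 with a warning. Idempotent up to floating point.
#'
#' @param table an [abundance_table()].
#' @return An [abundance_table()] with `value_kind = "scaled"`.
#' @export
autoscale <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- ab_values(table)
  if (ncol(v) < 2) stop("auto-scaling needs at least 2 samples", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance feature(s) set to 0 by auto-scaling",
            call. = FALSE)
    sds[flat] <- 1
  }
  scaled <- (v - rowMeans(v)) / sds
  scaled[flat, ] <- 0
  abundance_table(scaled, "scaled")
}

#' Two-sided Student's t-test (equal variance)
#'
#' Classical pooled-variance two-sample t-test. When the pooled variance is
#' zero the statistic is degenerate: equal means give `p = 1`, unequal means
#' give `p = 0` with a warning.
#'
#' @param x,y numeric sample vectors, each of length at least 2.
#' @param var_equal pool the variances (default); `FALSE` gives Welch's test.
#' @return `list(statistic, p.value)` where `statistic` is t for `x - y`.
#' @export
student_t <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 observations", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se2 <- vx / nx + vy / ny
    se <- sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (se == 0) {
    if (mx == my) return(list(statistic = 0, p.value = 1))
    warning("zero pooled variance with unequal means: p = 0", call. = FALSE)
    return(list(statistic = sign(mx - my) * Inf, p.value = 0))
  }
  tval <- (mx - my) / se
  list(statistic = tval, p.value = 2 * stats::pt(-abs(tval), df = df))
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration of the rank-sum null when the combined sample size is at
#' most 25 and there are no ties; otherwise the normal approximation with tie
#' and continuity corrections. The small-cohort regimes this package targets
#' make the exact branch the common one.
#'
#' @param x,y numeric sample vectors, each of length at least 2.
#' @return `list(statistic, p.value)`; `statistic` is the Mann-Whitney U of
#'   `x` over `y`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 observations", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    # fully tied: no evidence either way
    return(list(statistic = nx * ny / 2, p.value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (nx + ny <= 25) && !ties
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, returned in the original
#' order (delegates to `stats::p.adjust`).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and names as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric", call. = FALSE)
  if (anyNA(p)) stop("'p' contains missing values", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# Shared two-group testing engine: one row per feature.
two_group_table <- function(values, case, control, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  xs <- values[, case, drop = FALSE]
  ys <- values[, control, drop = FALSE]
  res <- t(vapply(seq_len(nrow(values)), function(i) {
    r <- if (test == "t") student_t(xs[i, ], ys[i, ]) else wilcoxon_rank_sum(xs[i, ], ys[i, ])
    c(r$statistic, r$p.value)
  }, numeric(2)))
  mean_case <- rowMeans(xs)
  mean_control <- rowMeans(ys)
  effect <- mean_case - mean_control
  data.frame(
    feature = rownames(values),
    mean_case = mean_case,
    mean_control = mean_control,
    effect = effect,
    direction = ifelse(effect > 0, "case_enriched",
                       ifelse(effect < 0, "case_depleted", "none")),
    statistic = res[, 1L],
    p = res[, 2L],
    row.names = NULL,
    stringsAsFactors = FALSE)
}

finish_differential <- function(df, selected, omic, vip = NA_real_) {
  df$q <- benjamini_hochberg(df$p)
  df$vip <- vip
  df$selected <- selected
  df <- df[, c("feature", "mean_case", "mean_control", "effect", "direction",
               "statistic", "p", "q", "vip", "selected")]
  structure(df, omic = omic, class = c("differential_table", "data.frame"))
}

#' Differential metabolites by the joint t-test / VIP rule
#'
#' A metabolite is selected when its two-sided Student's t-test p-value is
#' below `p_threshold` and its VIP score from the fitted discriminant model
#' exceeds `vip_threshold` (strictly). Direction is the sign of the
#' case-minus-control mean difference.
#'
#' @param table metabolite [abundance_table()] (typically auto-scaled; the
#'   per-feature t-test p-value is location/scale invariant so raw intensities
#'   give identical p).
#' @param metadata a [sample_metadata()].
#' @param vip named per-feature VIP vector aligned with the table features
#'   (e.g. from [vip_scores()]).
#' @param p_threshold,vip_threshold selection thresholds.
#' @return A `differential_table` data frame (feature, group means, effect,
#'   direction, statistic, p, BH q, vip, selected).
#' @export
differential_metabolites <- function(table, metadata, vip,
                                     p_threshold = 0.05, vip_threshold = 1.0) {
  al <- align_with_metadata(table, metadata)
  feats <- rownames(al$values)
  if (is.null(names(vip)) || !setequal(names(vip), feats) ||
      length(vip) != length(feats)) {
    stop("'vip' must be a named vector aligned with the table features", call. = FALSE)
  }
  vip <- vip[feats]
  df <- two_group_table(al$values, al$case, al$control, test = "t")
  selected <- df$p < p_threshold & vip > vip_threshold
  finish_differential(df, unname(selected), omic = "metabolite", vip = unname(vip))
}

#' Differential species by Wilcoxon test with an abundance floor
#'
#' Species absent from every sample are excluded before testing. A species is
#' selected when its two-sided Wilcoxon rank-sum p-value is below
#' `p_threshold` and its mean relative abundance across all analysed samples
#' exceeds `abundance_floor` (strictly) — the "key species" rule.
#'
#' @param table species [abundance_table()] with
#'   `value_kind = "relative_abundance"`.
#' @param metadata a [sample_metadata()].
#' @param p_threshold,abundance_floor selection thresholds.
#' @return A `differential_table` data frame.
#' @export
differential_species <- function(table, metadata, p_threshold = 0.05,
                                 abundance_floor = 1e-6) {
  stopifnot(inherits(table, "abundance_table"))
  if (ab_kind(table) != "relative_abundance") {
    stop("differential_species expects a relative-abundance table", call. = FALSE)
  }
  al <- align_with_metadata(table, metadata)
  present <- rowSums(al$values) > 0
  vals <- al$values[present, , drop = FALSE]
  df <- two_group_table(vals, al$case, al$control, test = "wilcoxon")
  mean_abund <- rowMeans(vals[, c(al$case, al$control), drop = FALSE])
  selected <- df$p < p_threshold & mean_abund > abundance_floor
  finish_differential(df, unname(selected), omic = "species")
}

#' Differential KEGG orthologs by Wilcoxon test
#'
#' @param table KO [abundance_table()].
#' @param metadata a [sample_metadata()].
#' @param p_threshold selection threshold on the raw p-value.
#' @return A `differential_table` data frame feeding [ora_enrichment()] via
#'   [split_hits_by_direction()].
#' @export
differential_kos <- function(table, metadata, p_threshold = 0.05) {
  al <- align_with_metadata(table, metadata)
  df <- two_group_table(al$values, al$case, al$control, test = "wilcoxon")
  finish_differential(df, df$p < p_threshold, omic = "ko")
}
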