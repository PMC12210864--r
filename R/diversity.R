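#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with natural logarithm; the input vector is
#' renormalized to sum to one and zero entries contribute nothing, so the
#' index is invariant to appending absent species.
#'
#' @param p non-negative abundance vector (need not sum to 1).
#' @return Shannon index, a non-negative scalar bounded by `log(richness)`.
#' @export
shannon_index <- function(p) {
  p <- check_abundance_vector(p)
  nz <- p[p > 0]
  -sum(nz * log(nz))
}

#' Gini-Simpson diversity index
#'
#' \eqn{1 - \sum_i p_i^2}: the probability that two randomly drawn individuals
#' belong to different species. The plain Simpson dominance \eqn{\sum p_i^2}
#' is available via `form = "dominance"`; the default matches what the vegan
#' package returns as its "simpson" index.
#'
#' @param p non-negative abundance vector.
#' @param form `"gini"` (1 - D, default) or `"dominance"` (D).
#' @return Index value; Gini-Simpson lies in `[0, 1)`.
#' @export
gini_simpson_index <- function(p, form = c("gini", "dominance")) {
  form <- match.arg(form)
  p <- check_abundance_vector(p)
  d <- sum(p^2)
  if (form == "gini") 1 - d else d
}

check_abundance_vector <- function(p) {
  if (!is.numeric(p) || length(p) == 0) stop("'p' must be a numeric vector", call. = FALSE)
  if (anyNA(p)) stop("'p' contains missing values", call. = FALSE)
  if (any(p < 0)) stop("'p' contains negative abundances", call. = FALSE)
  s <- sum(p)
  if (s == 0) stop("all-zero abundance vector: diversity undefined", call. = FALSE)
  p / s
}

#' Compare alpha diversity between groups
#'
#' Computes per-sample Shannon and (Gini-)Simpson indices from a species
#' profile and compares the two groups with the two-sided Wilcoxon rank-sum
#' test.
#'
#' @param table species [abundance_table()] (relative abundances).
#' @param metadata a [sample_metadata()]; each group must contribute at least
#'   two samples.
#' @param simpson_form passed to [gini_simpson_index()].
#' @return A list of class `diversity_result` with `per_sample` (data frame of
#'   sample, group, shannon, simpson) and `tests` (index, W statistic,
#'   two-sided p).
#' @export
compare_alpha_diversity <- function(table, metadata,
                                    simpson_form = c("gini", "dominance")) {
  simpson_form <- match.arg(simpson_form)
  al <- align_with_metadata(table, metadata)
  if (length(al$case) < 2 || length(al$control) < 2) {
    stop("each group needs at least 2 samples for diversity comparison", call. = FALSE)
  }
  ids <- c(al$case, al$control)
  shan <- apply(al$values[, ids, drop = FALSE], 2L, shannon_index)
  simp <- apply(al$values[, ids, drop = FALSE], 2L, gini_simpson_index,
                form = simpson_form)
  per_sample <- data.frame(
    sample_id = ids,
    group = rep(c("case", "control"), c(length(al$case), length(al$control))),
    shannon = unname(shan),
    simpson = unname(simp),
    stringsAsFactors = FALSE)
  tests <- do.call(rbind, lapply(c("shannon", "simpson"), function(ix) {
    res <- wilcoxon_rank_sum(per_sample[[ix]][per_sample$group == "case"],
                             per_sample[[ix]][per_sample$group == "control"])
    data.frame(index = ix, statistic = res$statistic, p = res$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sample = per_sample, tests = tests),
            class = "diversity_result")
}
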