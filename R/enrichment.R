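#' Over-representation analysis (hypergeometric ORA)
#'
#' For each set in the library: intersect the members with the universe,
#' count the hits falling inside, and compute the exact hypergeometric upper
#' tail \eqn{P(X \ge k)} together with the enrichment ratio
#' \eqn{k / (n K / N)} — observed hits in the set over the count expected if
#' hits were drawn uniformly from the universe. This is the ORA mode of
#' metabolite-set enrichment analysis and of KO pathway enrichment; run it
#' separately on case-depleted and case-enriched hit lists (see
#' [split_hits_by_direction()]).
#'
#' @param hits character vector of significant feature ids; must be a subset
#'   of `universe`.
#' @param universe all tested feature ids (e.g. every metabolite surviving QC,
#'   or every profiled KO).
#' @param library named list of sets ([read_set_library()]).
#' @param min_set_size sets with fewer in-universe members are dropped with a
#'   warning.
#' @return Data frame of class `enrichment_result`, sorted by p: set, N, K, n,
#'   k, enrichment_ratio, p, BH q.
#' @export
ora_enrichment <- function(hits, universe, library, min_set_size = 2) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  offenders <- setdiff(hits, universe)
  if (length(offenders) > 0) {
    stop("hit(s) not in universe: ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) ", ...", call. = FALSE)
  }
  members <- lapply(library, function(m) intersect(unique(m), universe))
  sizes <- vapply(members, length, integer(1))
  small <- sizes < min_set_size
  if (any(small)) {
    warning("dropping ", sum(small), " set(s) with fewer than ", min_set_size,
            " members in the universe", call. = FALSE)
    members <- members[!small]
    sizes <- sizes[!small]
  }
  N <- length(universe)
  n <- length(hits)
  k <- vapply(members, function(m) length(intersect(m, hits)), integer(1))
  ratio <- if (n == 0) rep(NA_real_, length(k)) else k / (n * sizes / N)
  p <- stats::phyper(k - 1, sizes, N - sizes, n, lower.tail = FALSE)
  df <- data.frame(set = names(members),
                   N = N, K = sizes, n = n, k = k,
                   enrichment_ratio = ratio,
                   p = p,
                   q = benjamini_hochberg(p),
                   row.names = NULL,
                   stringsAsFactors = FALSE)
  df <- df[order(df$p, df$set), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("enrichment_result", "data.frame"))
}

#' Split selected features by direction of change
#'
#' @param diff a `differential_table` (e.g. from
#'   [differential_metabolites()]).
#' @return `list(depleted, enriched)`: disjoint id vectors of the selected
#'   case-depleted and case-enriched features.
#' @export
split_hits_by_direction <- function(diff) {
  stopifnot(inherits(diff, "differential_table"))
  list(depleted = diff$feature[diff$selected & diff$direction == "case_depleted"],
       enriched = diff$feature[diff$selected & diff$direction == "case_enriched"])
}
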