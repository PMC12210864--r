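#' Pairwise Spearman correlation matrix with p-values
#'
#' Average ranks are used for ties. Two-sided p-values come from the
#' t-approximation on rho, or from the exact null distribution when there are
#' at most 9 samples and no ties within either feature. Constant features have
#' undefined correlations; these are recorded as rho 0 with p 1 and a warning.
#'
#' @param table an [abundance_table()] with at least 3 samples.
#' @return `list(rho, p)`: square matrices over the table features (diagonal
#'   rho 1 / p 0).
#' @export
spearman_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  X <- ab_values(table)
  n <- ncol(X)
  if (n < 3) stop("Spearman correlation needs at least 3 samples", call. = FALSE)
  const <- apply(X, 1L, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(t(X), method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant feature(s): correlations set to 0 with p = 1",
            call. = FALSE)
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  # t-approximation, vectorized over the whole matrix
  r <- pmin(pmax(rho, -1), 1)
  p <- matrix(0, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  off <- abs(r) < 1
  tval <- r[off] * sqrt((n - 2) / (1 - r[off]^2))
  p[off] <- 2 * stats::pt(-abs(tval), df = n - 2)
  # exact small-sample p where admissible
  if (n <= 9) {
    has_ties <- apply(X, 1L, anyDuplicated) > 0
    idx <- which(!const)
    for (a in idx) {
      for (b in idx[idx > a]) {
        if (!has_ties[a] && !has_ties[b]) {
          ct <- stats::cor.test(X[a, ], X[b, ], method = "spearman", exact = TRUE)
          p[a, b] <- p[b, a] <- ct$p.value
        }
      }
    }
  }
  p[const, ] <- 1
  p[, const] <- 1
  diag(p) <- 0
  list(rho = rho, p = p)
}

#' Detect correlation guilds by average-linkage clustering
#'
#' The guild-detection step: features are clustered on the Spearman distance
#' `1 - rho` (so strongly anti-correlated features do not merge; pass
#' `absolute = TRUE` for `1 - |rho|`) with average linkage, and the tree is
#' cut at the given height. Cutting at 0.4 on differential metabolites yields
#' metabolite modules; cutting at 0.5 on key species yields co-abundance
#' groups (CAGs). Singletons are retained as their own guilds. Labels are
#' assigned in decreasing order of guild size, ties broken by the
#' lexicographically smallest member id, which makes the labelling invariant
#' to feature input order.
#'
#' @param rho square symmetric correlation matrix with feature dimnames.
#' @param height tree cut height on the `1 - rho` scale.
#' @param linkage agglomeration method (the workflow uses `"average"`).
#' @param absolute cluster on `1 - |rho|` instead of `1 - rho`.
#' @param prefix guild label prefix, e.g. `"M"` for metabolite modules or
#'   `"CAG"` for species guilds.
#' @return A list of class `guild_assignment`: `assignment` (named
#'   feature -> label vector), `guilds` (label -> member list), and the
#'   clustering `params`.
#' @export
cluster_features <- function(rho, height, linkage = "average",
                             absolute = FALSE, prefix = "G") {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho)) {
    stop("'rho' must be a square matrix", call. = FALSE)
  }
  if (max(abs(rho - t(rho))) > 1e-8) {
    stop("'rho' must be symmetric", call. = FALSE)
  }
  ids <- rownames(rho)
  if (is.null(ids)) stop("'rho' must carry feature ids as dimnames", call. = FALSE)
  d <- if (absolute) 1 - abs(rho) else 1 - rho
  diag(d) <- 0
  if (nrow(d) == 1L) {
    cl <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    cl <- stats::cutree(hc, h = height)
    names(cl) <- ids
  }
  members <- split(names(cl), cl)
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, function(m) min(m), character(1)))
  members <- members[ord]
  labels <- paste0(prefix, seq_along(members))
  names(members) <- labels
  assignment <- stats::setNames(
    rep(labels, vapply(members, length, integer(1))),
    unlist(members, use.names = FALSE))
  assignment <- assignment[ids]
  structure(list(assignment = assignment,
                 guilds = members,
                 params = list(distance = if (absolute) "1-|rho|" else "1-rho",
                               linkage = linkage, height = height)),
            class = "guild_assignment")
}

#' @export
print.guild_assignment <- function(x, ...) {
  cat(sprintf("<guild_assignment> %d features in %d guilds (%s, %s linkage, cut %.3g)\n",
              length(x$assignment), length(x$guilds), x$params$distance,
              x$params$linkage, x$params$height))
  invisible(x)
}

#' Cumulative guild abundance
#'
#' Sums the member rows of each guild, producing a guild-by-sample table whose
#' per-sample totals equal the input totals. The value kind is inherited.
#'
#' @param table an [abundance_table()].
#' @param assignment a [cluster_features()] result covering every table
#'   feature.
#' @return An [abundance_table()] with one row per guild, ordered by guild
#'   label.
#' @export
guild_abundance <- function(table, assignment) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(assignment, "guild_assignment"))
  feats <- ab_features(table)
  unassigned <- setdiff(feats, names(assignment$assignment))
  if (length(unassigned) > 0) {
    stop("feature(s) without guild assignment: ",
         paste(utils::head(unassigned, 5), collapse = ", "),
         if (length(unassigned) > 5) ", ...", call. = FALSE)
  }
  labels <- assignment$assignment[feats]
  agg <- rowsum(ab_values(table), group = labels, reorder = FALSE)
  order_in <- names(assignment$guilds)[names(assignment$guilds) %in% rownames(agg)]
  abundance_table(agg[order_in, , drop = FALSE], ab_kind(table))
}

#' Signed co-occurrence network from a correlation matrix
#'
#' Benjamini-Hochberg adjusts the upper-triangle p-values and keeps edges with
#' `q < alpha` and `|rho| > threshold` (strict: a correlation of exactly the
#' threshold is excluded). Positive and negative edges carry sign `"+"` /
#' `"-"` (the red and blue edges of a co-occurrence plot).
#'
#' @param rho,p aligned square matrices from [spearman_matrix()].
#' @param threshold absolute-correlation cutoff (default 0.46).
#' @param alpha FDR cutoff on the adjusted p-value.
#' @param assignment optional [cluster_features()] result used to attach guild
#'   labels to nodes.
#' @return A list of class `cooc_network` with `nodes` (id, guild) and `edges`
#'   (from, to, rho, q, sign) data frames.
#' @export
cooccurrence_network <- function(rho, p, threshold = 0.46, alpha = 0.05,
                                 assignment = NULL) {
  if (!all(dim(rho) == dim(p))) stop("'rho' and 'p' must be aligned", call. = FALSE)
  ids <- rownames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  q <- benjamini_hochberg(p[ut])
  r <- rho[ut]
  keep <- q < alpha & abs(r) > threshold
  edges <- data.frame(from = ids[ut[keep, 1L]],
                      to = ids[ut[keep, 2L]],
                      rho = r[keep],
                      q = q[keep],
                      sign = ifelse(r[keep] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(assignment)) {
    nodes$guild <- unname(assignment$assignment[ids])
  }
  structure(list(nodes = nodes, edges = edges,
                 params = list(threshold = threshold, alpha = alpha)),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d nodes, %d edges (|rho| > %.3g, q < %.3g)\n",
              nrow(x$nodes), nrow(x$edges), x$params$threshold, x$params$alpha))
  invisible(x)
}
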