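#' Cross-block Spearman correlation with significance annotation
#'
#' Correlates every row entity of `a` against every row entity of `b` over
#' their shared samples (Spearman; binary clinical indices enter through their
#' 0/1 ranks). Samples with missing values are dropped pairwise; a pair with
#' fewer than 3 complete samples gets an `NA` entry with a warning. Entries
#' are annotated `"**"` for p < 0.01, `"*"` for 0.01 <= p < 0.05, `""`
#' otherwise — the heatmap-star convention on raw p-values. Set
#' `adjust = TRUE` to also report BH q-values across the block.
#'
#' @param a,b [abundance_table()]s or numeric entities-by-samples matrices
#'   with sample ids as column names (e.g. [clinical_matrix()]).
#' @param row_role,col_role free-text roles recorded in the result (e.g.
#'   `"CAG"`, `"module"`, `"clinical"`).
#' @param adjust also compute BH q-values over all block entries.
#' @return A list of class `correlation_block`: `rho`, `p`, `annotation`
#'   matrices (rows = entities of `a`), optional `q`, plus the roles.
#' @export
correlate_blocks <- function(a, b, row_role = "", col_role = "", adjust = FALSE) {
  A <- if (inherits(a, "abundance_table")) ab_values(a) else as.matrix(a)
  B <- if (inherits(b, "abundance_table")) ab_values(b) else as.matrix(b)
  shared <- intersect(colnames(A), colnames(B))
  if (length(shared) < 3) stop("fewer than 3 shared samples between blocks", call. = FALSE)
  A <- A[, shared, drop = FALSE]
  B <- B[, shared, drop = FALSE]
  rho <- matrix(NA_real_, nrow(A), nrow(B), dimnames = list(rownames(A), rownames(B)))
  p <- rho
  n_skipped <- 0L
  n_degenerate <- 0L
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      ok <- !is.na(A[i, ]) & !is.na(B[j, ])
      if (sum(ok) < 3) {
        n_skipped <- n_skipped + 1L
        next
      }
      st <- spearman_pair(A[i, ok], B[j, ok])
      n_degenerate <- n_degenerate + st[["degenerate"]]
      rho[i, j] <- st[["rho"]]
      p[i, j] <- st[["p"]]
    }
  }
  if (n_skipped > 0) {
    warning(n_skipped, " pair(s) with fewer than 3 complete samples set to NA",
            call. = FALSE)
  }
  if (n_degenerate > 0) {
    warning(n_degenerate, " pair(s) with a constant member: rho 0, p 1", call. = FALSE)
  }
  annotation <- matrix("", nrow(rho), ncol(rho), dimnames = dimnames(rho))
  annotation[!is.na(p) & p < 0.05] <- "*"
  annotation[!is.na(p) & p < 0.01] <- "**"
  out <- list(rho = rho, p = p, annotation = annotation,
              row_role = row_role, col_role = col_role)
  if (adjust) {
    q <- p
    ok <- !is.na(p)
    q[ok] <- benjamini_hochberg(p[ok])
    out$q <- q
  }
  structure(out, class = "correlation_block")
}

#' @export
print.correlation_block <- function(x, ...) {
  cat(sprintf("<correlation_block> %d %s x %d %s\n",
              nrow(x$rho), if (nzchar(x$row_role)) x$row_role else "rows",
              ncol(x$rho), if (nzchar(x$col_role)) x$col_role else "cols"))
  invisible(x)
}

#' Area under the ROC curve via the Mann-Whitney identity
#'
#' \eqn{AUC = U/(n_1 n_0)} where U counts case-control pairs in which the case
#' scores higher, with ties counted 0.5. The returned AUC is
#' orientation-preserving (below 0.5 when cases score lower); `oriented = TRUE`
#' returns `max(auc, 1 - auc)` instead. `direction` records which way the
#' cases scored.
#'
#' @param score per-sample numeric scores (e.g. a module's cumulative
#'   abundance).
#' @param labels binary labels: logical, 0/1, or `"case"`/`"control"`.
#' @param oriented return the orientation-free AUC.
#' @return `list(auc, direction)` with direction `"case_higher"` or
#'   `"case_lower"`.
#' @export
roc_auc <- function(score, labels, oriented = FALSE) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "case"
  }
  pos <- as.logical(labels)
  if (anyNA(score) || anyNA(pos)) stop("scores and labels must be complete", call. = FALSE)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(score)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc >= 0.5) "case_higher" else "case_lower"
  if (oriented) auc <- max(auc, 1 - auc)
  list(auc = auc, direction = direction)
}

#' Build tri-partite Sankey links from two correlation blocks
#'
#' Chains left entities (CAGs) through middle entities (metabolite modules) to
#' right entities (clinical indices): a left link survives when its
#' correlation has the required sign and p < `alpha`, likewise on the right,
#' and only middle entities present in both retained legs are kept. An empty
#' result is a valid (empty) link set.
#'
#' @param left [correlate_blocks()] result, rows = left entities, columns =
#'   middle entities.
#' @param right [correlate_blocks()] result, rows = middle entities, columns =
#'   right entities.
#' @param left_sign,right_sign required correlation sign per leg, `"+"` or
#'   `"-"`.
#' @param alpha significance cutoff on the raw p-value.
#' @return A list of class `sankey_links`: `links` data frame (source, target,
#'   rho, p, sign, leg) and the surviving `middle` entities.
#' @export
build_sankey_links <- function(left, right, left_sign = "+", right_sign = "+",
                               alpha = 0.05) {
  stopifnot(inherits(left, "correlation_block"), inherits(right, "correlation_block"))
  if (!all(colnames(left$rho) %in% rownames(right$rho)) &&
      length(intersect(colnames(left$rho), rownames(right$rho))) == 0) {
    stop("blocks share no middle entities", call. = FALSE)
  }
  sign_ok <- function(rho, s) if (s == "+") rho > 0 else rho < 0
  pick <- function(block, s) {
    keep <- which(!is.na(block$p) & block$p < alpha & sign_ok(block$rho, s),
                  arr.ind = TRUE)
    data.frame(source = rownames(block$rho)[keep[, 1L]],
               target = colnames(block$rho)[keep[, 2L]],
               rho = block$rho[keep],
               p = block$p[keep],
               sign = rep(s, nrow(keep)),
               stringsAsFactors = FALSE)
  }
  lf <- pick(left, left_sign)
  rt <- pick(right, right_sign)
  middle <- intersect(lf$target, rt$source)
  lf <- lf[lf$target %in% middle, , drop = FALSE]
  rt <- rt[rt$source %in% middle, , drop = FALSE]
  lf$leg <- if (nrow(lf)) "left" else character(0)
  rt$leg <- if (nrow(rt)) "right" else character(0)
  links <- rbind(lf, rt)
  rownames(links) <- NULL
  structure(list(links = links, middle = middle,
                 params = list(left_sign = left_sign, right_sign = right_sign,
                               alpha = alpha)),
            class = "sankey_links")
}

#' Bray-Curtis leaf order of samples
#'
#' Average-linkage hierarchical clustering of samples on Bray-Curtis
#' dissimilarity, returning the dendrogram leaf order — the sample ordering
#' used for abundance heatmaps.
#'
#' @param table a non-negative [abundance_table()].
#' @return Character vector of sample ids in leaf order.
#' @export
braycurtis_order <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- ab_values(table)
  zero <- colSums(v) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(v)[zero], collapse = ", "),
         call. = FALSE)
  }
  d <- vegan::vegdist(t(v), method = "bray")
  hc <- stats::hclust(d, method = "average")
  colnames(v)[hc$order]
}
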