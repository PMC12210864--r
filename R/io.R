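#' Read a feature-by-sample abundance table from tab-delimited text
#'
#' Expects a header row of sample ids and a first column of feature ids
#' (features in rows). Values must parse as numbers; any cell that does not is
#' reported with its feature and sample id. Missing values (empty cells or
#' `NA`) are a hard error except for intensity tables read with
#' `impute = "halfmin"`, which replaces them by half the per-feature minimum
#' observed value.
#'
#' @param path path to a TSV file.
#' @param value_kind what the values are; see [abundance_table()].
#' @param impute missing-value policy, `"none"` (default, error on NA) or
#'   `"halfmin"` (intensity tables only).
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`
#'   for transposed exports.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 value_kind = c("intensity", "relative_abundance", "scaled"),
                                 impute = c("none", "halfmin"),
                                 orientation = c("features_in_rows", "samples_in_rows")) {
  value_kind <- match.arg(value_kind)
  impute <- match.arg(impute)
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = c("", "NA"),
                           quote = "", comment.char = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("expected a feature-id column plus at least one sample column",
                          call. = FALSE)
  ids <- raw[[1L]]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    k <- bad[1L, ]
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 m[k[1L], k[2L]], ids[k[1L]], colnames(m)[k[2L]]), call. = FALSE)
  }
  rownames(num) <- ids
  if (anyNA(num)) {
    if (value_kind == "intensity" && impute == "halfmin") {
      n_missing <- sum(is.na(num))
      num <- t(apply(num, 1L, function(v) {
        if (anyNA(v)) {
          obs <- v[!is.na(v)]
          if (length(obs) == 0) {
            stop("feature with all values missing cannot be imputed", call. = FALSE)
          }
          v[is.na(v)] <- min(obs) / 2
        }
        v
      }))
      rownames(num) <- ids
      warning(sprintf("imputed %d missing intensit%s by half the per-feature minimum",
                      n_missing, if (n_missing == 1) "y" else "ies"), call. = FALSE)
    } else {
      miss <- which(is.na(num), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at feature '%s', sample '%s' (impute = 'none')",
                   ids[miss[1L]], colnames(num)[miss[2L]]), call. = FALSE)
    }
  }
  if (orientation == "samples_in_rows") num <- t(num)
  abundance_table(num, value_kind)
}

#' Write an abundance table as tab-delimited text
#'
#' Numbers are written with 17 significant digits so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param x an [abundance_table()].
#' @param path output file path.
#' @param id_column header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "abundance_table"))
  v <- ab_values(x)
  chr <- apply(v, 2L, function(col) sprintf("%.17g", col))
  if (!is.matrix(chr)) chr <- matrix(chr, nrow = nrow(v), dimnames = dimnames(v))
  out <- cbind(rownames(v), chr)
  colnames(out) <- c(id_column, colnames(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a GMT-like set library
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`. The
#' description column is required by the format but ignored. Sets with no
#' members are skipped with a warning; duplicated set names are an error.
#'
#' @param path path to the GMT file.
#' @return A named list of character vectors (class `set_library`).
#' @export
read_set_library <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    stop("duplicate set name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(f) {
    mem <- f[-(1:2)]
    mem[nzchar(mem)]
  })
  names(sets) <- nm
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    warning("skipping set(s) with no members: ",
            paste(nm[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  structure(sets, class = c("set_library", "list"))
}

#' Write a set library in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of descriptions (defaults to
#'   the set names).
#' @return `path`, invisibly.
#' @export
write_set_library <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a co-occurrence network to GraphML or edge-list TSV
#'
#' Accepts either the `cooc_network` object produced by
#' [cooccurrence_network()] or a plain edge data frame with columns
#' `from`, `to`, `rho`, `q`, `sign`. Edge attributes are preserved in both
#' formats; the edge TSV round-trips through [read_network_edges()].
#'
#' @param x network or edge data frame.
#' @param path output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param nodes optional data frame of node attributes (first column node id);
#'   taken from `x` when it is a `cooc_network`.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path, format = c("graphml", "edge_tsv"), nodes = NULL) {
  format <- match.arg(format)
  if (inherits(x, "cooc_network")) {
    if (is.null(nodes)) nodes <- x$nodes
    edges <- x$edges
  } else {
    edges <- as.data.frame(x)
  }
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    stop("edge list needs 'from' and 'to' columns", call. = FALSE)
  }
  if (format == "edge_tsv") {
    out <- edges
    for (col in names(out)) {
      if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (nrow(edges) == 0 && is.null(nodes)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(edges) > 0) edges else data.frame(from = character(0), to = character(0)),
      directed = FALSE, vertices = nodes)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an edge-list TSV written by [write_network()]
#'
#' @param path path to the edge TSV.
#' @return A data frame of edges.
#' @export
read_network_edges <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
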