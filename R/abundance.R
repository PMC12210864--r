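#' Construct an abundance table
#'
#' The central container of the package: a features-by-samples numeric matrix
#' with unique identifiers on both axes and a tag recording what the values
#' are. Relative-abundance tables must have column sums of at most 1 (up to
#' 1e-6 slack, so closed compositions pass); `scaled` tables (e.g. after
#' [autoscale()]) may hold negative values.
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimnames must be set and free of duplicates.
#' @param value_kind one of `"intensity"`, `"relative_abundance"`, `"scaled"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values,
                            value_kind = c("intensity", "relative_abundance", "scaled")) {
  value_kind <- match.arg(value_kind)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must carry feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  dup_f <- unique(fid[duplicated(fid)])
  if (length(dup_f) > 0) {
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s) > 0) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) {
    stop("abundance table contains missing values; see `impute` in read_abundance_table()",
         call. = FALSE)
  }
  if (value_kind != "scaled" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at feature '%s', sample '%s' (value_kind = '%s')",
                 fid[bad[1L]], sid[bad[2L]], value_kind), call. = FALSE)
  }
  if (value_kind == "relative_abundance") {
    cs <- colSums(values)
    bad <- sid[cs > 1 + 1e-6]
    if (length(bad) > 0) {
      stop("relative abundances sum to more than 1 in sample(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(values = values, value_kind = value_kind),
            class = "abundance_table")
}

#' Accessors for abundance tables
#'
#' @param x an `abundance_table`.
#' @return `ab_values()` the numeric matrix; `ab_features()` / `ab_samples()`
#'   the identifier vectors; `ab_kind()` the value-kind tag.
#' @export
ab_values <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  x$values
}

#' @rdname ab_values
#' @export
ab_features <- function(x) rownames(ab_values(x))

#' @rdname ab_values
#' @export
ab_samples <- function(x) colnames(ab_values(x))

#' @rdname ab_values
#' @export
ab_kind <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  x$value_kind
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table
#'
#' @param x an `abundance_table`.
#' @param i features to keep (ids, indices or logical); missing keeps all.
#' @param j samples to keep; missing keeps all.
#' @param ... ignored.
#' @return An `abundance_table` with the same `value_kind`.
#' @export
`[.abundance_table` <- function(x, i, j, ...) {
  v <- x$values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  abundance_table(v, x$value_kind)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  invisible(x)
}
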