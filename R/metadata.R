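#' Construct per-sample metadata
#'
#' Validates a data frame with one row per sample: a unique `sample_id`, a
#' non-missing two-level `group` (`"case"` / `"control"`), an optional
#' `subgroup` label (e.g. mix / neurologic / carrier), and any number of
#' clinical index columns. Numeric columns whose non-missing values are all 0
#' or 1 are classified as binary indices (e.g. cardiac amyloidosis); other
#' numeric columns as continuous indices.
#'
#' @param df data frame with at least `sample_id` and `group` columns.
#' @return The validated data frame, class `sample_metadata`, with attributes
#'   `binary_indices` and `continuous_indices` naming the index columns.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("metadata needs 'sample_id' and 'group' columns", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$group)) {
    stop("group label missing for sample(s): ",
         paste(df$sample_id[is.na(df$group)], collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad) > 0) {
    stop("group labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  index_cols <- setdiff(names(df), c("sample_id", "group", "subgroup"))
  is_num <- vapply(df[index_cols], is.numeric, logical(1))
  num_cols <- index_cols[is_num]
  binary <- num_cols[vapply(num_cols, function(cl) {
    v <- df[[cl]][!is.na(df[[cl]])]
    length(v) > 0 && all(v %in% c(0, 1))
  }, logical(1))]
  continuous <- setdiff(num_cols, binary)
  structure(df,
            binary_indices = binary,
            continuous_indices = continuous,
            class = c("sample_metadata", "data.frame"))
}

#' Read sample metadata from a TSV file
#'
#' @param path path to a tab-delimited file with a header row.
#' @return A [sample_metadata()] object.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          quote = "", fileEncoding = "UTF-8")
  sample_metadata(df)
}

#' Write sample metadata as TSV
#'
#' @param meta a [sample_metadata()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Split sample ids by group
#'
#' @param meta a [sample_metadata()] object.
#' @return `list(case = ids, control = ids)`.
#' @export
split_groups <- function(meta) {
  stopifnot(inherits(meta, "sample_metadata"))
  list(case = meta$sample_id[meta$group == "case"],
       control = meta$sample_id[meta$group == "control"])
}

#' Clinical index matrix (variables x samples)
#'
#' Extracts the binary and continuous clinical indices as a numeric matrix
#' suitable for [correlate_blocks()]; binary flags are carried as 0/1, which
#' Spearman correlation treats through their ranks.
#'
#' @param meta a [sample_metadata()] object.
#' @param vars which index columns to include (default: all binary then all
#'   continuous indices).
#' @return Numeric matrix, one row per clinical variable, columns named by
#'   sample id. May contain `NA` for missing clinical entries.
#' @export
clinical_matrix <- function(meta, vars = NULL) {
  stopifnot(inherits(meta, "sample_metadata"))
  if (is.null(vars)) {
    vars <- c(attr(meta, "binary_indices"), attr(meta, "continuous_indices"))
  }
  missing_vars <- setdiff(vars, names(meta))
  if (length(missing_vars) > 0) {
    stop("clinical variable(s) not in metadata: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  m <- t(as.matrix(as.data.frame(meta)[vars]))
  mode(m) <- "numeric"
  colnames(m) <- meta$sample_id
  rownames(m) <- vars
  m
}
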