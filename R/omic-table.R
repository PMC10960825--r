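#' A single omic's samples-by-features table
#'
#' An `omic_table` holds one omic layer (e.g. taxonomic relative abundances,
#' pathway abundances, or metabolite intensities) as a numeric matrix with
#' samples in rows and features in columns, together with a short omic tag
#' ("T", "P", "M", "S", ...) and a scale state recording which
#' transformations have been applied. Feature ids are namespaced with the
#' omic tag (`"T:Bacteroides uniformis"`) so that ids are unique across
#' omics when tables are combined.
#'
#' @param values numeric matrix or data frame, samples in rows. Row names
#'   are sample ids, column names feature ids.
#' @param omic_id short omic tag, e.g. `"T"`.
#' @param scale_state one of `"raw"`, `"relative"`, `"log"`,
#'   `"standardized"`.
#'
#' @return An `omic_table` object.
#' @export
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("s", 1:3), c("f1", "f2")))
#' omic_table(m, "T")
omic_table <- function(values, omic_id, scale_state = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and feature column names", call. = FALSE)
  }
  colnames(values) <- prefix_features(colnames(values), omic_id)
  out <- structure(
    list(
      omic_id = omic_id,
      values = values,
      scale_state = scale_state
    ),
    class = "omic_table"
  )
  validate_omic_table(out)
}

prefix_features <- function(ids, omic_id) {
  ids <- as.character(ids)
  if (length(ids) == 0) return(character(0))
  pre <- paste0(omic_id, ":")
  ifelse(startsWith(ids, pre), ids, paste0(pre, ids))
}

validate_omic_table <- function(x) {
  v <- x$values
  if (anyDuplicated(rownames(v))) {
    stop("duplicate sample ids in omic '", x$omic_id, "': ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(v))) {
    stop("duplicate feature ids in omic '", x$omic_id, "': ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(v) == 0L || ncol(v) == 0L) {
    stop("empty table for omic '", x$omic_id, "'", call. = FALSE)
  }
  if (!x$scale_state %in% c("raw", "relative", "log", "standardized")) {
    stop("unknown scale_state '", x$scale_state, "'", call. = FALSE)
  }
  if (any(!is.finite(v))) {
    stop("non-finite values in omic '", x$omic_id, "'", call. = FALSE)
  }
  if (x$scale_state == "relative") {
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-8)) {
      stop("relative-abundance rows must sum to 1 (omic '", x$omic_id, "')",
           call. = FALSE)
    }
  }
  x
}

#' @export
print.omic_table <- function(x, ...) {
  cat(sprintf("<omic_table '%s'> %d samples x %d features (%s scale)\n",
              x$omic_id, nrow(x$values), ncol(x$values), x$scale_state))
  invisible(x)
}

#' @export
dim.omic_table <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)

#' @importFrom tibble as_tibble
#' @export
#' @method as_tibble omic_table
as_tibble.omic_table <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "sample_id")
}

#' Read a feature table from tab-separated text
#'
#' Expects a header row of feature ids and a first column of sample ids
#' (samples in rows). Feature ids are prefixed with `omic_id` on read.
#' Negative values in abundance omics are unusual and trigger a warning but
#' are preserved.
#'
#' @param path path to a TSV file.
#' @param omic_id short omic tag to attach (e.g. `"T"`).
#' @return An [omic_table()] with `scale_state = "raw"`.
#' @export
read_feature_table <- function(path, omic_id) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table '", path, "' needs a sample column and at least one feature", call. = FALSE)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  non_num <- !vapply(body, is.numeric, logical(1))
  if (any(non_num)) {
    stop("non-numeric feature column(s) in '", path, "': ",
         paste(names(body)[non_num], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (any(m < 0) && omic_id %in% c("T", "P")) {
    warning("negative values in omic '", omic_id, "'; abundances are expected non-negative",
            call. = FALSE)
  }
  omic_table(m, omic_id, scale_state = "raw")
}

#' Write a feature table as tab-separated text
#'
#' Inverse of [read_feature_table()]: values round-trip bit-exactly via
#' full-precision formatting.
#'
#' @param table an [omic_table()].
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  # %.17g round-trips doubles exactly
  chr <- apply(table$values, 2, function(col) sprintf("%.17g", col))
  df <- data.frame(sample_id = sample_ids(table), chr, check.names = FALSE)
  names(df) <- c("sample_id", feature_ids(table))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binary phenotype labels from a metadata table
#'
#' @param path TSV with a sample-id column and a label column.
#' @param label_column name of the label column.
#' @param case_value value of `label_column` coding a case; every other
#'   non-missing value is a control.
#' @param sample_column name of the sample-id column (default: first column).
#' @return A named integer vector of 0/1 labels (1 = case), named by sample
#'   id. Samples with missing labels are dropped with a message.
#' @export
read_metadata <- function(path, label_column, case_value, sample_column = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_column <- sample_column %||% names(df)[1]
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in '", path, "'", call. = FALSE)
  }
  ids <- as.character(df[[sample_column]])
  lab <- df[[label_column]]
  keep <- !is.na(lab) & !is.na(ids)
  if (any(!keep)) {
    message(sum(!keep), " sample(s) dropped for missing label or id")
  }
  labels <- as.integer(lab[keep] == case_value)
  names(labels) <- ids[keep]
  check_two_classes(labels)
  labels
}

check_two_classes <- function(labels) {
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab < 2L)) {
    stop("need at least 2 samples per class; got ",
         tab[["0"]], " control(s) and ", tab[["1"]], " case(s)", call. = FALSE)
  }
  invisible(labels)
}
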