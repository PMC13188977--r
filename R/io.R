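#' Read a feature table from a delimited text file
#'
#' Expects a header row of feature ids and a first column of sample ids
#' (samples as rows). Files ending in `.csv` are comma-separated, anything
#' else tab-separated. With `orientation = "features"` the file holds
#' features as rows and is transposed after reading.
#'
#' @param path file path.
#' @param orientation `"samples"` (rows are samples, default) or
#'   `"features"` (rows are features).
#' @return numeric matrix, samples as rows, with sample/feature ids as
#'   dimnames.
#' @export
read_feature_table <- function(path, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- raw[, -1L, drop = FALSE]
  if (anyDuplicated(colnames(mat)))
    stop("duplicate column ids in ", path, ": ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      lab <- if (length(bad)) bad[1L] else which(is.na(col))[1L]
      stop("non-numeric value in ", path, " at row '", ids[lab],
           "', column '", colnames(mat)[j], "'")
    }
    if (anyNA(col))
      stop("missing value in ", path, " at row '", ids[which(is.na(col))[1L]],
           "', column '", colnames(mat)[j], "'")
  }
  m <- as.matrix(mat)
  rownames(m) <- ids
  if (orientation == "features") m <- t(m)
  as_feature_matrix(m)
}

#' Write a feature table to a delimited text file
#'
#' Inverse of [read_feature_table()] (samples as rows); values are written
#' with 15 significant digits so read-write round trips are lossless at
#' double precision.
#'
#' @param x numeric matrix, samples as rows.
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @export
write_feature_table <- function(x, path) {
  x <- as_feature_matrix(x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(x),
                   signif_frame(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

signif_frame <- function(x) {
  out <- as.data.frame(x, check.names = FALSE)
  out[] <- lapply(out, function(col)
    if (is.double(col)) formatC(col, digits = 15, format = "g") else col)
  out
}

#' Read a pairwise dissimilarity matrix
#'
#' Two dialects are supported:
#'
#' * `"square"`: a delimited file with a header of sample ids and a first
#'   column of sample ids matching the header, holding the full symmetric
#'   matrix.
#' * `"triangular"`: a lower-triangular whitespace-separated dialect — first
#'   line the number of samples \eqn{n}, then one line per sample: its id
#'   followed by its distances to the preceding samples.
#'
#' `"auto"` detects the triangular dialect by a single-integer first line.
#' Asymmetries up to `1e-8` are symmetrized with a warning; anything larger,
#' negative entries, or diagonal entries beyond `1e-12` are errors.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"square"` or `"triangular"`.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
read_distance_matrix <- function(path, dialect = c("auto", "square", "triangular")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    first <- trimws(readLines(path, n = 1L))
    dialect <- if (grepl("^[0-9]+$", first)) "triangular" else "square"
  }
  if (dialect == "square") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                             check.names = FALSE, comment.char = "")
    m <- as.matrix(raw)
    if (nrow(m) != ncol(m))
      stop("distance matrix in ", path, " is not square (",
           nrow(m), " x ", ncol(m), ")")
    if (!identical(rownames(m), colnames(m)))
      stop("row and column ids disagree in ", path)
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    n <- as.integer(trimws(lines[1L]))
    if (is.na(n) || length(lines) != n + 1L)
      stop("malformed triangular distance file ", path,
           ": expected a count line plus ", n, " rows")
    ids <- character(n)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
      if (length(parts) != i)
        stop("row ", i, " of ", path, " has ", length(parts) - 1L,
             " distances; expected ", i - 1L)
      ids[i] <- parts[1L]
      if (i > 1L) {
        vals <- suppressWarnings(as.numeric(parts[-1L]))
        if (anyNA(vals)) stop("non-numeric distance in row ", i, " of ", path)
        m[i, seq_len(i - 1L)] <- vals
        m[seq_len(i - 1L), i] <- vals
      }
    }
    if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
    dimnames(m) <- list(ids, ids)
  }
  as_distance_matrix(m)
}

#' Write a pairwise dissimilarity matrix
#'
#' @param x symmetric dissimilarity matrix.
#' @param path output path.
#' @param dialect `"square"` (TSV with ids) or `"triangular"` (count line
#'   then one row per sample: id plus distances to preceding samples).
#' @export
write_distance_matrix <- function(x, path, dialect = c("square", "triangular")) {
  dialect <- match.arg(dialect)
  x <- as_distance_matrix(x)
  if (dialect == "square") {
    df <- data.frame(sample_id = rownames(x), signif_frame(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(x)), con)
    for (i in seq_len(nrow(x))) {
      vals <- if (i > 1L)
        formatC(x[i, seq_len(i - 1L)], digits = 15, format = "g") else character(0)
      writeLines(paste(c(rownames(x)[i], vals), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a metadata table keyed by sample id
#'
#' First column must hold unique sample ids; remaining columns are grouping
#' variables or covariates.
#'
#' @param path file path (TSV, or CSV by extension).
#' @return data frame with sample ids as row names.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  out <- raw[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Serialize a test result to JSON
#'
#' Every field of the result object (per-pair statistics, Fisher statistic,
#' final p-value, settings) plus the package version, as a JSON string.
#' P-values are serialized at full precision.
#'
#' @param x a `"dth"` or `"dth_comparator"` object.
#' @return a JSON string (class `json`).
#' @export
as_dth_json <- function(x) {
  stopifnot(inherits(x, "dth") || inherits(x, "dth_comparator"))
  lst <- unclass(x)
  lst$call <- NULL
  lst$within <- NULL
  lst$distances <- NULL
  names(lst)[names(lst) == "p.value"] <- "p_value"
  lst$package_version <- as.character(utils::packageVersion("DTH"))
  jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "columns")
}

#' Write a test result as JSON plus a per-pair TSV
#'
#' Writes `<prefix>.json` (all result fields, see [as_dth_json()]) and, for
#' DTH results, `<prefix>_pairs.tsv` with one row per group pair.
#'
#' @param x a `"dth"` or `"dth_comparator"` object.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_dth_result <- function(x, prefix) {
  json_path <- paste0(prefix, ".json")
  writeLines(as_dth_json(x), json_path)
  paths <- json_path
  if (inherits(x, "dth")) {
    tsv_path <- paste0(prefix, "_pairs.tsv")
    utils::write.table(x$per_pair, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, tsv_path)
  }
  invisible(paths)
}
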