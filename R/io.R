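#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV file whose first column holds feature identifiers and
#' whose header row holds sample identifiers. The delimiter is auto-detected
#' from the header line. Missing-value tokens `NA`, `NaN` and the empty string
#' are accepted: feature rows with more than 20% missing entries are dropped
#' (with a message), remaining missing values are imputed by the feature's
#' observed mean so downstream algebra stays total.
#'
#' @param path Path to the delimited file.
#' @param feature_kind `"gene"` or `"mirna"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, feature_kind = c("gene", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (!nzchar(header)) stop_validation("malformed header in %s: empty first line", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "", "NaN"), colClasses = list(character = 1))
  if (ncol(dt) < 2) stop_validation("malformed header in %s: need id column plus samples", path)
  ids <- trimws(dt[[1]])
  if (anyDuplicated(ids)) {
    stop_validation("duplicate feature ids in %s: %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- dt[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop_validation("non-numeric expression values in column(s): %s",
                    paste(names(vals)[bad], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  frac_missing <- rowMeans(is.na(m))
  drop <- frac_missing > 0.2
  if (any(drop)) {
    message(sprintf("dropping %d feature(s) with > 20%% missing values", sum(drop)))
    m <- m[!drop, , drop = FALSE]
  }
  if (anyNA(m)) {
    for (i in which(rowSums(is.na(m)) > 0)) {
      row <- m[i, ]
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      m[i, ] <- row
    }
  }
  expression_matrix(m, feature_kind)
}

#' Write an expression matrix as TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  dt <- data.table::data.table(feature_id = em$feature_ids)
  dt <- cbind(dt, data.table::as.data.table(em$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `name TAB description TAB member TAB member ...` (MSigDB
#' dialect). Within-line duplicate members are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (class `gene_set_collection`)
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_validation("GMT format error at line %d: fewer than 3 fields", i)
    }
    nm <- trimws(fields[1])
    if (nm %in% names(sets)) {
      stop_validation("GMT format error at line %d: duplicate set name '%s'", i, nm)
    }
    members <- unique(trimws(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop_validation("GMT format error at line %d: empty member set", i)
    }
    sets[[nm]] <- members
    descriptions[nm] <- fields[2]
  }
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  nm <- names(sets)
  lines <- vapply(nm, function(s) {
    d <- if (!is.null(descriptions) && s %in% names(descriptions)) descriptions[[s]] else "na"
    paste(c(s, d, sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.subtype_levels <- c("mesenchymal", "differentiated", "proliferative", "immunoreactive")

#' Read a sample annotation table
#'
#' TSV/CSV with a mandatory `sample_id` column and optional `subtype`,
#' `time` (months), `event` (0/1), `age`, `stage`, `grade` columns. Subtype
#' labels are case-folded and must belong to the four recognized subtypes.
#'
#' @param path Path to the delimited file.
#' @return A validated `data.frame` (class `sample_table`).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  validate_sample_table(df)
}

#' Validate (and normalize) a sample annotation data.frame
#'
#' @param df A data.frame with at least a `sample_id` column.
#' @return The normalized `data.frame` with class `sample_table`.
#' @export
validate_sample_table <- function(df) {
  if (!"sample_id" %in% names(df)) stop_validation("sample table needs a 'sample_id' column")
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id)) {
    stop_validation("duplicate sample ids: %s",
                    paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if ("subtype" %in% names(df)) {
    st <- tolower(trimws(as.character(df$subtype)))
    bad <- !is.na(st) & !(st %in% .subtype_levels)
    if (any(bad)) {
      stop_validation("unknown subtype label(s) %s; allowed: %s",
                      paste(unique(st[bad]), collapse = ", "),
                      paste(.subtype_levels, collapse = ", "))
    }
    df$subtype <- st
  }
  if ("time" %in% names(df)) {
    if (any(!is.na(df$time) & df$time < 0)) stop_validation("survival time must be >= 0")
  }
  if ("event" %in% names(df)) {
    ev <- df$event
    if (any(!is.na(ev) & !(ev %in% c(0, 1)))) stop_validation("event must be 0 or 1")
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sequence-based target prediction list
#'
#' Two-column delimited text (header `regulator`, `target`) listing predicted
#' miRNA-target pairs, e.g. a miRDB-like or TargetScan-like list. Duplicate
#' pairs are collapsed.
#'
#' @param path Path to the file.
#' @param source_name Label for the prediction source.
#' @return A named list mapping regulator id to a character vector of
#'   predicted target gene ids (class `target_predictions`).
#' @export
read_target_predictions <- function(path, source_name) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  if (ncol(df) < 2) stop_validation("prediction table needs regulator and target columns")
  reg <- trimws(as.character(df[[1]]))
  tgt <- trimws(as.character(df[[2]]))
  keep <- !duplicated(paste0(reg, "\r", tgt))
  preds <- split(tgt[keep], reg[keep])
  preds <- lapply(preds, unique)
  structure(preds, source_name = source_name, class = "target_predictions")
}

#' Write a prediction list as two-column TSV
#' @param preds A `target_predictions` object or named list.
#' @param path Output path.
#' @export
write_target_predictions <- function(preds, path) {
  df <- data.frame(
    regulator = rep(names(preds), lengths(preds)),
    target = unlist(preds, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$regulator, df$target), ]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write a results table deterministically
#'
#' Writes a data.frame as TSV with rows sorted by the first (primary key)
#' column, so repeated runs emit byte-identical files.
#'
#' @param obj A data.frame.
#' @param path Output path.
#' @export
write_results_table <- function(obj, path) {
  stopifnot(is.data.frame(obj))
  if (ncol(obj) >= 1 && nrow(obj) > 1) {
    obj <- obj[order(obj[[1]]), , drop = FALSE]
  }
  data.table::fwrite(obj, path, sep = "\t")
  invisible(path)
}
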