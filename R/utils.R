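# Internal helpers shared across modules.

# Read a TSV (optionally gzip-compressed, detected by extension) as
# character columns; no quoting, UTF-8, header row required.
.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# Rename foreign headers to canonical ones. `map` is a named character
# vector / list: names are the headers found in the file, values the
# canonical names.
.apply_column_map <- function(df, columnMap) {
  if (is.null(columnMap)) return(df)
  columnMap <- unlist(columnMap)
  missing <- setdiff(names(columnMap), names(df))
  if (length(missing))
    stop("column_map refers to absent columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(names(columnMap), names(df))
  names(df)[idx] <- unname(columnMap)
  df
}

# Parse a character column to numeric, failing loudly on values that are
# neither blank nor parseable.
.parse_numeric <- function(x, what) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop("unparseable ", what, " value(s): ",
         paste(utils::head(unique(x[bad]), 3), collapse = ", "), call. = FALSE)
  out
}

.parse_logical <- function(x, what) {
  x0 <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("true", "t", "1", "yes")] <- TRUE
  out[x0 %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !(x0 %in% c("true", "t", "1", "yes", "false", "f", "0", "no", "", "na"))
  if (any(bad))
    stop("unparseable ", what, " value(s): ",
         paste(utils::head(unique(x[bad]), 3), collapse = ", "), call. = FALSE)
  out
}

# Attach a load/filter report to a data.frame result without changing its
# class; retrieved with loadReport().
.set_report <- function(x, report) {
  attr(x, "disnetReport") <- report
  x
}

#' Retrieve the load or filter report attached to a table
#'
#' Reader and filter functions attach a small report (rows dropped, terms
#' without records, per-criterion removal counts, ...) to their result.
#'
#' @param x a value returned by one of the reading or filtering functions.
#' @return a named list, or \code{NULL} when no report is attached.
#' @export
loadReport <- function(x) attr(x, "disnetReport")
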