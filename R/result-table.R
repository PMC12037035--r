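#' Write a result table to CSV
#'
#' Plain CSV with a header row and deterministic column order. Numeric
#' values use shortest round-trip representation so that
#' [read_table()] reproduces them to full double precision.
#'
#' @param table a data.frame with unique column names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) stop("column names must be unique")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  out <- table
  for (j in seq_along(out)) {
    # shortest exact decimal representation so reads reproduce doubles
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  data.table::fwrite(out, path, row.names = FALSE, quote = "auto")
  invisible(path)
}

#' Read a result table from CSV
#'
#' @param path CSV file written by [write_table()].
#' @return a data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path))
}

#' Read a flat TOML configuration file
#'
#' Supports the subset used for batch runs: `key = value` pairs with
#' quoted strings, numbers, booleans, and flat `[section]` headers (keys
#' become `section.key`). Comments start with `#`.
#'
#' @param path TOML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- ""
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    key <- if (nzchar(section)) paste0(section, ".", kv[2]) else kv[2]
    val <- trimws(kv[3])
    out[[key]] <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) val else num
    }
  }
  out
}

# One structured log line per operation: name, parameters, input checksums.
.log_op <- function(op, params = list(), quiet = FALSE) {
  if (quiet) return(invisible(NULL))
  fmt <- vapply(params, function(p) {
    if (is.numeric(p) && length(p) > 8) {
      sprintf("chk:%d:%.6g", length(p), sum(p))
    } else paste(format(p, digits = 10), collapse = ",")
  }, character(1))
  message("[memquant] op=", op,
          if (length(fmt)) paste0(" ", paste(names(fmt), fmt, sep = "=",
                                             collapse = " ")) else "")
  invisible(NULL)
}
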