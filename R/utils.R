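#' Read a tab-separated table in the package dialect
#'
#' UTF-8, tab-separated, lines starting with "#" are comments, "." denotes a
#' missing value. The conventional "#OTU ID" header line used by amplicon
#' tables is honoured by [read_count_table()], which strips the leading "#".
#'
#' @param path file path
#' @param header logical, whether the first non-comment line is a header
#' @return data.frame with character columns left unconverted
#' @keywords internal
read_tsv_dialect <- function(path, header = TRUE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines) & nzchar(lines)
  # the "#OTU ID" convention: a commented header directly above data
  otu_hdr <- grep("^#OTU ID\t", lines)
  if (length(otu_hdr) == 1L && header) {
    lines[otu_hdr] <- sub("^#", "", lines[otu_hdr])
    keep[otu_hdr] <- TRUE
  }
  txt <- lines[keep]
  if (length(txt) == 0L) stop("empty table: ", path, call. = FALSE)
  utils::read.table(
    text = txt, sep = "\t", header = header, na.strings = ".",
    check.names = FALSE, stringsAsFactors = FALSE, quote = "",
    comment.char = ""
  )
}

#' Write a table in the package dialect
#'
#' Deterministic column order (as given), tab-separated, "." for NA.
#'
#' @param x data.frame
#' @param path output path
#' @keywords internal
write_tsv_dialect <- function(x, path) {
  utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, na = ".", fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Derive a stage seed from a master seed and a stage name
#'
#' Hashes the stage name into an offset so that adding pipeline stages does
#' not shift the random streams of existing ones. The result is always a
#' valid 32-bit integer seed.
#'
#' @param master_seed integer master seed
#' @param stage character stage name
#' @return integer seed
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147481563
  as.integer((abs(master_seed) + h) %% 2147483647L)
}

# stop() with a classed condition so callers/tests can discriminate errors
mf_stop <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(class, "marshfun_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
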