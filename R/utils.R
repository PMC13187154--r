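`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise species labels for cross-table matching
#'
#' Species names arriving from trees, trait tables and count tables rarely
#' agree on case or on space-versus-underscore conventions.  This folds a
#' label to lower case, collapses runs of spaces/underscores to a single
#' underscore and trims leading/trailing separators, so that e.g.
#' `"Saturnispora dispora"` and `"saturnispora_dispora"` compare equal.
#'
#' @param x character vector of species labels.
#' @return character vector of normalised labels.
#' @export
#' @examples
#' normalize_species(c("Saturnispora dispora", "SATURNISPORA__DISPORA"))
normalize_species <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ _]+", "_", x)
  gsub("^_|_$", "", x)
}

# Guess the field separator of a delimited text file (tab or comma).
sniff_delim <- function(file) {
  line <- readLines(file, n = 1L)
  if (length(line) == 0L) return("\t")
  if (grepl("\t", line)) "\t" else ","
}

read_delim_auto <- function(file, header = TRUE) {
  utils::read.table(file, header = header, sep = sniff_delim(file),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"")
}

# Derive an integer sub-seed (< 2^31) for a named generator stream from a
# root seed, so that adding a generator never perturbs the draws of another.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.double(seed)) + 1009 * h) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
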