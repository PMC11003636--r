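#' @importFrom data.table data.table setDT setorder setorderv fread fwrite
#'   rbindlist setnames copy setkey setkeyv as.data.table :=
#' @importFrom stats runif setNames
#' @importFrom utils head tail
#' @useDynLib prokbrowse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.pkg_env <- new.env(parent = emptyenv())

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids plus X (unknown residue), in the fixed order
#' the alignment kernel and k-mer encoder use.
#' @return Character vector of 21 single-letter residue codes.
#' @export
aa_alphabet <- function() strsplit("ARNDCQEGHILKMFPSTWYVX", "")[[1]]

# Deterministic TSV writers/readers: all interchange files go through these so
# reruns with the same seed produce byte-identical output.
write_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- paste0(path, ".tmp")
  fwrite(x, tmp, sep = "\t", quote = FALSE, na = "NA", eol = "\n",
         logical01 = FALSE, scipen = 0)
  file.rename(tmp, path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  fread(path, sep = "\t", header = TRUE, na.strings = "NA",
        data.table = TRUE, ...)
}

write_json_file <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

# stable content hash for protein ids
hash_sequences <- function(seqs) .fnv1a64(as.character(seqs))

stop_if_not_scalar_flag <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.logical(x))
    stop("field '", name, "' must be a single non-missing logical", call. = FALSE)
  invisible(x)
}
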