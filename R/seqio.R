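#' @useDynLib seedalign, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

# 2-bit base coding. A=0, C=1, G=2, T=3: with this mapping the complement of
# a code is `3 - code` (bitwise XOR with 3), so reverse complementation of a
# coded read needs no lookup.
.CODE_TABLE <- local({
  tbl <- rep(NA_integer_, 127L)
  tbl[utf8ToInt("A")] <- 0L
  tbl[utf8ToInt("C")] <- 1L
  tbl[utf8ToInt("G")] <- 2L
  tbl[utf8ToInt("T")] <- 3L
  tbl
})
.BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as 2-bit codes
#'
#' Maps `A -> 0, C -> 1, G -> 2, T -> 3`, one integer code per base.  The
#' input must already be N-free (see [resolve_ns()]); any other character is
#' an error that reports the offending position.
#'
#' @param bases A single string over `A`/`C`/`G`/`T` (uppercase).
#' @return An integer vector of codes in `0:3` (length 0 for `""`).
#' @seealso [decode_bases()], [reverse_complement()]
#' @examples
#' encode_bases("ACGT")
#' decode_bases(encode_bases("GATTACA"))
#' @export
encode_bases <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  if (nchar(bases) == 0L) return(integer(0))
  ints <- utf8ToInt(bases)
  codes <- .CODE_TABLE[ints]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("non-ACGT character '%s' at position %d",
                 substr(bases, bad, bad), bad))
  }
  codes
}

#' Decode 2-bit codes back to a DNA string
#' @param codes Integer codes in `0:3`.
#' @return A single string.
#' @export
decode_bases <- function(codes) {
  if (length(codes) == 0L) return("")
  paste(.BASES[codes + 1L], collapse = "")
}

#' Reverse complement of a coded sequence
#'
#' Position `i` of the output is the complement of position
#' `length - i + 1` of the input; the operation is an involution.
#'
#' @param codes Integer codes in `0:3`.
#' @return Integer codes of the reverse complement.
#' @export
reverse_complement <- function(codes) {
  if (length(codes) == 0L) return(integer(0))
  rev(3L - codes)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Replace N (ambiguous) bases by random ACGT bases
#'
#' Each `N` is replaced by a base drawn uniformly from `A`/`C`/`G`/`T` using
#' a deterministic stream derived from `rng_seed`; all other positions are
#' unchanged.  Lowercase input is uppercased first.  This mirrors the common
#' preprocessing step for references and real read sets that contain
#' ambiguity codes the 2-bit coding cannot represent.
#'
#' @param bases A DNA string, possibly containing `N`.
#' @param rng_seed Integer seed; the same seed reproduces the same output.
#' @return The resolved string over `ACGT`.
#' @export
resolve_ns <- function(bases, rng_seed = 1L) {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  ns <- which(chars == "N")
  if (length(ns) == 0L) return(bases)
  repl <- .with_seed(rng_seed, sample(.BASES, length(ns), replace = TRUE))
  chars[ns] <- repl
  paste(chars, collapse = "")
}

#' Encode a read (forward and reverse complement)
#'
#' Produces the unit the aligner works on: the read identifier plus 2-bit
#' coded forward and reverse-complement base arrays.  Reads longer than
#' `max_len` are rejected unless `trim = TRUE`, in which case they are
#' trimmed at the 3' end (as is done to fit 101 bp instrument reads into a
#' 100 bp engine).
#'
#' @param id Read identifier.
#' @param bases Read bases over `ACGT`.
#' @param max_len Maximum supported read length (default 100).
#' @param trim Trim over-long reads at the 3' end instead of rejecting.
#' @return An object of class `encoded_read`: list with `id`, `length`,
#'   `fwd`, `rc`.
#' @export
encode_read <- function(id, bases, max_len = 100L, trim = FALSE) {
  if (nchar(bases) > max_len) {
    if (!trim)
      stop(sprintf("read '%s' is %d bp, longer than the maximum %d",
                   id, nchar(bases), max_len))
    bases <- substr(bases, 1L, max_len)
  }
  fwd <- encode_bases(bases)
  structure(list(id = id, length = length(fwd), fwd = fwd,
                 rc = reverse_complement(fwd)),
            class = "encoded_read")
}

#' @export
print.encoded_read <- function(x, ...) {
  cat(sprintf("<encoded_read> %s (%d bp)\n", x$id, x$length))
  invisible(x)
}

#' Split encoded reads into fixed-capacity chunks
#'
#' The pipelines stage reads in chunks (default 1,000 reads per iteration);
#' chunks preserve input order and all chunks are full except possibly the
#' last.
#'
#' @param reads List of [encode_read()] objects.
#' @param capacity Chunk capacity (>= 1).
#' @return A list of chunks, each a list of encoded reads.
#' @export
chunk_reads <- function(reads, capacity = 1000L) {
  stopifnot(capacity >= 1L)
  n <- length(reads)
  if (n == 0L) return(list())
  unname(split(reads, ceiling(seq_len(n) / capacity)))
}

#' Storage cost of a coded read chunk, in bits
#'
#' Each base costs 2 bits and each read is stored twice (forward plus
#' reverse complement), so the cost is `n_reads * read_len * 2 * 2` bits:
#' 1,000 reads of 100 bp occupy 400,000 bits.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length in bases.
#' @return Total storage in bits.
#' @export
chunk_storage_bits <- function(n_reads, read_len) {
  stopifnot(n_reads >= 0, read_len >= 0)
  as.numeric(n_reads) * as.numeric(read_len) * 2 * 2
}

#' Read a (possibly multi-record, line-wrapped) FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (first word of the header) and
#'   `bases` (uppercased sequence).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, bases = toupper(as.character(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a 4-line-record FASTQ file
#'
#' A strict reader for uncompressed FASTQ: every record must consist of a
#' `@`-header, sequence, `+`-separator and a quality string of matching
#' length.  Malformed records are reported with their line number.  Base
#' qualities are parsed but not used by the aligner (the scoring model
#' ignores them).
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `id` and `bases`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4", n))
  if (n == 0L)
    return(data.frame(id = character(0), bases = character(0),
                      stringsAsFactors = FALSE))
  hd <- seq(1L, n, by = 4L)
  sq <- hd + 1L
  pl <- hd + 2L
  qu <- hd + 3L
  bad <- which(!startsWith(lines[hd], "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ header at line %d", hd[bad[1L]]))
  bad <- which(!startsWith(lines[pl], "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ separator at line %d", pl[bad[1L]]))
  bad <- which(nchar(lines[qu]) != nchar(lines[sq]))
  if (length(bad))
    stop(sprintf("quality length mismatch at line %d", qu[bad[1L]]))
  data.frame(id = sub("\\s.*$", "", substring(lines[hd], 2L)),
             bases = toupper(lines[sq]), stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `id` and `bases` columns.
#' @param path Output path.
#' @param qual Constant quality character used for every base.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- as.vector(rbind(paste0("@", reads$id),
                         reads$bases,
                         "+",
                         vapply(nchar(reads$bases),
                                function(n) strrep(qual, n), "")))
  writeLines(out, path)
  invisible(path)
}

#' Write a FASTA file
#' @param id Sequence identifier.
#' @param bases Sequence string.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(id, bases, path, width = 70L) {
  n <- nchar(bases)
  starts <- seq(1L, max(n, 1L), by = width)
  writeLines(c(paste0(">", id),
               if (n > 0) substring(bases, starts, pmin(starts + width - 1L, n))),
             path)
  invisible(path)
}
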