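# Seeding: turn each read into candidate (read, strand, window) pairs ----

#' Seeding configuration
#'
#' @param stride Bases between successive seed offsets within a read
#'   (default 1: every offset).  The final offset `length - seed_len` is
#'   always included so the read's 3' end is always covered.
#' @param max_candidates_per_read Optional cap on candidates per read and
#'   strand (`Inf` = unlimited); when capped, candidates with the most
#'   supporting seed offsets are kept.
#' @return An object of class `seeding_config`.
#' @export
seeding_config <- function(stride = 1L, max_candidates_per_read = Inf) {
  stopifnot(stride >= 1L)
  structure(list(stride = as.integer(stride),
                 max_candidates_per_read = max_candidates_per_read),
            class = "seeding_config")
}

# Seed offsets for a read of length `len`: 0, stride, 2*stride, ... plus
# always the final offset len - k.
.seed_offsets <- function(len, k, stride) {
  if (len < k) return(integer(0))
  last <- len - k
  unique(c(seq(0L, last, by = stride), last))
}

#' Extract seed k-mers from a read
#'
#' @param read An [encode_read()] object.
#' @param strand `"forward"` or `"reverse"`; the reverse strand uses the
#'   read's reverse-complement codes.
#' @param index_cfg An [index_config()] (for the seed length).
#' @param seed_cfg A [seeding_config()].
#' @return A data.frame with columns `offset` (0-based offset within the
#'   strand's sequence) and `kmer`.  Reads shorter than the seed length
#'   yield zero rows with a warning.
#' @export
extract_seeds <- function(read, strand = c("forward", "reverse"),
                          index_cfg = index_config(),
                          seed_cfg = seeding_config()) {
  strand <- match.arg(strand)
  k <- index_cfg$seed_len
  if (read$length < k) {
    warning(sprintf("read '%s' (%d bp) shorter than seed length %d: no seeds",
                    read$id, read$length, k))
    return(data.frame(offset = integer(0), kmer = character(0)))
  }
  codes <- if (strand == "forward") read$fwd else read$rc
  offs <- .seed_offsets(read$length, k, seed_cfg$stride)
  data.frame(offset = offs,
             kmer = vapply(offs, function(o)
               decode_bases(codes[(o + 1L):(o + k)]), ""),
             stringsAsFactors = FALSE)
}

#' Generate candidate (read, strand, window) pairs for one read
#'
#' Each seed hit at genome position `p` and read offset `q` votes for the
#' diagonal `window_start = p - q`; hits on the same (strand, diagonal)
#' are merged into one candidate (duplicate seeds would only repeat the
#' same extension work).  The reverse strand is handled by querying the
#' read's reverse-complement codes against the forward-only index, so
#' reverse candidates carry forward-reference coordinates.
#' `window_start` may fall outside the genome near its boundaries; the
#' window fetch clamps it rather than discarding the candidate.
#'
#' @param index A [build_index()] result.
#' @param read An [encode_read()] object.
#' @param seed_cfg A [seeding_config()].
#' @return A data.frame with columns `read_id`, `strand`, `window_start`,
#'   `n_support` and a list column `supporting_offsets`.
#' @export
generate_candidates <- function(index, read, seed_cfg = seeding_config()) {
  cfg <- index$config
  k <- cfg$seed_len
  out <- list()
  for (strand in c("forward", "reverse")) {
    if (read$length < k) next
    codes <- if (strand == "forward") read$fwd else read$rc
    offs <- .seed_offsets(read$length, k, seed_cfg$stride)
    packed <- .pack_all(codes, k)[offs + 1L]
    slots <- .slots_of(packed, index$h3, cfg)
    hits <- .lookup_slots(index, slots)
    if (nrow(hits) == 0L) next
    hits[, offset := offs[query]]
    hits[, diag := pos - offset]
    agg <- hits[, list(n_support = .N,
                       supporting_offsets = list(sort(offset))),
                by = diag]
    data.table::setorder(agg, diag)
    if (is.finite(seed_cfg$max_candidates_per_read) &&
        nrow(agg) > seed_cfg$max_candidates_per_read) {
      keep <- order(-agg$n_support, agg$diag)[
        seq_len(seed_cfg$max_candidates_per_read)]
      agg <- agg[sort(keep)]
    }
    out[[strand]] <- data.frame(read_id = read$id, strand = strand,
                                window_start = agg$diag,
                                n_support = agg$n_support,
                                stringsAsFactors = FALSE)
    out[[strand]]$supporting_offsets <- agg$supporting_offsets
  }
  if (!length(out))
    return(data.frame(read_id = character(0), strand = character(0),
                      window_start = integer(0), n_support = integer(0)))
  do.call(rbind, unname(out))
}

#' Fetch the reference windows for a candidate
#'
#' Returns the pieces the dual-engine extension needs: the normal window
#' `genome[window_start .. window_start + read_len)`, the window shifted
#' one base to the left, and the extra base to the right of each (used to
#' correct the lower-diagonal exit).  Positions outside the genome are
#' clamped away, never fabricated: a clipped window is simply shorter and
#' the extension engine charges gap penalties for the missing coverage.
#'
#' @param genome_codes Integer code vector of the genome.
#' @param window_start 0-based candidate window start (may be negative).
#' @param read_len Read length.
#' @return A list with `normal`, `shifted` (code vectors), `normal_extra`,
#'   `shifted_extra` (length-1 code or `NULL` when absent), and the
#'   clamped 0-based starts `normal_start`, `shifted_start`.
#' @export
fetch_window <- function(genome_codes, window_start, read_len) {
  L <- length(genome_codes)
  ns <- max(window_start, 0L)
  ne <- min(window_start + read_len, L)  # exclusive
  normal <- if (ne > ns) genome_codes[(ns + 1L):ne] else integer(0)
  normal_extra <- if (window_start + read_len < L)
    genome_codes[window_start + read_len + 1L] else NULL
  ss <- max(window_start - 1L, 0L)
  se <- min(window_start - 1L + read_len, L)
  shifted <- if (se > ss) genome_codes[(ss + 1L):se] else integer(0)
  shifted_extra <- if (window_start - 1L + read_len < L && window_start - 1L + read_len >= 0L)
    genome_codes[window_start + read_len] else NULL
  list(normal = normal, shifted = shifted,
       normal_extra = normal_extra, shifted_extra = shifted_extra,
       normal_start = ns, shifted_start = ss)
}
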