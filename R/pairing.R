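# Paired-end pairing and Smith-Waterman mate rescue ----------------------

#' Paired-end parameters
#'
#' The insert model is the wgsim convention: the outer distance is
#' measured from the leftmost base of the left mate to the rightmost base
#' of the right mate, with mean `D` and standard deviation `sd`.  A pair
#' is proper when its observed outer distance lies within `D +/- k * sd`
#' and the mates are on opposite strands (FR orientation).  Rescue uses
#' unit Smith-Waterman scores so the identity cutoff stays interpretable
#' as a fraction of read bases matched.
#'
#' @param outer_distance Mean outer distance `D` (default 200).
#' @param std_dev Insert standard deviation (default 20).
#' @param window_sigmas Window multiplier `k` (default 3: ~99.7% of a
#'   normal insert distribution).
#' @param sw_match,sw_mismatch,sw_gap Smith-Waterman unit scores.
#' @param rescue_min_identity Minimum fraction of read bases matched for
#'   an accepted rescue (default 0.90).
#' @return An object of class `pair_params`.
#' @export
pair_params <- function(outer_distance = 200L, std_dev = 20L,
                        window_sigmas = 3L, sw_match = 1L, sw_mismatch = -1L,
                        sw_gap = -1L, rescue_min_identity = 0.90) {
  stopifnot(outer_distance > 0, std_dev >= 0, window_sigmas >= 1)
  structure(list(outer_distance = as.integer(outer_distance),
                 std_dev = as.integer(std_dev),
                 window_sigmas = as.integer(window_sigmas),
                 sw_match = as.integer(sw_match),
                 sw_mismatch = as.integer(sw_mismatch),
                 sw_gap = as.integer(sw_gap),
                 rescue_min_identity = rescue_min_identity),
            class = "pair_params")
}

# Observed outer distance of a (leftmost, rightmost) placement.
.outer_distance <- function(p_left, p_right, len_right) {
  p_right + len_right - p_left
}

#' Pair two per-end hit lists (both mates mapped)
#'
#' Forms all cross-products of the two ends' hits with opposite strands
#' and an observed outer distance within `D +/- k * sd`, ranked by
#' combined score and then by deviation from `D`.
#'
#' @param hits1,hits2 data.frames of single-end hits for mate 1 and 2
#'   (columns `strand`, `ref_start`, `score`) plus read lengths `len1`,
#'   `len2`.
#' @param len1,len2 Read lengths of the two mates.
#' @param params A [pair_params()].
#' @return A data.frame of candidate proper pairs, best first: `p1`,
#'   `p2`, `strand1`, `strand2`, `combined_score`, `insert`.
#' @export
pair_both_mapped <- function(hits1, hits2, len1, len2,
                             params = pair_params()) {
  empty <- data.frame(p1 = integer(0), p2 = integer(0),
                      strand1 = character(0), strand2 = character(0),
                      combined_score = numeric(0), insert = integer(0))
  if (nrow(hits1) == 0L || nrow(hits2) == 0L) return(empty)
  g <- expand.grid(i = seq_len(nrow(hits1)), j = seq_len(nrow(hits2)))
  s1 <- hits1$strand[g$i]; s2 <- hits2$strand[g$j]
  p1 <- hits1$ref_start[g$i]; p2 <- hits2$ref_start[g$j]
  opp <- s1 != s2
  # leftmost mate must be the forward one (FR orientation)
  left_is_1 <- s1 == "forward"
  ins <- ifelse(left_is_1, .outer_distance(p1, p2, len2),
                .outer_distance(p2, p1, len1))
  ok <- opp & ifelse(left_is_1, p1 <= p2, p2 <= p1) &
    abs(ins - params$outer_distance) <=
      params$window_sigmas * params$std_dev
  if (!any(ok)) return(empty)
  out <- data.frame(p1 = p1[ok], p2 = p2[ok],
                    strand1 = s1[ok], strand2 = s2[ok],
                    combined_score = hits1$score[g$i[ok]] + hits2$score[g$j[ok]],
                    insert = as.integer(ins[ok]))
  out[order(out$combined_score,
            abs(out$insert - params$outer_distance), out$p1), , drop = FALSE]
}

#' Smith-Waterman rescue of an unmapped mate
#'
#' Searches the genome window implied by the mapped mate's position and
#' the insert model (length about `2 k sd` plus the read length) with a
#' full-matrix local Smith-Waterman of the unmapped read, in both
#' orientations.  A hit is accepted only when the optimal local path
#' matches at least `rescue_min_identity` of the read's bases.
#'
#' @param read An [encode_read()] object (the unmapped mate).
#' @param genome_codes Integer code vector of the genome.
#' @param anchor_pos 0-based position of the mapped mate.
#' @param anchor_strand Strand of the mapped mate (`"forward"` or
#'   `"reverse"`).
#' @param anchor_len Length of the mapped mate.
#' @param params A [pair_params()].
#' @return A one-row data.frame (`strand`, `ref_start`, `score`,
#'   `sw_score`, `identity`) or `NULL` when no rescue passes the cutoff.
#' @export
sw_rescue <- function(read, genome_codes, anchor_pos, anchor_strand,
                      anchor_len, params = pair_params()) {
  L <- length(genome_codes)
  D <- params$outer_distance
  slack <- params$window_sigmas * params$std_dev
  # expected span of the missing mate under the FR model
  if (anchor_strand == "forward") {
    lo <- anchor_pos + D - read$length - slack
    hi <- anchor_pos + D + slack
  } else {
    lo <- anchor_pos + anchor_len - D - slack
    hi <- anchor_pos + anchor_len - D + read$length + slack
  }
  lo <- max(lo, 0L)
  hi <- min(hi, L)
  if (hi - lo < read$length) {
    lo <- max(min(lo, L - read$length), 0L)
    hi <- min(max(hi, lo + read$length), L)
  }
  if (hi <= lo) return(NULL)
  window <- genome_codes[(lo + 1L):hi]
  best <- NULL
  for (strand in c("forward", "reverse")) {
    codes <- if (strand == "forward") read$fwd else read$rc
    al <- sw_local_cpp(codes, window, params$sw_match, params$sw_mismatch,
                       params$sw_gap)
    identity <- al$n_match / read$length
    if (identity < params$rescue_min_identity) next
    if (is.null(best) || al$score > best$sw_score) {
      # leftmost genome position of the read under this placement
      # (extrapolate the unaligned read prefix)
      ref_start <- lo + (al$ref_start - 1L) - (al$read_start - 1L)
      best <- data.frame(strand = strand, ref_start = max(ref_start, 0L),
                         score = as.numeric(read$length - al$n_match),
                         sw_score = al$score, identity = identity,
                         stringsAsFactors = FALSE)
    }
  }
  best
}

#' Pair per-end alignment results (three-case scheme)
#'
#' Case 1: both mates have single-end hits; proper pairs are formed with
#' [pair_both_mapped()].  Case 2/3: only one mate is mapped; the other is
#' rescued with [sw_rescue()] anchored on the mapped mate's best hit.
#' When both mates are mapped but no combination satisfies the insert
#' window, rescue is attempted from each mate's best hit as a fallback.
#' One best pair per read pair is reported (ties broken by leftmost
#' `p1`).
#'
#' @param results1,results2 data.frames of single-end results for the two
#'   mate files (columns `read_id`, `strand`, `ref_start`, `score`).
#' @param reads1,reads2 Lists of [encode_read()] objects, parallel to the
#'   read pairs (used for rescue and read lengths); ids of mate `i` must
#'   match `results{i}$read_id`.
#' @param genome_codes Integer code vector of the genome.
#' @param params A [pair_params()].
#' @return A data.frame, one row per rescued or properly paired read
#'   pair: `read_pair_id`, `p1`, `p2`, `strand1`, `strand2`,
#'   `combined_score`, `insert`, `source`.
#' @export
pair_reads <- function(results1, results2, reads1, reads2, genome_codes,
                       params = pair_params()) {
  stopifnot(length(reads1) == length(reads2))
  out <- vector("list", length(reads1))
  for (i in seq_along(reads1)) {
    r1 <- reads1[[i]]; r2 <- reads2[[i]]
    h1 <- results1[results1$read_id == r1$id, , drop = FALSE]
    h2 <- results2[results2$read_id == r2$id, , drop = FALSE]
    pid <- sub("/[12]$", "", r1$id)
    row <- NULL
    if (nrow(h1) && nrow(h2)) {
      pp <- pair_both_mapped(h1, h2, r1$length, r2$length, params)
      if (nrow(pp)) {
        row <- cbind(read_pair_id = pid, pp[1L, , drop = FALSE],
                     source = "both_mapped")
      }
    }
    if (is.null(row) && nrow(h1)) {
      b1 <- h1[order(h1$score, h1$ref_start)[1L], ]
      rs <- sw_rescue(r2, genome_codes, b1$ref_start, b1$strand, r1$length,
                      params)
      if (!is.null(rs) && rs$strand != b1$strand) {
        left1 <- b1$strand == "forward"
        ins <- if (left1) .outer_distance(b1$ref_start, rs$ref_start, r2$length)
               else .outer_distance(rs$ref_start, b1$ref_start, r1$length)
        row <- data.frame(read_pair_id = pid, p1 = b1$ref_start,
                          p2 = rs$ref_start, strand1 = b1$strand,
                          strand2 = rs$strand,
                          combined_score = b1$score + rs$score,
                          insert = as.integer(ins), source = "rescued_end2",
                          stringsAsFactors = FALSE)
      }
    }
    if (is.null(row) && nrow(h2)) {
      b2 <- h2[order(h2$score, h2$ref_start)[1L], ]
      rs <- sw_rescue(r1, genome_codes, b2$ref_start, b2$strand, r2$length,
                      params)
      if (!is.null(rs) && rs$strand != b2$strand) {
        left1 <- rs$strand == "forward"
        ins <- if (left1) .outer_distance(rs$ref_start, b2$ref_start, r2$length)
               else .outer_distance(b2$ref_start, rs$ref_start, r1$length)
        row <- data.frame(read_pair_id = pid, p1 = rs$ref_start,
                          p2 = b2$ref_start, strand1 = rs$strand,
                          strand2 = b2$strand,
                          combined_score = rs$score + b2$score,
                          insert = as.integer(ins), source = "rescued_end1",
                          stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- row
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(read_pair_id = character(0), p1 = integer(0),
                      p2 = integer(0), strand1 = character(0),
                      strand2 = character(0), combined_score = numeric(0),
                      insert = integer(0), source = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
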