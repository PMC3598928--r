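# Banded semi-global extension engine ------------------------------------
#
# Scoring: 0 for a match, 1 for a mismatch, 1 per indel (lower is better).
# The band width is fixed at d = 1 in the block engine (at most one net
# indel); the conventional DP accepts a general band and serves as the
# reference implementation.  Pruned / unreachable scores are represented
# by Inf (the "x" sentinel): absorbing under addition, ignored by min.
#
# Boundary convention (shared by both routes so that the exact block mode
# equals the banded DP): leading read gaps cost S(0,j) = j, leading
# reference gaps inside the candidate window cost S(i,0) = i, and trailing
# reference bases are free -- the result is the minimum over the last DP
# column across the three band diagonals.  Alignments that genuinely start
# one base left of the window are recovered by the shifted engine of
# [dual_engine_align()], not by free leading gaps.

#' Banded-alignment parameters
#'
#' @param band_width Band half-width `d`; the block engine supports only
#'   `d = 1` (its three-diagonal state), the conventional DP any `d`.
#' @param block_width Columns per alignment block (default 8).
#' @param head_width Columns handled by the initial boundary segment
#'   (default 4); with the defaults a 100 bp read occupies the head plus
#'   twelve 8 bp blocks.  `head_width = 0` makes the first block the
#'   initial segment (the three 4 bp block geometry used in examples).
#' @param max_read_len Maximum supported read length.
#' @return An object of class `banded_params`.
#' @export
banded_params <- function(band_width = 1L, block_width = 8L, head_width = 4L,
                          max_read_len = 100L) {
  stopifnot(band_width >= 1L, block_width >= 1L, head_width >= 0L)
  structure(list(band_width = as.integer(band_width),
                 block_width = as.integer(block_width),
                 head_width = as.integer(head_width),
                 max_read_len = as.integer(max_read_len)),
            class = "banded_params")
}

.as_codes <- function(x) if (is.character(x)) encode_bases(x) else as.integer(x)

#' Banded semi-global Needleman-Wunsch (conventional DP)
#'
#' Computes the unit-cost recurrence over cells with `|i - j| <= d` and
#' returns the minimum over the last column together with the 1-based
#' reference row attaining it.
#'
#' @param read,ref Strings over `ACGT` or integer code vectors.
#' @param d Band half-width.
#' @return List with `score` and `ref_end`.
#' @seealso [full_nw()], [block_align()]
#' @export
banded_nw <- function(read, ref, d = 1L) {
  nw_band_cpp(.as_codes(read), .as_codes(ref), as.integer(d))
}

#' Unbanded semi-global Needleman-Wunsch
#'
#' The same recurrence and boundary convention as [banded_nw()] with the
#' band removed; a lower bound on every banded score.
#'
#' @inheritParams banded_nw
#' @return The alignment score.
#' @export
full_nw <- function(read, ref) {
  nw_band_cpp(.as_codes(read), .as_codes(ref), -1L)$score
}

#' Partition the banded search space into v-shaped blocks
#'
#' Builds the per-block 3 x w substitution matrices: row `u`/`m`/`l` of
#' column `j` holds the match/mismatch cost of read base `j` against the
#' reference base on the upper/main/lower band diagonal (`i = j - 1`,
#' `j`, `j + 1`).  Reference positions outside the window are `Inf`
#' (absent, never fabricated).
#'
#' @param read,window Strings or code vectors.
#' @param params A [banded_params()].
#' @return List with `head` (3 x head-width matrix or `NULL`) and
#'   `blocks` (list of 3 x w matrices, the last possibly narrower).
#' @export
partition_blocks <- function(read, window, params = banded_params()) {
  rd <- .as_codes(read); rf <- .as_codes(window)
  n <- length(rd); m <- length(rf)
  if (n > params$max_read_len)
    stop(sprintf("read length %d exceeds max_read_len %d",
                 n, params$max_read_len))
  submat <- function(cols) {
    out <- matrix(Inf, 3L, length(cols), dimnames = list(c("u", "m", "l"), NULL))
    for (jj in seq_along(cols)) {
      j <- cols[jj]
      for (r in 1:3) {
        i <- j + (r - 2L)  # u: j-1, m: j, l: j+1
        if (i >= 1L && i <= m) out[r, jj] <- if (rf[i] == rd[j]) 0 else 1
      }
    }
    out
  }
  h <- min(params$head_width, n)
  head <- if (h > 0L) submat(seq_len(h)) else NULL
  blocks <- list()
  j0 <- h + 1L
  while (j0 <= n) {
    j1 <- min(n, j0 + params$block_width - 1L)
    blocks[[length(blocks) + 1L]] <- submat(j0:j1)
    j0 <- j1 + 1L
  }
  list(head = head, blocks = blocks)
}

#' Construct a block score
#'
#' The triple of best within-block path costs exiting on the upper, main
#' and lower band diagonals, each annotated with the set of entry
#' ("start") diagonals achieving it.  `Inf` encodes the pruned score `x`;
#' its label set is empty.
#'
#' @param scores Numeric length-3 vector (u, m, l order); `Inf` allowed.
#' @param starts List of 3 character vectors over `c("u", "m", "l")`.
#' @return An object of class `block_score`.
#' @export
block_score <- function(scores, starts) {
  scores <- as.numeric(scores)
  stopifnot(length(scores) == 3L, length(starts) == 3L,
            all(scores >= 0))
  names(scores) <- c("u", "m", "l")
  starts <- lapply(starts, function(s) {
    s <- as.character(s)
    stopifnot(all(s %in% c("u", "m", "l")))
    s
  })
  names(starts) <- c("u", "m", "l")
  for (x in 1:3)
    if (is.finite(scores[x]) && length(starts[[x]]) == 0L)
      stop("finite score requires a non-empty start-label set")
  structure(list(scores = scores, starts = starts), class = "block_score")
}

#' @export
print.block_score <- function(x, ...) {
  fmt <- function(v, s) {
    if (!is.finite(v)) "x" else sprintf("%g[%s]", v, paste(s, collapse = ""))
  }
  cat("<block_score> (",
      paste(mapply(fmt, x$scores, x$starts), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# One column of the three-diagonal band recurrence.  s = (u, m, l) are the
# costs at cells (j-1, j), (j, j), (j+1, j); du/dm/dl the substitution
# entries of the next column.  An Inf entry marks an absent reference row,
# which invalidates the whole cell -- except the u entry of the initial
# block's first column, which is the DP boundary S(0,1) reached by one
# charged insertion.
.block_step_r <- function(s, du, dm, dl, u_boundary = FALSE) {
  nu <- min(s[1L] + du, s[2L] + 1)
  if (!is.finite(du) && !u_boundary) nu <- Inf
  nm <- min(s[2L] + dm, s[3L] + 1, nu + 1)
  if (!is.finite(dm)) nm <- Inf
  nl <- min(s[3L] + dl, nm + 1)
  if (!is.finite(dl)) nl <- Inf
  c(nu, nm, nl)
}

#' Score the initial block
#'
#' The initial block starts at the alignment origin: entry state
#' `(x, 0, 1)` -- origin on the main diagonal, a charged leading reference
#' gap on the lower one -- plus the charged leading-insertion boundary on
#' the upper diagonal of column 1.  All start labels are `m` (the origin).
#'
#' @param submat A 3 x w substitution matrix from [partition_blocks()].
#' @return A [block_score()].
#' @export
align_block_initial <- function(submat) {
  s <- c(Inf, 0, 1)
  for (jj in seq_len(ncol(submat)))
    s <- .block_step_r(s, submat[1L, jj], submat[2L, jj], submat[3L, jj],
                       u_boundary = (jj == 1L))
  block_score(s, lapply(s, function(v) if (is.finite(v)) "m" else character(0)))
}

#' Score a later block from all three entry diagonals
#'
#' Runs the within-block recurrence once per possible entry diagonal and
#' reports, for each exit diagonal, the best cost over entries together
#' with every entry diagonal achieving it (ties keep all labels).
#'
#' @param submat A 3 x w substitution matrix.
#' @return A [block_score()] whose start labels are entry diagonals.
#' @export
align_block_later <- function(submat) {
  Tm <- block_transfer_r(submat)
  scores <- apply(Tm, 2L, min)
  starts <- lapply(1:3, function(x) {
    if (!is.finite(scores[x])) return(character(0))
    c("u", "m", "l")[which(Tm[, x] == scores[x])]
  })
  block_score(scores, starts)
}

#' Full 3 x 3 transfer table of a later block
#'
#' `T[e, x]` is the best within-block path cost from entry diagonal `e`
#' to exit diagonal `x` -- the min-plus element whose composition is
#' associative and underlies the exact alignment mode.
#'
#' @param submat A 3 x w substitution matrix.
#' @return A 3 x 3 numeric matrix with dimnames `u`/`m`/`l`.
#' @export
block_transfer_r <- function(submat) {
  Tm <- matrix(Inf, 3L, 3L, dimnames = list(c("u", "m", "l"), c("u", "m", "l")))
  for (e in 1:3) {
    s <- c(Inf, Inf, Inf)
    s[e] <- 0
    for (jj in seq_len(ncol(submat)))
      s <- .block_step_r(s, submat[1L, jj], submat[2L, jj], submat[3L, jj])
    Tm[e, ] <- s
  }
  Tm
}

#' Concatenate two block scores
#'
#' For each exit diagonal `x` of `right`, the new score is
#' `right$scores[x] + min(left$scores[d])` over the entry diagonals `d`
#' labelled in `right$starts[[x]]`; the new label set is the union of
#' `left$starts[[d]]` over the minimising `d`.  Scores exceeding
#' `threshold` are pruned to `x` (Inf).
#'
#' @param left,right [block_score()] objects (left precedes right).
#' @param threshold Prune scores above this value (`Inf` = no pruning).
#' @return A [block_score()].
#' @export
concatenate_blocks <- function(left, right, threshold = Inf) {
  scores <- c(u = Inf, m = Inf, l = Inf)
  starts <- list(u = character(0), m = character(0), l = character(0))
  for (x in 1:3) {
    rs <- right$scores[x]
    ent <- right$starts[[x]]
    if (!is.finite(rs) || length(ent) == 0L) next
    pred <- left$scores[ent]
    add <- min(pred)
    if (!is.finite(add)) next
    val <- rs + add
    if (val > threshold) next
    scores[x] <- val
    starts[[x]] <- sort(unique(unlist(left$starts[ent[pred == add]])))
  }
  block_score(scores, starts)
}

#' Neutral element of block-score concatenation
#'
#' `(0, 0, 0)` with start labels `(u, m, l)`: a zero-cost pass-through
#' that leaves any right operand's scores unchanged.
#' @return A [block_score()].
#' @export
identity_block_score <- function() {
  block_score(c(0, 0, 0), list("u", "m", "l"))
}

#' Final alignment score of a concatenated block score
#'
#' @param bs A fully concatenated [block_score()].
#' @return The minimum over the three exit diagonals, `Inf` ("x") when
#'   all are pruned.
#' @export
finalize_score <- function(bs) {
  min(bs$scores)
}

#' Block-decomposed banded alignment
#'
#' Scores a read against a candidate window by the block decomposition.
#' `mode = "exact"` composes full 3 x 3 transfer tables under min-plus
#' and equals [banded_nw()] with `d = 1` exactly; `mode = "heuristic"`
#' reproduces the fixed-function pipeline -- one [block_score()] per block with
#' start-label chaining -- and never reports a score below the banded
#' optimum (every chained score is the cost of a realizable banded path).
#'
#' @param read,window Strings or code vectors.  The window may carry one
#'   extra base beyond the read length; the lower-diagonal exit then uses
#'   it (the boundary correction of [dual_engine_align()]).
#' @param params A [banded_params()].
#' @param threshold Prune scores above this value.
#' @param mode `"exact"` or `"heuristic"`.
#' @return The alignment score, or `Inf` when no alignment survives the
#'   threshold.
#' @export
block_align <- function(read, window, params = banded_params(),
                        threshold = Inf, mode = c("exact", "heuristic")) {
  mode <- match.arg(mode)
  block_align_cpp(.as_codes(read), .as_codes(window),
                  params$head_width, params$block_width,
                  threshold, mode == "exact")
}

#' Dual-engine alignment of one candidate
#'
#' Runs the block engine on the normal window and on the window shifted
#' one base to the left, each extended by the extra base to its right so
#' the lower-diagonal exit is charged against the true next reference
#' base (an absent base stays `x`: missing sequence is never fabricated).
#' The shifted engine recovers alignments that start one base left of the
#' candidate window (which the normal engine can only reach through a
#' charged initial insertion); the extra-base correction removes the
#' false positives a clipped window would otherwise admit.  The better
#' of the two engines is reported.
#'
#' @param read An [encode_read()] object or code vector.
#' @param win A window list from [fetch_window()].
#' @param strand Strand tag copied into the result.
#' @param params A [banded_params()].
#' @param threshold Score threshold (see [error_threshold()]).
#' @param mode Alignment mode passed to [block_align()].
#' @param read_id Identifier copied into the result.
#' @return A one-row data.frame: `read_id`, `strand`, `ref_start` (0-based
#'   position of the winning engine's window), `score`, `engine`,
#'   `passed`.
#' @export
dual_engine_align <- function(read, win, strand = "forward",
                              params = banded_params(), threshold = Inf,
                              mode = "exact", read_id = "read") {
  codes <- if (inherits(read, "encoded_read")) {
    if (strand == "forward") read$fwd else read$rc
  } else .as_codes(read)
  if (inherits(read, "encoded_read")) read_id <- read$id
  ref_n <- c(win$normal, win$normal_extra)
  ref_s <- c(win$shifted, win$shifted_extra)
  s_n <- if (length(ref_n)) block_align(codes, ref_n, params, threshold, mode) else Inf
  s_s <- if (length(ref_s)) block_align(codes, ref_s, params, threshold, mode) else Inf
  if (s_s < s_n) {
    score <- s_s; engine <- "shifted"; ref_start <- win$shifted_start
  } else {
    score <- s_n; engine <- "normal"; ref_start <- win$normal_start
  }
  data.frame(read_id = read_id, strand = strand, ref_start = ref_start,
             score = score, engine = engine,
             passed = is.finite(score) && score <= threshold,
             stringsAsFactors = FALSE)
}

#' Error threshold for a read length
#'
#' With an identification percentage of 90%, a read of length `L` may
#' accumulate at most `floor(L * 0.1)` unit errors (e.g. 3 for a 36 bp
#' read); of these, at most one may be an indel -- which the `d = 1` band
#' enforces structurally.
#'
#' @param read_len Read length in bases.
#' @param identity_fraction Required identity (default 0.90).
#' @return The integer score threshold.
#' @export
error_threshold <- function(read_len, identity_fraction = 0.90) {
  stopifnot(identity_fraction > 0, identity_fraction < 1)
  # the epsilon guards against binary-fraction artefacts such as
  # 100 * (1 - 0.9) evaluating just below 10
  as.integer(floor(read_len * (1 - identity_fraction) + 1e-6))
}

#' Parallel-time cost model of the block decomposition
#'
#' In the cost model of the block design, a sequential banded DP needs
#' one step per read column (`read_len` cycles), while the block engine
#' needs `block_width` cycles for the (parallel) block alignments plus
#' `ceil(log2(n_blocks))` cycles for the concatenation tree: a 12 bp read
#' in three 4 bp blocks takes 6 cycles instead of 12.
#'
#' @param read_len Read length.
#' @param block_width Block width.
#' @param mode `"parallel"` or `"sequential"`.
#' @return The cycle count.
#' @export
estimate_cycles <- function(read_len, block_width,
                            mode = c("parallel", "sequential")) {
  mode <- match.arg(mode)
  stopifnot(read_len >= block_width, block_width >= 1)
  if (mode == "sequential") return(as.integer(read_len))
  n_blocks <- ceiling(read_len / block_width)
  as.integer(block_width + ceiling(log2(n_blocks)))
}
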