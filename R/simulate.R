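# wgsim-style read simulation and mapping evaluation ---------------------

#' Simulation configuration
#'
#' Emulates wgsim-style sampling: uniform read start positions and
#' strands, i.i.d. per-base substitution errors, at most one 1-bp indel
#' per read, and -- in paired mode -- FR-oriented mates whose outer
#' distance is drawn from `Normal(D, sd)` and rounded.  The single-indel
#' model matches the aligner's error regime (a band of one admits at most
#' one indel), which is also the regime the evaluation operates in.
#'
#' @param genome_len Genome length used by [random_genome()] callers.
#' @param n_reads Number of reads (or read pairs in paired mode).
#' @param read_len Read length in bases.
#' @param err_rate Per-base substitution probability.
#' @param indel_prob Fraction of reads receiving exactly one 1-bp indel.
#' @param paired Generate read pairs.
#' @param outer_distance,std_dev Insert model (paired mode); defaults 200
#'   and 20.
#' @param rng_seed Seed; the same seed reproduces the same dataset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_len = 100000L, n_reads = 1000L, read_len = 76L,
                       err_rate = 0.04, indel_prob = 0.10, paired = FALSE,
                       outer_distance = 200L, std_dev = 20L, rng_seed = 1L) {
  stopifnot(err_rate >= 0, err_rate < 1, indel_prob >= 0, indel_prob <= 1,
            read_len >= 1, read_len <= genome_len)
  structure(list(genome_len = as.integer(genome_len),
                 n_reads = as.integer(n_reads),
                 read_len = as.integer(read_len), err_rate = err_rate,
                 indel_prob = indel_prob, paired = isTRUE(paired),
                 outer_distance = as.integer(outer_distance),
                 std_dev = as.integer(std_dev),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Generate a random genome
#'
#' I.i.d. uniform bases; deterministic under the seed.
#'
#' @param length Genome length (>= 1).
#' @param rng_seed Integer seed.
#' @return A single string over `ACGT`.
#' @export
random_genome <- function(length, rng_seed = 1L) {
  if (length < 1) stop("genome length must be >= 1")
  .with_seed(rng_seed,
             paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                   collapse = ""))
}

# Mutate one template string: substitutions at err_rate, optionally one
# 1-bp indel already applied by the caller.  Returns list(bases, n_subs).
.apply_subs <- function(chars, err_rate) {
  n <- length(chars)
  hit <- which(stats::runif(n) < err_rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  list(chars = chars, n_subs = length(hit))
}

# Draw one read of length `read_len` from genome position `start`
# (0-based, forward coordinates) and strand, with at most one indel.
.make_read <- function(gchars, start, strand, read_len, err_rate, indel_prob) {
  n_indel <- 0L
  if (stats::runif(1) < indel_prob) {
    n_indel <- 1L
    if (stats::runif(1) < 0.5) {
      # insertion: read carries a base absent from the genome
      tpl <- gchars[(start + 1L):(start + read_len - 1L)]
      at <- sample(seq_len(read_len - 1L), 1L)
      tpl <- append(tpl, sample(c("A", "C", "G", "T"), 1L), after = at)
    } else {
      # deletion: read skips one genome base
      tpl <- gchars[(start + 1L):(start + read_len + 1L)]
      at <- sample(2:read_len, 1L)
      tpl <- tpl[-at]
    }
  } else {
    tpl <- gchars[(start + 1L):(start + read_len)]
  }
  if (strand == "reverse") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    tpl <- unname(comp[rev(tpl)])
  }
  mut <- .apply_subs(tpl, err_rate)
  list(bases = paste(mut$chars, collapse = ""), n_subs = mut$n_subs,
       n_indels = n_indel)
}

#' Simulate reads with ground truth
#'
#' @param genome A genome string (or [read_fasta()] one-row data.frame).
#' @param config A [sim_config()].
#' @return A list with `reads` (data.frame `id`, `bases`; in paired mode
#'   also `reads2`) and `truth` (data.frame `read_id`, `true_pos`
#'   (0-based, leftmost forward-strand base), `true_strand`, `n_subs`,
#'   `n_indels`).
#' @export
simulate_reads <- function(genome, config = sim_config()) {
  if (is.data.frame(genome)) genome <- genome$bases[1L]
  gchars <- strsplit(genome, "", fixed = TRUE)[[1]]
  L <- length(gchars)
  rl <- config$read_len
  .with_seed(config$rng_seed, {
    if (!config$paired) {
      n <- config$n_reads
      # keep one base of slack for deletion templates
      starts <- sample.int(L - rl, n, replace = TRUE) - 1L
      strands <- sample(c("forward", "reverse"), n, replace = TRUE)
      recs <- lapply(seq_len(n), function(i)
        .make_read(gchars, starts[i], strands[i], rl, config$err_rate,
                   config$indel_prob))
      ids <- sprintf("sim_%06d", seq_len(n))
      list(reads = data.frame(id = ids,
                              bases = vapply(recs, `[[`, "", "bases"),
                              stringsAsFactors = FALSE),
           truth = data.frame(read_id = ids, true_pos = starts,
                              true_strand = strands,
                              n_subs = vapply(recs, `[[`, 0L, "n_subs"),
                              n_indels = vapply(recs, `[[`, 0L, "n_indels"),
                              stringsAsFactors = FALSE))
    } else {
      n <- config$n_reads
      D <- config$outer_distance
      ins <- pmax(round(stats::rnorm(n, D, config$std_dev)), 2L * rl)
      starts <- vapply(ins, function(t)
        sample.int(max(L - t - 1L, 1L), 1L) - 1L, 0L)
      recs1 <- lapply(seq_len(n), function(i)
        .make_read(gchars, starts[i], "forward", rl, config$err_rate,
                   config$indel_prob))
      starts2 <- as.integer(starts + ins - rl)
      recs2 <- lapply(seq_len(n), function(i)
        .make_read(gchars, starts2[i], "reverse", rl, config$err_rate,
                   config$indel_prob))
      ids <- sprintf("sim_%06d", seq_len(n))
      truth <- rbind(
        data.frame(read_id = paste0(ids, "/1"), true_pos = starts,
                   true_strand = "forward",
                   n_subs = vapply(recs1, `[[`, 0L, "n_subs"),
                   n_indels = vapply(recs1, `[[`, 0L, "n_indels"),
                   stringsAsFactors = FALSE),
        data.frame(read_id = paste0(ids, "/2"), true_pos = starts2,
                   true_strand = "reverse",
                   n_subs = vapply(recs2, `[[`, 0L, "n_subs"),
                   n_indels = vapply(recs2, `[[`, 0L, "n_indels"),
                   stringsAsFactors = FALSE))
      list(reads = data.frame(id = paste0(ids, "/1"),
                              bases = vapply(recs1, `[[`, "", "bases"),
                              stringsAsFactors = FALSE),
           reads2 = data.frame(id = paste0(ids, "/2"),
                               bases = vapply(recs2, `[[`, "", "bases"),
                               stringsAsFactors = FALSE),
           truth = truth)
    }
  })
}

#' Write / read a truth sidecar TSV
#'
#' Ground truth is carried in a TSV file (`read_id`, `true_pos`,
#' `true_strand`, `n_subs`, `n_indels`) rather than encoded in read
#' names; [parse_wgsim_names()] covers real wgsim output.
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Recover truth records from wgsim-style read names
#'
#' wgsim encodes `chromosome_pos1_pos2_...` in each read name; this
#' extracts the leftmost coordinate per mate so real wgsim output can be
#' evaluated with [evaluate()].  Positions are converted to 0-based.
#'
#' @param ids Character vector of wgsim read names.
#' @return A truth data.frame (`n_subs`/`n_indels` are `NA`: wgsim names
#'   do not carry per-read error counts).
#' @export
parse_wgsim_names <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_(\\d+)_(\\d+)_[^_]*_[^_]*.*/([12])$", ids))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad))
    stop(sprintf("not a wgsim-style read name: '%s'", ids[which(bad)[1L]]))
  p1 <- as.integer(vapply(m, `[`, "", 3L))
  p2 <- as.integer(vapply(m, `[`, "", 4L))
  mate <- vapply(m, `[`, "", 5L)
  data.frame(read_id = ids,
             true_pos = ifelse(mate == "1", p1, p2) - 1L,
             true_strand = ifelse(mate == "1", "forward", "reverse"),
             n_subs = NA_integer_, n_indels = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Harmonic mean of precision and recall
#'
#' `f_score = 2 p r / (p + r)`, defined as 0 when both are 0.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return The F-score as a fraction.
#' @export
f_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Evaluate mapping results against ground truth
#'
#' A read counts as aligned when it has at least one reported hit; its
#' best hit (minimum score, ties broken by leftmost position) counts as
#' correct when the strand matches and the reported position is within
#' `tolerance` bases of the true position (the +/- 5 bp rule by
#' default).  Sensitivity is the fraction of reads aligned; accuracy and
#' precision are true alignments over total alignments; recall is true
#' alignments over reads; the F-score combines precision and recall.
#'
#' @param results data.frame of alignment results (`read_id`, `strand`,
#'   `ref_start`, `score`); multiple hits per read are allowed.
#' @param truth Truth data.frame (see [simulate_reads()]).
#' @param tolerance Maximum |reported - true| distance (default 5).
#' @return An object of class `eval_report`.
#' @export
evaluate <- function(results, truth, tolerance = 5L) {
  unknown <- setdiff(results$read_id, truth$read_id)
  if (length(unknown))
    stop(sprintf("result for unknown read id '%s'", unknown[1L]))
  n_reads <- nrow(truth)
  best <- NULL
  if (nrow(results)) {
    dt <- data.table::as.data.table(results)
    data.table::setorder(dt, read_id, score, ref_start)
    best <- as.data.frame(dt[, .SD[1L], by = read_id])
  }
  n_aligned <- if (is.null(best)) 0L else nrow(best)
  n_true <- 0L
  if (n_aligned) {
    tr <- truth[match(best$read_id, truth$read_id), ]
    n_true <- sum(best$strand == tr$true_strand &
                    abs(best$ref_start - tr$true_pos) <= tolerance)
  }
  precision <- if (n_aligned) n_true / n_aligned else 0
  recall <- if (n_reads) n_true / n_reads else 0
  structure(list(n_reads = n_reads, n_aligned = n_aligned, n_true = n_true,
                 sensitivity = if (n_reads) n_aligned / n_reads else 0,
                 accuracy = precision, precision = precision,
                 recall = recall, f_score = f_score(precision, recall)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d reads, %d aligned, %d correct\n",
                     "  sensitivity %.4f  accuracy %.4f  precision %.4f  ",
                     "recall %.4f  F-score %.4f\n"),
              x$n_reads, x$n_aligned, x$n_true, x$sensitivity, x$accuracy,
              x$precision, x$recall, x$f_score))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(n_reads = x$n_reads, n_aligned = x$n_aligned, n_true = x$n_true,
             sensitivity = x$sensitivity, accuracy = x$accuracy,
             precision = x$precision, recall = x$recall, f_score = x$f_score)
}
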