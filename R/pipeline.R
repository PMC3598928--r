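# End-to-end pipelines: index, align, pair, simulate, evaluate -----------

#' Run configuration for the pipelines
#'
#' Mirrors the per-module defaults and is recorded in SAM output headers;
#' round-trips through a plain `key=value` text file.
#'
#' @param seed_len Seed length (15).
#' @param identity Required identity fraction; sets the error threshold
#'   via [error_threshold()].
#' @param max_indels Maximum indels per alignment (1; enforced by the
#'   band).
#' @param band Band half-width (1).
#' @param chunk_size Reads staged per iteration (1,000).
#' @param max_read_len Maximum read length (100).
#' @param align_mode `"exact"` or `"heuristic"` block concatenation.
#' @param stride Seed stride within reads.
#' @param trim_to_max Trim over-long reads instead of rejecting.
#' @param best_only Keep only minimum-score hits per read.
#' @param pair Pairing parameters ([pair_params()]).
#' @param rng_seed Seed for N-resolution and index hashing.
#' @param verbosity 0 silent, 1 progress messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed_len = 15L, identity = 0.90, max_indels = 1L,
                       band = 1L, chunk_size = 1000L, max_read_len = 100L,
                       align_mode = c("exact", "heuristic"), stride = 1L,
                       trim_to_max = FALSE, best_only = FALSE,
                       pair = pair_params(), rng_seed = 1L, verbosity = 0L) {
  align_mode <- match.arg(align_mode)
  structure(list(seed_len = as.integer(seed_len), identity = identity,
                 max_indels = as.integer(max_indels), band = as.integer(band),
                 chunk_size = as.integer(chunk_size),
                 max_read_len = as.integer(max_read_len),
                 align_mode = align_mode, stride = as.integer(stride),
                 trim_to_max = isTRUE(trim_to_max),
                 best_only = isTRUE(best_only), pair = pair,
                 rng_seed = as.integer(rng_seed),
                 verbosity = as.integer(verbosity)),
            class = "run_config")
}

#' Write / read a run configuration as key=value text
#' @param config A [run_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  flat <- config
  flat$pair <- NULL
  p <- config$pair
  lines <- c(
    vapply(names(flat), function(k) sprintf("%s=%s", k, flat[[k]]), ""),
    sprintf("pair.%s=%s", names(p)[names(p) != "class"],
            unlist(p[names(p) != "class"])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  conv <- function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  }
  main <- !startsWith(keys, "pair.")
  cfgargs <- lapply(vals[main], conv)
  names(cfgargs) <- keys[main]
  pargs <- lapply(vals[!main], conv)
  names(pargs) <- sub("^pair\\.", "", keys[!main])
  cfgargs$pair <- do.call(pair_params, pargs)
  do.call(run_config, cfgargs)
}

.log_msg <- function(config, ...) {
  if (config$verbosity > 0L) message(sprintf(...))
}

.index_cfg_of <- function(config) {
  index_config(seed_len = config$seed_len, rng_seed = config$rng_seed)
}

#' Build and save a genome index (pipeline entry point)
#'
#' Reads the genome FASTA, resolves any N bases with the configured seed
#' (logged), builds the bucket-hash index and saves it.
#'
#' @param genome_fasta Path to the reference FASTA.
#' @param out_index Output index path.
#' @param config A [run_config()].
#' @return The loaded-back `seed_index`, invisibly.
#' @export
run_index <- function(genome_fasta, out_index, config = run_config()) {
  g <- read_fasta(genome_fasta)
  bases <- g$bases[1L]
  if (grepl("N", bases, fixed = TRUE)) {
    .log_msg(config, "resolving N bases with seed %d", config$rng_seed)
    bases <- resolve_ns(bases, config$rng_seed)
  }
  idx <- build_index(bases, .index_cfg_of(config), genome_id = g$id[1L])
  .log_msg(config,
           "indexed %d bp: %d occupied slots, %d collision positions",
           idx$genome_len, length(idx$slots), length(idx$collision))
  save_index(idx, out_index)
  invisible(idx)
}

# Encode a reads data.frame into encoded_read objects.
.encode_all <- function(reads_df, config) {
  lapply(seq_len(nrow(reads_df)), function(i)
    encode_read(reads_df$id[i], reads_df$bases[i],
                max_len = config$max_read_len, trim = config$trim_to_max))
}

# Vectorised seeding of one chunk: returns a data.table of candidates
# (read_i, strand, window_start, n_support).
.chunk_candidates <- function(index, chunk, config) {
  cfg <- index$config
  k <- cfg$seed_len
  parts <- list()
  for (strand in c("forward", "reverse")) {
    codes <- unlist(lapply(chunk, function(r) {
      c(if (strand == "forward") r$fwd else r$rc, NA_integer_)
    }))
    lens <- vapply(chunk, `[[`, 0L, "length")
    read_of <- rep(seq_along(chunk), lens + 1L)
    base_off <- c(0L, cumsum(lens + 1L))
    keep <- unlist(lapply(seq_along(chunk), function(i) {
      offs <- .seed_offsets(lens[i], k, config$stride)
      if (!length(offs)) return(integer(0))
      base_off[i] + offs + 1L
    }))
    if (!length(keep)) next
    packed <- .pack_all(codes, k)[keep]
    offsets <- keep - base_off[read_of[keep]] - 1L
    slots <- .slots_of(packed, index$h3, cfg)
    hits <- .lookup_slots(index, slots)
    if (nrow(hits) == 0L) next
    hits[, read_i := read_of[keep[query]]]
    hits[, window_start := pos - offsets[query]]
    agg <- hits[, list(n_support = .N), by = list(read_i, window_start)]
    agg[, strand := ..strand]
    parts[[strand]] <- agg
  }
  if (!length(parts))
    return(data.table::data.table(read_i = integer(0), strand = character(0),
                                  window_start = integer(0),
                                  n_support = integer(0)))
  data.table::rbindlist(parts)
}

#' Align encoded reads against an indexed genome (in memory)
#'
#' The single-end engine: chunked seeding, dual-engine block extension,
#' threshold filtering and duplicate removal.  All threshold-passing
#' deduplicated hits are reported unless `config$best_only` is set.
#'
#' @param index A `seed_index`.
#' @param genome_codes Integer code vector of the (N-resolved) genome.
#' @param reads List of [encode_read()] objects.
#' @param config A [run_config()].
#' @return A list with `hits` (data.frame `read_id`, `strand`,
#'   `ref_start`, `score`, `engine`) and `unmapped` (character vector of
#'   read ids without a passing hit).
#' @export
align_reads <- function(index, genome_codes, reads, config = run_config()) {
  params <- banded_params(band_width = config$band)
  exact <- config$align_mode == "exact"
  chunks <- chunk_reads(reads, config$chunk_size)
  all_hits <- list()
  for (ci in seq_along(chunks)) {
    chunk <- chunks[[ci]]
    cand <- .chunk_candidates(index, chunk, config)
    .log_msg(config, "chunk %d/%d: %d reads, %d candidates",
             ci, length(chunks), length(chunk), nrow(cand))
    if (nrow(cand) == 0L) next
    n <- nrow(cand)
    read_id <- character(n); ref_start <- integer(n)
    score <- numeric(n); engine <- character(n)
    for (i in seq_len(n)) {
      rd <- chunk[[cand$read_i[i]]]
      thr <- error_threshold(rd$length, config$identity)
      win <- fetch_window(genome_codes, cand$window_start[i], rd$length)
      codes <- if (cand$strand[i] == "forward") rd$fwd else rd$rc
      ref_n <- c(win$normal, win$normal_extra)
      ref_s <- c(win$shifted, win$shifted_extra)
      s_n <- if (length(ref_n))
        block_align_cpp(codes, ref_n, params$head_width, params$block_width,
                        thr, exact) else Inf
      s_s <- if (length(ref_s))
        block_align_cpp(codes, ref_s, params$head_width, params$block_width,
                        thr, exact) else Inf
      read_id[i] <- rd$id
      if (s_s < s_n) {
        score[i] <- s_s; engine[i] <- "shifted"; ref_start[i] <- win$shifted_start
      } else {
        score[i] <- s_n; engine[i] <- "normal"; ref_start[i] <- win$normal_start
      }
    }
    hits <- data.table::data.table(read_id = read_id, strand = cand$strand,
                                   ref_start = ref_start, score = score,
                                   engine = engine)
    all_hits[[ci]] <- hits[is.finite(score)]
  }
  hits <- if (length(all_hits)) data.table::rbindlist(all_hits)
          else data.table::data.table(read_id = character(0),
                                      strand = character(0),
                                      ref_start = integer(0),
                                      score = numeric(0),
                                      engine = character(0))
  if (nrow(hits)) {
    # duplicate removal: one entry per (read, strand, position), best score
    data.table::setorder(hits, read_id, strand, ref_start, score)
    hits <- hits[, .SD[1L], by = list(read_id, strand, ref_start)]
    if (config$best_only) {
      hits <- hits[, .SD[score == min(score)], by = read_id]
    }
  }
  hits <- as.data.frame(hits)[, c("read_id", "strand", "ref_start",
                                  "score", "engine")]
  unmapped <- setdiff(vapply(reads, `[[`, "", "id"), hits$read_id)
  list(hits = hits, unmapped = unmapped)
}

# SAM emission ------------------------------------------------------------

.sam_header <- function(genome_id, genome_len, config, extra = character(0)) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", genome_id, genome_len),
    sprintf("@PG\tID:seedalign\tPN:seedalign\tVN:%s\tCL:%s",
            as.character(utils::packageVersion("seedalign")),
            sprintf("identity=%g band=%d seed_len=%d mode=%s",
                    config$identity, config$band, config$seed_len,
                    config$align_mode)),
    extra)
}

# One SAM line per hit plus unmapped records.  CIGAR is <len>M: the engine
# reports scores and positions, not tracebacks; the edit cost is carried in
# the NM tag.  MAPQ is 255 (unavailable).
.sam_body_single <- function(hits, unmapped, reads_by_id, genome_id) {
  lines <- character(0)
  if (nrow(hits)) {
    # SAM stores the reverse-strand SEQ as the reverse complement
    rev_i <- hits$strand == "reverse"
    seqs <- vapply(seq_len(nrow(hits)), function(i) {
      r <- reads_by_id[[hits$read_id[i]]]
      decode_bases(if (rev_i[i]) r$rc else r$fwd)
    }, "")
    lens <- vapply(hits$read_id, function(id) reads_by_id[[id]]$length, 0L)
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                     hits$read_id, ifelse(rev_i, 16L, 0L), genome_id,
                     hits$ref_start + 1L, lens, seqs, as.integer(hits$score))
  }
  if (length(unmapped)) {
    useqs <- vapply(unmapped, function(id)
      decode_bases(reads_by_id[[id]]$fwd), "")
    lines <- c(lines, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                              unmapped, useqs))
  }
  lines
}

#' Align a FASTQ file against an index (pipeline entry point)
#'
#' Chunked single-end alignment with SAM output; a summary line with the
#' fraction of reads aligned is returned invisibly.
#'
#' @param index_path Path to a saved index (or a `seed_index` object).
#' @param genome_fasta Path to the reference FASTA the index was built
#'   from (windows are fetched from it).
#' @param reads_fastq Path to the reads FASTQ.
#' @param out_sam Output SAM path.
#' @param config A [run_config()].
#' @return Invisibly, a list with `hits`, `unmapped`, `fraction_aligned`.
#' @export
run_align <- function(index_path, genome_fasta, reads_fastq, out_sam,
                      config = run_config()) {
  index <- if (inherits(index_path, "seed_index")) index_path
           else load_index(index_path)
  g <- read_fasta(genome_fasta)
  bases <- resolve_ns(g$bases[1L], config$rng_seed)
  genome_codes <- encode_bases(bases)
  reads_df <- read_fastq(reads_fastq)
  reads <- .encode_all(reads_df, config)
  res <- align_reads(index, genome_codes, reads, config)
  reads_by_id <- stats::setNames(reads, vapply(reads, `[[`, "", "id"))
  writeLines(c(.sam_header(index$genome_id, index$genome_len, config),
               .sam_body_single(res$hits, res$unmapped, reads_by_id,
                                index$genome_id)),
             out_sam)
  n <- length(reads)
  frac <- if (n) (n - length(res$unmapped)) / n else 0
  .log_msg(config, "aligned %d/%d reads (%.2f%%)",
           n - length(res$unmapped), n, 100 * frac)
  invisible(c(res, list(fraction_aligned = frac)))
}

#' Paired-end alignment of two FASTQ files (pipeline entry point)
#'
#' Aligns both ends single-end, applies the three-case pairing scheme
#' (including Smith-Waterman rescue of unmapped mates) and writes a
#' paired SAM with mate fields and proper-pair flags.
#'
#' @param index_path Saved index path or `seed_index`.
#' @param genome_fasta Reference FASTA path.
#' @param reads1_fastq,reads2_fastq Mate FASTQ paths (same read count and
#'   order).
#' @param out_sam Output SAM path.
#' @param config A [run_config()].
#' @return Invisibly, the data.frame of paired alignments.
#' @export
run_pair <- function(index_path, genome_fasta, reads1_fastq, reads2_fastq,
                     out_sam, config = run_config()) {
  index <- if (inherits(index_path, "seed_index")) index_path
           else load_index(index_path)
  g <- read_fasta(genome_fasta)
  genome_codes <- encode_bases(resolve_ns(g$bases[1L], config$rng_seed))
  df1 <- read_fastq(reads1_fastq)
  df2 <- read_fastq(reads2_fastq)
  if (nrow(df1) != nrow(df2))
    stop(sprintf("mate file length mismatch: %d vs %d reads",
                 nrow(df1), nrow(df2)))
  reads1 <- .encode_all(df1, config)
  reads2 <- .encode_all(df2, config)
  r1 <- align_reads(index, genome_codes, reads1, config)
  r2 <- align_reads(index, genome_codes, reads2, config)
  pairs <- pair_reads(r1$hits, r2$hits, reads1, reads2, genome_codes,
                      config$pair)
  lines <- .sam_header(index$genome_id, index$genome_len, config)
  if (nrow(df1)) {
    pid <- sub("/[12]$", "", df1$id)
    pmap <- match(pid, pairs$read_pair_id)
    for (i in seq_len(nrow(df1))) {
      r1i <- reads1[[i]]; r2i <- reads2[[i]]
      pj <- pmap[i]
      if (!is.na(pj)) {
        p <- pairs[pj, ]
        rev1 <- p$strand1 == "reverse"; rev2 <- p$strand2 == "reverse"
        tlen <- if (p$strand1 == "forward") p$insert else -p$insert
        f1 <- 1L + 2L + 64L + (if (rev1) 16L else 0L) + (if (rev2) 32L else 0L)
        f2 <- 1L + 2L + 128L + (if (rev2) 16L else 0L) + (if (rev1) 32L else 0L)
        lines <- c(lines,
          sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t%s\t*\tNM:i:%d",
                  r1i$id, f1, index$genome_id, p$p1 + 1L, r1i$length,
                  p$p2 + 1L, tlen,
                  decode_bases(if (rev1) r1i$rc else r1i$fwd), 0L),
          sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t%s\t*\tNM:i:%d",
                  r2i$id, f2, index$genome_id, p$p2 + 1L, r2i$length,
                  p$p1 + 1L, -tlen,
                  decode_bases(if (rev2) r2i$rc else r2i$fwd), 0L))
      } else {
        lines <- c(lines,
          sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t*", r1i$id,
                  1L + 4L + 8L + 64L, decode_bases(r1i$fwd)),
          sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t*", r2i$id,
                  1L + 4L + 8L + 128L, decode_bases(r2i$fwd)))
      }
    }
  }
  writeLines(lines, out_sam)
  invisible(pairs)
}

#' Simulate a dataset to files (pipeline entry point)
#'
#' @param genome_fasta Reference FASTA path.
#' @param out_prefix Output prefix: writes `<prefix>.fq` (or `_1.fq` /
#'   `_2.fq` in paired mode) and `<prefix>.truth.tsv`.
#' @param config A [sim_config()].
#' @return Invisibly, the [simulate_reads()] result.
#' @export
run_simulate <- function(genome_fasta, out_prefix, config = sim_config()) {
  g <- read_fasta(genome_fasta)
  sim <- simulate_reads(g$bases[1L], config)
  if (config$paired) {
    write_fastq(sim$reads, paste0(out_prefix, "_1.fq"))
    write_fastq(sim$reads2, paste0(out_prefix, "_2.fq"))
  } else {
    write_fastq(sim$reads, paste0(out_prefix, ".fq"))
  }
  write_truth(sim$truth, paste0(out_prefix, ".truth.tsv"))
  invisible(sim)
}

#' Parse alignment records from a SAM file written by this package
#'
#' @param path SAM path.
#' @return data.frame `read_id`, `strand`, `ref_start` (0-based),
#'   `score` for mapped records.
#' @export
read_sam_hits <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body))
    return(data.frame(read_id = character(0), strand = character(0),
                      ref_start = integer(0), score = numeric(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 0L)
  mapped <- bitwAnd(flag, 4L) == 0L
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x, value = TRUE)
    if (length(tag)) as.numeric(sub("^NM:i:", "", tag[1])) else NA_real_
  }, 0)
  data.frame(read_id = vapply(f, `[`, "", 1L)[mapped],
             strand = ifelse(bitwAnd(flag[mapped], 16L) > 0L,
                             "reverse", "forward"),
             ref_start = vapply(f, function(x) as.integer(x[4]), 0L)[mapped] - 1L,
             score = nm[mapped], stringsAsFactors = FALSE)
}

#' Evaluate a SAM file against a truth TSV (pipeline entry point)
#'
#' @param sam_path SAM path (as written by [run_align()]).
#' @param truth_path Truth TSV path (as written by [write_truth()]).
#' @param tolerance Position tolerance in bases (default 5).
#' @param out_tsv Optional path to write the report as TSV.
#' @return The [evaluate()] report.
#' @export
run_evaluate <- function(sam_path, truth_path, tolerance = 5L,
                         out_tsv = NULL) {
  if (!file.exists(truth_path)) stop("missing truth file: ", truth_path)
  hits <- read_sam_hits(sam_path)
  truth <- read_truth(truth_path)
  rep <- evaluate(hits, truth, tolerance)
  if (!is.null(out_tsv))
    utils::write.table(as.data.frame(rep), out_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  rep
}
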