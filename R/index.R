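# Bucket-hash k-mer index -----------------------------------------------
#
# A constant-length seed (default 15 bp, 30 bits) is split into a prefix
# (bucket selector) and a suffix.  Each bucket owns an H3-family hash
# function (XOR of random binary-matrix rows selected by the set bits of
# the suffix), and the primary-table address is (prefix << hash_bits) | h,
# so collisions are confined within a bucket.  Slots holding one genome
# position store it directly (collision flag C = 0); slots holding two or
# more positions -- a repeated seed, or distinct seeds colliding in the
# bucket -- move all their positions to the collision table (C = 1) and
# store the collision-table offset instead.  The primary table is held
# sparsely (only occupied slots) with semantics identical to the dense
# 2^(prefix_bits + hash_bits)-slot layout.

#' Index configuration
#'
#' The default geometry matches the 15 bp seed design: a 30-bit packed
#' seed split into a 16-bit prefix and a 14-bit suffix, hashed to 12 bits,
#' giving a 2^28-slot primary address space (64 K buckets x 4 K slots).
#' The 7-bit occupancy count caps at 127 positions per slot.
#'
#' @param seed_len Seed length in bases.
#' @param prefix_bits Bits of the packed seed used as the bucket selector.
#' @param hash_bits Width of the per-bucket hash value.
#' @param count_cap Maximum positions stored per slot (7-bit field: <= 127).
#' @param rng_seed Seed for the deterministic generation of the per-bucket
#'   H3 matrices.
#' @return An object of class `index_config`.
#' @export
index_config <- function(seed_len = 15L, prefix_bits = 16L, hash_bits = 12L,
                         count_cap = 127L, rng_seed = 1L) {
  seed_len <- as.integer(seed_len)
  prefix_bits <- as.integer(prefix_bits)
  hash_bits <- as.integer(hash_bits)
  suffix_bits <- 2L * seed_len - prefix_bits
  stopifnot(seed_len >= 1L, prefix_bits >= 1L, hash_bits >= 1L,
            suffix_bits >= 1L, count_cap >= 1L, count_cap <= 127L)
  if (prefix_bits + hash_bits > 30L)
    stop("prefix_bits + hash_bits > 30: slot addresses would not fit an integer")
  structure(list(seed_len = seed_len, prefix_bits = prefix_bits,
                 suffix_bits = suffix_bits, hash_bits = hash_bits,
                 count_cap = as.integer(count_cap),
                 rng_seed = as.integer(rng_seed)),
            class = "index_config")
}

#' Pack a k-mer into a 2k-bit integer
#'
#' Big-endian base order: the leftmost base occupies the most significant
#' two bits, so packing is the base-4 positional expansion of the coded
#' sequence.  A 15 bp seed fits in 30 bits.
#'
#' @param kmer A k-mer string over `ACGT`, or an integer code vector.
#' @param seed_len Expected length (checked).
#' @return The packed value as a double (exact: < 2^30 by default).
#' @export
pack_kmer <- function(kmer, seed_len = 15L) {
  codes <- if (is.character(kmer)) encode_bases(kmer) else as.integer(kmer)
  if (length(codes) != seed_len)
    stop(sprintf("k-mer length %d != seed length %d", length(codes), seed_len))
  sum(codes * 4^((seed_len - 1):0))
}

#' Split a packed seed into prefix and suffix
#'
#' @param packed Packed seed value.
#' @param config An [index_config()].
#' @return List with `prefix` (top `prefix_bits`) and `suffix`
#'   (bottom `suffix_bits`); `(prefix << suffix_bits) | suffix`
#'   recombines to `packed`.
#' @export
split_prefix_suffix <- function(packed, config) {
  base <- 2^config$suffix_bits
  list(prefix = packed %/% base, suffix = packed %% base)
}

# Per-bucket H3 matrices, generated deterministically from the config seed:
# an integer matrix with 2^prefix_bits rows (buckets) and suffix_bits
# columns; entry [b + 1, i] is the hash_bits-wide row i of bucket b's
# binary matrix.
.h3_matrices <- function(config) {
  .with_seed(config$rng_seed, {
    n <- 2^config$prefix_bits * config$suffix_bits
    matrix(sample.int(2^config$hash_bits, n, replace = TRUE) - 1L,
           nrow = 2^config$prefix_bits, ncol = config$suffix_bits)
  })
}

#' H3-family hash of a seed suffix
#'
#' The H3 construction: XOR of the matrix rows selected by the set bits of
#' the suffix.  Linear by construction:
#' `h3_hash(a XOR b) == h3_hash(a) XOR h3_hash(b)`.
#'
#' @param suffix Suffix value (`< 2^suffix_bits`).
#' @param matrix_rows Integer vector of `suffix_bits` values, each
#'   `hash_bits` wide (one bucket's matrix; bit `i` of the suffix selects
#'   `matrix_rows[i + 1]`, least-significant bit first).
#' @return The hash value.
#' @export
h3_hash <- function(suffix, matrix_rows) {
  h <- 0L
  s <- as.numeric(suffix)
  for (i in seq_along(matrix_rows)) {
    if (s %% 2 == 1) h <- bitwXor(h, matrix_rows[i])
    s <- s %/% 2
  }
  h
}

# Vectorised hashing of many (prefix, suffix) pairs against the bucket
# matrix table; NA suffixes propagate.
.h3_hash_many <- function(prefix, suffix, h3, config) {
  h <- integer(length(suffix))
  s <- suffix
  for (i in seq_len(config$suffix_bits)) {
    sel <- which(s %% 2 == 1)
    if (length(sel))
      h[sel] <- bitwXor(h[sel], h3[cbind(prefix[sel] + 1L, i)])
    s <- s %/% 2
  }
  h[is.na(suffix)] <- NA_integer_
  h
}

#' Primary-table slot address
#'
#' @param prefix Bucket selector.
#' @param h Hash value.
#' @param config An [index_config()].
#' @return `(prefix << hash_bits) | h`.
#' @export
table_address <- function(prefix, h, config) {
  prefix * 2^config$hash_bits + h
}

# Packed seed values for every k-mer start of a code vector; windows that
# contain an NA code yield NA.
.pack_all <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0))
  packed <- numeric(n)
  for (j in 0:(k - 1L)) {
    packed <- packed + codes[(1L + j):(n + j)] * 4^(k - 1L - j)
  }
  packed
}

# Slot address for each packed seed (NA packed -> NA slot).
.slots_of <- function(packed, h3, config) {
  base <- 2^config$suffix_bits
  prefix <- packed %/% base
  suffix <- packed %% base
  h <- .h3_hash_many(prefix, suffix, h3, config)
  table_address(prefix, h, config)
}

#' Build the bucket-hash index of a reference genome
#'
#' Every k-mer start position of the (N-free, forward-strand) genome is
#' hashed and stored.  Slots that receive a single position store it
#' directly (`C = 0`); slots with two or more positions store all of them
#' in the collision table (`C = 1`, primary `ptr` = collision-table start).
#' Slots exceeding `count_cap` positions keep the first `count_cap` (in
#' genome order) and are recorded in `overflow_slots`.
#'
#' @param genome A genome string over `ACGT`, or a one-row data.frame as
#'   returned by [read_fasta()].
#' @param config An [index_config()].
#' @param genome_id Identifier stored with the index.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(genome, config = index_config(), genome_id = "ref") {
  if (is.data.frame(genome)) {
    genome_id <- genome$id[1L]
    genome <- genome$bases[1L]
  }
  codes <- encode_bases(genome)
  L <- length(codes)
  k <- config$seed_len
  if (L < k) stop(sprintf("genome (%d bp) shorter than seed length %d", L, k))
  if (L > 2^24) {
    stop("genome longer than 2^24 bases: positions would not fit the ",
         "24-bit Ptr/Pos fields; raise the field widths via a custom config")
  }
  h3 <- .h3_matrices(config)
  packed <- .pack_all(codes, k)
  slot <- .slots_of(packed, h3, config)
  dt <- data.table::data.table(slot = slot, pos = 0:(L - k))
  data.table::setorder(dt, slot, pos)
  grp <- dt[, list(count = .N, positions = list(pos)), by = slot]
  single <- grp$count == 1L
  n_over <- sum(grp$count > config$count_cap)
  stored <- pmin(grp$count, config$count_cap)
  cflag <- as.integer(!single)
  ptr <- integer(nrow(grp))
  ptr[single] <- vapply(grp$positions[single], `[`, integer(1), 1L)
  multi <- which(!single)
  collision <- integer(0)
  if (length(multi)) {
    kept <- lapply(multi, function(i) grp$positions[[i]][seq_len(stored[i])])
    offs <- cumsum(c(0L, vapply(kept, length, integer(1))))
    ptr[multi] <- offs[seq_along(multi)]
    collision <- unlist(kept, use.names = FALSE)
  }
  structure(list(config = config, genome_id = genome_id, genome_len = L,
                 slots = grp$slot, cflag = cflag,
                 count = pmin(grp$count, 127L), n_stored = stored, ptr = ptr,
                 collision = collision,
                 overflow_slots = grp$slot[grp$count > config$count_cap],
                 n_overflow = n_over, h3 = h3),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf(paste0("<seed_index> genome '%s' (%d bp), seed %d bp\n",
                     "  %d occupied slots of 2^%d; %d direct, %d collision ",
                     "slots (%d positions); %d slots overflowed the %d cap\n"),
              x$genome_id, x$genome_len, x$config$seed_len,
              length(x$slots), x$config$prefix_bits + x$config$hash_bits,
              sum(x$cflag == 0L), sum(x$cflag == 1L), length(x$collision),
              x$n_overflow, x$config$count_cap))
  invisible(x)
}

#' Look up a k-mer in the index
#'
#' Returns every genome position stored at the k-mer's slot.  The result
#' is a superset of the k-mer's true occurrence positions: distinct seeds
#' that collide within a bucket share a slot and are not disambiguated
#' here -- false candidates are eliminated by the extension stage, never by
#' the index.
#'
#' @param index A [build_index()] result.
#' @param kmer A seed-length k-mer string or code vector.
#' @return Integer vector of 0-based genome positions (possibly empty).
#' @export
lookup <- function(index, kmer) {
  packed <- pack_kmer(kmer, index$config$seed_len)
  slot <- .slots_of(packed, index$h3, index$config)
  i <- match(slot, index$slots)
  if (is.na(i)) return(integer(0))
  if (index$cflag[i] == 0L) return(index$ptr[i])
  index$collision[(index$ptr[i] + 1L):(index$ptr[i] + index$n_stored[i])]
}

# Vectorised lookup used by the seeding stage: returns a data.table with
# one row per stored position hit: (query = index into `slots_query`, pos).
.lookup_slots <- function(index, slots_query) {
  i <- match(slots_query, index$slots)
  hit <- which(!is.na(i))
  if (!length(hit))
    return(data.table::data.table(query = integer(0), pos = integer(0)))
  ii <- i[hit]
  direct <- index$cflag[ii] == 0L
  q1 <- hit[direct]
  p1 <- index$ptr[ii[direct]]
  im <- ii[!direct]
  qm <- hit[!direct]
  if (length(im)) {
    counts <- index$n_stored[im]
    q2 <- rep(qm, counts)
    p2 <- index$collision[sequence(counts, from = index$ptr[im] + 1L)]
  } else {
    q2 <- integer(0); p2 <- integer(0)
  }
  data.table::data.table(query = c(q1, q2), pos = c(p1, p2))
}

#' Pack a primary-table entry into a 32-bit word
#'
#' Bit layout (most significant first): `c:1 | count:7 | ptr:24`.
#'
#' @param c Collision flag (0 or 1).
#' @param count 7-bit occupancy count.
#' @param ptr 24-bit position or collision-table offset.
#' @return The unsigned word value as a double.
#' @export
pack_primary_entry <- function(c, count, ptr) {
  stopifnot(c %in% c(0, 1), count >= 0, count <= 127, ptr >= 0, ptr < 2^24)
  c * 2^31 + count * 2^24 + ptr
}

# unsigned double word <-> signed 32-bit integer (two's complement)
.word_to_int <- function(w) as.integer(ifelse(w >= 2^31, w - 2^32, w))
.int_to_word <- function(i) { w <- as.numeric(i); ifelse(w < 0, w + 2^32, w) }

.INDEX_MAGIC <- "SBIX"
.INDEX_VERSION <- 1L

#' Serialize an index to a binary file
#'
#' Little-endian 32-bit words: a header (magic `"SBIX"`, version, config
#' fields, genome id and length), then the primary entries packed as
#' `c:1 | count:7 | ptr:24`, then the collision-table positions.  When the
#' configured address space is small (at most 2^22 slots) the primary
#' block is written densely in address order; otherwise only occupied
#' slots are written, preceded by their addresses.  The per-bucket H3
#' matrices are not stored: they are regenerated from the config seed on
#' load, so a saved index is only portable together with its `rng_seed`.
#'
#' @param index A `seed_index`.
#' @param path Output path.
#' @export
save_index <- function(index, path) {
  cfg <- index$config
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.INDEX_MAGIC), con)
  id_raw <- charToRaw(index$genome_id)
  dense <- 2^(cfg$prefix_bits + cfg$hash_bits) <= 2^22
  writeBin(c(.INDEX_VERSION, cfg$seed_len, cfg$prefix_bits, cfg$suffix_bits,
             cfg$hash_bits, cfg$count_cap, cfg$rng_seed,
             as.integer(dense), length(id_raw)),
           con, size = 4L, endian = "little")
  writeBin(id_raw, con)
  writeBin(as.integer(index$genome_len), con, size = 4L, endian = "little")
  words <- pack_primary_entry(index$cflag, index$count, index$ptr)
  if (dense) {
    n_slots <- 2^(cfg$prefix_bits + cfg$hash_bits)
    all_words <- numeric(n_slots)
    all_words[index$slots + 1] <- words
    writeBin(.word_to_int(all_words), con, size = 4L, endian = "little")
  } else {
    writeBin(length(index$slots), con, size = 4L, endian = "little")
    writeBin(as.integer(index$slots), con, size = 4L, endian = "little")
    writeBin(.word_to_int(words), con, size = 4L, endian = "little")
  }
  writeBin(length(index$collision), con, size = 4L, endian = "little")
  writeBin(as.integer(index$collision), con, size = 4L, endian = "little")
  invisible(path)
}

#' Load an index saved by [save_index()]
#' @param path Path to the index file.
#' @return A `seed_index` with lookup behaviour identical to the saved one.
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, charToRaw(.INDEX_MAGIC)))
    stop("not a seed index file (bad magic number)")
  hdr <- readBin(con, "integer", 9L, size = 4L, endian = "little")
  if (length(hdr) < 9L) stop("truncated index file")
  if (hdr[1] != .INDEX_VERSION)
    stop(sprintf("unsupported index version %d", hdr[1]))
  cfg <- index_config(seed_len = hdr[2], prefix_bits = hdr[3],
                      hash_bits = hdr[5], count_cap = hdr[6],
                      rng_seed = hdr[7])
  if (cfg$suffix_bits != hdr[4]) stop("corrupt index header")
  dense <- hdr[8] == 1L
  genome_id <- rawToChar(readBin(con, "raw", hdr[9]))
  genome_len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (dense) {
    n_slots <- 2^(cfg$prefix_bits + cfg$hash_bits)
    words <- readBin(con, "integer", n_slots, size = 4L, endian = "little")
    if (length(words) < n_slots) stop("truncated index file")
    words <- .int_to_word(words)
    occ <- which(words != 0)
    slots <- occ - 1
    words <- words[occ]
  } else {
    ns <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(ns) < 1L) stop("truncated index file")
    slots <- readBin(con, "integer", ns, size = 4L, endian = "little")
    words <- readBin(con, "integer", ns, size = 4L, endian = "little")
    if (length(slots) < ns || length(words) < ns) stop("truncated index file")
    words <- .int_to_word(words)
  }
  nc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(nc) < 1L) stop("truncated index file")
  collision <- readBin(con, "integer", nc, size = 4L, endian = "little")
  if (length(collision) < nc) stop("truncated index file")
  cflag <- as.integer(words %/% 2^31)
  count <- as.integer((words %/% 2^24) %% 2^7)
  ptr <- as.integer(words %% 2^24)
  n_stored <- ifelse(cflag == 0L, 1L, pmin(count, cfg$count_cap))
  structure(list(config = cfg, genome_id = genome_id, genome_len = genome_len,
                 slots = as.numeric(slots), cflag = cflag, count = count,
                 n_stored = as.integer(n_stored), ptr = ptr,
                 collision = collision,
                 overflow_slots = numeric(0), n_overflow = NA_integer_,
                 h3 = .h3_matrices(cfg)),
            class = "seed_index")
}
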