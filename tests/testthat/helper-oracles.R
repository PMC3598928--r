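# Independent reference implementations used as test oracles.  These are
# deliberately naive (enumeration / dictionary / textbook DP) and share no
# code with the package's engines.

# Brute-force banded semi-global alignment by exhaustive path enumeration
# (no DP): paths start at the origin, may begin with charged gaps along
# either boundary, must stay inside the band, and may end on any row of
# the last column (trailing reference bases free).  d < 0 disables the
# band.
oracle_banded <- function(read_codes, ref_codes, d = 1) {
  n <- length(read_codes); m <- length(ref_codes)
  usable <- function(i, j) {
    if (i < 0 || j < 0 || i > m || j > n) return(FALSE)
    if (d < 0) return(TRUE)
    if (i == 0) return(TRUE)          # top boundary row
    if (j == 0) return(i <= d)        # charged leading reference gaps
    abs(i - j) <= d
  }
  best <- Inf
  rec <- function(i, j, cost) {
    if (cost >= best) return(invisible())
    if (j == n && i >= 1) best <<- min(best, cost)
    if (usable(i + 1, j + 1) && j < n) {
      dlt <- if (ref_codes[i + 1] == read_codes[j + 1]) 0 else 1
      rec(i + 1, j + 1, cost + dlt)
    }
    if (usable(i + 1, j)) rec(i + 1, j, cost + 1)
    if (usable(i, j + 1) && j < n) rec(i, j + 1, cost + 1)
    invisible()
  }
  rec(0, 0, 0)
  best
}

# Dictionary oracle: 0-based genome positions of every k-mer, found by
# direct substring comparison.
oracle_kmer_positions <- function(genome, kmer) {
  k <- nchar(kmer)
  n <- nchar(genome) - k + 1
  if (n < 1) return(integer(0))
  starts <- seq_len(n)
  which(substring(genome, starts, starts + k - 1) == kmer) - 1L
}

# All k-mers of a genome keyed by sequence (0-based positions).
oracle_kmer_dict <- function(genome, k) {
  n <- nchar(genome) - k + 1
  if (n < 1) return(list())
  kmers <- substring(genome, seq_len(n), seq_len(n) + k - 1)
  split(0:(n - 1), kmers)
}

# Textbook Smith-Waterman score (score only, full matrix).
oracle_sw_score <- function(read_codes, ref_codes, match = 1, mismatch = -1,
                            gap = -1) {
  n <- length(read_codes); m <- length(ref_codes)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (ref_codes[i] == read_codes[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Reverse complement of a base string (independent of the package's coded
# implementation).
oracle_revcomp <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(bases, "")[[1]]])), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Small scaled index geometry used throughout the index tests: 8-bit
# prefix, 6-bit hash (2^14 addressable slots) -- the same semantics as the
# full 2^28-slot geometry at test scale.
small_geometry <- function(seed_len = 7L, rng_seed = 42L) {
  index_config(seed_len = seed_len, prefix_bits = 8L, hash_bits = 6L,
               rng_seed = rng_seed)
}
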