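test_that("k-mer packing is big-endian base-4 expansion", {
  expect_identical(pack_kmer(strrep("A", 15)), 0)
  expect_identical(pack_kmer(strrep("T", 15)), 2^30 - 1)
  # independent base-4 arithmetic oracle
  km <- "ACGTACGTACGTACG"
  digits <- encode_bases(km)
  expected <- 0
  for (d in digits) expected <- expected * 4 + d
  expect_identical(pack_kmer(km), expected)
  expect_error(pack_kmer("ACGT"), "length")
  expect_error(pack_kmer(strrep("N", 15)), "non-ACGT")
})

test_that("prefix/suffix split recombines and respects field widths", {
  cfg <- index_config()
  expect_identical(split_prefix_suffix(0, cfg), list(prefix = 0, suffix = 0))
  top <- split_prefix_suffix(2^30 - 1, cfg)
  expect_identical(top$prefix, 2^16 - 1)
  expect_identical(top$suffix, 2^14 - 1)
  set.seed(103)
  for (v in sample(0:(2^30 - 1), 25)) {
    ps <- split_prefix_suffix(v, cfg)
    expect_identical(ps$prefix * 2^cfg$suffix_bits + ps$suffix, as.numeric(v))
  }
})

test_that("H3 hashing is the XOR-of-selected-rows construction and linear", {
  cfg <- small_geometry()
  rows <- sample.int(2^cfg$hash_bits, cfg$suffix_bits, TRUE) - 1L
  expect_identical(h3_hash(0, rows), 0L)
  for (i in seq_along(rows))
    expect_identical(h3_hash(2^(i - 1), rows), rows[i])
  expect_identical(h3_hash(2^0 + 2^2, rows), bitwXor(rows[1], rows[3]))
  set.seed(104)
  for (k in 1:25) {
    a <- sample(0:(2^cfg$suffix_bits - 1), 1)
    b <- sample(0:(2^cfg$suffix_bits - 1), 1)
    expect_identical(h3_hash(bitwXor(a, b), rows),
                     bitwXor(h3_hash(a, rows), h3_hash(b, rows)))
  }
})

test_that("table addresses combine prefix and hash; buckets are disjoint", {
  cfg <- index_config()
  expect_identical(table_address(0, 0, cfg), 0)
  expect_identical(table_address(2^16 - 1, 2^12 - 1, cfg), 2^28 - 1)
  # two different buckets can never share an address
  expect_true(table_address(3, 2^12 - 1, cfg) < table_address(4, 0, cfg))
})

test_that("index build/lookup agrees with the k-mer dictionary oracle", {
  cfg <- small_geometry()
  k <- cfg$seed_len
  set.seed(105)
  genome <- random_dna(2000)
  idx <- build_index(genome, cfg)
  dict <- oracle_kmer_dict(genome, k)

  # completeness: every indexed position is retrievable from its own k-mer
  for (p in seq(0, nchar(genome) - k, by = 17)) {
    km <- substr(genome, p + 1, p + k)
    expect_true(p %in% lookup(idx, km))
  }
  # lookup is a superset of the true positions, bounded by the slot count
  for (km in names(dict)[seq(1, length(dict), by = 37)]) {
    got <- lookup(idx, km)
    expect_true(all(dict[[km]] %in% got))
    expect_identical(anyDuplicated(got), 0L)
  }
  # absent k-mer whose slot is empty yields the empty set
  absent <- "AAAAAAA"
  while (!is.null(dict[[absent]])) absent <- random_dna(k)
  got <- lookup(idx, absent)
  expect_true(length(got) == 0 || all(!(substring(genome, got + 1,
                                                  got + k) == absent)))
  # every position is stored exactly once across direct + collision storage
  expect_identical(sum(idx$cflag == 0L) + length(idx$collision),
                   nchar(genome) - k + 1L)
  # collision-table length equals positions stored in c=1 slots
  expect_identical(length(idx$collision), sum(idx$n_stored[idx$cflag == 1L]))
})

test_that("a repeated seed moves all its positions to the collision table", {
  cfg <- small_geometry()
  k <- cfg$seed_len
  core <- "ACGTTCA"
  set.seed(106)
  genome <- paste0(core, random_dna(50), core, random_dna(50))
  idx <- build_index(genome, cfg)
  pos <- lookup(idx, core)
  expect_true(all(oracle_kmer_positions(genome, core) %in% pos))
  packed <- pack_kmer(core, k)
  ps <- split_prefix_suffix(packed, cfg)
  slot <- table_address(ps$prefix,
                        h3_hash(ps$suffix, idx$h3[ps$prefix + 1, ]), cfg)
  i <- match(slot, idx$slots)
  expect_identical(idx$cflag[i], 1L)
  expect_gte(idx$count[i], 2L)
})

test_that("exhaustive position recovery on a 10 kb genome", {
  cfg <- small_geometry(rng_seed = 9L)
  k <- cfg$seed_len
  set.seed(107)
  genome <- random_dna(10000)
  idx <- build_index(genome, cfg)
  g_codes <- encode_bases(genome)
  ok <- vapply(seq(0, nchar(genome) - k), function(p) {
    p %in% lookup(idx, g_codes[(p + 1):(p + k)])
  }, TRUE)
  expect_true(all(ok))
})

test_that("degenerate genomes are rejected with clear errors", {
  cfg <- small_geometry()
  expect_error(build_index("ACGT", cfg), "shorter than seed length")
})

test_that("primary entries pack into the 32-bit c|count|ptr layout", {
  expect_identical(pack_primary_entry(1, 2, 5),
                   2^31 + 2 * 2^24 + 5)  # 0x80000000 | (2<<24) | 5
  expect_identical(pack_primary_entry(0, 1, 2^24 - 1), 2^24 + 2^24 - 1)
  expect_error(pack_primary_entry(0, 200, 0))
})

test_that("index serialization round-trips and detects corruption", {
  td <- withr::local_tempdir()
  cfg <- small_geometry()
  set.seed(108)
  genome <- random_dna(3000)
  idx <- build_index(genome, cfg)
  f1 <- file.path(td, "a.idx"); f2 <- file.path(td, "b.idx")
  save_index(idx, f1)
  idx2 <- load_index(f1)
  save_index(idx2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # identical lookup behaviour after the round-trip
  for (p in seq(0, nchar(genome) - cfg$seed_len, by = 113)) {
    km <- substr(genome, p + 1, p + cfg$seed_len)
    expect_identical(sort(lookup(idx2, km)), sort(lookup(idx, km)))
  }
  # truncation and bad magic are rejected
  raw <- readBin(f1, "raw", file.size(f1))
  writeBin(raw[1:40], f2)
  expect_error(load_index(f2), "truncated")
  raw[1] <- as.raw(0)
  writeBin(raw, f2)
  expect_error(load_index(f2), "magic")
})

test_that("default geometry addresses 2^28 slots; scaled geometries keep the invariants", {
  cfg <- index_config()
  expect_identical(2^(cfg$prefix_bits + cfg$hash_bits), 2^28)
  # geometry independence: a different split preserves retrievability
  cfg2 <- index_config(seed_len = 9L, prefix_bits = 10L, hash_bits = 5L,
                       rng_seed = 3L)
  set.seed(109)
  genome <- random_dna(1500)
  idx <- build_index(genome, cfg2)
  for (p in seq(0, nchar(genome) - 9, by = 23)) {
    expect_true(p %in% lookup(idx, substr(genome, p + 1, p + 9)))
  }
})
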