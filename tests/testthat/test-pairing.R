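test_that("proper pairs respect the insert window and FR orientation", {
  pp <- pair_params()  # D = 200, sd = 20, k = 3
  h1 <- data.frame(strand = "forward", ref_start = 1000L, score = 0)
  mk2 <- function(pos) data.frame(strand = "reverse", ref_start = pos,
                                  score = 0)
  # insert exactly D: reported first
  exact <- pair_both_mapped(h1, mk2(1000L + 200L - 76L), 76L, 76L, pp)
  expect_identical(nrow(exact), 1L)
  expect_identical(exact$insert, 200L)
  # window boundary: D + k*sd is in, D + k*sd + 1 is out
  edge_in <- pair_both_mapped(h1, mk2(1000L + 260L - 76L), 76L, 76L, pp)
  expect_identical(nrow(edge_in), 1L)
  edge_out <- pair_both_mapped(h1, mk2(1000L + 261L - 76L), 76L, 76L, pp)
  expect_identical(nrow(edge_out), 0L)
  # same strand is never a proper pair
  same <- pair_both_mapped(h1, data.frame(strand = "forward",
                                          ref_start = 1124L, score = 0),
                           76L, 76L, pp)
  expect_identical(nrow(same), 0L)
  # ranking: lower combined score first, then closest to D
  h2 <- rbind(mk2(1124L), mk2(1114L))
  h2$score <- c(2, 0)
  ranked <- pair_both_mapped(h1, h2, 76L, 76L, pp)
  expect_identical(ranked$p2[1], 1114L)
})

test_that("simulated proper pairs fall inside the 3-sigma window", {
  set.seed(401)
  g <- random_genome(40000, 402)
  cfg <- sim_config(genome_len = 40000, n_reads = 400, read_len = 50,
                    err_rate = 0, indel_prob = 0, paired = TRUE,
                    rng_seed = 403)
  sim <- simulate_reads(g, cfg)
  t1 <- sim$truth[grepl("/1$", sim$truth$read_id), ]
  t2 <- sim$truth[grepl("/2$", sim$truth$read_id), ]
  ins <- t2$true_pos + 50 - t1$true_pos
  expect_gte(mean(abs(ins - 200) <= 60), 0.99)
})

test_that("SW rescue finds a mate planted at distance D and matches the SW oracle", {
  set.seed(404)
  g_str <- random_dna(5000)
  g <- encode_bases(g_str)
  pp <- pair_params()
  anchor <- 1000L
  mate_pos <- anchor + 200L - 60L  # outer distance exactly D
  mate_bases <- substr(g_str, mate_pos + 1, mate_pos + 60)
  mate <- encode_read("m/2", oracle_revcomp(mate_bases))
  hit <- sw_rescue(mate, g, anchor, "forward", 60L, pp)
  expect_false(is.null(hit))
  expect_identical(hit$strand, "reverse")
  expect_identical(hit$ref_start, mate_pos)
  expect_identical(hit$score, 0)
  # the reported SW score equals the textbook full-matrix oracle on the
  # same window
  lo <- anchor + 200L - 60L - 60L
  hi <- anchor + 200L + 60L
  window <- g[(lo + 1):hi]
  expect_equal(hit$sw_score, oracle_sw_score(mate$rc, window))
})

test_that("rescue refuses windows of unrelated sequence", {
  set.seed(405)
  g <- encode_bases(random_dna(5000))
  pp <- pair_params()
  refused <- 0L
  for (i in 1:20) {
    mate <- encode_read("x", random_dna(60))
    hit <- sw_rescue(mate, g, sample(1000:3000, 1), "forward", 60L, pp)
    if (is.null(hit)) refused <- refused + 1L
    else expect_gte(hit$identity, pp$rescue_min_identity)
  }
  expect_identical(refused, 20L)
})

test_that("the three-case pairing scheme pairs, rescues, and stays empty", {
  set.seed(406)
  g_str <- random_dna(8000)
  g <- encode_bases(g_str)
  pp <- pair_params()
  # case 1: both ends exact substrings at distance D
  p1 <- 2000L
  p2 <- p1 + 200L - 60L
  r1 <- encode_read("p/1", substr(g_str, p1 + 1, p1 + 60))
  r2 <- encode_read("p/2", oracle_revcomp(substr(g_str, p2 + 1, p2 + 60)))
  res1 <- data.frame(read_id = "p/1", strand = "forward", ref_start = p1,
                     score = 0)
  res2 <- data.frame(read_id = "p/2", strand = "reverse", ref_start = p2,
                     score = 0)
  both <- pair_reads(res1, res2, list(r1), list(r2), g, pp)
  expect_identical(both$source, "both_mapped")
  expect_identical(both$p1, p1)
  expect_identical(both$p2, p2)
  expect_identical(both$insert, 200L)

  # case 2: end 2 unmapped (no hits): rescued from the window
  none <- res2[0, ]
  resc <- pair_reads(res1, none, list(r1), list(r2), g, pp)
  expect_identical(resc$source, "rescued_end2")
  expect_identical(resc$p2, p2)

  # case 3 mirror
  resc1 <- pair_reads(none, res2, list(r1), list(r2), g, pp)
  expect_identical(resc1$source, "rescued_end1")
  expect_identical(resc1$p1, p1)

  # neither end mapped: empty output
  expect_identical(nrow(pair_reads(res1[0, ], res2[0, ], list(r1), list(r2),
                                   g, pp)), 0L)
})

test_that("pairing is symmetric under swapping the two ends", {
  set.seed(407)
  g_str <- random_dna(10000)
  g <- encode_bases(g_str)
  pp <- pair_params()
  reads1 <- list(); reads2 <- list(); rows1 <- list(); rows2 <- list()
  for (i in 1:8) {
    p1 <- sample(1000:8000, 1)
    p2 <- p1 + sample(180:220, 1) - 60L
    id1 <- sprintf("s%02d/1", i); id2 <- sprintf("s%02d/2", i)
    reads1[[i]] <- encode_read(id1, substr(g_str, p1 + 1, p1 + 60))
    reads2[[i]] <- encode_read(id2, oracle_revcomp(substr(g_str, p2 + 1,
                                                          p2 + 60)))
    rows1[[i]] <- data.frame(read_id = id1, strand = "forward",
                             ref_start = p1, score = 0)
    rows2[[i]] <- data.frame(read_id = id2, strand = "reverse",
                             ref_start = p2, score = 0)
  }
  res1 <- do.call(rbind, rows1); res2 <- do.call(rbind, rows2)
  ab <- pair_reads(res1, res2, reads1, reads2, g, pp)
  ba <- pair_reads(res2, res1, reads2, reads1, g, pp)
  expect_identical(ab$p1, ba$p2)
  expect_identical(ab$p2, ba$p1)
  expect_identical(ab$insert, ba$insert)
  # every reported pair satisfies the window and opposite strands
  expect_true(all(abs(ab$insert - 200) <= 60))
  expect_true(all(ab$strand1 != ab$strand2))
})
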