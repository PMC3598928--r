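# Geometry used in the small worked examples: no head, 4 bp blocks (the
# three-block illustration layout); the full-width default is head 4 +
# 8 bp blocks.
p_illus <- banded_params(head_width = 0L, block_width = 4L)
p_full <- banded_params()

test_that("banded NW scores identities, substrings and forced gaps", {
  s <- random_dna(12)
  expect_identical(banded_nw(s, s, 1)$score, 0)
  # trailing reference bases are free; a leading reference base costs one
  # indel inside the window (the shifted engine, not a free gap, recovers
  # alignments that start left of the window)
  expect_identical(banded_nw("ACGT", "ACGTT", 1)$score, 0)
  expect_identical(banded_nw("ACGT", "AACGTT", 1)$score, 1)
  expect_identical(full_nw("AC", "A"), 1)
  expect_error(banded_nw("", "ACGT"), "empty read")
})

test_that("banded NW equals the brute-force path-enumeration oracle", {
  set.seed(301)
  for (i in 1:150) {
    n <- sample(1:8, 1); m <- sample(max(1, n - 2):(n + 2), 1)
    rd <- sample(0:3, n, TRUE); rf <- sample(0:3, m, TRUE)
    d <- sample(c(1L, 2L), 1)
    expect_identical(banded_nw(rd, rf, d)$score, oracle_banded(rd, rf, d),
                     label = sprintf("case %d", i))
    expect_identical(full_nw(rd, rf), oracle_banded(rd, rf, -1))
  }
})

test_that("band restriction only raises scores: full <= banded", {
  set.seed(302)
  for (i in 1:100) {
    n <- sample(2:20, 1)
    rd <- sample(0:3, n, TRUE); rf <- sample(0:3, n, TRUE)
    expect_lte(full_nw(rd, rf), banded_nw(rd, rf, 1)$score)
    expect_lte(banded_nw(rd, rf, 2)$score, banded_nw(rd, rf, 1)$score)
  }
})

test_that("block partition geometry matches the design layouts", {
  rd <- random_dna(12); wn <- random_dna(12)
  pb <- partition_blocks(rd, wn, p_illus)
  expect_null(pb$head)
  expect_length(pb$blocks, 3L)
  expect_true(all(vapply(pb$blocks, ncol, 0L) == 4L))

  rd100 <- random_dna(100); wn100 <- random_dna(100)
  pb100 <- partition_blocks(rd100, wn100, p_full)
  expect_identical(ncol(pb100$head), 4L)
  expect_length(pb100$blocks, 12L)

  pb20 <- partition_blocks(random_dna(20), random_dna(20), p_full)
  expect_length(pb20$blocks, 2L)
  expect_identical(vapply(pb20$blocks, ncol, 0L), c(8L, 8L))
})

test_that("initial block: off-diagonal exits of an all-match block cost one indel", {
  allmatch <- matrix(0, 3, 4, dimnames = list(c("u", "m", "l"), NULL))
  allmatch[1, 1] <- Inf  # column 1's upper cell is the DP boundary
  bs <- align_block_initial(allmatch)
  expect_identical(unname(bs$scores), c(1, 0, 1))
  expect_identical(bs$starts, list(u = "m", m = "m", l = "m"))
})

test_that("later block: all-match block passes each diagonal through freely", {
  allmatch <- matrix(0, 3, 4, dimnames = list(c("u", "m", "l"), NULL))
  bs <- align_block_later(allmatch)
  expect_identical(unname(bs$scores), c(0, 0, 0))
  expect_identical(bs$starts, list(u = "u", m = "m", l = "l"))
})

test_that("later-block transfer tables equal exhaustive path enumeration", {
  # reconstruct sequences realizing a random substitution matrix is not
  # always possible; instead check against independent enumeration on the
  # real sequences' blocks
  set.seed(303)
  for (i in 1:40) {
    rd <- sample(0:3, 8, TRUE); rf <- sample(0:3, 8, TRUE)
    pb <- partition_blocks(rd, rf, p_illus)
    tr <- block_transfers_cpp(rd, rf, 0L, 4L)
    for (b in seq_along(pb$blocks)[-1]) {
      Tr <- block_transfer_r(pb$blocks[[b]])
      expect_equal(unname(Tr), unname(tr$transfers[[b - 1]]))
    }
  }
})

test_that("concatenation reproduces the printed worked-example chain", {
  S1 <- block_score(c(1, 0, 1), list("m", "m", "m"))
  S2 <- block_score(c(1, 2, 2), list("m", "m", "m"))
  S3 <- block_score(c(1, 2, 3), list("u", "u", c("u", "l")))
  S23 <- concatenate_blocks(S2, S3, threshold = 3)
  expect_identical(unname(S23$scores), c(2, 3, Inf))
  expect_identical(S23$starts[c("u", "m")], list(u = "m", m = "m"))
  S123 <- concatenate_blocks(S1, S23, threshold = 3)
  expect_identical(unname(S123$scores), c(2, 3, Inf))
  expect_identical(finalize_score(S123), 2)
})

test_that("the neutral element leaves any block score unchanged", {
  set.seed(304)
  for (i in 1:10) {
    sc <- sample(0:5, 3, TRUE)
    st <- lapply(1:3, function(j) sample(c("u", "m", "l"), sample(1:2, 1)))
    bs <- block_score(sc, st)
    out <- concatenate_blocks(identity_block_score(), bs)
    expect_identical(out$scores, bs$scores)
  }
  expect_identical(finalize_score(block_score(c(Inf, Inf, Inf),
                                              list(character(0), character(0),
                                                   character(0)))), Inf)
})

test_that("exact block mode equals banded NW; heuristic never scores lower", {
  set.seed(305)
  for (i in 1:400) {
    n <- sample(4:96, 1)
    m <- n + sample(-1:1, 1)
    rd <- sample(0:3, n, TRUE)
    rf <- if (runif(1) < 0.5) sample(0:3, m, TRUE) else {
      # related pair: mutate a copy so non-trivial scores arise
      x <- rd[seq_len(min(n, m))]
      idx <- sample(length(x), min(length(x), sample(0:5, 1)))
      x[idx] <- sample(0:3, length(idx), TRUE)
      if (m > length(x)) c(x, sample(0:3, m - length(x), TRUE)) else x
    }
    o <- banded_nw(rd, rf, 1)$score
    expect_identical(block_align(rd, rf, p_full, Inf, "exact"), o)
    expect_gte(block_align(rd, rf, p_full, Inf, "heuristic"), o)
  }
})

test_that("threshold pruning never changes a surviving score", {
  set.seed(306)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    rd <- sample(0:3, n, TRUE)
    rf <- rd
    idx <- sample(n, sample(0:6, 1))
    rf[idx] <- sample(0:3, length(idx), TRUE)
    thr <- error_threshold(n)
    unpruned <- block_align(rd, rf, p_full, Inf, "exact")
    pruned <- block_align(rd, rf, p_full, thr, "exact")
    if (unpruned <= thr) expect_identical(pruned, unpruned)
    else expect_identical(pruned, Inf)
  }
})

test_that("exact concatenation is associative in any composition order", {
  set.seed(307)
  minplus <- function(A, B) {
    C <- matrix(Inf, 3, 3)
    for (e in 1:3) for (x in 1:3)
      C[e, x] <- min(A[e, ] + B[, x])
    C
  }
  for (i in 1:25) {
    rd <- sample(0:3, 20, TRUE); rf <- sample(0:3, 20, TRUE)
    tr <- block_transfers_cpp(rd, rf, 0L, 4L)
    Ts <- tr$transfers
    left <- Reduce(minplus, Ts)
    right <- Reduce(minplus, Ts, right = TRUE)
    # balanced tree
    tree <- function(lst) {
      if (length(lst) == 1) return(lst[[1]])
      h <- ceiling(length(lst) / 2)
      minplus(tree(lst[seq_len(h)]), tree(lst[-seq_len(h)]))
    }
    expect_equal(left, right)
    expect_equal(left, tree(Ts))
    # composing with the initial vector reproduces the engine's score
    v <- tr$initial
    for (Tm in Ts) v <- vapply(1:3, function(x) min(v + Tm[, x]), 0)
    expect_identical(min(v), block_align(rd, rf, p_illus, Inf, "exact"))
  }
})

test_that("R-level block algebra reproduces the compiled heuristic engine", {
  set.seed(308)
  for (i in 1:50) {
    n <- sample(8:48, 1)
    rd <- sample(0:3, n, TRUE)
    rf <- rd
    idx <- sample(n, sample(0:4, 1))
    rf[idx] <- sample(0:3, length(idx), TRUE)
    pb <- partition_blocks(rd, rf, p_illus)
    acc <- align_block_initial(pb$blocks[[1]])
    for (b in seq_along(pb$blocks)[-1])
      acc <- concatenate_blocks(acc, align_block_later(pb$blocks[[b]]))
    expect_identical(finalize_score(acc),
                     block_align(rd, rf, p_illus, Inf, "heuristic"))
  }
})

test_that("dual engine recovers alignments starting one base left of the window", {
  set.seed(309)
  for (i in 1:20) {
    genome <- encode_bases(random_dna(500))
    w <- sample(50:400, 1)
    L <- 30L
    # read = genome[w-1] + genome[w .. w+L-2]: true start is w-1
    rd <- c(genome[w], genome[(w + 1):(w + L - 1)])
    win <- fetch_window(genome, w, L)
    res <- dual_engine_align(rd, win, "forward", p_full, Inf, "exact", "t")
    shifted_ref <- c(win$shifted, win$shifted_extra)
    normal_ref <- c(win$normal, win$normal_extra)
    s_s <- banded_nw(rd, shifted_ref, 1)$score
    s_n <- banded_nw(rd, normal_ref, 1)$score
    expect_lt(s_s, s_n)
    expect_identical(res$engine, "shifted")
    expect_identical(res$ref_start, w - 1L)
    expect_identical(res$score, s_s)
  }
})

test_that("an exact window match scores zero through the normal engine", {
  genome <- encode_bases(random_dna(300))
  win <- fetch_window(genome, 100L, 40L)
  rd <- genome[101:140]
  res <- dual_engine_align(rd, win, "forward", p_full, Inf, "exact", "t")
  expect_identical(res$score, 0)
  expect_identical(res$engine, "normal")
  expect_identical(res$ref_start, 100L)
})

test_that("missing right context is charged, matching the widened-region oracle", {
  set.seed(310)
  # window at the genome end: the read's last base would need the base
  # beyond the window; absent context must count as a mismatch, never a
  # free pass
  genome <- encode_bases(random_dna(200))
  L <- 29L
  ws <- 171L  # normal window [171, 200): runs to the genome end
  rd <- c(genome[(ws + 2):200], sample(0:3, 1))  # needs one base beyond end
  win <- fetch_window(genome, ws, L)
  expect_null(win$normal_extra)
  res <- dual_engine_align(rd, win, "forward", p_full, Inf, "exact", "t")
  # oracle on the true (unwidened -- the genome just ends) region
  o <- min(banded_nw(rd, genome[(ws + 1):200], 1)$score,
           banded_nw(rd, genome[ws:200], 1)$score)
  expect_identical(res$score, o)
  expect_gt(res$score, 0)
})

test_that("simulated single-indel reads score their injected error count", {
  set.seed(311)
  genome_s <- random_dna(2000)
  genome <- encode_bases(genome_s)
  for (i in 1:30) {
    p <- sample(100:1800, 1)
    L <- 40L
    tpl <- genome[(p + 1):(p + L + 1)]
    kind <- sample(c("none", "ins", "del"), 1)
    if (kind == "ins") {
      at <- sample(2:(L - 1), 1)
      rd <- append(tpl[1:(L - 1)], sample(0:3, 1), after = at)
    } else if (kind == "del") {
      at <- sample(2:L, 1)
      rd <- tpl[-at][1:L]
    } else rd <- tpl[1:L]
    injected <- if (kind == "none") 0 else 1
    win <- fetch_window(genome, p, L)
    res <- dual_engine_align(rd, win, "forward", p_full, Inf, "exact", "t")
    expect_lte(res$score, injected)
  }
})

test_that("error thresholds follow the 90%-identity rule", {
  expect_identical(error_threshold(36), 3L)
  expect_identical(error_threshold(100), 10L)
  expect_identical(error_threshold(76), 7L)
  expect_identical(error_threshold(50, 0.95), 2L)
})

test_that("the parallel cost model beats the sequential one as reads grow", {
  expect_identical(estimate_cycles(12, 4, "parallel"), 6L)
  expect_identical(estimate_cycles(12, 4, "sequential"), 12L)
  expect_identical(estimate_cycles(96, 8, "parallel"), 12L)
  for (L in c(16, 24, 48, 96)) {
    expect_lt(estimate_cycles(L, 8, "parallel"),
              estimate_cycles(L, 8, "sequential"))
  }
})
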