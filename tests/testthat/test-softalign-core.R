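test_that("similarity matrix equals elementwise cosine and transposes cleanly", {
  set.seed(31)
  A <- matrix(rnorm(32), 4, 8)
  B <- matrix(rnorm(40), 5, 8)
  D <- similarity_matrix(A, B)
  expect_equal(unclass(D), brute_cosine_matrix(A, B),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(similarity_matrix(B, A)), t(unclass(D)),
               ignore_attr = TRUE)
  expect_true(all(D >= -1 - 1e-6 & D <= 1 + 1e-6))
  # self-similarity diagonal is exactly 1
  expect_equal(unname(diag(similarity_matrix(A, A))), rep(1, 4),
               tolerance = 1e-12)
  expect_equal(similarity_matrix(matrix(c(1, 0), 1), matrix(c(0, 1), 1))[1, 1], 0)
  expect_error(similarity_matrix(A, matrix(rnorm(10), 5, 2)), "dimension")
  expect_error(similarity_matrix(rbind(A, 0), B), "zero-norm")
})

test_that("candidate lists hold the top-t indices, ties to the lower index", {
  D <- matrix(c(0.2, 0.9, 0.5, 0.1), 1, 4, byrow = TRUE)
  cl <- candidate_lists(D, t = 3L)
  expect_equal(cl$C_q[[1]], c(2L, 3L, 1L))
  # tie 0.5 at columns 3 and 4 -> lower index first
  Dt <- matrix(c(0.9, 0.1, 0.5, 0.5), 1, 4, byrow = TRUE)
  expect_equal(candidate_lists(Dt, 3L)$C_q[[1]], c(1L, 3L, 4L))
  # dimension smaller than t: whole dimension returned
  D1 <- matrix(0.4, 1, 1)
  cl1 <- candidate_lists(D1)
  expect_equal(cl1$C_q[[1]], 1L)
  expect_equal(cl1$C_s[[1]], 1L)
})

test_that("mutual and secondary classification follows the reciprocal rules", {
  # both diagonal cells are row- and column-argmaxes
  m1 <- classify_of(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  expect_equal(m1[m1$kind == "mutual", c("i", "j")],
               data.frame(i = 0:1, j = 0:1), ignore_attr = TRUE)
  expect_false(any(m1$kind == "secondary"))

  # off-diagonal mutual pairs are possible before filtering
  m2 <- classify_of(matrix(c(0.5, 0.6, 0.7, 0.4), 2, byrow = TRUE))
  expect_setequal(paste(m2$i[m2$kind == "mutual"], m2$j[m2$kind == "mutual"]),
                  c("0 1", "1 0"))

  # spec-sized 3x3: one mutual, secondaries only among residues free of it
  D3 <- matrix(c(0.5, 0.6, 0.4,
                 0.2, 0.9, 0.1,
                 0.45, 0.3, 0.35), 3, byrow = TRUE)
  m3 <- classify_of(D3)
  expect_equal(m3[m3$kind == "mutual", c("i", "j")],
               data.frame(i = 1L, j = 1L), ignore_attr = TRUE)
  sec <- paste(m3$i[m3$kind == "secondary"], m3$j[m3$kind == "secondary"])
  expect_true(all(c("0 0", "2 0") %in% sec))
  expect_false(any(grepl("^1 | 1$", sec)))  # residues in the mutual pair excluded

  # diagonal always records j - i
  expect_equal(m3$diagonal, m3$j - m3$i)
})

test_that("classification invariants hold on random matrices", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(2:15, 1); m <- sample(2:15, 1)
    D <- matrix(runif(n * m, -1, 1), n, m)
    ms <- classify_of(D)
    mut <- ms[ms$kind == "mutual", ]
    # one-to-one partial bijection
    expect_false(anyDuplicated(mut$i) > 0)
    expect_false(anyDuplicated(mut$j) > 0)
    # no duplicated (i, j) pair of any kind
    expect_false(anyDuplicated(ms[, c("i", "j")]) > 0)
    # mutual definition holds cell by cell
    for (r in seq_len(nrow(mut))) {
      expect_equal(which.max(D[mut$i[r] + 1L, ]), mut$j[r] + 1L)
      expect_equal(which.max(D[, mut$j[r] + 1L]), mut$i[r] + 1L)
    }
    # secondary residues never touch a mutual pair
    sec <- ms[ms$kind == "secondary", ]
    expect_length(intersect(sec$i, mut$i), 0L)
    expect_length(intersect(sec$j, mut$j), 0L)
    # symmetry: mutual pairs of t(D) are the transposed mutual pairs
    mt <- classify_of(t(D))
    mutt <- mt[mt$kind == "mutual", ]
    expect_setequal(paste(mut$i, mut$j), paste(mutt$j, mutt$i))
  }
})

test_that("diagonal filtering keeps strong diagonals and their neighbours", {
  six_on_0 <- match_set(0:5, 0:5, rep(0.9, 6))
  # a lone weak diagonal far away is removed
  f1 <- filter_diagonals(rbind(six_on_0, match_set(2, 9, 0.8)))
  expect_equal(sort(unique(f1$diagonal)), 0L)
  # a weak diagonal within the window of a >5 diagonal is rescued
  f2 <- filter_diagonals(rbind(six_on_0, match_set(c(2, 4), c(5, 7), 0.8)))
  expect_setequal(unique(f2$diagonal), c(0L, 3L))
  # exactly five mutual matches on a lone diagonal: kept (only "fewer than
  # five" are removed)
  five <- match_set(0:4, 0:4, rep(0.9, 5))
  expect_equal(nrow(filter_diagonals(five)), 5L)
  # four on a lone diagonal: removed
  four <- match_set(0:3, 0:3, rep(0.9, 4))
  expect_equal(nrow(filter_diagonals(four)), 0L)
  # neighbour rescue needs an anchor with strictly more than five
  five_plus_weak <- rbind(five, match_set(c(2, 4), c(5, 7), 0.8))
  expect_equal(sort(unique(filter_diagonals(five_plus_weak)$diagonal)), 0L)
  # secondaries on removed diagonals vanish; on retained diagonals they stay
  mixed <- rbind(six_on_0, match_set(7, 7, 0.5, kind = "secondary"),
                 match_set(1, 9, 0.5, kind = "secondary"))
  f3 <- filter_diagonals(mixed)
  expect_setequal(paste(f3$i, f3$j), c(paste(0:5, 0:5), "7 7"))
  # filtering never adds matches
  expect_lte(nrow(f3), nrow(mixed))
  # empty in, empty out
  expect_equal(nrow(filter_diagonals(six_on_0[0, ])), 0L)
})

test_that("single identical-residue gaps are rescued, longer runs are not", {
  q <- protein_record("q", "AAACAAAAAA")
  s <- protein_record("s", "AAACAAAAAA")
  D <- matrix(0.5, 10, 10); diag(D) <- 0.99
  base <- match_set(c(0:2, 4:9), c(0:2, 4:9), 0.99)  # gap at (3,3), q4==s4=="C"
  attr(base, "retained_diagonals") <- 0L
  r1 <- rescue_single_gaps(base, q, s, D)
  resc <- r1[r1$kind == "rescued", ]
  expect_equal(nrow(resc), 1L)
  expect_equal(c(resc$i, resc$j), c(3L, 3L))
  expect_equal(resc$similarity, D[4, 4])

  # differing residues at the gap: nothing added
  s2 <- protein_record("s", "AAAWAAAAAA")
  expect_equal(nrow(rescue_single_gaps(base, q, s2, D)), 9L)

  # a two-cell gap is never rescued
  base2 <- match_set(c(0:2, 5:9), c(0:2, 5:9), 0.99)
  attr(base2, "retained_diagonals") <- 0L
  r2 <- rescue_single_gaps(base2, q, s, D)
  expect_false(any(r2$kind == "rescued"))

  # X == X counts as identity
  qx <- protein_record("q", "AAAXAAAAAA")
  sx <- protein_record("s", "AAAXAAAAAA")
  r3 <- rescue_single_gaps(base, qx, sx, D)
  expect_equal(sum(r3$kind == "rescued"), 1L)

  # rescue accepts secondary flanks as retained matches
  base3 <- base
  base3$kind[base3$i == 2L] <- "secondary"
  r4 <- rescue_single_gaps(base3, q, s, D)
  expect_equal(sum(r4$kind == "rescued"), 1L)
})

test_that("chaining matches the exhaustive-subset maximum", {
  # hand example: the crossing third match is excluded
  ms <- match_set(c(0, 1, 2), c(0, 1, 0), c(0.9, 0.8, 0.7))
  res <- chain_and_score(ms, min_score = 20)
  expect_equal(res$score, 1.7, tolerance = 1e-9)
  expect_equal(paste(res$chain$i, res$chain$j), c("0 0", "1 1"))
  expect_false(res$significant)

  # empty set scores zero
  e <- chain_and_score(ms[0, ])
  expect_equal(e$score, 0)
  expect_false(e$significant)
  expect_null(e$query_range)

  # random sets against the 2^M oracle
  set.seed(55)
  for (rep in 1:60) {
    ms <- random_match_set(sample(1:12, 1))
    expect_equal(chain_and_score(ms)$score, brute_chain_score(ms),
                 tolerance = 1e-9)
  }
})

test_that("chain respects strict monotonicity and the score identity", {
  set.seed(99)
  for (rep in 1:25) {
    ms <- random_match_set(sample(2:20, 1))
    res <- chain_and_score(ms)
    ch <- res$chain
    if (nrow(ch) > 1L) {
      expect_true(all(diff(ch$i) > 0))
      expect_true(all(diff(ch$j) > 0))
    }
    expect_equal(res$score, sum(ch$similarity), tolerance = 1e-9)
    expect_identical(res$significant, res$score >= res$min_score)
  }
})

test_that("self-alignment recovers every residue with score equal to length", {
  for (L in c(25L, 135L)) {
    q <- protein_record("self", random_seq(L, seed = L))
    r <- soft_align(q, q)
    expect_equal(r$counts[["mutual"]], L)
    expect_equal(r$score, L, tolerance = 1e-6)
    expect_true(all(r$chain$diagonal == 0L))
    expect_true(r$significant)
  }
})

test_that("score is symmetric and bounded on homologous fixtures", {
  fx <- generate_homologous_pair(60, 70,
                                 blocks = data.frame(q_start = 11, offset = 8,
                                                     length = 30),
                                 seed = 21)
  r_qs <- soft_align(fx$q, fx$s, E_q = fx$E_q, E_s = fx$E_s)
  r_sq <- soft_align(fx$s, fx$q, E_q = fx$E_s, E_s = fx$E_q)
  expect_equal(r_qs$score, r_sq$score, tolerance = 1e-9)
  mut_qs <- r_qs$matches[r_qs$matches$kind == "mutual", ]
  mut_sq <- r_sq$matches[r_sq$matches$kind == "mutual", ]
  expect_setequal(paste(mut_qs$i, mut_qs$j), paste(mut_sq$j, mut_sq$i))
  expect_lte(r_qs$score, min(r_qs$n, r_qs$m) + 1e-6)
  expect_gte(r_qs$score, 0)
})

test_that("short sequences warn that filtering cannot apply", {
  q <- protein_record("tiny", "MKV")
  expect_warning(soft_align(q, q), "min_mutual")
  r <- suppressWarnings(soft_align(q, q))
  expect_equal(r$score, 0)
  r_nf <- soft_align(q, q, filter = FALSE)
  expect_equal(r_nf$score, 3, tolerance = 1e-6)
})

test_that("filtering plus rescue on a clean single diagonal leaves the chain score unchanged", {
  # all-distinct letters: every match sits on diagonal 0, nothing spurious
  q <- protein_record("clean", "ACDEFGHIKLMNPQRSTVWY")
  with_f <- soft_align(q, q)
  no_f <- soft_align(q, q, filter = FALSE)
  expect_equal(with_f$score, no_f$score, tolerance = 1e-9)
  expect_equal(with_f$score, 20, tolerance = 1e-6)

  # on noisy fixtures filtering can only remove score, never add
  fx <- generate_homologous_pair(80, 80,
                                 blocks = data.frame(q_start = 16, offset = 0,
                                                     length = 50),
                                 block_cosine = 0.99, seed = 5)
  with_f <- soft_align(fx$q, fx$s, E_q = fx$E_q, E_s = fx$E_s)
  no_f <- soft_align(fx$q, fx$s, E_q = fx$E_q, E_s = fx$E_s, filter = FALSE)
  expect_lte(with_f$score, no_f$score + 1e-9)
  expect_gte(with_f$score, 50 * 0.99 - 2)  # the planted block survives intact
})
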