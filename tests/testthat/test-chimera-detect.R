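# constructed chimera triple: parents differ at `k` diagnostic positions
# in each half, query is left-half(A) + right-half(B), no other noise
make_triple <- function(len = 400, k = 10, seed = 1) {
  withr::with_seed(seed, {
    a <- rand_dna(len)
    av <- strsplit(a, "")[[1]]
    bv <- av
    flip <- function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1)
    left_pos <- sort(sample(seq_len(len / 2), k))
    right_pos <- sort(sample((len / 2 + 1):len, k))
    for (p in c(left_pos, right_pos)) bv[p] <- flip(bv[p])
    b <- paste0(bv, collapse = "")
    q <- paste0(c(av[seq_len(len / 2)], bv[(len / 2 + 1):len]),
                collapse = "")
    list(query = q, a = a, b = b,
         left_pos = left_pos, right_pos = right_pos)
  })
}

test_that("query segmentation covers the sequence in near-equal pieces", {
  segs <- segment_query(strrep("A", 400), 4)
  expect_equal(nchar(segs), rep(100L, 4))
  segs <- segment_query("ACGTACGTAC", 4)
  expect_equal(nchar(segs), c(3L, 3L, 2L, 2L))
  for (k in 1:10) {
    s <- rand_dna(sample(10:500, 1))
    n <- sample(2:6, 1)
    expect_equal(paste0(segment_query(s, n), collapse = ""), s)
  }
  expect_error(segment_query("ACG", 4), "cleaved")
})

test_that("candidate search ranks true relatives first", {
  corpus <- generate_corpus(3, 2, 2, seed = 10)
  refs <- build_reference_set(corpus)
  # a reference queried as itself (no self-exclusion) ranks first
  p <- detector_params(self_exclude = FALSE)
  cand <- find_candidate_parents(refs$seq[1], refs, p)
  expect_equal(cand$id[1], refs$id[1])

  # a perfect chimera's candidate set contains both parents
  ann <- locate_58s(refs, consensus_58s(corpus))
  chim <- withr::with_seed(2, make_chimera_replicate(ann))
  cand <- find_candidate_parents(chim$seq[1], refs, detector_params())
  expect_true(all(c(chim$left_parent_id[1], chim$right_parent_id[1]) %in%
                    cand$id))

  # single-reference set with self-exclusion: nothing to propose
  cand <- find_candidate_parents(refs$seq[1], refs[1, ], detector_params(),
                                 query_id = refs$id[1])
  expect_equal(nrow(cand), 0L)
})

test_that("pair scoring matches hand-computed values on constructed triples", {
  tr <- make_triple(400, 10)
  p <- detector_params()
  res <- score_pair(tr$query, tr$a, tr$b, p)
  expect_equal(unname(res$votes),
               c(10L, 0L, 0L, 10L, 0L, 0L), ignore_attr = TRUE)
  expect_equal(res$score, (10 / (p$beta * p$reg))^2)
  expect_equal(res$left_parent, "A")

  # orientation symmetry: exchanging the parents preserves the score
  swapped <- score_pair(tr$query, tr$b, tr$a, p)
  expect_equal(swapped$score, res$score)
  expect_equal(swapped$left_parent, "B")

  # query identical to one parent: one side has no support, score 0
  res0 <- score_pair(tr$a, tr$a, tr$b, p)
  expect_equal(res0$score, 0)
})

test_that("score responds monotonically to added evidence", {
  p <- detector_params()
  base <- score_pair(make_triple(400, 8)$query, make_triple(400, 8)$a,
                     make_triple(400, 8)$b, p)
  more <- make_triple(400, 14)
  stronger <- score_pair(more$query, more$a, more$b, p)
  expect_gte(stronger$score, base$score)

  # turning a left yes-column into a wrong-parent vote lowers the score
  tr <- make_triple(400, 10)
  qv <- strsplit(tr$query, "")[[1]]
  bv <- strsplit(tr$b, "")[[1]]
  qv[tr$left_pos[5]] <- bv[tr$left_pos[5]]  # now matches B on the left
  noisy <- score_pair(paste0(qv, collapse = ""), tr$a, tr$b, p)
  expect_lt(noisy$score, score_pair(tr$query, tr$a, tr$b, p)$score)
})

test_that("crossover search equals an exhaustive scan on random triples", {
  set.seed(77)
  p <- detector_params(min_diffs = 1)
  for (k in 1:50) {
    base <- rand_dna(150)
    a <- mutate_sequence(base, 0.08, 0.1)
    b <- mutate_sequence(base, 0.08, 0.1)
    cut <- sample(40:110, 1)
    q <- paste0(substr(a, 1, cut), substr(b, cut + 1, nchar(b)))
    expect_equal(score_pair(q, a, b, p)$score,
                 score_pair_oracle(q, a, b, p))
  }
})

test_that("detect_one equals brute force over all pairs and crossovers", {
  set.seed(31)
  for (k in 1:30) {
    corpus <- generate_corpus(2, 2, 2, its1_len = c(60, 80),
                              its2_len = c(60, 80), r58s_len = 100,
                              seed = k)
    refs <- build_reference_set(corpus)
    p <- detector_params(hits_per_segment = nrow(refs), max_pairs = 100)
    ann <- locate_58s(refs, consensus_58s(corpus))
    query <- if (k %% 2 == 0) {
      withr::with_seed(k, make_chimera_replicate(ann))[1, c("id", "seq")]
    } else {
      corpus[sample(nrow(corpus), 1), c("id", "seq")]
    }
    call <- detect_one(query, refs, p)
    expect_equal(call$score, detect_oracle(query, refs, p))
  }
})

test_that("screening separates simulated chimeras from clean references", {
  corpus <- generate_corpus(4, 3, 3, seed = 55)
  refs <- build_reference_set(corpus)
  ann <- locate_58s(refs, consensus_58s(corpus))
  bench <- simulate_benchmark(ann, n_replicates = 2, seed = 3)
  calls <- screen_corpus(bench, refs)
  expect_s3_class(calls, "chimera_screen")
  expect_equal(nrow(calls), nrow(bench))
  expect_true(all(calls$flag == (calls$score > 0.28)))
  expect_gte(mean(calls$flag), 0.99)

  # flagged chimeras recover their true parents (as an unordered pair)
  m <- dplyr::left_join(calls, bench, by = c(query_id = "id"))
  pair_ok <- mapply(function(pa, pb, lp, rp) setequal(c(pa, pb), c(lp, rp)),
                    m$parent_a_id, m$parent_b_id,
                    m$left_parent_id, m$right_parent_id)
  expect_gte(mean(pair_ok), 0.95)

  clean <- screen_corpus(refs, refs)
  expect_lt(mean(clean$flag), 0.05)

  # empty query set
  none <- screen_corpus(refs[0, ], refs)
  expect_equal(nrow(none), 0L)
})

test_that("screening results are deterministic and exportable", {
  corpus <- generate_corpus(2, 2, 2, seed = 5)
  refs <- build_reference_set(corpus)
  c1 <- screen_corpus(corpus, refs)
  c2 <- screen_corpus(corpus, refs)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(c1, f)
  back <- read_results_table(f)
  expect_equal(nrow(back), nrow(c1))
  expect_equal(sort(back$score), sort(c1$score))
})
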