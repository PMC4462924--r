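test_that("pairwise identity handles exact and single-mismatch cases", {
  a <- strrep("ACGTT", 20)
  expect_equal(pairwise_identity(a, a), 1.0)
  b <- paste0(substr(a, 1, 49), "A", substr(a, 51, 100))
  expect_false(substr(a, 50, 50) == "A")
  expect_equal(pairwise_identity(a, b), 0.99)
  # symmetric
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
})

test_that("alignment scores agree exactly with a dynamic-programming oracle", {
  set.seed(101)
  for (k in 1:20) {
    a <- rand_dna(30); b <- rand_dna(30)
    o <- nw_oracle(a, b)
    aln <- refchimera:::.align_global(b, a)
    expect_equal(Biostrings::score(aln), o$score)
    # identity of co-optimal alignments can differ slightly between
    # tracebacks; the optimum score cannot
    expect_lt(abs(pairwise_identity(a, b) - o$identity), 0.1)
  }
  # where the optimal alignment is essentially unique, identity is exact
  for (k in 1:10) {
    a <- rand_dna(100)
    b <- withr::with_seed(k, mutate_sequence(a, 0.05, indel_fraction = 0.2))
    expect_equal(pairwise_identity(a, b), nw_oracle(a, b)$identity)
  }
})

test_that("greedy clustering follows the centroid contract", {
  recs <- tibble::tibble(id = c("a", "b", "c"), seq = rep(strrep("ACGT", 30), 3))
  expect_equal(dplyr::n_distinct(greedy_cluster(recs, 0.97)$cluster), 1L)

  # two groups at ~70% mutual identity split at 0.80
  base <- withr::with_seed(5, rand_dna(300))
  far <- withr::with_seed(6, mutate_sequence(base, 0.35, 0.1))
  recs2 <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    seq = c(base,
            withr::with_seed(7, mutate_sequence(base, 0.01)),
            far,
            withr::with_seed(8, mutate_sequence(far, 0.01))))
  expect_lt(pairwise_identity(base, far), 0.80)
  cl <- greedy_cluster(recs2, 0.80)
  expect_equal(dplyr::n_distinct(cl$cluster), 2L)
  expect_equal(cl$cluster[1], cl$cluster[2])

  # threshold 1.0 with unique sequences: all singletons
  recs3 <- tibble::tibble(id = letters[1:4],
                          seq = withr::with_seed(9, replicate(4, rand_dna(60))))
  expect_equal(dplyr::n_distinct(greedy_cluster(recs3, 1.0)$cluster), 4L)
})

test_that("species hypotheses nest monotonically across thresholds", {
  corpus <- generate_corpus(1, 4, 5, seed = 23)  # one genus, 20 records
  sh <- build_species_hypotheses(corpus)
  thresholds <- sort(unique(sh$threshold))
  for (j in seq_along(thresholds)[-1]) {
    fine <- sh[sh$threshold == thresholds[j], ]
    coarse <- sh[sh$threshold == thresholds[j - 1], ]
    parent_of <- coarse$sh_id[match(fine$member_id, coarse$member_id)]
    # every fine SH maps into exactly one coarse SH
    n_parents <- tapply(parent_of, fine$sh_id, dplyr::n_distinct)
    expect_true(all(n_parents == 1L))
  }
  # single-member input: one singleton SH per threshold
  solo <- build_species_hypotheses(corpus[1, ])
  expect_equal(nrow(solo), length(thresholds))
  expect_true(all(solo$n_members == 1L))
  expect_true(all(solo$representative_id == corpus$id[1]))
})

test_that("two species at 5% divergence give two SHs at 0.97", {
  corpus <- generate_corpus(1, 2, 4, seed = 31)
  sh <- build_species_hypotheses(corpus)
  at97 <- sh[abs(sh$threshold - 0.97) < 1e-9, ]
  expect_equal(dplyr::n_distinct(at97$sh_id), 2L)
  split_by_truth <- split(at97$member_id, at97$sh_id)
  expect_setequal(vapply(split_by_truth, function(ids)
    dplyr::n_distinct(corpus$species[match(ids, corpus$id)]), integer(1)),
    c(1L, 1L))
})

test_that("representative selection follows modal type, length, id tie-breaks", {
  expect_equal(select_representative(
    tibble::tibble(id = c("A", "B", "C"), seq = c("ACGT", "ACGT", "ACGG"))),
    "A")
  expect_equal(select_representative(
    tibble::tibble(id = "only", seq = "ACGT")), "only")
  # 3 types with counts 5/3/2: a member of the count-5 type wins
  members <- tibble::tibble(
    id = sprintf("m%02d", 1:10),
    seq = rep(c("AAAAT", "CCCCT", "GGGGT"), c(5, 3, 2)))
  expect_equal(select_representative(members), "m01")
  # tie between types: pooled members, longest sequence wins
  tie <- tibble::tibble(id = c("x", "y"), seq = c("ACGT", "ACGTA"))
  expect_equal(select_representative(tie), "y")
})

test_that("reference sets count one representative per multi-member SH", {
  corpus <- generate_corpus(3, 3, 3, seed = 13)  # 9 species x 3 seqs
  refs <- build_reference_set(corpus)
  expect_equal(nrow(refs), 9L)
  expect_true(all(refs$provenance == "automatic"))
  expect_equal(anyDuplicated(refs$id), 0L)
  # each representative is a member of its own species
  expect_equal(dplyr::n_distinct(corpus$species[match(refs$id, corpus$id)]),
               9L)
})

test_that("SH count at 0.985 matches true species with >= 2 sequences", {
  for (seed in 1:20) {
    corpus <- generate_corpus(2, 3, 3, seed = seed)
    refs <- build_reference_set(corpus)
    n_true <- sum(table(corpus$species) >= 2)
    expect_equal(nrow(refs), n_true)
  }
})

test_that("singleton policy and manual overrides behave as documented", {
  corpus <- generate_corpus(2, 2, 3, seed = 77)
  # make one species a singleton
  drop <- corpus$species == corpus$species[1] & corpus$id != corpus$id[1]
  pruned <- corpus[!drop, ]
  refs <- build_reference_set(pruned)
  expect_equal(nrow(refs), 3L)  # singleton excluded
  refs_s <- build_reference_set(pruned, sanctioned = corpus$id[1])
  expect_equal(nrow(refs_s), 4L)
  row <- refs_s[refs_s$id == corpus$id[1], ]
  expect_true(row$sanctioned_singleton)

  # override: point a multi-member SH at a non-representative member
  sh <- attr(refs, "sh_table")
  at_rep <- sh[abs(sh$threshold - 0.985) < 1e-9 & sh$n_members >= 2, ]
  target_sh <- at_rep$sh_id[1]
  members <- at_rep$member_id[at_rep$sh_id == target_sh]
  auto_rep <- at_rep$representative_id[at_rep$sh_id == target_sh][1]
  alt <- setdiff(members, auto_rep)[1]
  refs_o <- build_reference_set(pruned,
                                overrides = tibble::tibble(
                                  sh_id = target_sh, record_id = alt))
  row <- refs_o[refs_o$sh_id == target_sh, ]
  expect_equal(row$id, alt)
  expect_equal(row$provenance, "manual")

  # invalid overrides error
  expect_error(build_reference_set(pruned,
                                   overrides = tibble::tibble(
                                     sh_id = "SHnope", record_id = alt)),
               "unknown species hypothesis")
  outsider <- setdiff(pruned$id, members)[1]
  expect_error(build_reference_set(pruned,
                                   overrides = tibble::tibble(
                                     sh_id = target_sh,
                                     record_id = outsider)),
               "not a member")
})

test_that("reference-set construction is deterministic", {
  corpus <- generate_corpus(2, 2, 3, seed = 4)
  r1 <- build_reference_set(corpus)
  r2 <- build_reference_set(corpus[sample(nrow(corpus)), ])
  expect_equal(dplyr::arrange(tibble::as_tibble(r1), id)[c("id", "seq", "sh_id")],
               dplyr::arrange(tibble::as_tibble(r2), id)[c("id", "seq", "sh_id")])
})
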