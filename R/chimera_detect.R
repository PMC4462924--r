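#' Chimera detector parameters
#'
#' Reference-mode detection settings. The query is cleaved into
#' `n_segments` contiguous segments (default 4); candidate parents are the
#' top `hits_per_segment` references per segment by shared `word_size`-mer
#' count; up to `max_pairs` candidate pairs are scored over all crossover
#' positions, and a query is flagged when its best score exceeds
#' `threshold` (default 0.28).
#'
#' The score of a parent pair at a crossover is the product of two
#' per-side vote ratios `Y / (beta * (N + reg) + alpha * A)`, where on
#' each side `Y` counts columns supporting that side's parent (query
#' matches it, differs from the other), `N` columns supporting the wrong
#' parent, and `A` abstentions (query differs from both). `reg` is a
#' pseudo-count prior on wrong-parent votes, so a side with no opposing
#' evidence still needs several supporting columns before it contributes;
#' `min_diffs` yes-votes are additionally required on each side for a
#' non-zero score. The score is unbounded above: clear chimeras commonly
#' score in the tens to hundreds, while clean queries whose mismatches
#' scatter over both putative parents stay well below the 0.28 default
#' threshold.
#'
#' @param n_segments Number of query segments (>= 2, default 4).
#' @param threshold Flagging threshold on the score (default 0.28).
#' @param word_size k-mer length for candidate search (default 8).
#' @param hits_per_segment Candidates retained per segment (default 4).
#' @param max_pairs Maximum ordered candidate pairs scored (default 24).
#' @param beta Weight of a wrong-parent ("no") vote (default 8).
#' @param alpha Weight of an abstention (default 0.5).
#' @param reg Pseudo-count prior on wrong-parent votes (default 1.4).
#' @param min_diffs Minimum yes-votes per side (default 3).
#' @param self_exclude Drop references whose id equals the query id
#'   (default TRUE).
#' @return A list of class `"detector_params"`.
#' @export
detector_params <- function(n_segments = 4, threshold = 0.28,
                            word_size = 8, hits_per_segment = 4,
                            max_pairs = 24, beta = 8, alpha = 0.5,
                            reg = 1.4, min_diffs = 3, self_exclude = TRUE) {
  stopifnot(n_segments >= 2, threshold > 0, word_size >= 1,
            hits_per_segment >= 1, max_pairs >= 1, beta > 0,
            alpha >= 0, reg > 0, min_diffs >= 1)
  structure(list(n_segments = n_segments, threshold = threshold,
                 word_size = word_size,
                 hits_per_segment = hits_per_segment,
                 max_pairs = max_pairs, beta = beta, alpha = alpha,
                 reg = reg, min_diffs = min_diffs,
                 self_exclude = self_exclude),
            class = "detector_params")
}

#' Cleave a query sequence into contiguous segments
#'
#' Segments cover the sequence exactly and their lengths differ by at most
#' one, longer segments first.
#'
#' @param seq A DNA string of length >= `n_segments`.
#' @param n_segments Number of segments.
#' @return A character vector of `n_segments` subsequences.
#' @export
#' @examples
#' segment_query("ACGTACGTAC", 4)  # lengths 3, 3, 2, 2
segment_query <- function(seq, n_segments = 4) {
  len <- nchar(seq)
  if (len < n_segments) {
    stop("sequence of length ", len, " cannot be cleaved into ",
         n_segments, " segments", call. = FALSE)
  }
  base <- len %/% n_segments
  sizes <- rep(base, n_segments)
  extra <- len %% n_segments
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  substring(seq, starts, ends)
}

# distinct k-mers of one sequence
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Build a k-mer index over a reference set
#'
#' Maps each distinct `word_size`-mer to the reference rows containing it;
#' built once per reference set and reused across queries.
#'
#' @param refset Reference record tibble (`id`, `seq`).
#' @param word_size k-mer length.
#' @return An opaque index object for [find_candidate_parents()].
#' @export
build_kmer_index <- function(refset, word_size = 8) {
  stopifnot(is.data.frame(refset))
  km <- lapply(refset$seq, .kmers, k = word_size)
  idx <- split(rep.int(seq_len(nrow(refset)), lengths(km)), unlist(km))
  structure(list(index = idx, ids = refset$id, n = nrow(refset),
                 word_size = word_size),
            class = "kmer_index")
}

#' Find candidate parent references for a query
#'
#' For each query segment, references are ranked by the count of distinct
#' shared `word_size`-mers (ties broken by id, references sharing no word
#' ranking last); the top `hits_per_segment` references per segment are
#' retained, and the candidate set is their union.
#'
#' @param query_seq Query sequence string.
#' @param refset Reference record tibble (`id`, `seq`).
#' @param params A [detector_params()] object.
#' @param query_id Optional query id, used for self-exclusion.
#' @param index Optional prebuilt [build_kmer_index()] for `refset`.
#' @return A tibble of candidates: `id`, `total_count` (shared words
#'   summed over segments), `rank` (1 = best), ordered best first. May be
#'   empty.
#' @export
find_candidate_parents <- function(query_seq, refset,
                                   params = detector_params(),
                                   query_id = NULL, index = NULL) {
  stopifnot(nrow(refset) >= 1)
  if (is.null(index)) index <- build_kmer_index(refset, params$word_size)
  keep <- rep(TRUE, length(index$ids))
  if (isTRUE(params$self_exclude) && !is.null(query_id)) {
    keep <- index$ids != query_id
  }
  segments <- segment_query(query_seq, params$n_segments)
  chosen <- integer(0)
  total <- numeric(length(index$ids))
  for (seg in segments) {
    hits <- unlist(index$index[.kmers(seg, index$word_size)],
                   use.names = FALSE)
    if (is.null(hits)) hits <- integer(0)  # no shared words at all
    counts <- tabulate(hits, nbins = index$n)
    counts[!keep] <- 0L
    total <- total + counts
    # all retained references are ranked (zero-count ones last), so a
    # hits_per_segment >= |refset| admits every possible parent
    pos <- which(keep)
    if (length(pos) == 0L) next
    pos <- pos[order(-counts[pos], index$ids[pos])]
    chosen <- union(chosen, pos[seq_len(min(params$hits_per_segment,
                                            length(pos)))])
  }
  if (length(chosen) == 0L) {
    return(tibble(id = character(0), total_count = numeric(0),
                  rank = integer(0)))
  }
  out <- tibble(id = index$ids[chosen], total_count = total[chosen])
  out <- arrange(out, desc(.data$total_count), .data$id)
  mutate(out, rank = row_number())
}

# project `parents` onto query coordinates: global alignment, then drop
# columns where the query has a gap (parent insertions). Returns a list of
# character vectors of length nchar(query); "-" marks a parent deletion.
.project_parents <- function(query_seq, parent_seqs) {
  aln <- .align_global(parent_seqs, query_seq)
  # pattern()/subject() return the aligned strings restricted to the
  # pattern's aligned span; query (= subject) positions outside it are
  # terminal parent deletions, padded below as "-"
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "", fixed = TRUE)
  sub <- strsplit(as.character(Biostrings::subject(aln)), "", fixed = TRUE)
  s_aln <- Biostrings::subject(aln)
  s_start <- BiocGenerics::start(s_aln)
  s_end <- BiocGenerics::end(s_aln)
  len <- nchar(query_seq)
  lapply(seq_along(pat), function(i) {
    out <- rep("-", len)
    out[s_start[i]:s_end[i]] <- pat[[i]][sub[[i]] != "-"]
    out
  })
}

# vote-based crossover search on projected columns (see detector_params).
# qv, pa, pb: character vectors of identical length (query coordinates).
.score_projected <- function(qv, pa, pb, params) {
  ya <- qv == pa & qv != pb    # supports A
  yb <- qv == pb & qv != pa    # supports B
  ab <- qv != pa & qv != pb    # abstain
  info <- which(ya | yb | ab)
  empty <- list(score = 0, crossover = NA_integer_,
                votes = c(Y_L = 0L, N_L = 0L, A_L = 0L,
                          Y_R = 0L, N_R = 0L, A_R = 0L),
                left_parent = "A")
  m <- length(info)
  if (m == 0L) return(empty)
  cya <- c(0L, cumsum(ya[info]))
  cyb <- c(0L, cumsum(yb[info]))
  cab <- c(0L, cumsum(ab[info]))
  side <- function(y, n, a) {
    y / (params$beta * (n + params$reg) + params$alpha * a)
  }
  best <- empty
  for (left_parent in c("A", "B")) {
    yl <- if (left_parent == "A") cya else cyb
    yr_tot <- if (left_parent == "A") cyb[m + 1L] else cya[m + 1L]
    nl <- if (left_parent == "A") cyb else cya
    Y_L <- yl
    N_L <- nl
    A_L <- cab
    Y_R <- yr_tot - nl
    N_R <- (if (left_parent == "A") cya[m + 1L] else cyb[m + 1L]) - yl
    A_R <- cab[m + 1L] - cab
    s <- side(Y_L, N_L, A_L) * side(Y_R, N_R, A_R)
    s[Y_L < params$min_diffs | Y_R < params$min_diffs] <- 0
    x <- which.max(s)
    if (s[x] > best$score) {
      best <- list(score = s[x], crossover = x - 1L,
                   votes = c(Y_L = Y_L[x], N_L = N_L[x], A_L = A_L[x],
                             Y_R = Y_R[x], N_R = N_R[x], A_R = A_R[x]),
                   left_parent = left_parent)
    }
  }
  best
}

#' Score one parent pair against a query
#'
#' Aligns both putative parents to the query, projects the alignments
#' onto query coordinates, and searches all crossover positions (gaps
#' between informative columns) and both parent orientations for the
#' maximal chimera score (see [detector_params()] for the score
#' definition). Symmetric in the two parents.
#'
#' @param query_seq,parent_a_seq,parent_b_seq Non-empty DNA strings.
#' @param params A [detector_params()] object.
#' @return A list: `score`, `crossover` (index into the informative
#'   columns; the cut lies after that many informative columns),
#'   `votes` (named Y/N/A counts per side at the optimum, oriented so the
#'   left side is the left parent's), and `left_parent` (`"A"` or `"B"`).
#' @export
score_pair <- function(query_seq, parent_a_seq, parent_b_seq,
                       params = detector_params()) {
  stopifnot(nzchar(query_seq), nzchar(parent_a_seq), nzchar(parent_b_seq))
  proj <- .project_parents(query_seq, c(parent_a_seq, parent_b_seq))
  qv <- strsplit(query_seq, "", fixed = TRUE)[[1]]
  .score_projected(qv, proj[[1]], proj[[2]], params)
}

# shared scoring core: score every candidate pair for one query, given
# precomputed projections; returns the best call as a one-row tibble.
.detect_core <- function(query_id, query_seq, cand, refset, params) {
  null_call <- tibble(query_id = query_id, score = 0,
                      parent_a_id = NA_character_,
                      parent_b_id = NA_character_,
                      crossover = NA_integer_,
                      y_l = 0L, n_l = 0L, a_l = 0L,
                      y_r = 0L, n_r = 0L, a_r = 0L, flag = FALSE)
  if (nrow(cand) < 2L) return(null_call)
  pairs <- utils::combn(seq_len(nrow(cand)), 2L)
  pair_rank <- cand$rank[pairs[1L, ]] + cand$rank[pairs[2L, ]]
  ord <- order(pair_rank, cand$id[pairs[1L, ]], cand$id[pairs[2L, ]])
  ord <- ord[seq_len(min(params$max_pairs, length(ord)))]
  ref_rows <- match(cand$id, refset$id)
  proj <- .project_parents(query_seq, refset$seq[ref_rows])
  qv <- strsplit(query_seq, "", fixed = TRUE)[[1]]
  best <- NULL
  best_score <- -1
  for (j in ord) {
    ia <- pairs[1L, j]; ib <- pairs[2L, j]
    res <- .score_projected(qv, proj[[ia]], proj[[ib]], params)
    if (res$score > best_score) {
      best_score <- res$score
      # orient so parent_a is the left-side parent
      ab <- if (res$left_parent == "A") c(ia, ib) else c(ib, ia)
      best <- list(res = res, a = ab[1L], b = ab[2L])
    }
  }
  if (is.null(best) || best$res$score <= 0) return(null_call)
  v <- best$res$votes
  tibble(query_id = query_id, score = best$res$score,
         parent_a_id = cand$id[best$a], parent_b_id = cand$id[best$b],
         crossover = best$res$crossover,
         y_l = unname(v["Y_L"]), n_l = unname(v["N_L"]),
         a_l = unname(v["A_L"]),
         y_r = unname(v["Y_R"]), n_r = unname(v["N_R"]),
         a_r = unname(v["A_R"]),
         flag = best$res$score > params$threshold)
}

#' Detect whether one query is a reference-mode chimera
#'
#' Finds candidate parents by shared-word counting, scores up to
#' `max_pairs` candidate pairs (ordered by combined k-mer rank) over all
#' crossovers and orientations, and reports the maximum-scoring call.
#'
#' @param query One-row record tibble (or any row with `id`, `seq`).
#' @param refset Reference record tibble.
#' @param params A [detector_params()] object.
#' @param index Optional prebuilt [build_kmer_index()] for `refset`.
#' @return A one-row call tibble: `query_id`, `score`, `parent_a_id`
#'   (left-side parent), `parent_b_id`, `crossover`, the six vote counts
#'   `y_l`..`a_r`, and logical `flag` (`score > threshold`). An empty
#'   candidate set yields score 0 and `flag = FALSE`.
#' @export
detect_one <- function(query, refset, params = detector_params(),
                       index = NULL) {
  stopifnot(is.data.frame(query), nrow(query) == 1L, nrow(refset) >= 1L)
  cand <- find_candidate_parents(query$seq, refset, params,
                                 query_id = query$id, index = index)
  .detect_core(query$id, query$seq, cand, refset, params)
}

#' Screen a query collection against a chimera-free reference set
#'
#' Runs [detect_one()] for every query, reusing one k-mer index across the
#' corpus. Deterministic given its inputs.
#'
#' @param queries Record tibble of queries (`id`, `seq`).
#' @param refset Reference record tibble.
#' @param params A [detector_params()] object.
#' @return A tibble of calls (class `"chimera_screen"`), one row per
#'   query, with the columns of [detect_one()]; detector parameters are
#'   attached as attribute `"params"`. Use [glance()] for summary counts,
#'   [bin_scores()] for score bins, and [write_results_table()] to export.
#' @export
screen_corpus <- function(queries, refset, params = detector_params()) {
  stopifnot(is.data.frame(queries), is.data.frame(refset))
  if (nrow(queries) == 0L) {
    out <- .detect_core("x", "ACGT", tibble(id = character(0)),
                        refset, params)[0, ]
  } else {
    validate_records(refset)
    index <- build_kmer_index(refset, params$word_size)
    out <- bind_rows(lapply(seq_len(nrow(queries)), function(i) {
      cand <- find_candidate_parents(queries$seq[i], refset, params,
                                     query_id = queries$id[i],
                                     index = index)
      .detect_core(queries$id[i], queries$seq[i], cand, refset, params)
    }))
  }
  class(out) <- c("chimera_screen", class(out))
  attr(out, "params") <- params
  out
}
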