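#' Bisect annotated sequences at the 5.8S midpoint
#'
#' The cut position is `r58s_start + floor((r58s_end - r58s_start) / 2)`
#' (0-based; floor rule for odd 5.8S lengths), so each sequence splits
#' into ITS1 + the first half of 5.8S, and the remainder of 5.8S + ITS2.
#' Concatenating the two fragments reproduces the input exactly.
#'
#' @param records An annotated record tibble (`id`, `seq`, `r58s_start`,
#'   `r58s_end`); rows with missing annotation are an error.
#' @return A tibble with columns `id`, `cut`, `left`, `right`.
#' @export
bisect_58s <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "seq", "r58s_start", "r58s_end") %in%
                  names(records)))
  if (anyNA(records$r58s_start) || anyNA(records$r58s_end)) {
    stop("missing 5.8S annotation for id(s): ",
         paste(records$id[is.na(records$r58s_start) |
                            is.na(records$r58s_end)], collapse = ", "),
         call. = FALSE)
  }
  cut <- records$r58s_start +
    floor((records$r58s_end - records$r58s_start) / 2)
  tibble(id = records$id,
         cut = as.integer(cut),
         left = substr(records$seq, 1L, cut),
         right = substr(records$seq, cut + 1L, nchar(records$seq)))
}

# uniform random derangement by rejection sampling (expected ~e tries)
.random_derangement <- function(n) {
  stopifnot(n >= 2)
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Build one replicate of simulated chimeras from a reference set
#'
#' Every reference is bisected at its 5.8S midpoint and the right halves
#' are reassigned to the left halves by a uniformly sampled derangement:
#' each fragment is used exactly once, and no fragment regrafts onto its
#' own parent. Output size equals input size.
#'
#' Draws from R's global random number stream; use [simulate_benchmark()]
#' (or [withr::with_seed()]) for seeded reproducibility.
#'
#' @param records Annotated reference records (at least 2 rows).
#' @param prefix Prefix for chimera ids (default `"chim"`).
#' @return A tibble of chimeras: `id`, `seq`, `left_parent_id`,
#'   `right_parent_id`, `breakpoint` (position of the join in chimera
#'   coordinates, equal to the left parent's cut).
#' @export
make_chimera_replicate <- function(records, prefix = "chim") {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) {
    stop("at least 2 annotated references are required (no derangement ",
         "exists for n = 1)", call. = FALSE)
  }
  halves <- bisect_58s(records)
  p <- .random_derangement(nrow(halves))
  tibble(
    id = sprintf("%s_%05d", prefix, seq_len(nrow(halves))),
    seq = paste0(halves$left, halves$right[p]),
    left_parent_id = halves$id,
    right_parent_id = halves$id[p],
    breakpoint = halves$cut
  )
}

#' Simulate a multi-replicate chimera benchmark
#'
#' Repeats [make_chimera_replicate()] `n_replicates` times from a single
#' seed-derived random stream, mirroring the classic evaluation design in
#' which the whole reference set is turned into chimeras ten times over.
#'
#' @param records Annotated reference records.
#' @param n_replicates Number of replicates (default 10).
#' @param seed Integer seed; the benchmark is a pure function of its
#'   arguments.
#' @return A tibble of chimeras with a leading `replicate` column.
#' @export
#' @examples
#' corpus <- generate_corpus(2, 2, 2, seed = 1)
#' bench <- simulate_benchmark(corpus, n_replicates = 2, seed = 7)
#' dplyr::count(bench, replicate)
simulate_benchmark <- function(records, n_replicates = 10, seed = 1) {
  stopifnot(n_replicates >= 1)
  withr::with_seed(as.integer(seed), {
    bind_rows(lapply(seq_len(n_replicates), function(r) {
      mutate(make_chimera_replicate(records,
                                    prefix = sprintf("rep%02d", r)),
             replicate = r, .before = 1L)
    }))
  })
}
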