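#' Locate the 5.8S gene by consensus-anchored alignment
#'
#' Aligns a 5.8S consensus against each record with the consensus forced
#' to align end-to-end inside the record (pattern-global, subject-local),
#' the appropriate regime for a short, highly conserved gene embedded in
#' variable spacers. The best placement defines the 5.8S interval; ITS1 is
#' everything before it and ITS2 everything after. Records whose best
#' placement scores below `min_score` are marked not found (with a
#' warning) rather than aborting the run.
#'
#' @param records A record tibble (`id`, `seq`).
#' @param consensus A 5.8S consensus string (e.g. from [consensus_58s()]).
#' @param min_score Minimum alignment score to accept a placement;
#'   default half the maximum attainable score
#'   (`0.5 * nchar(consensus)` with the +1/-1 scoring).
#' @return `records` with added 0-based half-open region columns
#'   (`its1_start` ... `its2_end`), the placement `aln_score`, and a
#'   logical `r58s_found`. Coordinates are `NA` where not found.
#' @export
locate_58s <- function(records, consensus,
                       min_score = 0.5 * nchar(consensus)) {
  stopifnot(is.data.frame(records), nzchar(consensus))
  validate_records(records)
  too_short <- nchar(records$seq) <= nchar(consensus)
  n <- nrow(records)
  start <- end <- rep(NA_integer_, n)
  score <- rep(NA_real_, n)
  submat <- .iupac_submat()
  for (i in seq_len(n)) {
    if (too_short[i]) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(consensus),
      subject = Biostrings::DNAString(records$seq[i]),
      type = "global-local",
      substitutionMatrix = submat,
      gapOpening = GAP_OPEN, gapExtension = GAP_EXT
    )
    score[i] <- Biostrings::score(aln)
    rng <- aln@subject@range
    start[i] <- BiocGenerics::start(rng) - 1L  # to 0-based
    end[i] <- BiocGenerics::end(rng)
  }
  found <- !too_short & !is.na(score) & score >= min_score
  if (any(!found)) {
    warning("5.8S not found in ", sum(!found), " record(s): ",
            paste(utils::head(records$id[!found], 10), collapse = ", "),
            if (sum(!found) > 10) ", ..." else "",
            call. = FALSE)
  }
  len <- nchar(records$seq)
  mutate(as_tibble(records),
         its1_start = ifelse(found, 0L, NA_integer_),
         its1_end = ifelse(found, start, NA_integer_),
         r58s_start = ifelse(found, start, NA_integer_),
         r58s_end = ifelse(found, end, NA_integer_),
         its2_start = ifelse(found, end, NA_integer_),
         its2_end = ifelse(found, len, NA_integer_),
         aln_score = score,
         r58s_found = found)
}

#' Extract ITS1-only and ITS2-only views of an annotated collection
#'
#' Slices the annotated ITS1 and ITS2 subregions out of each record,
#' producing the subregion files that accompany a full-length reference
#' set. Records lacking an annotation (`r58s_found == FALSE` or `NA`
#' coordinates) and empty subregions are dropped with a warning.
#'
#' @param records An annotated record tibble, e.g. from [locate_58s()] or
#'   [generate_corpus()].
#' @return A tibble with columns `id` (suffix-tagged, e.g. `"x|ITS1"`),
#'   `source_id`, `region` (`"ITS1"`/`"ITS2"`), and `seq`.
#' @export
extract_subregions <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "seq", "its1_start", "its1_end",
                  "its2_start", "its2_end") %in% names(records)))
  ok <- if ("r58s_found" %in% names(records)) records$r58s_found else
    !is.na(records$its1_end)
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    warning(sum(!ok), " record(s) without a 5.8S annotation excluded ",
            "from subregion extraction", call. = FALSE)
  }
  ann <- records[ok, , drop = FALSE]
  long <- bind_rows(
    tibble(source_id = ann$id, region = "ITS1",
           seq = substr(ann$seq, ann$its1_start + 1L, ann$its1_end)),
    tibble(source_id = ann$id, region = "ITS2",
           seq = substr(ann$seq, ann$its2_start + 1L, ann$its2_end))
  )
  empty <- !nzchar(long$seq)
  if (any(empty)) {
    warning(sum(empty), " empty subregion(s) dropped: ",
            paste(utils::head(paste0(long$source_id[empty], "|",
                                     long$region[empty]), 10),
                  collapse = ", "),
            call. = FALSE)
    long <- long[!empty, , drop = FALSE]
  }
  mutate(long, id = paste0(.data$source_id, "|", .data$region),
         .before = 1L)
}
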