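#' Read a FASTA file into a sequence record tibble
#'
#' Parses a (possibly multi-line) FASTA file into the tabular record form
#' used throughout the package: one row per sequence with the header token
#' before the first whitespace as `id` and the remainder as `description`.
#' Sequences are uppercased on ingest and validated against the IUPAC
#' nucleotide alphabet (`ACGTRYSWKMBDHVN`).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`, in file order.
#' @details Duplicate ids, empty sequences, and non-IUPAC characters are
#'   errors (the message names the offending id, and for alphabet
#'   violations the first bad position). An empty file yields a zero-row
#'   tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "ACGT", "ACGT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(id = character(), description = character(),
                  seq = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("Not a FASTA file (first non-blank line is not a header): ", path,
         call. = FALSE)
  }
  rec_idx <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!is_header], rec_idx[!is_header]),
                 paste0, character(1), collapse = "")
  # headers with no sequence lines at all are absent from `seqs`
  seq <- character(length(headers))
  seq[as.integer(names(seqs))] <- seqs
  records <- tibble(id = id, description = description,
                    seq = toupper(seq))
  validate_records(records)
  records
}

#' Validate a sequence record tibble
#'
#' Checks the record invariants shared by every collection in the package:
#' unique ids, non-empty sequences, IUPAC-only alphabet.
#'
#' @param records A tibble with at least `id` and `seq` columns.
#' @return `records`, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  empty <- records$id[!nzchar(records$seq)]
  if (length(empty) > 0L) {
    stop("empty sequence for id(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_CODES, collapse = "")),
                 records$seq)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    stop(sprintf("non-IUPAC character '%s' in sequence '%s' at position %d",
                 substr(records$seq[i], bad[i], bad[i]),
                 records$id[i], bad[i]),
         call. = FALSE)
  }
  invisible(records)
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces
#' `id`, `description` and `seq` exactly.
#'
#' @param records Tibble with `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @param wrap Line width for sequence lines (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 80) {
  stopifnot(is.data.frame(records), wrap >= 1)
  if (nrow(records) > 0L) validate_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else
      records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a chimera-screening results table
#'
#' Tab-separated, one row per query, fixed column order
#' (`score`, `query_id`, `parent_a_id`, `parent_b_id`, `crossover`, `flag`),
#' sorted by descending score then query id. `flag` is written as `Y`/`N`.
#'
#' @param calls A tibble of chimera calls (e.g. from [screen_corpus()]),
#'   with columns `query_id`, `score`, `parent_a_id`, `parent_b_id`,
#'   `crossover` and a logical (or `Y`/`N`) `flag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  flag <- calls$flag %||% logical(0)
  if (is.logical(flag)) flag <- ifelse(flag, "Y", "N")
  rows <- tibble(
    score = as.numeric(calls$score %||% numeric(0)),
    query_id = as.character(calls$query_id %||% character(0)),
    parent_a_id = as.character(calls$parent_a_id %||% character(0)),
    parent_b_id = as.character(calls$parent_b_id %||% character(0)),
    crossover = as.integer(calls$crossover %||% integer(0)),
    flag = flag
  )
  rows <- arrange(rows, desc(.data$score), .data$query_id)
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to a results TSV.
#' @return A tibble with the written columns; `flag` as logical.
#' @export
read_results_table <- function(path) {
  rows <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            score = readr::col_double(),
                            query_id = readr::col_character(),
                            parent_a_id = readr::col_character(),
                            parent_b_id = readr::col_character(),
                            crossover = readr::col_integer(),
                            flag = readr::col_character()
                          ))
  mutate(rows, flag = .data$flag == "Y")
}

#' Write a region-annotation table
#'
#' Coordinates are 0-based, half-open throughout the package; the written
#' file records this convention in a leading comment line.
#'
#' @param records Tibble with `id` and the six region columns
#'   `its1_start`, `its1_end`, `r58s_start`, `r58s_end`, `its2_start`,
#'   `its2_end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(records, path) {
  cols <- c("id", "its1_start", "its1_end", "r58s_start", "r58s_end",
            "its2_start", "its2_end")
  stopifnot(all(cols %in% names(records)))
  con <- file(path, open = "wt")
  writeLines("# coordinates are 0-based, half-open [start, end)", con)
  close(con)
  readr::write_tsv(records[, cols], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a region-annotation table written by [write_region_table()]
#'
#' @param path Path to an annotation TSV.
#' @return A tibble with `id` and the six region columns.
#' @export
read_region_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    .default = readr::col_integer()
                  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# checks the six region columns against the ordering invariant
# 0 <= its1_start < ... <= its2_end <= len(seq)  (its1/its2 may be empty)
.check_regions <- function(records) {
  with(records, {
    ok <- its1_start >= 0 & its1_start <= its1_end &
      its1_end <= r58s_start & r58s_start < r58s_end &
      r58s_end <= its2_start & its2_start <= its2_end &
      its2_end == nchar(seq)
    if (!all(ok)) {
      stop("invalid region annotation for id(s): ",
           paste(records$id[!ok], collapse = ", "), call. = FALSE)
    }
  })
  invisible(records)
}
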