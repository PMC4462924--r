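#' Global pairwise sequence identity
#'
#' Identity of the optimal global alignment (match +1, mismatch -1, gap of
#' length L costing 2 + L), defined as matching columns divided by
#' alignment columns after trimming terminal gap columns. Ambiguity codes
#' match only themselves. Symmetric in its arguments.
#'
#' @param a A single DNA string.
#' @param b A character vector of DNA strings (vectorized).
#' @return A numeric vector of identities in `[0, 1]`, one per element of
#'   `b`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", c("ACGTACGT", "ACGTACGA"))
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), all(nzchar(b)))
  aln <- .align_global(b, a)
  # pattern()/subject() drop terminal pattern-gap columns, which the
  # trimming step below removes anyway; they are much cheaper to extract
  # than the fully padded aligned strings
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "", fixed = TRUE)
  sub <- strsplit(as.character(Biostrings::subject(aln)), "", fixed = TRUE)
  vapply(seq_along(pat), function(i) {
    p <- pat[[i]]; s <- sub[[i]]
    both <- which(p != "-" & s != "-")
    if (length(both) == 0L) return(0)
    cols <- both[1L]:both[length(both)]   # trim terminal gap columns
    sum(p[cols] == s[cols]) / length(cols)
  }, numeric(1))
}

#' Clustering and reference-set parameters
#'
#' Bundles the thresholds of the two-round clustering scheme: a coarse
#' genus-level pass (default 80% identity) followed by species-hypothesis
#' (SH) clustering at stepped thresholds from 97% to 100% in 0.5% steps.
#' Representatives are drawn at the 98.5% threshold, and SHs below
#' `min_sh_size` members are singletons, excluded from the reference set
#' unless explicitly sanctioned.
#'
#' @param genus_threshold Coarse clustering identity threshold
#'   (default 0.80).
#' @param sh_thresholds Ascending SH thresholds
#'   (default `seq(0.97, 1.00, by = 0.005)`).
#' @param representative_threshold Threshold whose SHs feed the reference
#'   set (default 0.985); must be one of `sh_thresholds`.
#' @param min_sh_size Minimum SH size for automatic inclusion (default 2).
#' @return A list of class `"sh_params"`.
#' @export
sh_params <- function(genus_threshold = 0.80,
                      sh_thresholds = seq(0.97, 1.00, by = 0.005),
                      representative_threshold = 0.985,
                      min_sh_size = 2) {
  stopifnot(genus_threshold > 0, genus_threshold <= 1,
            all(sh_thresholds > 0), all(sh_thresholds <= 1),
            !is.unsorted(sh_thresholds),
            any(abs(sh_thresholds - representative_threshold) < 1e-9),
            min_sh_size >= 1)
  structure(list(genus_threshold = genus_threshold,
                 sh_thresholds = sh_thresholds,
                 representative_threshold = representative_threshold,
                 min_sh_size = min_sh_size),
            class = "sh_params")
}

#' Greedy centroid clustering at an identity threshold
#'
#' Deterministic single-pass centroid clustering: records are processed in
#' decreasing length order (ties broken by lexicographic id); each record
#' joins the first existing centroid (in founding order) whose
#' [pairwise_identity()] to it meets the threshold, otherwise it founds a
#' new centroid.
#'
#' @param records A record tibble (`id`, `seq`, other columns preserved).
#' @param threshold Identity threshold in `(0, 1]`.
#' @return `records` with an added `cluster` column holding the centroid
#'   record's id.
#' @export
greedy_cluster <- function(records, threshold) {
  stopifnot(is.data.frame(records), threshold > 0, threshold <= 1)
  validate_records(records)
  if (nrow(records) == 0L) {
    return(mutate(records, cluster = character(0)))
  }
  ord <- order(-nchar(records$seq), records$id)
  cent_id <- character(0)
  cent_seq <- character(0)
  assign <- character(nrow(records))
  for (i in ord) {
    s <- records$seq[i]
    joined <- FALSE
    if (length(cent_seq) > 0L) {
      ident <- pairwise_identity(s, cent_seq)
      hit <- which(ident >= threshold - 1e-12)
      if (length(hit) > 0L) {
        assign[i] <- cent_id[hit[1L]]
        joined <- TRUE
      }
    }
    if (!joined) {
      cent_id <- c(cent_id, records$id[i])
      cent_seq <- c(cent_seq, s)
      assign[i] <- records$id[i]
    }
  }
  mutate(records, cluster = assign)
}

# deterministic content hash for SH ids (FNV-1a style, 32-bit)
.sh_hash <- function(member_ids, threshold) {
  key <- paste(c(sort(member_ids), sprintf("%.4f", threshold)),
               collapse = "|")
  h <- 2166136261
  for (code in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("SH%08X.%03d", as.integer(h), as.integer(round(threshold * 1000)))
}

#' Species-hypothesis clustering at stepped thresholds
#'
#' Within one coarse (genus-level) cluster, clusters the members at each
#' threshold in `params$sh_thresholds`. Thresholds are applied in
#' ascending order and each level subdivides the clusters of the previous
#' one, so SHs refine monotonically: every SH at a threshold `t` is
#' contained in exactly one SH at any lower threshold.
#'
#' @param records Members of one genus-level cluster (tibble with `id`,
#'   `seq`).
#' @param params An [sh_params()] object.
#' @return A tibble with one row per (threshold, member): `threshold`,
#'   `sh_id` (content-derived, deterministic), `member_id`,
#'   `representative_id` (see [select_representative()]) and `n_members`.
#' @export
build_species_hypotheses <- function(records, params = sh_params()) {
  stopifnot(is.data.frame(records))
  validate_records(records)
  groups <- list(records$id)
  out <- vector("list", length(params$sh_thresholds))
  for (j in seq_along(params$sh_thresholds)) {
    t <- params$sh_thresholds[j]
    new_groups <- list()
    for (ids in groups) {
      sub <- records[match(ids, records$id), , drop = FALSE]
      cl <- greedy_cluster(sub, t)
      new_groups <- c(new_groups, split(cl$id, cl$cluster))
    }
    groups <- unname(new_groups)
    out[[j]] <- bind_rows(lapply(groups, function(ids) {
      ids <- sort(ids)  # canonical order: output independent of input order
      members <- records[match(ids, records$id), , drop = FALSE]
      tibble(threshold = t,
             sh_id = .sh_hash(ids, t),
             member_id = ids,
             representative_id = select_representative(members),
             n_members = length(ids))
    })) |>
      arrange(.data$sh_id, .data$member_id)
  }
  bind_rows(out)
}

#' Select the representative sequence of a species hypothesis
#'
#' Members are grouped into sequence types by exact (uppercased) string
#' equality; the most frequent type wins. Ties between types are resolved
#' among their pooled members; within the winning set the longest sequence
#' wins, and remaining ties go to the lexicographically smallest id. Fully
#' deterministic.
#'
#' @param members Tibble of SH members (`id`, `seq`).
#' @return The representative record's id (length-1 character).
#' @export
#' @examples
#' select_representative(tibble::tibble(id = c("A", "B", "C"),
#'                                      seq = c("ACGT", "ACGT", "ACGG")))
select_representative <- function(members) {
  stopifnot(is.data.frame(members), nrow(members) >= 1)
  counts <- table(members$seq)
  modal_types <- names(counts)[counts == max(counts)]
  pool <- members[members$seq %in% modal_types, , drop = FALSE]
  pool <- pool[order(-nchar(pool$seq), pool$id), , drop = FALSE]
  pool$id[1L]
}

#' Build a chimera-control reference set
#'
#' The full pipeline of the reference-set compilation: coarse clustering
#' at `genus_threshold`, SH clustering within each coarse cluster at the
#' stepped thresholds, then one sequence per SH at the representative
#' threshold. Singleton SHs (fewer than `min_sh_size` members) are
#' excluded unless their member id appears in `sanctioned`. Manual
#' `overrides` replace the automatic representative of an SH and are
#' recorded with provenance `"manual"`.
#'
#' @param records The input record tibble (`id`, `description`, `seq`).
#' @param params An [sh_params()] object.
#' @param overrides Optional tibble with columns `sh_id`, `record_id`
#'   naming a member that supersedes the automatic representative.
#'   Referencing an unknown SH or a non-member id is an error.
#' @param sanctioned Character vector of record ids whose singleton SHs
#'   are sanctioned as formal species hypotheses.
#' @return A tibble of reference records (one per retained SH): `id`,
#'   `description`, `seq`, `sh_id`, `n_members`, `provenance`
#'   (`"automatic"`/`"manual"`), `sanctioned_singleton`. The complete SH
#'   membership table across all thresholds is attached as attribute
#'   `"sh_table"`.
#' @export
build_reference_set <- function(records, params = sh_params(),
                                overrides = NULL, sanctioned = character()) {
  stopifnot(is.data.frame(records))
  validate_records(records)
  clustered <- greedy_cluster(records, params$genus_threshold)
  sh_table <- clustered |>
    group_by(.data$cluster) |>
    dplyr::group_map(~ build_species_hypotheses(.x, params)) |>
    bind_rows()
  at_rep <- filter(sh_table,
                   abs(.data$threshold - params$representative_threshold) <
                     1e-9)
  shs <- at_rep |>
    group_by(.data$sh_id) |>
    summarise(representative_id = .data$representative_id[1L],
              n_members = .data$n_members[1L],
              member_ids = list(.data$member_id), .groups = "drop")
  keep <- shs$n_members >= params$min_sh_size |
    vapply(shs$member_ids, function(ids) any(ids %in% sanctioned),
           logical(1))
  shs <- shs[keep, , drop = FALSE]
  shs$provenance <- "automatic"
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    stopifnot(all(c("sh_id", "record_id") %in% names(overrides)))
    for (i in seq_len(nrow(overrides))) {
      j <- which(shs$sh_id == overrides$sh_id[i])
      if (length(j) != 1L) {
        stop("override references unknown species hypothesis: ",
             overrides$sh_id[i], call. = FALSE)
      }
      if (!overrides$record_id[i] %in% shs$member_ids[[j]]) {
        stop(sprintf("override record '%s' is not a member of SH '%s'",
                     overrides$record_id[i], overrides$sh_id[i]),
             call. = FALSE)
      }
      shs$representative_id[j] <- overrides$record_id[i]
      shs$provenance[j] <- "manual"
    }
  }
  refset <- records[match(shs$representative_id, records$id), , drop = FALSE]
  refset$sh_id <- shs$sh_id
  refset$n_members <- shs$n_members
  refset$provenance <- shs$provenance
  refset$sanctioned_singleton <- shs$n_members < params$min_sh_size
  refset <- arrange(as_tibble(refset), .data$sh_id)
  attr(refset, "sh_table") <- sh_table
  refset
}
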