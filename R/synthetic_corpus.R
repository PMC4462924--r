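#' Mutate a DNA sequence by random substitutions and indels
#'
#' Each position is hit by a mutation event independently with probability
#' `divergence`. A fraction `indel_fraction` of events are single-base
#' indels (half deletions, half insertions before the position); the rest
#' are substitutions to one of the three other bases, never reproducing
#' the original base.
#'
#' Draws from R's global random number stream: wrap calls in
#' [withr::with_seed()] (or `set.seed()`) for reproducibility.
#'
#' @param seq A DNA string.
#' @param divergence Per-position mutation probability in `[0, 1]`.
#' @param indel_fraction Fraction of mutation events that are indels
#'   (default 0).
#' @return The mutated sequence string.
#' @export
#' @examples
#' withr::with_seed(1, mutate_sequence("ACGTACGTACGT", 0.25))
mutate_sequence <- function(seq, divergence, indel_fraction = 0) {
  stopifnot(divergence >= 0, divergence <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  if (divergence == 0 || !nzchar(seq)) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hit <- which(stats::runif(n) < divergence)
  if (length(hit) == 0L) return(seq)
  is_indel <- stats::runif(length(hit)) < indel_fraction
  out <- as.list(chars)
  for (k in seq_along(hit)) {
    i <- hit[k]
    if (is_indel[k]) {
      if (stats::runif(1) < 0.5) {
        out[[i]] <- character(0)                        # deletion
      } else {
        out[[i]] <- c(sample(bases, 1L), chars[i])      # insertion before i
      }
    } else {
      out[[i]] <- sample(setdiff(bases, chars[i]), 1L)  # substitution
    }
  }
  paste0(unlist(out), collapse = "")
}

#' Generate a synthetic fungal-ITS-like corpus with known truth
#'
#' Emulates the structure of a curated fungal ITS collection: a highly
#' conserved 5.8S gene flanked by the variable ITS1 and ITS2 spacers, with
#' hierarchical divergence tiers (genus > species > individual) so that
#' similarity clustering at the usual thresholds recovers the taxonomy.
#' Every record carries its exact region boundaries and taxonomic labels,
#' providing ground truth for clustering, extraction and detection tests.
#'
#' Construction: one corpus-level 5.8S ancestor is mutated (substitutions
#' only) at `r58s_div` once per species; corpus-level root spacers are
#' mutated at `inter_genus_div` to give per-genus ITS1/ITS2 ancestors
#' (independently for the two spacers), at `inter_species_div` from genus
#' to species templates, and at `intra_species_div` from species template
#' to each record. Indels are confined to the spacers so the 5.8S anchor
#' and its midpoint stay well defined.
#'
#' @param n_genera,species_per_genus,seqs_per_species Corpus shape.
#' @param its1_len,its2_len Length ranges (2-vectors) for the root spacers,
#'   drawn uniformly; defaults give a mean total length of about 550 bp.
#' @param r58s_len Length of the 5.8S gene (default 158).
#' @param inter_genus_div,inter_species_div,intra_species_div,r58s_div
#'   Divergence tiers; must satisfy
#'   `intra_species_div < inter_species_div < inter_genus_div`.
#' @param indel_fraction Fraction of spacer mutation events that are
#'   single-base indels (default 0.1).
#' @param seed Integer seed; the corpus is a pure function of the
#'   arguments including `seed`.
#' @return A tibble with one row per record: `id`, `description`, `seq`,
#'   truth labels `genus`, `species`, and exact 0-based half-open region
#'   columns `its1_start`, `its1_end`, `r58s_start`, `r58s_end`,
#'   `its2_start`, `its2_end`. The corpus-level 5.8S ancestor is attached
#'   as attribute `"r58s_ancestor"` (see [consensus_58s()]).
#' @export
#' @examples
#' corpus <- generate_corpus(2, 2, 3, seed = 1)
#' dplyr::count(corpus, species)
generate_corpus <- function(n_genera = 8, species_per_genus = 3,
                            seqs_per_species = 3,
                            its1_len = c(170, 220), its2_len = c(172, 222),
                            r58s_len = 158,
                            inter_genus_div = 0.25,
                            inter_species_div = 0.05,
                            intra_species_div = 0.005,
                            r58s_div = 0.002,
                            indel_fraction = 0.1,
                            seed = 1) {
  stopifnot(n_genera >= 1, species_per_genus >= 1, seqs_per_species >= 1,
            r58s_len > 0, length(its1_len) == 2, length(its2_len) == 2,
            all(its1_len > 0), all(its2_len > 0),
            intra_species_div >= 0,
            intra_species_div < inter_species_div,
            inter_species_div < inter_genus_div,
            inter_genus_div <= 1)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste0(sample(bases, n, replace = TRUE),
                                 collapse = "")
  withr::with_seed(as.integer(seed), {
    root_58s <- rand_seq(r58s_len)
    root_its1 <- rand_seq(sample(its1_len[1]:its1_len[2], 1L))
    root_its2 <- rand_seq(sample(its2_len[1]:its2_len[2], 1L))
    rows <- vector("list", n_genera * species_per_genus * seqs_per_species)
    k <- 0L
    for (g in seq_len(n_genera)) {
      genus <- sprintf("g%02d", g)
      g_its1 <- mutate_sequence(root_its1, inter_genus_div, indel_fraction)
      g_its2 <- mutate_sequence(root_its2, inter_genus_div, indel_fraction)
      for (s in seq_len(species_per_genus)) {
        species <- sprintf("%s_s%02d", genus, s)
        sp_its1 <- mutate_sequence(g_its1, inter_species_div, indel_fraction)
        sp_its2 <- mutate_sequence(g_its2, inter_species_div, indel_fraction)
        sp_58s <- mutate_sequence(root_58s, r58s_div, 0)  # no indels in 5.8S
        for (r in seq_len(seqs_per_species)) {
          its1 <- mutate_sequence(sp_its1, intra_species_div, indel_fraction)
          its2 <- mutate_sequence(sp_its2, intra_species_div, indel_fraction)
          n1 <- nchar(its1); n58 <- nchar(sp_58s)
          k <- k + 1L
          rows[[k]] <- tibble(
            id = sprintf("%s_r%02d", species, r),
            description = sprintf("synthetic ITS genus=%s species=%s",
                                  genus, species),
            seq = paste0(its1, sp_58s, its2),
            genus = genus, species = species,
            its1_start = 0L, its1_end = n1,
            r58s_start = n1, r58s_end = n1 + n58,
            its2_start = n1 + n58, its2_end = n1 + n58 + nchar(its2)
          )
        }
      }
    }
    corpus <- bind_rows(rows)
    .check_regions(corpus)
    attr(corpus, "r58s_ancestor") <- root_58s
    corpus
  })
}

#' 5.8S consensus of a record collection
#'
#' For a corpus generated by [generate_corpus()] this returns the stored
#' 5.8S ancestor. For any other collection carrying region annotations it
#' computes a per-column majority consensus over the annotated 5.8S
#' slices (columns are positional; the slices are near-identical by
#' definition of the gene, so no alignment is performed).
#'
#' @param records An annotated record tibble.
#' @return A single 5.8S consensus string, usable as the anchor for
#'   [locate_58s()].
#' @export
consensus_58s <- function(records) {
  anc <- attr(records, "r58s_ancestor", exact = TRUE)
  if (!is.null(anc)) return(anc)
  stopifnot(all(c("r58s_start", "r58s_end", "seq") %in% names(records)),
            nrow(records) > 0)
  slices <- substr(records$seq, records$r58s_start + 1L, records$r58s_end)
  len <- min(nchar(slices))
  mat <- do.call(rbind, strsplit(substr(slices, 1L, len), "", fixed = TRUE))
  paste0(apply(mat, 2L, function(col) names(which.max(table(col)))),
         collapse = "")
}
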