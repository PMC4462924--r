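# Independent oracles used across the test suite. These deliberately
# re-derive results by brute force (explicit DP, exhaustive enumeration)
# rather than calling the code paths they check.

rand_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- global affine-gap alignment oracle (match +1, mismatch -1,
# gap of length L costs 2 + L), with traceback-based identity ------------
nw_oracle <- function(a, b, open = 2, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- -(open + (1:n) * ext)
  if (m > 0) Y[1, 2:(m + 1)] <- -(open + (1:m) * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) 1 else -1
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback one optimal alignment (M preferred, then X, then Y)
  ac <- bc <- character(0)
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  while (i > 0 || j > 0) {
    if (state == 1) {
      s <- if (av[i] == bv[j]) 1 else -1
      prev <- c(M[i, j], X[i, j], Y[i, j])
      ac <- c(av[i], ac); bc <- c(bv[j], bc)
      state <- which.max(round(prev + s, 9) == round(M[i + 1, j + 1], 9))
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      prev <- c(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                Y[i, j + 1] - open - ext)
      ac <- c(av[i], ac); bc <- c("-", bc)
      state <- which.max(round(prev, 9) == round(X[i + 1, j + 1], 9))
      i <- i - 1
    } else {
      prev <- c(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                Y[i + 1, j] - ext)
      ac <- c("-", ac); bc <- c(bv[j], bc)
      state <- which.max(round(prev, 9) == round(Y[i + 1, j + 1], 9))
      j <- j - 1
    }
  }
  both <- which(ac != "-" & bc != "-")
  identity <- if (length(both) == 0) 0 else {
    cols <- both[1]:both[length(both)]
    sum(ac[cols] == bc[cols]) / length(cols)
  }
  list(score = score, identity = identity)
}

# --- brute-force chimera score oracle -----------------------------------
# Projects each reference onto query coordinates with its own Biostrings
# call, then exhaustively loops over every ordered reference pair and
# every crossover, recomputing votes by explicit subset sums.
project_oracle <- function(query, parent) {
  mat <- matrix(-1L, 15, 15,
                dimnames = list(refchimera:::IUPAC_CODES,
                                refchimera:::IUPAC_CODES))
  diag(mat) <- 1L
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(parent),
    subject = Biostrings::DNAString(query),
    type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  p[s != "-"]
}

score_pair_oracle <- function(query, pa, pb, params) {
  qv <- strsplit(query, "")[[1]]
  a <- project_oracle(query, pa)
  b <- project_oracle(query, pb)
  ya <- qv == a & qv != b
  yb <- qv == b & qv != a
  ab <- qv != a & qv != b
  info <- which(ya | yb | ab)
  m <- length(info)
  if (m == 0) return(0)
  best <- 0
  side <- function(y, n, aa) {
    y / (params$beta * (n + params$reg) + params$alpha * aa)
  }
  for (x in 0:m) {
    left <- info[seq_len(x)]; right <- setdiff(info, left)
    for (orient in 1:2) {
      yl <- if (orient == 1) ya else yb
      yr <- if (orient == 1) yb else ya
      Y_L <- sum(yl[left]); N_L <- sum(yr[left]); A_L <- sum(ab[left])
      Y_R <- sum(yr[right]); N_R <- sum(yl[right]); A_R <- sum(ab[right])
      if (Y_L < params$min_diffs || Y_R < params$min_diffs) next
      best <- max(best, side(Y_L, N_L, A_L) * side(Y_R, N_R, A_R))
    }
  }
  best
}

detect_oracle <- function(query, refset, params) {
  ids <- setdiff(refset$id, if (isTRUE(params$self_exclude)) query$id else
    character(0))
  if (length(ids) < 2) return(0)
  best <- 0
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      sa <- refset$seq[refset$id == ids[i]]
      sb <- refset$seq[refset$id == ids[j]]
      best <- max(best, score_pair_oracle(query$seq, sa, sb, params))
    }
  }
  best
}

# --- exact Wilcoxon rank-sum enumeration (small groups) -----------------
wilcox_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  combos <- utils::combn(length(pooled), n_a)
  W <- apply(combos, 2, function(idx) sum(r[idx]))
  w_obs <- sum(r[seq_len(n_a)])
  mu <- mean(W)
  mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
}

# --- Rand index ---------------------------------------------------------
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((x[i] == x[j]) == (y[i] == y[j]))
    }
  }
  agree / choose(n, 2)
}
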