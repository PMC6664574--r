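# Independent oracles and small generators used across the test files.
# These deliberately re-derive results by brute force, without reusing the
# package's scanning/alignment internals.

# Independent motif validity check (direct transcription of the rules).
oracle_valid <- function(s, class = c("pyrimidine", "purine"),
                         min_length = 5L, min_gap = 3L,
                         max_anchor = 3L, max_partner = 2,
                         anchor_bounded = FALSE) {
  class <- match.arg(class)
  anchor <- if (class == "pyrimidine") "T" else "A"
  partner <- if (class == "pyrimidine") "C" else "G"
  s <- chartr("U", "T", toupper(s))
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < min_length) return(FALSE)
  if (!all(ch %in% c(anchor, partner))) return(FALSE)
  a <- which(ch == anchor)
  if (length(a) < 2L) return(FALSE)
  if (a[length(a)] - a[1L] - 1L < min_gap) return(FALSE)
  if (grepl(paste0(anchor, "{", max_anchor + 1L, "}"), s)) return(FALSE)
  if (is.finite(max_partner) &&
      grepl(paste0(partner, "{", max_partner + 1L, "}"), s)) return(FALSE)
  if (anchor_bounded && (ch[1L] != anchor || ch[length(ch)] != anchor))
    return(FALSE)
  TRUE
}

# All valid windows of a sequence by exhaustive enumeration (0-based
# half-open coordinates), optionally restricted to a length range.
oracle_windows <- function(seq, class = "pyrimidine", lengths = NULL, ...) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (!is.null(lengths) && !(len %in% lengths)) next
      if (oracle_valid(substr(s, i, j), class, ...))
        out[[length(out) + 1L]] <- c(i - 1L, j)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L])[order(m[, 1L], m[, 2L]), ]
}

# Maximal valid windows: all valid windows minus those contained in another.
oracle_sites <- function(seq, class = "pyrimidine", ...) {
  w <- oracle_windows(seq, class, lengths = NULL, ...)
  if (!nrow(w)) return(w)
  keep <- vapply(seq_len(nrow(w)), function(k) {
    !any(w$start <= w$start[k] & w$end >= w$end[k] &
           (w$start != w$start[k] | w$end != w$end[k]))
  }, logical(1))
  out <- w[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive affine-gap global alignment score (Gotoh), for short strings.
# Gap of length L costs gap_open + (L - 1) * gap_extend.
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  A <- strsplit(toupper(a), "")[[1]]; B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) X[i, 1] <- gap_open + (i - 2L) * gap_extend
  for (j in 2:(m + 1L)) Y[1, j] <- gap_open + (j - 2L) * gap_extend
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      sc <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sc
      X[i, j] <- max(M[i - 1L, j] + gap_open, X[i - 1L, j] + gap_extend)
      Y[i, j] <- max(M[i, j - 1L] + gap_open, Y[i, j - 1L] + gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Write a minimal RepeatMasker .out fixture and return its path.
local_rm_fixture <- function(chrom, start, end, family,
                             strand = rep("+", length(chrom)),
                             subfamily = sprintf("rep%d", seq_along(chrom))) {
  f <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query      position in query",
    "score  div. del. ins.  sequence   begin end (left)",
    "",
    sprintf(" 100 1.0 1.0 1.0 %s %d %d (0) %s %s %s 1 %d (0) %d",
            chrom, start + 1L, end, strand, subfamily, family,
            end - start, seq_along(chrom))), f)
  f
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Random length distribution for KS metric checks.
random_length_dist <- function() {
  lens <- sample(5:17, sample(2:6, 1))
  length_distribution(rep(lens, sample(1:20, length(lens), replace = TRUE)))
}
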