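#' Locate maximal triplex-forming motif sites in a sequence
#'
#' A motif *site* is a maximal valid window: a window satisfying
#' [is_valid_motif()] that is not contained in any longer valid window of the
#' same class.  Sites are confined to maximal same-class runs of the sequence
#' (pyrimidine-only or purine-only stretches); `N` and any base of the other
#' purine/pyrimidine category break a run.  A run that as a whole violates a
#' run-length criterion is not discarded: its maximal valid sub-windows are
#' reported, so e.g. `"UCUUUUC"` (four U in a row) still yields the site
#' `"UCUUU"`.
#'
#' @param seq a residue string (or a length-1 element of [read_fasta()]
#'   output); U/T interchangeable, case-insensitive.
#' @param criteria a [motif_criteria()] object.
#' @param seq_id identifier used in the output; defaults to `names(seq)` or
#'   `"seq"`.
#' @return A `motif_sites` data frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open), `length`, `motif_class` and `sequence`, sorted by
#'   `start`.
#' @examples
#' find_motif_sites("aaUUUCUaa", motif_criteria("pyrimidine"))
#' @export
find_motif_sites <- function(seq, criteria, seq_id = NULL) {
  stopifnot(inherits(criteria, "motif_criteria"))
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq)[1L] else "seq"
  s <- .normalize_residues(as.character(seq)[1L])
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  segs <- .class_segments(ch, criteria)
  out <- lapply(segs, function(seg) {
    w <- .maximal_windows(ch[seg$from:seg$to], criteria)
    if (nrow(w) == 0L) return(NULL)
    data.frame(start = seg$from - 1L + w$start - 1L,
               end = seg$from - 1L + w$end)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(start = integer(), end = integer())
  out <- out[order(out$start), , drop = FALSE]
  new_motif_sites(seq_id, out$start, out$end, criteria$motif_class, s)
}

# Maximal same-class runs (1-based from/to) of length >= min_length.
.class_segments <- function(ch, criteria) {
  in_class <- ch %in% c(criteria$anchor, criteria$partner)
  r <- rle(in_class)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= criteria$min_length
  mapply(function(f, t) list(from = f, to = t),
         starts[keep], ends[keep], SIMPLIFY = FALSE)
}

# Maximal valid windows within one same-class segment (character vector over
# the class's two bases).  For every start i the candidate end e_i is the
# largest end reachable without a run-length violation (run violations are
# monotone under window extension, so e_i is well defined and non-decreasing
# in i); a candidate is a site iff it passes the remaining criteria and no
# earlier start reaches the same end (which would contain it).
.maximal_windows <- function(ch, criteria) {
  n <- length(ch)
  empty <- data.frame(start = integer(), end = integer())
  if (n < criteria$min_length) return(empty)
  run_id <- cumsum(c(TRUE, ch[-1L] != ch[-n]))
  run_start <- ave(seq_len(n), run_id, FUN = min)
  run_len_ending <- seq_len(n) - run_start + 1L
  limit <- ifelse(ch == criteria$anchor,
                  criteria$max_anchor_run, criteria$max_partner_run)
  # minstart[j]: smallest window start such that [minstart[j], j] has no
  # over-long run; non-decreasing in j.
  minstart <- integer(n)
  cur <- 1L
  for (j in seq_len(n)) {
    if (is.finite(limit[j]) && run_len_ending[j] > limit[j])
      cur <- max(cur, j - as.integer(limit[j]) + 1L)
    minstart[j] <- cur
  }
  # e_i = largest j with minstart[j] <= i
  e <- integer(n)
  j <- n
  for (i in rev(seq_len(n))) {
    if (j < i) j <- i
    while (minstart[j] > i) j <- j - 1L
    e[i] <- j
  }
  anchors <- ch == criteria$anchor
  anchor_pos <- which(anchors)
  if (criteria$anchor_bounded) {
    # restrict starts to anchors, pull each end back to the last anchor <= e_i
    starts <- anchor_pos
    if (length(starts) == 0L) return(empty)
    idx <- findInterval(e[starts], anchor_pos)
    ends <- ifelse(idx >= 1L, anchor_pos[pmax(idx, 1L)], 0L)
    keep <- idx >= 1L & ends >= starts
    starts <- starts[keep]; ends <- ends[keep]
  } else {
    starts <- seq_len(n)
    ends <- e
  }
  if (length(starts) == 0L) return(empty)
  # containment removal: ends are non-decreasing in start, so a window is
  # contained iff an earlier start reaches the same end
  first <- !duplicated(ends)
  starts <- starts[first]; ends <- ends[first]
  ok <- vapply(seq_along(starts), function(k) {
    .window_valid(ch, starts[k], ends[k], anchor_pos, criteria)
  }, logical(1))
  data.frame(start = starts[ok], end = ends[ok])
}

# length + internal-gap (+ boundary) checks for a window known to be free of
# run violations
.window_valid <- function(ch, from, to, anchor_pos, criteria) {
  if (to - from + 1L < criteria$min_length) return(FALSE)
  a <- anchor_pos[anchor_pos >= from & anchor_pos <= to]
  if (length(a) < 2L) return(FALSE)
  if (a[length(a)] - a[1L] - 1L < criteria$min_internal_gap) return(FALSE)
  if (criteria$anchor_bounded &&
      (ch[from] != criteria$anchor || ch[to] != criteria$anchor)) return(FALSE)
  TRUE
}

#' Enumerate all valid motif windows, overlaps included
#'
#' Unlike [find_motif_sites()], which reports only maximal windows, this
#' returns *every* window satisfying the criteria, including nested and
#' overlapping ones — the counting used for cumulative short-motif ratios
#' (e.g. the 10-mer `uuucuuccuu` contains four valid 5-mers: `uuucu`,
#' `uucuu`, `uuccu`, `uccuu`).
#'
#' @inheritParams find_motif_sites
#' @param length_range integer vector of window lengths to consider, e.g.
#'   `5:10` or a single length; default `criteria$min_length` up to the
#'   longest same-class run.
#' @return A `motif_sites` data frame (see [find_motif_sites()]); windows may
#'   overlap.
#' @export
enumerate_motif_windows <- function(seq, criteria, length_range = NULL,
                                    seq_id = NULL) {
  stopifnot(inherits(criteria, "motif_criteria"))
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq)[1L] else "seq"
  s <- .normalize_residues(as.character(seq)[1L])
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  segs <- .class_segments(ch, criteria)
  res <- list()
  for (seg in segs) {
    seg_ch <- ch[seg$from:seg$to]
    L <- length(seg_ch)
    lens <- if (is.null(length_range)) criteria$min_length:L
            else length_range[length_range <= L]
    lens <- lens[lens >= criteria$min_length]
    for (len in lens) {
      for (i in seq_len(L - len + 1L)) {
        if (.valid_motif_chars(seg_ch[i:(i + len - 1L)], criteria)) {
          res[[length(res) + 1L]] <-
            c(seg$from - 1L + i - 1L, seg$from - 1L + i - 1L + len)
        }
      }
    }
  }
  if (length(res) == 0L) return(new_motif_sites(seq_id, integer(), integer(),
                                                criteria$motif_class, s))
  m <- do.call(rbind, res)
  o <- order(m[, 1L], m[, 2L])
  new_motif_sites(seq_id, m[o, 1L], m[o, 2L], criteria$motif_class, s)
}

#' Replace a region of a sequence by its reverse complement
#'
#' Models a genomic inversion of part of a transcript (as in the inverted
#' Xist allele): the region `[start, end)` (0-based half-open) is replaced by
#' its reverse complement.  Applying the same inversion twice restores the
#' original.  Inversion swaps motif classes within the region: pyrimidine
#' (r-UC) motifs re-appear as purine (r-AG) motifs and vice versa.
#'
#' @param seq residue string; U/T interchangeable.
#' @param start,end 0-based half-open region bounds.
#' @return The modified sequence (normalized alphabet, single string).
#' @export
invert_region <- function(seq, start, end) {
  s <- .normalize_residues(as.character(seq)[1L])
  n <- nchar(s)
  if (!(start >= 0 && start < end && end <= n))
    stop("region out of range: need 0 <= start < end <= ", n)
  mid <- substr(s, start + 1L, end)
  rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(mid, "")[[1]]),
                                       collapse = ""))
  paste0(substr(s, 1L, start), rc,
         if (end < n) substr(s, end + 1L, n) else "")
}

# constructor for the motif_sites data frame
new_motif_sites <- function(seq_id, start, end, motif_class, full_seq = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  seqs <- if (length(start) && !is.null(full_seq))
    substring(full_seq, start + 1L, end) else character(length(start))
  df <- data.frame(seq_id = rep_len(seq_id, length(start)),
                   start = start, end = end,
                   length = end - start,
                   motif_class = rep_len(motif_class, length(start)),
                   sequence = seqs,
                   stringsAsFactors = FALSE)
  class(df) <- c("motif_sites", "data.frame")
  df
}

#' @export
print.motif_sites <- function(x, ...) {
  cat(sprintf("%d motif site(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
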