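#' Motif validity criteria for triplex-forming r-UC/r-AG motifs
#'
#' Parameterises the rules a short sequence window must satisfy to count as a
#' redundant pyrimidine (r-UC/TC) or purine (r-AG) triplex-forming motif.
#' With defaults, a pyrimidine motif is at least 5 nt of U(T)/C only, with at
#' least three nucleotides strictly between the first and last U(T), no more
#' than three U(T) in a row and at most two C in a row (Hoogsteen mode).  The
#' purine class mirrors this with U(T) replaced by A and C by G; in reverse
#' Hoogsteen mode the consecutive-G limit is lifted, because runs of G
#' increase the affinity of reverse Hoogsteen triplexes.
#'
#' @param motif_class `"pyrimidine"` (r-UC/TC) or `"purine"` (r-AG).
#' @param mode `"hoogsteen"` or `"reverse_hoogsteen"`.  Controls the default
#'   `max_partner_run`: 2 for Hoogsteen, unlimited (`Inf`) for the purine
#'   reverse Hoogsteen class.
#' @param min_length minimum motif length in nucleotides.
#' @param min_internal_gap minimum number of nucleotides strictly between the
#'   first and the last anchor base (U/T for pyrimidine, A for purine).
#' @param max_anchor_run longest allowed run of the anchor base.
#' @param max_partner_run longest allowed run of the partner base (C or G);
#'   `Inf` disables the check.  Defaults by `mode` as described above.
#' @param anchor_bounded if `TRUE`, motifs must additionally begin and end
#'   with the anchor base.  The published criteria do not require this; the
#'   flag exists because the original scanning software's behaviour at motif
#'   boundaries is not documented.  Default `FALSE`.
#'
#' @return An object of class `"motif_criteria"`.
#' @examples
#' uc <- motif_criteria("pyrimidine")
#' ag <- motif_criteria("purine")
#' is_valid_motif("uuucu", uc)
#' is_valid_motif("aggaagaaggga", ag)
#' @export
motif_criteria <- function(motif_class = c("pyrimidine", "purine"),
                           mode = NULL,
                           min_length = 5L,
                           min_internal_gap = 3L,
                           max_anchor_run = 3L,
                           max_partner_run = NULL,
                           anchor_bounded = FALSE) {
  motif_class <- match.arg(motif_class)
  if (is.null(mode)) {
    mode <- if (motif_class == "purine") "reverse_hoogsteen" else "hoogsteen"
  }
  mode <- match.arg(mode, c("hoogsteen", "reverse_hoogsteen"))
  if (is.null(max_partner_run)) {
    max_partner_run <- if (mode == "reverse_hoogsteen" &&
                           motif_class == "purine") Inf else 2L
  }
  min_length <- as.integer(min_length)
  min_internal_gap <- as.integer(min_internal_gap)
  max_anchor_run <- as.integer(max_anchor_run)
  if (min_length < min_internal_gap + 2L)
    stop("min_length must be >= min_internal_gap + 2 ",
         "(first anchor + gap + last anchor)")
  if (max_anchor_run < 1L || max_partner_run < 1L)
    stop("maximum run lengths must be >= 1")
  structure(
    list(motif_class = motif_class,
         mode = mode,
         min_length = min_length,
         min_internal_gap = min_internal_gap,
         max_anchor_run = max_anchor_run,
         max_partner_run = max_partner_run,
         anchor_bounded = isTRUE(anchor_bounded),
         # anchor/partner in normalized (DNA) alphabet
         anchor = if (motif_class == "pyrimidine") "T" else "A",
         partner = if (motif_class == "pyrimidine") "C" else "G"),
    class = "motif_criteria"
  )
}

#' @export
print.motif_criteria <- function(x, ...) {
  cat(sprintf("Motif criteria: %s class, %s mode\n", x$motif_class, x$mode))
  cat(sprintf("  bases %s/%s; min length %d nt; >= %d nt between first/last %s\n",
              x$anchor, x$partner, x$min_length, x$min_internal_gap, x$anchor))
  cat(sprintf("  max %s run %d; max %s run %s%s\n", x$anchor, x$max_anchor_run,
              x$partner,
              if (is.finite(x$max_partner_run))
                as.character(x$max_partner_run) else "unlimited",
              if (x$anchor_bounded) "; anchor-bounded" else ""))
  invisible(x)
}

# Normalize a residue string to the internal DNA alphabet (upper case, U->T).
# Characters outside A,C,G,T,N raise an error.
.normalize_residues <- function(s) {
  s <- chartr("u", "T", toupper(s))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (any(nchar(bad) > 0L))
    stop("illegal residue character(s): ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = ", "))
  s
}

#' Test whether a residue string is a valid triplex-forming motif
#'
#' Applies the full set of motif criteria to one string: minimum length, the
#' two-base class alphabet, the internal-gap rule between the first and last
#' anchor base, and the maximum run lengths of anchor and partner bases.
#' `N` never belongs to a motif, so any string containing `N` is invalid.
#'
#' @param s residue string (U and T interchangeable, case-insensitive).
#' @param criteria a [motif_criteria()] object.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_motif <- function(s, criteria) {
  stopifnot(inherits(criteria, "motif_criteria"))
  if (length(s) != 1L || !nzchar(s)) stop("s must be one non-empty string")
  s <- .normalize_residues(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  .valid_motif_chars(ch, criteria)
}

# Core validity check on a character vector already normalized to A/C/G/T/N.
.valid_motif_chars <- function(ch, criteria) {
  n <- length(ch)
  if (n < criteria$min_length) return(FALSE)
  if (!all(ch %in% c(criteria$anchor, criteria$partner))) return(FALSE)
  anchors <- which(ch == criteria$anchor)
  if (length(anchors) < 2L) return(FALSE)
  gap <- anchors[length(anchors)] - anchors[1L] - 1L
  if (gap < criteria$min_internal_gap) return(FALSE)
  r <- rle(ch)
  if (max(c(0L, r$lengths[r$values == criteria$anchor])) >
      criteria$max_anchor_run) return(FALSE)
  if (is.finite(criteria$max_partner_run) &&
      max(c(0L, r$lengths[r$values == criteria$partner])) >
      criteria$max_partner_run) return(FALSE)
  if (criteria$anchor_bounded &&
      (ch[1L] != criteria$anchor || ch[n] != criteria$anchor)) return(FALSE)
  TRUE
}
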