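#' Per-sequence motif profile: counts, occupancy, frequency and class ratio
#'
#' Scans one sequence with both motif classes and summarises the maximal
#' sites: site count, occupancy (fraction of nucleotides covered by the
#' union of sites of a class), frequency (sites per kb) and the
#' pyrimidine/purine occupancy ratio — the r-UC/r-AG ratio used as a lncRNA
#' fingerprint.  The ratio is computed from unrounded occupancies and only
#' rounded for display.
#'
#' @inheritParams find_motif_sites
#' @param criteria_uc criteria for the pyrimidine (r-UC/TC) class; default
#'   `motif_criteria("pyrimidine")`.
#' @param criteria_ag criteria for the purine (r-AG) class; default
#'   `motif_criteria("purine")` (reverse Hoogsteen, unlimited G runs).
#' @return A `motif_profile` list with elements `seq_id`, `seq_length`,
#'   `uc`/`ag` (each with `site_count`, `occupancy`, `frequency`, `sites`),
#'   and `ratio_uc_over_ag` (`NA` when purine occupancy is zero).
#' @examples
#' p <- profile_sequence(strrep("TTCTT A AGGAA ", 20))
#' @export
profile_sequence <- function(seq,
                             criteria_uc = motif_criteria("pyrimidine"),
                             criteria_ag = motif_criteria("purine"),
                             seq_id = NULL) {
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq)[1L] else "seq"
  s <- .normalize_residues(gsub("\\s", "", as.character(seq)[1L]))
  n <- nchar(s)
  if (n == 0L) stop("zero-length sequence")
  one <- function(criteria) {
    sites <- find_motif_sites(s, criteria, seq_id = seq_id)
    cov <- if (nrow(sites)) sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = sites$start + 1L, end = sites$end)))) else 0L
    list(site_count = nrow(sites),
         occupancy = cov / n,
         frequency = nrow(sites) / (n / 1000),
         sites = sites)
  }
  uc <- one(criteria_uc)
  ag <- one(criteria_ag)
  structure(list(seq_id = seq_id, seq_length = n, uc = uc, ag = ag,
                 ratio_uc_over_ag = if (ag$occupancy > 0)
                   uc$occupancy / ag$occupancy else NA_real_),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("Motif profile of %s (%d nt)\n", x$seq_id, x$seq_length))
  for (cl in c("uc", "ag"))
    cat(sprintf("  r-%s: %d sites, occupancy %.1f%%, %.1f sites/kb\n",
                toupper(cl), x[[cl]]$site_count, 100 * x[[cl]]$occupancy,
                x[[cl]]$frequency))
  cat(sprintf("  r-UC/r-AG ratio: %s\n",
              if (is.na(x$ratio_uc_over_ag)) "undefined"
              else sprintf("%.2f", x$ratio_uc_over_ag)))
  invisible(x)
}

#' Profile every sequence of a FASTA-style record set
#'
#' @param records named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @inheritParams profile_sequence
#' @return A data frame with one row per sequence: `seq_id`, `seq_length`,
#'   `uc_sites`, `uc_occupancy`, `uc_per_kb`, `ag_sites`, `ag_occupancy`,
#'   `ag_per_kb`, `ratio_uc_over_ag`.
#' @export
profile_sequences <- function(records,
                              criteria_uc = motif_criteria("pyrimidine"),
                              criteria_ag = motif_criteria("purine")) {
  rows <- lapply(seq_along(records), function(i) {
    p <- profile_sequence(records[[i]], criteria_uc, criteria_ag,
                          seq_id = names(records)[i])
    data.frame(seq_id = p$seq_id, seq_length = p$seq_length,
               uc_sites = p$uc$site_count, uc_occupancy = p$uc$occupancy,
               uc_per_kb = p$uc$frequency,
               ag_sites = p$ag$site_count, ag_occupancy = p$ag$occupancy,
               ag_per_kb = p$ag$frequency,
               ratio_uc_over_ag = p$ratio_uc_over_ag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Empirical motif-length distribution
#'
#' @param sites a `motif_sites` data frame (one class), or an integer vector
#'   of motif lengths.
#' @return A `length_distribution` object: `lengths` (sorted unique lengths),
#'   `counts`, `n`, and `cdf(x)` = P(length <= x).
#' @export
length_distribution <- function(sites) {
  lens <- if (is.data.frame(sites)) sites$length else as.integer(sites)
  tab <- table(lens)
  lengths <- as.integer(names(tab))
  counts <- as.integer(tab)
  n <- sum(counts)
  cum <- cumsum(counts)
  cdf <- function(x) {
    if (n == 0L) stop("empty distribution has no CDF")
    vapply(x, function(v) {
      k <- findInterval(v, lengths)
      if (k == 0L) 0 else cum[k] / n
    }, numeric(1))
  }
  structure(list(lengths = lengths, counts = counts, n = n, cdf = cdf),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("Motif-length distribution: n = %d%s\n", x$n,
              if (x$n) sprintf(", lengths %d-%d nt", min(x$lengths),
                               max(x$lengths)) else ""))
  if (x$n) print(stats::setNames(x$counts, x$lengths))
  invisible(x)
}

#' @export
plot.length_distribution <- function(x, main = "Motif-length distribution",
                                     xlab = "Motif length (nt)",
                                     ylab = "Count", ...) {
  if (x$n == 0L) stop("nothing to plot: empty distribution")
  full <- stats::setNames(integer(max(x$lengths) - min(x$lengths) + 1L),
                          min(x$lengths):max(x$lengths))
  full[as.character(x$lengths)] <- x$counts
  graphics::barplot(full, main = main, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Kolmogorov-Smirnov distance between two motif-length distributions
#'
#' The maximum absolute difference between the two empirical cumulative
#' distribution functions, evaluated on the union of observed lengths.  This
#' is a descriptive distance (no continuity correction, no test); by the
#' convention used throughout the package, two distributions are "similar"
#' when the distance is below 0.100.
#'
#' @param d1,d2 [length_distribution()] objects (both non-empty).
#' @return A number in `[0, 1]`.
#' @seealso [motif_lengths_similar()]
#' @export
ks_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "length_distribution"),
            inherits(d2, "length_distribution"))
  if (d1$n == 0L || d2$n == 0L) stop("both distributions must be non-empty")
  x <- sort(unique(c(d1$lengths, d2$lengths)))
  max(abs(d1$cdf(x) - d2$cdf(x)))
}

#' Similarity predicate on motif-length distributions
#'
#' @inheritParams ks_distance
#' @param threshold similarity threshold on the KS distance; default 0.100.
#' @return `TRUE` iff `ks_distance(d1, d2) < threshold`.
#' @export
motif_lengths_similar <- function(d1, d2, threshold = 0.100) {
  ks_distance(d1, d2) < threshold
}

#' Cumulative ratio of short motif windows, overlaps included
#'
#' Fraction of all valid windows (from [enumerate_motif_windows()], i.e.
#' counting overlapping and nested windows) whose length falls in a band —
#' e.g. the share of 5-7-nt windows among all windows.
#'
#' @param windows a `motif_sites` data frame from
#'   [enumerate_motif_windows()].
#' @param length_band inclusive length band `c(min, max)`; default `c(5, 7)`.
#' @return A fraction in `[0, 1]`.
#' @export
cumulative_short_motif_ratio <- function(windows, length_band = c(5L, 7L)) {
  if (nrow(windows) == 0L) stop("no motif windows")
  mean(windows$length >= length_band[1L] & windows$length <= length_band[2L])
}

#' Genomic proportions of repeat families per chromosome
#'
#' For each chromosome and repeat family, the summed element length divided
#' by the chromosome length.  Lengths are summed as annotated; overlapping
#' records (rare in RepeatMasker output) are summed raw with a warning.
#' With `bins`, proportions are additionally broken down by element-length
#' bin.
#'
#' @param annotations a `repeat_annotation` data frame.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   names must cover `annotations$chrom`.
#' @param bins optional length-bin breaks (right-closed), e.g. from
#'   [line_length_bins()].
#' @return A data frame with columns `chrom`, `repeat_family` (and `bin` if
#'   binned), `n_elements`, `bp`, `proportion`.
#' @export
family_proportions <- function(annotations, chrom_lengths, bins = NULL) {
  a <- as.data.frame(annotations)
  miss <- setdiff(unique(a$chrom), names(chrom_lengths))
  if (length(miss))
    stop("no chromosome length for: ", paste(miss, collapse = ", "))
  if (any(a$end > chrom_lengths[a$chrom]))
    stop("annotation extends beyond chromosome end")
  # overlap check per chromosome
  for (cm in unique(a$chrom)) {
    b <- a[a$chrom == cm, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)]))
      warning("overlapping annotations on ", cm,
              "; proportions use raw summed lengths")
  }
  keys <- list(chrom = a$chrom, repeat_family = a$repeat_family)
  if (!is.null(bins)) keys$bin <- bin_label(a$length, bins)
  agg_bp <- stats::aggregate(a$length, keys, FUN = sum)
  agg_n <- stats::aggregate(a$length, keys, FUN = length)
  out <- agg_bp
  names(out)[names(out) == "x"] <- "bp"
  out$n_elements <- agg_n$x
  out$proportion <- out$bp / chrom_lengths[out$chrom]
  cols <- c("chrom", "repeat_family", if (!is.null(bins)) "bin",
            "n_elements", "bp", "proportion")
  out <- out[do.call(order, out[setdiff(cols, c("n_elements", "bp",
                                                "proportion"))]),
             cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standard LINE element-length bins
#'
#' Right-closed bins of 100 bp up to 1,000 bp and of 1,000 bp above:
#' (0,100], (100,200], ..., (900,1000], (1000,2000], (2000,3000], ...
#'
#' @param max_bp largest element length the bins must cover.
#' @return Numeric vector of bin breaks (starting at 0).
#' @export
line_length_bins <- function(max_bp = 10000) {
  upper <- max(2000, ceiling(max_bp / 1000) * 1000)
  c(seq(0, 1000, by = 100), seq(2000, upper, by = 1000))
}

#' Label element lengths by right-closed bin
#' @param lengths element lengths (bp).
#' @param breaks bin breaks as from [line_length_bins()].
#' @return Character labels like `"<=100"`, `"101-200"`, `"1001-2000"`.
#' @export
bin_label <- function(lengths, breaks) {
  lab <- c("<=100", paste0(utils::head(breaks[-1L], -1L) + 1L, "-",
                           breaks[-(1:2)]))
  idx <- findInterval(lengths, breaks, left.open = TRUE) + 0L
  idx[lengths <= breaks[1L]] <- NA_integer_
  if (anyNA(idx) || any(idx > length(lab)))
    stop("element length outside bin range")
  lab[idx]
}

#' Random per-bin sampling of annotated elements
#'
#' Samples up to `k` elements uniformly without replacement from each
#' element-length bin, reproducibly under `seed`.  Bins holding fewer than
#' `k` elements contribute all of them (as happens for the shortest and
#' longest LINE-1 bins on real X chromosomes).
#'
#' @param annotations a `repeat_annotation` data frame.
#' @param bins length-bin breaks (right-closed), e.g. [line_length_bins()].
#' @param k maximum elements per bin.
#' @param seed integer seed.
#' @return The sampled subset of `annotations` (bin-major order, with a
#'   `bin` column appended).
#' @export
sample_by_length_bin <- function(annotations, bins, k, seed) {
  if (length(bins) < 2L) stop("need at least one bin")
  a <- as.data.frame(annotations)
  a$bin <- bin_label(a$length, bins)
  lvl <- unique(bin_label(bins[-1L], bins))
  picked <- with_seed(seed, {
    unlist(lapply(lvl, function(b) {
      idx <- which(a$bin == b)
      if (length(idx) <= k) idx
      else sort(idx[sample.int(length(idx), k)])
    }))
  })
  out <- a[picked, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_annotation", "data.frame")
  out
}
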