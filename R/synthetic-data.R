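#' Generate a sequence with planted triplex-forming motifs
#'
#' Builds a random background sequence and plants valid motifs of one or
#' both classes at known positions, at a target per-class occupancy.  Every
#' planted motif is a maximal valid window by construction: the bases
#' immediately flanking a pyrimidine plant are purines and vice versa, so
#' plants never merge with each other or with the background, and a scan
#' with [find_motif_sites()] recovers each plant exactly.  Accidental
#' background motifs may still arise by chance; they are legitimate sites
#' and are reported separately by comparing scan output with the ledger.
#'
#' @param seq_length sequence length in nucleotides.
#' @param target_occupancy named fractions, e.g. `c(uc = 0.05, ag = 0.15)`;
#'   classes with 0 are not planted.  The sum must stay well below 1.
#' @param motif_length_dist either a probability vector over the lengths
#'   `5:17` (recycled/normalised) or a function `n -> lengths`.  Default:
#'   geometric decay (ratio 0.6) over 5-17 nt, matching the bottom-heavy
#'   motif-length distributions seen in real scans, where minimum-length
#'   motifs dominate and 15-17-nt motifs are rare.
#' @param background_composition base probabilities for A, C, G, T
#'   (default uniform).
#' @param seed integer seed; output is fully reproducible.
#' @return A list with `sequence` (single string), `planted` (a
#'   `motif_sites` ledger with 0-based coordinates) and `realized_occupancy`
#'   (named per-class fractions, planted bases / length).
#' @export
generate_motif_sequence <- function(seq_length,
                                    target_occupancy = c(uc = 0.05, ag = 0.05),
                                    motif_length_dist = NULL,
                                    background_composition =
                                      c(A = .25, C = .25, G = .25, T = .25),
                                    seed = 1L) {
  stopifnot(seq_length >= 20, all(target_occupancy >= 0),
            sum(target_occupancy) < 0.8)
  classes <- intersect(names(target_occupancy), c("uc", "ag"))
  if (length(classes) != length(target_occupancy))
    stop("target_occupancy must be named with 'uc' and/or 'ag'")
  draw_len <- .motif_length_sampler(motif_length_dist)
  with_seed(seed, {
    plants <- list()
    for (cl in classes) {
      occ <- target_occupancy[[cl]]
      if (occ <= 0) next
      crit <- motif_criteria(if (cl == "uc") "pyrimidine" else "purine")
      total <- 0L
      while (total < occ * seq_length) {
        len <- draw_len(1L)
        plants[[length(plants) + 1L]] <-
          list(class = cl, seq = .random_motif(len, crit))
        total <- total + len
      }
    }
    n_pl <- length(plants)
    if (n_pl) plants <- plants[sample.int(n_pl)]
    plant_len <- vapply(plants, function(p) nchar(p$seq), integer(1))
    spare <- seq_length - sum(plant_len) - 2L * (n_pl + 1L)
    if (spare < 0L)
      stop("infeasible occupancy/length combination: plants do not fit")
    # n_pl + 1 gaps, each >= 2 nt so both flanks of every plant can be forced
    extra <- if (n_pl >= 0L) stats::rmultinom(1L, spare,
                                              rep(1, n_pl + 1L))[, 1L]
    gaps <- 2L + extra
    bg <- function(k) sample(names(background_composition), k, replace = TRUE,
                             prob = background_composition)
    chunks <- character(0)
    pos <- 0L
    ledger <- list()
    for (i in seq_len(n_pl + 1L)) {
      g <- bg(gaps[i])
      # force flanking bases to the opposite purine/pyrimidine category
      if (i > 1L)
        g[1L] <- if (plants[[i - 1L]]$class == "uc")
          sample(c("A", "G"), 1L) else sample(c("C", "T"), 1L)
      if (i <= n_pl)
        g[length(g)] <- if (plants[[i]]$class == "uc")
          sample(c("A", "G"), 1L) else sample(c("C", "T"), 1L)
      chunks <- c(chunks, paste(g, collapse = ""))
      pos <- pos + gaps[i]
      if (i <= n_pl) {
        ledger[[i]] <- data.frame(start = pos,
                                  end = pos + nchar(plants[[i]]$seq),
                                  class = plants[[i]]$class)
        chunks <- c(chunks, plants[[i]]$seq)
        pos <- pos + nchar(plants[[i]]$seq)
      }
    }
    seqstr <- paste(chunks, collapse = "")
    led <- if (length(ledger)) do.call(rbind, ledger)
           else data.frame(start = integer(), end = integer(),
                           class = character())
    led <- led[order(led$start), , drop = FALSE]
    planted <- new_motif_sites("synthetic", led$start, led$end,
                               ifelse(led$class == "uc", "pyrimidine",
                                      "purine"), seqstr)
    realized <- vapply(classes, function(cl)
      sum(led$end[led$class == cl] - led$start[led$class == cl]) / seq_length,
      numeric(1))
    list(sequence = seqstr, planted = planted,
         realized_occupancy = stats::setNames(realized, classes))
  })
}

# Default motif-length distribution: geometric decay over 5-17 nt.  Real
# motif-length distributions are strongly bottom-heavy -- minimum-length
# motifs dominate and counts fall steeply with length, with the longest
# (15-17 nt) motifs rare -- so a decaying law, not a uniform one, is the
# realistic default.
.motif_length_sampler <- function(motif_length_dist) {
  if (is.function(motif_length_dist)) return(motif_length_dist)
  lens <- 5:17
  prob <- if (is.null(motif_length_dist)) 0.6^(lens - 5L)
          else rep_len(motif_length_dist, length(lens))
  function(n) sample(lens, n, replace = TRUE, prob = prob)
}

# Random valid motif of given length: rejection sampling with a
# deterministic repeating-block fallback (TTC/AAG repeats are valid at any
# length >= 5 under the default criteria).
.random_motif <- function(len, criteria) {
  bases <- c(criteria$anchor, criteria$partner)
  for (try in seq_len(200L)) {
    ch <- sample(bases, len, replace = TRUE, prob = c(0.65, 0.35))
    if (.valid_motif_chars(ch, criteria)) return(paste(ch, collapse = ""))
  }
  substr(strrep(paste0(strrep(criteria$anchor, 2L), criteria$partner),
                ceiling(len / 3) + 1L), 1L, len)
}

#' Generate a 5'-truncated LINE-1-like element family
#'
#' Creates a motif-planted consensus and derives `n_elements` elements from
#' it as 3'-anchored suffixes (5' truncation, the dominant mode of L1
#' truncation in genomes), with element lengths drawn from a configurable
#' truncation-length distribution.  Because every element is a suffix of
#' one consensus, pooled motif statistics are length-independent by
#' construction — the property real L1 assemblies show.  A matching
#' RepeatMasker-dialect annotation fixture is returned (elements laid
#' end-to-end with 100-bp gaps on a synthetic chromosome).
#'
#' @param consensus_length consensus length in bp (default 6000, a
#'   full-length L1 scale).
#' @param n_elements number of elements to generate.
#' @param truncation_dist function `n -> element lengths`; default uniform
#'   over 30 bp to the consensus length.
#' @param ag_occupancy target r-AG occupancy of the consensus (default
#'   0.15, the 10-20% band observed in real L1s).
#' @param seed integer seed.
#' @return A list with `consensus`, `elements` (named character vector;
#'   elements shorter than 5 nt are dropped with a warning), `annotations`
#'   (a `repeat_annotation` data frame, one row per element) and `planted`
#'   (the consensus motif ledger).
#' @export
generate_l1_family <- function(consensus_length = 6000L, n_elements = 100L,
                               truncation_dist = NULL,
                               ag_occupancy = 0.15, seed = 1L) {
  if (is.null(truncation_dist))
    truncation_dist <- function(n)
      sample(30:consensus_length, n, replace = TRUE)
  gen <- generate_motif_sequence(consensus_length,
                                 target_occupancy = c(ag = ag_occupancy),
                                 seed = derive_seeds(seed, 2L)[1L])
  with_seed(derive_seeds(seed, 2L)[2L], {
    lens <- as.integer(truncation_dist(n_elements))
    if (any(lens > consensus_length))
      stop("truncation distribution produced lengths beyond the consensus")
    drop <- lens < 5L
    if (any(drop)) {
      warning(sum(drop), " element(s) truncated below 5 nt were skipped")
      lens <- lens[!drop]
    }
    elements <- vapply(lens, function(l)
      substr(gen$sequence, consensus_length - l + 1L, consensus_length),
      character(1))
    names(elements) <- sprintf("L1_syn_%03d", seq_along(elements))
    gapped_starts <- cumsum(c(0L, utils::head(lens, -1L) + 100L))
    ann <- new_repeat_annotation(
      chrom = rep("chrX_syn", length(lens)),
      start = gapped_starts, end = gapped_starts + lens,
      strand = rep("+", length(lens)),
      class_family = rep("LINE/L1", length(lens)),
      subfamily = names(elements))
    list(consensus = gen$sequence, elements = elements, annotations = ann,
         planted = gen$planted)
  })
}

#' Mutate a sequence under a substitution/indel model
#'
#' Produces a diverged copy of a sequence, as between two genomic copies of
#' one repeat subfamily: independent per-site substitutions (transitions
#' A<->G / C<->T with probability `transition_fraction`, transversions
#' otherwise) and optional indels.  The returned edit list reconstructs the
#' mutant from the original.
#'
#' @param seq residue string.
#' @param substitution_rate per-site substitution probability.
#' @param transition_fraction fraction of substitutions that are
#'   transitions (default 2/3, the usual genomic bias).
#' @param indel_rate per-site probability of starting an indel.
#' @param indel_length_dist function `n -> indel lengths` (default: 1-3 nt,
#'   geometric-ish weights 4:2:1).
#' @param seed integer seed.
#' @return A list with `sequence` (the mutant), `edits` (data frame with
#'   1-based `pos` on the original, `type` in sub/ins/del, `ref`, `alt`)
#'   and `n_sub`, `n_ins`, `n_del` counts.
#' @export
mutate_pair <- function(seq, substitution_rate = 0.05,
                        transition_fraction = 2 / 3,
                        indel_rate = 0, indel_length_dist = NULL,
                        seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1 ||
      transition_fraction < 0 || transition_fraction > 1)
    stop("rates must lie in [0, 1]")
  if (is.null(indel_length_dist))
    indel_length_dist <- function(n)
      sample(1:3, n, replace = TRUE, prob = c(4, 2, 1))
  s <- .normalize_residues(as.character(seq)[1L])
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  with_seed(seed, {
    edits <- list()
    sub_pos <- which(stats::runif(n) < substitution_rate & ch != "N")
    for (p in sub_pos) {
      alt <- if (stats::runif(1) < transition_fraction) transition[[ch[p]]]
             else sample(setdiff(c("A", "C", "G", "T"),
                                 c(ch[p], transition[[ch[p]]])), 1L)
      edits[[length(edits) + 1L]] <-
        data.frame(pos = p, type = "sub", ref = ch[p], alt = alt)
    }
    if (indel_rate > 0) {
      ind_pos <- which(stats::runif(n) < indel_rate)
      ind_pos <- ind_pos[!ind_pos %in% sub_pos]
      for (p in ind_pos) {
        len <- indel_length_dist(1L)
        if (stats::runif(1) < 0.5 && p + len - 1L <= n) {
          edits[[length(edits) + 1L]] <-
            data.frame(pos = p, type = "del",
                       ref = paste(ch[p:(p + len - 1L)], collapse = ""),
                       alt = "")
        } else {
          edits[[length(edits) + 1L]] <-
            data.frame(pos = p, type = "ins", ref = "",
                       alt = paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = ""))
        }
      }
    }
    edits <- if (length(edits)) do.call(rbind, edits)
             else data.frame(pos = integer(), type = character(),
                             ref = character(), alt = character())
    # drop overlapping deletions (later ones win by position order)
    if (nrow(edits)) {
      edits <- edits[order(edits$pos), , drop = FALSE]
      keep <- rep(TRUE, nrow(edits))
      covered_to <- 0L
      for (i in seq_len(nrow(edits))) {
        if (edits$pos[i] <= covered_to) { keep[i] <- FALSE; next }
        if (edits$type[i] == "del")
          covered_to <- edits$pos[i] + nchar(edits$ref[i]) - 1L
      }
      edits <- edits[keep, , drop = FALSE]
      rownames(edits) <- NULL
    }
    list(sequence = apply_edits(s, edits), edits = edits,
         n_sub = sum(edits$type == "sub"),
         n_ins = sum(edits$type == "ins"),
         n_del = sum(edits$type == "del"))
  })
}

#' Apply an edit list to a sequence
#'
#' Replays the edits produced by [mutate_pair()] on the original sequence.
#' Substitutions replace the base at `pos`; deletions remove
#' `nchar(ref)` bases starting at `pos`; insertions add `alt` before `pos`.
#'
#' @param seq the original residue string.
#' @param edits edit data frame from [mutate_pair()].
#' @return The edited sequence (single string).
#' @export
apply_edits <- function(seq, edits) {
  ch <- strsplit(.normalize_residues(as.character(seq)[1L]), "",
                 fixed = TRUE)[[1]]
  pieces <- as.list(ch)
  if (nrow(edits)) {
    for (i in seq_len(nrow(edits))) {
      p <- edits$pos[i]
      switch(edits$type[i],
             sub = { pieces[[p]] <- edits$alt[i] },
             del = { for (q in p:(p + nchar(edits$ref[i]) - 1L))
                       pieces[[q]] <- "" },
             ins = { pieces[[p]] <- paste0(edits$alt[i], pieces[[p]]) })
    }
  }
  paste(unlist(pieces), collapse = "")
}

#' Generate a dot-bracket structure fixture
#'
#' Constructs a balanced, pseudoknot-free dot-bracket string of a given
#' length with (approximately) a target paired fraction, optionally forcing
#' exact unpaired windows: each forced window becomes the loop of its own
#' hairpin, with stems placed immediately on both flanks, so the window's
#' nucleotides are accessible and the flanking nucleotides are paired.
#' With `paired_fraction = 0` the structure is all dots (and forced windows
#' are trivially unpaired, in the exterior loop).  Windows too close to the
#' sequence ends to take a stem on both sides are left unflanked (exterior).
#'
#' @param seq_length structure length.
#' @param paired_fraction target fraction of paired positions, in `[0, 1]`.
#' @param loop_spec optional list of 0-based half-open windows
#'   (`c(start, end)`) forced to be unpaired.
#' @param stem stem length used for hairpins (default 4).
#' @param seed integer seed (placement of filler hairpins).
#' @return A dot-bracket string; always parses with [parse_dot_bracket()].
#' @export
generate_structure_fixture <- function(seq_length, paired_fraction = 0.5,
                                       loop_spec = NULL, stem = 4L,
                                       seed = 1L) {
  if (paired_fraction < 0 || paired_fraction > 1)
    stop("paired_fraction must lie in [0, 1]")
  L <- as.integer(seq_length)
  ch <- rep(".", L)
  if (paired_fraction == 0) return(paste(ch, collapse = ""))
  reserved <- rep(FALSE, L)   # positions that must stay unpaired
  if (!is.null(loop_spec)) {
    for (w in loop_spec) {
      if (w[1L] < 0L || w[2L] > L || w[1L] >= w[2L])
        stop("infeasible loop_spec window")
      reserved[(w[1L] + 1L):w[2L]] <- TRUE
    }
  }
  assigned <- reserved
  npairs <- 0L
  if (!is.null(loop_spec)) {
    for (w in loop_spec) {
      from <- w[1L] + 1L; to <- w[2L]
      s_left <- 0L
      while (s_left < stem && from - s_left - 1L >= 1L &&
             !assigned[from - s_left - 1L]) s_left <- s_left + 1L
      s_right <- 0L
      while (s_right < stem && to + s_right + 1L <= L &&
             !assigned[to + s_right + 1L]) s_right <- s_right + 1L
      s <- min(s_left, s_right)
      if (s >= 1L) {
        ch[(from - s):(from - 1L)] <- "("
        ch[(to + 1L):(to + s)] <- ")"
        assigned[(from - s):(from - 1L)] <- TRUE
        assigned[(to + 1L):(to + s)] <- TRUE
        npairs <- npairs + s
      }
    }
  }
  target_pairs <- round(paired_fraction * L / 2)
  with_seed(seed, {
    # fill remaining free gaps with independent hairpin modules
    repeat {
      if (npairs >= target_pairs) break
      r <- rle(assigned)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      free <- which(!r$values & r$lengths >= 5L)
      if (length(free) == 0L) break
      g <- free[which.max(r$lengths[free])]
      gl <- r$lengths[g]; gs <- starts[g]
      s <- min((gl - 3L) %/% 2L, max(1L, target_pairs - npairs))
      # one compact hairpin (stem s, loop 3) at the gap start; the rest of
      # the gap stays free for further modules
      ch[gs:(gs + s - 1L)] <- "("
      ch[(gs + s + 3L):(gs + 2L * s + 2L)] <- ")"
      assigned[gs:(gs + 2L * s + 2L)] <- TRUE
      npairs <- npairs + s
    }
  })
  paste(ch, collapse = "")
}
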