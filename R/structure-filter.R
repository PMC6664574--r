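#' Classify every position of a secondary structure by loop type
#'
#' Standard loop taxonomy on a pseudoknot-free pairing table: paired
#' positions are `"paired"`; an unpaired position belongs to the loop closed
#' by its innermost enclosing base pair, and the loop's type follows from the
#' number of helix branches it contains: none = `"hairpin"`, one =
#' `"internal"` (unpaired nucleotides on both sides of the branch) or
#' `"bulge"` (one side only), two or more = `"multibranch"`.  Positions
#' enclosed by no pair lie in the `"exterior"` loop.
#'
#' @param pairing integer pairing vector (1-based partner index, `NA` when
#'   unpaired), e.g. from [parse_dot_bracket()] or [read_structure()].
#' @return A `secondary_structure` object: list with `pairing`, `loop_label`
#'   (character per position) and `loop_id` (integer id of the loop instance
#'   each unpaired position belongs to; 0 for the exterior loop, `NA` for
#'   paired positions).
#' @examples
#' classify_positions(parse_dot_bracket("((((....))))"))
#' @export
classify_positions <- function(pairing) {
  n <- length(pairing)
  paired <- which(!is.na(pairing))
  if (any(pairing[paired] == paired)) stop("position paired to itself")
  if (!identical(pairing[pairing[paired]], paired))
    stop("pairing table is not an involution")
  # pseudoknot check + loop membership in one pass: stack of open pairs.
  # Every opening pair is charged as a branch of its innermost enclosing
  # loop; stacked helix continuations then sit in zero-nucleotide loops,
  # which never get labelled, so the count is right wherever it matters.
  loop_id <- rep(NA_integer_, n)       # enclosing pair's opening position
  stack <- integer(0)
  parent <- rep(NA_integer_, n)        # enclosing loop id of each opening pos
  nbranch <- stats::setNames(integer(n + 1L), 0:n) # loop id -> branch count
  for (i in seq_len(n)) {
    p <- pairing[i]
    if (is.na(p)) {
      loop_id[i] <- if (length(stack)) stack[length(stack)] else 0L
    } else if (p > i) {
      enc <- if (length(stack)) stack[length(stack)] else 0L
      nbranch[as.character(enc)] <- nbranch[as.character(enc)] + 1L
      parent[i] <- enc
      stack <- c(stack, i)
    } else {
      if (length(stack) == 0L || stack[length(stack)] != p)
        stop(sprintf("crossing base pairs (pseudoknot) involving pair (%d, %d)",
                     p, i))
      stack <- stack[-length(stack)]
    }
  }
  label <- rep("paired", n)
  un <- which(is.na(pairing))
  for (i in un) {
    id <- loop_id[i]
    if (id == 0L) { label[i] <- "exterior"; next }
    nb <- nbranch[as.character(id)]
    if (nb == 0L) label[i] <- "hairpin"
    else if (nb >= 2L) label[i] <- "multibranch"
    else {
      # one branch: internal if unpaired on both sides of the branch
      j <- pairing[id]                     # enclosing pair (id, j)
      inner <- which(!is.na(loop_id) & loop_id == id)
      helix_open <- which(!is.na(parent) & parent == id)
      helix_open <- helix_open[helix_open > id & helix_open < j]
      # positions of the single child helix: first opening after id
      k <- min(helix_open)
      left <- any(inner > id & inner < k)
      right <- any(inner > pairing[k] & inner < j)
      label[i] <- if (left && right) "internal" else "bulge"
    }
  }
  structure(list(pairing = pairing, loop_label = label, loop_id = loop_id),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  n <- length(x$pairing)
  cat(sprintf("Secondary structure: %d nt, %d base pairs\n",
              n, sum(!is.na(x$pairing)) %/% 2L))
  print(table(x$loop_label))
  invisible(x)
}

#' Usable (single-stranded) length of a motif site under a structure
#'
#' The number of a motif's nucleotides available for triplex formation: the
#' longest run of consecutive site positions that are unpaired, lie in an
#' eligible loop type, and belong to the same loop instance.
#'
#' @param site one row of a `motif_sites` data frame (or any list with
#'   0-based `start` and `end`).
#' @param structure a `secondary_structure` from [classify_positions()].
#' @param eligible loop types that count as accessible; default hairpin,
#'   internal and bulge loops (bulges being one-sided internal loops).
#' @param contiguous if `TRUE` (default) the accessible stretch must be
#'   contiguous within one loop; if `FALSE` the total count of accessible
#'   positions is returned instead.
#' @return Integer number of nucleotides, between 0 and the site length.
#' @export
usable_length <- function(site, structure,
                          eligible = c("hairpin", "internal", "bulge"),
                          contiguous = TRUE) {
  stopifnot(inherits(structure, "secondary_structure"))
  n <- length(structure$pairing)
  start <- site$start[1L]; end <- site$end[1L]
  if (start < 0L || end > n) stop("site out of structure bounds")
  pos <- (start + 1L):end
  ok <- structure$loop_label[pos] %in% eligible &
    is.na(structure$pairing[pos])
  if (!contiguous) return(sum(ok))
  if (!any(ok)) return(0L)
  id <- ifelse(ok, structure$loop_id[pos], -1L)
  r <- rle(id)
  max(r$lengths[r$values >= 0L])
}

#' Filter motif sites by secondary-structure accessibility
#'
#' Applies [usable_length()] to every site; a site is retained when its
#' usable length still satisfies the minimum motif length.  The "before"
#' length distribution uses the full site lengths, the "after" distribution
#' the usable lengths of the retained sites — the comparison that shows the
#' reduction in number and length of motifs imposed by RNA folding.
#'
#' @param sites a `motif_sites` data frame (all on the structure's sequence).
#' @param structure a `secondary_structure` from [classify_positions()].
#' @param criteria the [motif_criteria()] that produced the sites (supplies
#'   `min_length`).
#' @inheritParams usable_length
#' @return A list with `usable` (the sites with `usable_length` and
#'   `retained` columns appended), `retained` (retained subset), `before`
#'   and `after` ([length_distribution()]s).
#' @export
filter_sites <- function(sites, structure, criteria,
                         eligible = c("hairpin", "internal", "bulge"),
                         contiguous = TRUE) {
  ul <- vapply(seq_len(nrow(sites)), function(i)
    as.integer(usable_length(sites[i, ], structure, eligible, contiguous)),
    integer(1))
  out <- as.data.frame(sites)
  out$usable_length <- if (nrow(sites)) ul else integer(0)
  out$retained <- out$usable_length >= criteria$min_length
  retained <- out[out$retained, , drop = FALSE]
  list(usable = out,
       retained = retained,
       before = length_distribution(sites),
       after = length_distribution(retained$usable_length))
}
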