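#' Read a FASTA file into normalized nucleotide sequences
#'
#' Sequences are normalized to the internal DNA alphabet: upper case, U
#' mapped to T (RNA and DNA motifs are treated on one alphabet, as motif
#' sequences derive from genomic sequence), and IUPAC ambiguity codes
#' collapsed to `N` with a warning.  `N` breaks motifs during scanning.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of residue strings, in input order, with
#'   attribute `alphabet_note` (`"RNA"` if the record contained U, else
#'   `"DNA"`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  raw <- as.character(x)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier")
  up <- toupper(raw)
  note <- ifelse(grepl("U", up, fixed = TRUE), "RNA", "DNA")
  s <- chartr("U", "T", up)
  bad <- gsub("[ACGTN]", "", s)
  if (any(nzchar(bad))) {
    badchars <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
    amb <- badchars[badchars %in% strsplit("RYSWKMBDHV", "")[[1]]]
    if (length(amb) < length(badchars))
      stop("illegal residue character(s): ",
           paste(setdiff(badchars, amb), collapse = ", "))
    warning("IUPAC ambiguity code(s) ", paste(amb, collapse = ", "),
            " mapped to N")
    s <- chartr("RYSWKMBDHV", strrep("N", 10L), s)
  }
  names(s) <- ids
  attr(s, "alphabet_note") <- note
  s
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector of residue strings (as returned by
#'   [read_fasta()] or the synthetic generators).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.  `read_fasta(write_fasta(x))` reproduces ids
#'   and residues.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (length(records) == 0L) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    n <- nchar(s)
    if (n > 0L)
      writeLines(substring(s, seq(1L, n, width),
                           pmin(seq(1L, n, width) + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a RepeatMasker .out annotation table
#'
#' Parses the standard RepeatMasker `.out` dialect: three header lines
#' followed by whitespace-separated columns.  Parsing is lenient about the
#' exact number of trailing columns; the first eleven are required.
#' Coordinates are converted from RepeatMasker's 1-based inclusive convention
#' to 0-based half-open, and strand `"C"` (complement) is mapped to `"-"`.
#' The class/family column (`"LINE/L1"`) is split into `repeat_class`
#' (`"LINE"`) and `repeat_family` (`"L1"`).
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return A `repeat_annotation` data frame with columns `chrom`, `start`,
#'   `end`, `strand`, `repeat_class`, `repeat_family`, `subfamily`, `length`,
#'   in file order.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # drop the banner (header lines start with SW/score) and blank lines
  body <- lines[!grepl("^\\s*(SW|score)", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L)
    return(new_repeat_annotation(character(), integer(), integer(),
                                 character(), character(), character()))
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 11L))
    stop("malformed RepeatMasker line (fewer than 11 columns): line ",
         which(ncol < 11L)[1L])
  get <- function(k) vapply(fields, `[[`, character(1), k)
  qbegin <- suppressWarnings(as.integer(get(6L)))
  qend <- suppressWarnings(as.integer(get(7L)))
  if (anyNA(qbegin) || anyNA(qend))
    stop("non-numeric coordinates in RepeatMasker file")
  strand <- get(9L)
  if (!all(strand %in% c("+", "C", "-")))
    stop("unrecognized strand symbol(s): ",
         paste(setdiff(unique(strand), c("+", "C", "-")), collapse = ", "))
  strand[strand == "C"] <- "-"
  cf <- get(11L)
  new_repeat_annotation(chrom = get(5L), start = qbegin - 1L, end = qend,
                        strand = strand,
                        class_family = cf, subfamily = get(10L))
}

new_repeat_annotation <- function(chrom, start, end, strand, class_family,
                                  subfamily) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L | start >= end))
    stop("invalid annotation interval(s): need 0 <= start < end")
  cls <- sub("/.*$", "", class_family)
  fam <- ifelse(grepl("/", class_family),
                sub("^[^/]*/", "", class_family), class_family)
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   repeat_class = cls, repeat_family = fam,
                   subfamily = subfamily, length = end - start,
                   stringsAsFactors = FALSE)
  class(df) <- c("repeat_annotation", "data.frame")
  df
}

#' Write annotations in RepeatMasker .out dialect
#'
#' Emits the three banner lines and the eleven leading columns
#' [read_repeatmasker_out()] consumes (score/divergence columns are filled
#' with zeros).  Used to produce synthetic annotation fixtures;
#' `read_repeatmasker_out(write_repeatmasker_out(x))` reproduces the
#' intervals, strands and family fields.
#'
#' @param annotations a `repeat_annotation` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat       position in repeat",
    "score  div. del. ins.  sequence  begin  end   (left)  repeat   class/family begin  end (left)  ID",
    ""), con)
  if (nrow(annotations)) {
    strand <- ifelse(annotations$strand == "-", "C", "+")
    cf <- ifelse(annotations$repeat_family == annotations$repeat_class,
                 annotations$repeat_class,
                 paste0(annotations$repeat_class, "/",
                        annotations$repeat_family))
    writeLines(sprintf("%5d %5.1f %4.1f %4.1f  %s %d %d (0) %s %s %s 1 %d (0) %d",
                       0L, 0, 0, 0, annotations$chrom,
                       annotations$start + 1L, annotations$end, strand,
                       annotations$subfamily, cf, annotations$length,
                       seq_len(nrow(annotations))), con)
  }
  invisible(path)
}

#' Parse a dot-bracket secondary structure string
#'
#' @param db a dot-bracket string over `"."`, `"("`, `")"`.
#' @return An integer pairing vector: position `i` holds the 1-based partner
#'   index, or `NA` if unpaired.  The table is an involution.
#' @export
parse_dot_bracket <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c(".", "(", ")")))
    stop("dot-bracket string may contain only '.', '(' and ')'")
  pairing <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets: ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairing[i] <- j; pairing[j] <- i
    }
  }
  if (length(stack) > 0L)
    stop("unbalanced brackets: unmatched '(' at position ", stack[1L])
  pairing
}

#' Read a secondary structure file (dot-bracket or CT)
#'
#' Dot-bracket (Vienna) files may contain an optional `>` header line and an
#' optional sequence line before the structure line.  CT files use the
#' six-column connectivity-table layout with partner index 0 for unpaired
#' positions; partner columns must be symmetric.
#'
#' @param path path to the structure file.
#' @param format `"dot-bracket"`, `"ct"`, or `"auto"` (by file extension:
#'   `.ct` means CT, anything else dot-bracket).
#' @return Integer pairing vector as in [parse_dot_bracket()].
#' @export
read_structure <- function(path, format = c("auto", "dot-bracket", "ct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.ct$", path, ignore.case = TRUE)) "ct"
              else "dot-bracket"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "dot-bracket") {
    lines <- lines[!grepl("^>", lines)]
    is_struct <- grepl("^[.()]+$", trimws(lines))
    if (!any(is_struct)) stop("no dot-bracket structure line found in ", path)
    parse_dot_bracket(trimws(lines[is_struct][1L]))
  } else {
    n <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]),
                                              "\\s+")[[1]][1L]))
    if (is.na(n)) stop("malformed CT header line")
    body <- lines[-1L][seq_len(n)]
    fields <- strsplit(trimws(body), "\\s+")
    if (any(vapply(fields, length, integer(1)) < 6L))
      stop("malformed CT line (fewer than 6 columns)")
    partner <- vapply(fields, function(f) as.integer(f[5L]), integer(1))
    pairing <- ifelse(partner == 0L, NA_integer_, partner)
    paired <- which(!is.na(pairing))
    if (any(pairing[paired] == paired))
      stop("CT position paired to itself")
    if (!all(pairing[pairing[paired]] == paired, na.rm = TRUE) ||
        anyNA(pairing[pairing[paired]]))
      stop("CT partner columns are not symmetric")
    pairing
  }
}

#' Write motif sites to a TSV table (and optionally BED6)
#'
#' @param sites a `motif_sites` data frame.
#' @param path output TSV path.
#' @param bed_path optional path for a BED6 export (same 0-based half-open
#'   coordinates; score column holds the motif length).
#' @return `path`, invisibly.
#' @export
write_sites_table <- function(sites, path, bed_path = NULL) {
  cols <- c("seq_id", "start", "end", "length", "motif_class", "sequence")
  df <- as.data.frame(sites)[, cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(df$seq_id, df$start, df$end,
                      sprintf("%s_%d", df$motif_class, seq_len(nrow(df))),
                      df$length, rep("+", nrow(df)))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a motif sites TSV written by [write_sites_table()]
#' @param path path to the TSV.
#' @return A `motif_sites` data frame.
#' @export
read_sites_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(seq_id = "character",
                                         sequence = "character"))
  class(df) <- c("motif_sites", "data.frame")
  df
}
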