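#' Fetch a single nucleotide accession from NCBI as FASTA
#'
#' Convenience helper for the accession-based workflow (e.g. the XIST, Xist
#' and Rsx reference transcripts NR_001564, NR_001463, JQ937282).  Requires
#' network access; everything else in the package works offline.
#'
#' @param accession NCBI nucleotide accession.
#' @param dest destination FASTA path (default: `<accession>.fa` in the
#'   current directory).
#' @param timeout download timeout in seconds.
#' @return `dest`, invisibly.
#' @export
fetch_transcript <- function(accession, dest = paste0(accession, ".fa"),
                             timeout = 60) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=", accession)
  old <- options(timeout = timeout)
  on.exit(options(old))
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "w"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) ||
      file.size(dest) == 0L || !startsWith(readLines(dest, n = 1L), ">")) {
    unlink(dest)
    stop("could not fetch accession ", accession,
         " (no network access, or the accession does not exist)")
  }
  invisible(dest)
}
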