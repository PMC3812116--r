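#' Read and write multi-record FASTA
#'
#' Thin wrappers around Biostrings; sequences are handled package-wide as
#' named character vectors of uppercase DNA.
#'
#' @param file Path to a FASTA file.
#' @param sequences Named character vector of DNA strings.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns its input invisibly.
#' @export
read_fasta <- function(file) {
  if (!file.exists(file)) stop("FASTA file not found: ", file)
  set <- tryCatch(Biostrings::readDNAStringSet(file),
                  error = function(e)
                    stop("malformed FASTA '", file, "': ",
                         conditionMessage(e)))
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, file) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, file)
  invisible(sequences)
}

#' Write a BED6 file of candidate intervals
#'
#' @param candidates List of classified [crm_candidate()] objects.
#' @param file Output path.
#' @return The input, invisibly.
#' @export
write_candidates_bed <- function(candidates, file) {
  rows <- lapply(candidates, function(x)
    data.frame(x$seq_id, x$start, x$end,
               paste0(x$architecture, "_", x$n_confident, "site"),
               x$n_confident, "+"))
  bed <- do.call(rbind, rows)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(candidates)
}
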