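#' Construct a genome set
#'
#' A genome set is the in-memory form of one assembly: a named set of
#' uppercase chromosome sequences plus an assembly identifier.  All
#' package-internal coordinates on these sequences are 0-based half-open;
#' conversion to the 1-based inclusive convention of FASTA-adjacent text
#' formats happens only in the readers and writers.
#'
#' @param sequences named character vector of DNA sequences (or a
#'   [Biostrings::DNAStringSet]); lowercase is folded to uppercase.
#' @param assembly_id single string naming the assembly.
#' @return object of class `genome_set`: a named character vector with an
#'   `assembly_id` attribute.
#' @export
genome_set <- function(sequences, assembly_id = "genome") {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    abort("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    abort(paste("duplicate sequence names:",
                paste(unique(names(sequences)[duplicated(names(sequences))]),
                      collapse = ", ")))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    abort(paste("non-ACGTN characters in:", paste(names(sequences)[bad], collapse = ", ")))
  structure(sequences, assembly_id = assembly_id, class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set>", attr(x, "assembly_id"), "-", length(x), "sequence(s),",
      format(sum(nchar(x)), big.mark = ","), "bp\n")
  for (nm in names(x)) cat(" ", nm, ":", nchar(x[[nm]]), "bp\n")
  invisible(x)
}

#' Chromosome lengths of a genome set
#' @param genome a `genome_set`.
#' @return named integer vector of sequence lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' @export
`[.genome_set` <- function(x, i) {
  genome_set(unclass(x)[i], assembly_id = attr(x, "assembly_id"))
}

# Extract [start, end) (0-based half-open) from one chromosome.
genome_slice <- function(genome, chrom, start, end) {
  substr(unclass(genome)[[chrom]], start + 1L, end)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @param assembly_id assembly name; defaults to the file stem.
#' @return a [genome_set()].
#' @export
read_genome <- function(path, assembly_id = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) abort(paste("empty FASTA:", path))
  names(ss) <- sub("\\s.*$", "", names(ss))
  genome_set(ss, assembly_id = assembly_id %||%
               sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path)))
}

#' Write a genome to FASTA
#'
#' @param genome a `genome_set`.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
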