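# Standard-format I/O thin wrappers.

#' Read a codon alignment from multi-FASTA
#'
#' @param path FASTA file of aligned, in-frame nucleotide sequences.
#' @param gene Gene identifier (defaults to the file name).
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, gene = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
  codon_alignment(seqs, gene = gene %||%
                    sub("\\.[^.]*$", "", basename(path)))
}

#' Write a codon alignment to multi-FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  x <- Biostrings::DNAStringSet(aln$seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a species tree in newick format
#'
#' @param path Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_species_tree <- function(path) ape::read.tree(path)

#' Write a filter report as TSV
#'
#' @param report A [filter_report()] (or the `report` element of
#'   [qc_alignments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
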