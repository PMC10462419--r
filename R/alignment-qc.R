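# Alignment hygiene: frame checks, gap-column trimming, and the gene-set
# filters producing the "aligned gene set" from raw codon alignments.

#' Construct a codon alignment
#'
#' @param seqs Named character vector: one in-frame gapped sequence per
#'   lineage, all of equal length divisible by 3.
#' @param gene Gene identifier.
#' @return Object of class `codon_alignment`: a list with `gene`,
#'   `lineages`, `seqs`, `n_codons`.
#' @export
codon_alignment <- function(seqs, gene = "gene") {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences have unequal lengths")
  if (len %% 3L != 0L) stop("alignment length not divisible by 3: ", len)
  structure(list(gene = gene, lineages = names(seqs), seqs = seqs,
                 n_codons = len %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment '", x$gene, "': ", length(x$seqs), " lineages x ",
      x$n_codons, " codons\n", sep = "")
  invisible(x)
}

# Matrix of codons: lineages x codon columns.
codon_matrix <- function(aln) {
  m <- t(vapply(aln$seqs, split_codons, character(aln$n_codons)))
  if (aln$n_codons == 1L) m <- matrix(m, ncol = 1L,
                                      dimnames = list(aln$lineages, NULL))
  rownames(m) <- aln$lineages
  m
}

is_gap_codon <- function(codon) grepl("-", codon, fixed = TRUE)
is_missing_codon <- function(codon) !grepl("^[ACGT]{3}$", codon)

#' Check reading-frame integrity of an alignment
#'
#' An alignment fails if any sequence contains an interspersed (internal)
#' stop codon in its ungapped reading frame, or a gap run whose length is
#' not a multiple of three (a frame-shifting indel). A terminal stop
#' codon is permitted.
#'
#' @param aln A [codon_alignment()].
#' @inheritParams genetic_code
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
check_frame_integrity <- function(aln, code = NULL) {
  stops <- stop_codons(code)
  for (s in aln$seqs) {
    runs <- regmatches(s, gregexpr("-+", s))[[1]]
    if (any(nchar(runs) %% 3L != 0L)) return(FALSE)
    ungapped <- gsub("-", "", s, fixed = TRUE)
    if (nchar(ungapped) == 0L) next
    cods <- split_codons(ungapped)
    internal <- cods[-length(cods)]
    if (any(internal %in% stops)) return(FALSE)
  }
  TRUE
}

#' Remove codon columns with too many gaps
#'
#' Codon columns in which the fraction of lineages carrying a gap codon
#' is strictly greater than `max_gap_fraction` are removed; whole codons
#' are always removed so the frame is preserved.
#'
#' @param aln A [codon_alignment()].
#' @param max_gap_fraction Gap-fraction threshold (default 0.5, i.e.
#'   columns with more than 50% gaps across lineages are dropped).
#' @return Trimmed `codon_alignment`. An attribute `"columns_removed"`
#'   records the 1-based indices of the dropped codon columns. If every
#'   column is removed the result has zero codons.
#' @export
trim_gap_columns <- function(aln, max_gap_fraction = 0.5) {
  m <- codon_matrix(aln)
  gap_frac <- colMeans(matrix(is_gap_codon(m), nrow = nrow(m)))
  drop <- which(gap_frac > max_gap_fraction)
  keep <- setdiff(seq_len(ncol(m)), drop)
  seqs <- vapply(seq_len(nrow(m)),
                 function(i) paste(m[i, keep], collapse = ""), character(1))
  names(seqs) <- rownames(m)
  if (length(keep) == 0L) seqs[] <- ""
  out <- structure(list(gene = aln$gene, lineages = aln$lineages,
                        seqs = seqs, n_codons = length(keep)),
                   class = "codon_alignment")
  attr(out, "columns_removed") <- drop
  out
}

#' Apply the aligned-gene-set filters to a trimmed alignment
#'
#' Rejects an alignment if any lineage has more than
#' `max_missing_per_lineage` missing codons (gap or fully ambiguous),
#' if the mean per-sequence gap fraction (nucleotide level) exceeds
#' `max_mean_gap_fraction`, or if the alignment is shorter than
#' `min_length_bp`.
#'
#' @param aln A trimmed [codon_alignment()].
#' @param min_length_bp Minimum alignment length in base pairs
#'   (default 300, i.e. 100 codons).
#' @param max_missing_per_lineage Maximum tolerated missing-codon
#'   fraction in any single lineage (default 0.5).
#' @param max_mean_gap_fraction Maximum tolerated mean per-sequence gap
#'   fraction (default 0.25).
#' @return List with `keep` (logical) and `report`, a [filter_report()]
#'   data frame with one row per rule.
#' @export
filter_alignment <- function(aln, min_length_bp = 300,
                             max_missing_per_lineage = 0.5,
                             max_mean_gap_fraction = 0.25) {
  m <- codon_matrix(aln)
  len_bp <- 3L * aln$n_codons
  missing_frac <- if (aln$n_codons > 0L) {
    rowMeans(matrix(is_missing_codon(m), nrow = nrow(m)))
  } else rep(1, length(aln$seqs))
  gap_frac <- if (len_bp > 0L) {
    vapply(aln$seqs,
           function(s) sum(strsplit(s, "")[[1]] == "-") / nchar(s),
           numeric(1))
  } else rep(1, length(aln$seqs))
  rules <- data.frame(
    gene = aln$gene,
    rule = c("min_length_bp", "max_missing_per_lineage",
             "max_mean_gap_fraction"),
    value = c(len_bp, max(missing_frac), mean(gap_frac)),
    threshold = c(min_length_bp, max_missing_per_lineage,
                  max_mean_gap_fraction),
    fail = c(len_bp < min_length_bp,
             max(missing_frac) > max_missing_per_lineage,
             mean(gap_frac) > max_mean_gap_fraction),
    stringsAsFactors = FALSE)
  list(keep = !any(rules$fail), report = filter_report(rules))
}

#' Per-gene filter report
#'
#' @param df Data frame with columns `gene`, `rule`, `value`,
#'   `threshold`, `fail`.
#' @return The data frame with class `filter_report` prepended.
#' @export
filter_report <- function(df) {
  stopifnot(all(c("gene", "rule", "value", "threshold", "fail") %in%
                  names(df)))
  class(df) <- c("filter_report", class(df))
  df
}

#' Exclude genes with saturated or unestimable substitution rates
#'
#' @param ds Numeric vector of gene-wide synonymous rates.
#' @param omega Numeric vector of gene-wide dN/dS.
#' @param max_ds Saturation bound; genes with `ds > max_ds` are rejected
#'   (default 30).
#' @param max_omega Genes with `omega >= max_omega` are rejected
#'   (default 999; flags absence of synonymous substitutions).
#' @return Logical vector, `TRUE` = keep. Genes with missing rates are
#'   rejected (unestimable).
#' @export
filter_rate_outliers <- function(ds, omega, max_ds = 30, max_omega = 999) {
  keep <- !is.na(ds) & !is.na(omega) & ds <= max_ds & omega < max_omega
  keep
}

#' Run the full QC chain on a batch of raw alignments
#'
#' Frame check, gap-column trimming, and gene-set filters, in the order
#' applied to the aligned gene set.
#'
#' @param alignments List of [codon_alignment()] objects.
#' @param ... Passed to [filter_alignment()].
#' @return List with `kept` (list of trimmed alignments that passed) and
#'   `report`, a data frame of per-gene rule outcomes.
#' @export
qc_alignments <- function(alignments, ...) {
  kept <- list()
  rows <- list()
  for (aln in alignments) {
    if (!check_frame_integrity(aln)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = aln$gene, rule = "frame_integrity", value = NA_real_,
        threshold = NA_real_, fail = TRUE, stringsAsFactors = FALSE)
      next
    }
    trimmed <- trim_gap_columns(aln)
    res <- filter_alignment(trimmed, ...)
    rows[[length(rows) + 1L]] <- res$report
    if (res$keep) kept[[trimmed$gene]] <- trimmed
  }
  list(kept = kept, report = do.call(rbind, rows))
}
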