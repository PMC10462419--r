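# tRNA gene repertoire: parsing tRNAscan-SE 2.x tabular output,
# filtering non-functional models, anticodon copy numbers, RAIT, and
# the GC3 of the codon-equivalent population. Wobble pairing is NOT
# modeled: each anticodon is linked only to its direct reverse-
# complement codon (recorded in summaries as a caveat).

#' Parse tRNAscan-SE 2.x tabular output
#'
#' Reads the whitespace-separated table produced by tRNAscan-SE
#' (`-o` output): header lines up to the dashed rule are skipped;
#' minus-strand genes (begin > end in the source) are normalized to
#' `begin < end` with `strand = "-"`; rows whose note field contains
#' `pseudo` or `trunc` are flagged non-functional. Malformed rows are
#' skipped with a warning.
#'
#' @param path Path to a tRNAscan-SE output file.
#' @return Data frame with columns `chrom`, `begin`, `end`, `strand`,
#'   `isotype`, `anticodon`, `score`, `pseudo`, `truncated`, `retained`,
#'   `note`. Attribute `"n_skipped"` counts malformed rows.
#' @export
parse_trnascan <- function(path) {
  lines <- readLines(path)
  rule <- grep("^-+\\s", lines)
  body <- if (length(rule)) lines[-seq_len(rule[1])] else
    lines[!grepl("^(Sequence|Name|-)", lines)]
  body <- body[nzchar(trimws(body))]
  rows <- list()
  skipped <- 0L
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 9L || is.na(suppressWarnings(as.integer(f[3])))) {
      warning("skipping malformed tRNAscan row: ", ln)
      skipped <- skipped + 1L
      next
    }
    b <- as.integer(f[3]); e <- as.integer(f[4])
    note <- if (length(f) >= 10L) paste(f[10:length(f)], collapse = " ")
      else ""
    pseudo <- grepl("pseudo", note, ignore.case = TRUE)
    trunc <- grepl("trunc", note, ignore.case = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = f[1], begin = min(b, e), end = max(b, e),
      strand = if (b > e) "-" else "+",
      isotype = f[5], anticodon = toupper(f[6]),
      score = as.numeric(f[9]),
      pseudo = pseudo, truncated = trunc,
      retained = !pseudo && !trunc, note = note,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), begin = integer(), end = integer(),
               strand = character(), isotype = character(),
               anticodon = character(), score = numeric(),
               pseudo = logical(), truncated = logical(),
               retained = logical(), note = character())
  attr(out, "n_skipped") <- skipped
  out
}

#' Convert an anticodon to its codon equivalent
#'
#' The codon read 5'->3' is the reverse complement of the anticodon read
#' 5'->3'.
#'
#' @param anticodon Character vector of triplets.
#' @return Character vector of codons.
#' @export
#' @examples
#' anticodon_to_codon("GCC") # GGC
anticodon_to_codon <- function(anticodon) revcomp(anticodon)

#' Summarize tRNA-gene copy numbers
#'
#' Filters to functional gene models (no pseudogene/truncation flags,
#' optionally restricted to an allowlist of sequence names), then counts
#' copies per anticodon and per amino acid, with median/range summaries
#' and an outlier report (anticodons above the Tukey fence
#' `Q3 + 3 * IQR` of copy numbers).
#'
#' @param genes Data frame from [parse_trnascan()].
#' @param allowlist Optional character vector of chromosome names to
#'   keep (e.g. chromosome-level scaffolds only).
#' @inheritParams genetic_code
#' @return Object of class `trna_summary`: `anticodon_counts` (named
#'   integer vector), `aa_counts`, `codon_equivalent` (named character),
#'   `median_copies`, `range_copies`, `outliers`, `n_parsed`,
#'   `n_retained`.
#' @export
copy_numbers <- function(genes, allowlist = NULL, code = NULL) {
  keep <- genes$retained
  if (!is.null(allowlist)) keep <- keep & genes$chrom %in% allowlist
  g <- genes[keep, , drop = FALSE]
  cnt <- table(g$anticodon)
  counts <- stats::setNames(as.integer(cnt), names(cnt))
  gcode <- genetic_code(code)
  cod <- if (length(counts)) anticodon_to_codon(names(counts)) else
    character(0)
  aa <- stats::setNames(unname(gcode[cod]), names(counts))
  aa_counts <- if (length(counts)) tapply(counts, aa, sum) else integer(0)
  fence <- if (length(counts) >= 4L) {
    q <- stats::quantile(counts, c(0.25, 0.75))
    q[2] + 3 * (q[2] - q[1])
  } else Inf
  structure(list(
    anticodon_counts = counts,
    aa_counts = aa_counts,
    codon_equivalent = stats::setNames(cod, names(counts)),
    anticodon_aa = aa,
    median_copies = if (length(counts)) stats::median(counts) else NA,
    range_copies = if (length(counts)) range(counts) else c(NA, NA),
    outliers = names(counts)[counts > fence],
    n_parsed = nrow(genes), n_retained = nrow(g),
    wobble_modeled = FALSE), class = "trna_summary")
}

#' @export
print.trna_summary <- function(x, ...) {
  cat("trna_summary:", x$n_retained, "functional tRNA genes (of",
      x$n_parsed, "parsed),", length(x$anticodon_counts),
      "unique anticodons; median copies", x$median_copies, "\n")
  if (length(x$outliers)) cat("  outlier anticodons:",
                              paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Relative abundance of isoacceptor tRNAs (RAIT)
#'
#' RSCU-equivalent statistic on anticodon copy numbers:
#' `RAIT = k * copies / family_total`, where the family is the set of
#' anticodons serving one amino acid and `k` is the number of synonymous
#' codons of that amino acid. RAIT > 1 marks overrepresented anticodons.
#'
#' @param summary A `trna_summary` from [copy_numbers()].
#' @param exclude Anticodons to drop before computing (e.g. a suspected
#'   repeat-driven outlier).
#' @inheritParams genetic_code
#' @return Data frame: `anticodon`, `codon`, `aa`, `copies`, `rait`,
#'   `ending` (S/W class of the codon-equivalent third base).
#' @export
rait <- function(summary, exclude = character(), code = NULL) {
  stopifnot(inherits(summary, "trna_summary"))
  counts <- summary$anticodon_counts
  counts <- counts[!(names(counts) %in% exclude)]
  if (!length(counts)) {
    return(data.frame(anticodon = character(), codon = character(),
                      aa = character(), copies = integer(),
                      rait = numeric(), ending = character()))
  }
  gcode <- genetic_code(code)
  cod <- anticodon_to_codon(names(counts))
  aa <- unname(gcode[cod])
  fam_size <- table(gcode[sense_codons(code)])   # synonymous codons per aa
  fam_total <- tapply(counts, aa, sum)
  out <- data.frame(
    anticodon = names(counts), codon = cod, aa = aa,
    copies = as.integer(counts),
    rait = as.numeric(fam_size[aa]) * as.integer(counts) /
      as.numeric(fam_total[aa]),
    ending = classify_base(substr(cod, 3, 3)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' GC3 of the tRNA codon-equivalent population
#'
#' GC-content at third codon positions of the codon equivalents of the
#' tRNA repertoire, weighted by gene copy number (default) or counting
#' each represented anticodon once.
#'
#' @param summary A `trna_summary`.
#' @param exclude Anticodons to drop (outlier toggle).
#' @param weighted Copy-weighted (default) or per-unique-anticodon.
#' @return GC3 fraction in `[0, 1]`.
#' @export
trna_gc3 <- function(summary, exclude = character(), weighted = TRUE) {
  stopifnot(inherits(summary, "trna_summary"))
  counts <- summary$anticodon_counts
  counts <- counts[!(names(counts) %in% exclude)]
  if (!length(counts)) return(NA_real_)
  third <- substr(anticodon_to_codon(names(counts)), 3, 3)
  w <- if (weighted) as.numeric(counts) else rep(1, length(counts))
  sum(w[third %in% c("G", "C")]) / sum(w)
}
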