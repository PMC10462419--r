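# Genetic-code tables, strong/weak base classes, site degeneracy, and
# codon-position GC metrics shared by every downstream stage.

BASES <- c("A", "C", "G", "T")

# Standard nuclear genetic code; injectable everywhere via the `code`
# argument so alternative translation tables can be supplied later.
.standard_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(code), names(code))
}

.pkg_cache <- new.env(parent = emptyenv())

#' Standard genetic code table
#'
#' Returns the standard nuclear genetic code as a named character vector
#' mapping each of the 64 codons to its one-letter amino acid, with `"*"`
#' for the three stop codons.
#'
#' @param code Optional replacement code table (named character vector of
#'   length 64, names = codons, values = amino acids or `"*"`).
#' @return Named character vector of length 64.
#' @export
#' @examples
#' gc <- genetic_code()
#' gc["ATG"]
genetic_code <- function(code = NULL) {
  if (!is.null(code)) {
    stopifnot(is.character(code), length(code) == 64L, !is.null(names(code)))
    return(code)
  }
  if (is.null(.pkg_cache$code)) .pkg_cache$code <- .standard_code()
  .pkg_cache$code
}

#' Sense codons of a genetic code
#'
#' @inheritParams genetic_code
#' @return Character vector of the 61 non-stop codons (standard code).
#' @export
sense_codons <- function(code = NULL) {
  code <- genetic_code(code)
  names(code)[code != "*"]
}

#' Stop codons of a genetic code
#' @inheritParams genetic_code
#' @return Character vector of stop codons.
#' @export
stop_codons <- function(code = NULL) {
  code <- genetic_code(code)
  names(code)[code == "*"]
}

#' Classify bases as strong (S) or weak (W)
#'
#' G and C pair with three hydrogen bonds and are classed strong (S);
#' A and T pair with two and are classed weak (W).
#'
#' @param base Character vector of single bases.
#' @param strict If `TRUE` (default), any base outside A/C/G/T raises an
#'   error; if `FALSE`, such bases return `NA` so the caller can mask them.
#' @return Character vector of `"S"`/`"W"` (possibly `NA` when
#'   `strict = FALSE`).
#' @export
#' @examples
#' classify_base(c("G", "T"))
classify_base <- function(base, strict = TRUE) {
  base <- toupper(base)
  out <- ifelse(base %in% c("G", "C"), "S",
                ifelse(base %in% c("A", "T"), "W", NA_character_))
  if (strict && anyNA(out)) {
    stop("unclassifiable base(s): ",
         paste(unique(base[is.na(out)]), collapse = ", "))
  }
  out
}

# Mutation class of a single-base change: "SW" (GC-decreasing),
# "WS" (GC-increasing) or "conservative" (S->S / W->W).
mutation_class <- function(from, to) {
  cf <- classify_base(from)
  ct <- classify_base(to)
  ifelse(cf == ct, "conservative", ifelse(cf == "S", "SW", "WS"))
}

.degeneracy_table <- function(code = NULL) {
  code <- genetic_code(code)
  sense <- names(code)[code != "*"]
  out <- matrix(NA_integer_, nrow = length(sense), ncol = 3L,
                dimnames = list(sense, NULL))
  for (cd in sense) {
    sp <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      alt <- vapply(BASES, function(b) {
        x <- sp; x[pos] <- b
        code[[paste(x, collapse = "")]]
      }, character(1))
      k <- sum(alt == code[[cd]])
      out[cd, pos] <- if (k == 1L) 0L else k
    }
  }
  out
}

#' Site degeneracy of a codon position
#'
#' Number of nucleotides at a position that preserve the encoded amino
#' acid (holding the other two positions fixed). A position with no
#' synonymous alternative is reported as 0-fold; fully synonymous
#' positions are 4-fold. The 3-fold class (isoleucine third positions)
#' is kept distinct.
#'
#' @param codon Character vector of sense codons.
#' @param position Integer vector in 1..3 (recycled).
#' @inheritParams genetic_code
#' @return Integer vector with values in \{0, 2, 3, 4\}; `NA` for codons
#'   containing gaps or ambiguity codes (masked).
#' @export
#' @examples
#' site_degeneracy("GGA", 3) # 4-fold
#' site_degeneracy("ATG", 3) # 0-fold
site_degeneracy <- function(codon, position, code = NULL) {
  codon <- toupper(codon)
  stopifnot(all(position %in% 1:3))
  n <- max(length(codon), length(position))
  codon <- rep_len(codon, n)
  position <- rep_len(as.integer(position), n)
  tab <- if (is.null(code)) {
    if (is.null(.pkg_cache$deg)) .pkg_cache$deg <- .degeneracy_table()
    .pkg_cache$deg
  } else .degeneracy_table(code)
  gcode <- genetic_code(code)
  out <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    cd <- codon[j]
    if (!grepl("^[ACGT]{3}$", cd)) next   # gap/ambiguous codon -> masked
    if (gcode[[cd]] == "*") stop("stop codon has no site degeneracy: ", cd)
    out[j] <- tab[cd, position[j]]
  }
  out
}

#' Codon-position GC content of an in-frame sequence
#'
#' Computes GC1, GC2, GC3 (fraction of G/C at first, second, and third
#' codon positions), their combination GC12 = (GC1 + GC2)/2, and the
#' number of codons used. Codons containing gaps or ambiguity codes are
#' masked before counting.
#'
#' @param sequence Character scalar (in-frame nucleotide sequence, gaps
#'   allowed as `-`), or character vector of codons.
#' @param gene Optional gene identifier recorded in the output.
#' @param lineage Optional lineage identifier recorded in the output.
#' @return One-row data frame with columns `gene`, `lineage`, `gc1`,
#'   `gc2`, `gc3`, `gc12`, `n_codons`. If no clean codon remains all GC
#'   fields are `NA` (profile undefined; exclude downstream).
#' @export
#' @examples
#' gc_by_position("ATGATG")
gc_by_position <- function(sequence, gene = NA_character_,
                           lineage = NA_character_) {
  cods <- if (length(sequence) == 1L && nchar(sequence[1]) > 3L) {
    split_codons(sequence)
  } else toupper(sequence)
  cods <- cods[grepl("^[ACGT]{3}$", cods)]
  if (length(cods) == 0L) {
    return(data.frame(gene = gene, lineage = lineage, gc1 = NA_real_,
                      gc2 = NA_real_, gc3 = NA_real_, gc12 = NA_real_,
                      n_codons = 0L, stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, strsplit(cods, ""))
  gc <- colMeans(matrix(m %in% c("G", "C"), ncol = 3L))
  data.frame(gene = gene, lineage = lineage,
             gc1 = gc[1], gc2 = gc[2], gc3 = gc[3],
             gc12 = (gc[1] + gc[2]) / 2, n_codons = length(cods),
             stringsAsFactors = FALSE)
}

#' Split an in-frame sequence into codons
#'
#' @param sequence Character scalar; `nchar` must be divisible by 3.
#' @return Character vector of codons (uppercase).
#' @export
split_codons <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3: ", n)
  if (n == 0L) return(character(0))
  substring(sequence, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Reverse complement for plain character vectors of triplets/bases.
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(sp) {
    if (!all(sp %in% BASES)) stop("non-ACGT base in: ", paste(sp, collapse = ""))
    paste(rev(unname(comp[sp])), collapse = "")
  }, character(1))
}
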