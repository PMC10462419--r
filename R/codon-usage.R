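# Codon usage tables, RSCU, and the effective number of codons:
# observed (Wright's homozygosity formulation), expected from GC3, and
# their normalized difference used as a codon-usage-bias score.

#' Codon usage table over the 61 sense codons
#'
#' Counts sense codons across one or more in-frame sequences; stop
#' codons and codons containing gaps or ambiguity codes are excluded
#' from both counts and denominator.
#'
#' @param sequences Character vector of in-frame nucleotide sequences
#'   (or a single sequence), or a `codon_alignment`.
#' @param scope Label recorded in the output (gene or lineage id).
#' @inheritParams genetic_code
#' @return Data frame of class `codon_usage_table` with one row per
#'   sense codon: `codon`, `aa`, `count`, `per_1000`. Attribute
#'   `"total_codons"` holds the denominator. Zero sense codons yields an
#'   all-zero table with `per_1000 = NA`.
#' @export
#' @examples
#' tab <- codon_frequencies(strrep("ATG", 100))
#' tab[tab$codon == "ATG", ]
codon_frequencies <- function(sequences, scope = NA_character_,
                              code = NULL) {
  if (inherits(sequences, "codon_alignment")) sequences <- sequences$seqs
  gcode <- genetic_code(code)
  sense <- sense_codons(code)
  cods <- unlist(lapply(sequences, split_codons), use.names = FALSE)
  cods <- cods[cods %in% sense]
  counts <- table(factor(cods, levels = sense))
  total <- sum(counts)
  out <- data.frame(codon = sense, aa = unname(gcode[sense]),
                    count = as.integer(counts),
                    per_1000 = if (total > 0L) 1000 * as.integer(counts) /
                      total else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "total_codons") <- total
  attr(out, "scope") <- scope
  class(out) <- c("codon_usage_table", class(out))
  out
}

#' Pool several codon usage tables
#'
#' Per-lineage usage "per 1,000 codons" is computed from pooled counts
#' across genes, not as a mean of per-gene frequencies.
#'
#' @param tables List of `codon_usage_table` objects.
#' @param scope Label for the pooled table.
#' @return A pooled `codon_usage_table`.
#' @export
pool_codon_usage <- function(tables, scope = NA_character_) {
  stopifnot(length(tables) >= 1L)
  out <- tables[[1]]
  counts <- Reduce(`+`, lapply(tables, function(t) t$count))
  out$count <- counts
  total <- sum(counts)
  out$per_1000 <- if (total > 0L) 1000 * counts / total else NA_real_
  if ("rscu" %in% names(out)) out$rscu <- NULL
  attr(out, "total_codons") <- total
  attr(out, "scope") <- scope
  out
}

#' Relative synonymous codon usage
#'
#' RSCU divides each codon's observed count by the count expected if all
#' synonymous codons of its amino acid were used equally:
#' `RSCU = k * n_codon / n_family` with `k` the family size. RSCU = 1
#' means equal usage; values above 1 mark overrepresented codons.
#'
#' @param table A `codon_usage_table` from [codon_frequencies()].
#' @return The table with an `rscu` column appended (`NA` for codons in
#'   families with zero total usage, flagged via the
#'   `"undefined_families"` attribute).
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  fam_total <- stats::ave(table$count, table$aa, FUN = sum)
  fam_size <- stats::ave(rep(1L, nrow(table)), table$aa, FUN = sum)
  table$rscu <- ifelse(fam_total > 0, fam_size * table$count / fam_total,
                       NA_real_)
  attr(table, "undefined_families") <- sort(unique(table$aa[fam_total == 0]))
  table
}

#' Observed effective number of codons (ENC)
#'
#' Wright-style ENC from synonymous-family homozygosities. For each
#' amino-acid family with total usage `n >= 2`,
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`; class means `Fbar_k` over
#' families of `k` synonymous codons combine as
#' `ENC = 2 + 9/Fbar_2 + 1/Fbar_3 + 5/Fbar_4 + 3/Fbar_6`, clamped to
#' the theoretical range 20 (one codon per amino acid) to 61 (uniform
#' usage). A degeneracy class with no estimable family has its mean
#' imputed from the mean of estimated classes (Wright's convention);
#' if no family at all is estimable the result is `NA`.
#'
#' @param table A `codon_usage_table`, or a named integer vector of
#'   codon counts.
#' @inheritParams genetic_code
#' @return ENC value in `[20, 61]`, or `NA` if undefined.
#' @export
enc_obs <- function(table, code = NULL) {
  if (inherits(table, "codon_usage_table")) {
    counts <- stats::setNames(table$count, table$codon)
  } else {
    counts <- table
    stopifnot(!is.null(names(counts)))
  }
  gcode <- genetic_code(code)
  sense <- sense_codons(code)
  counts <- counts[sense]
  counts[is.na(counts)] <- 0
  aa <- unname(gcode[sense])
  fam_sizes <- table(aa)              # codons per amino acid
  f_by_class <- list()
  for (a in names(fam_sizes)) {
    k <- as.integer(fam_sizes[[a]])
    if (k < 2L) next                  # Met, Trp carry the constant 2
    n <- sum(counts[aa == a])
    if (n < 2) next                   # family not estimable
    p <- counts[aa == a] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], f)
  }
  classes <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)  # families per class
  fbar <- vapply(names(classes), function(k) {
    v <- f_by_class[[k]]
    if (is.null(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (all(is.na(fbar))) return(NA_real_)
  fbar[is.na(fbar)] <- mean(fbar, na.rm = TRUE)   # impute missing class
  if (any(fbar <= 0)) return(61)    # no homozygosity signal: treat as even
  enc <- 2 + sum(classes / fbar)
  min(max(enc, 20), 61)
}

#' Configuration of the expected-ENC curve
#'
#' Constants of the composition-expected ENC curve
#' `ENC_exp = a + GC3 + b / (GC3^2 + (c - GC3)^2)`. The defaults
#' (`a = 6`, `b = 34`, `c = 1.025`) are simulation-optimized constants;
#' `enc_config(2, 29, 1)` gives Wright's classic published curve.
#'
#' @param a,b,c Curve constants.
#' @return List of class `enc_config`.
#' @export
enc_config <- function(a = 6, b = 34, c = 1.025) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  structure(list(a = a, b = b, c = c), class = "enc_config")
}

#' Composition-expected effective number of codons
#'
#' Expected ENC under base composition alone (no selection on codons),
#' as a function of GC-content at third codon positions, clamped to
#' `[20, 61]`.
#'
#' @param gc3 Numeric vector of GC3 fractions in `[0, 1]`.
#' @param config An [enc_config()].
#' @return Numeric vector of expected ENC values.
#' @export
#' @examples
#' enc_exp(0)     # ~38.36 with the default constants
#' enc_exp(0.5)   # clamped at 61
enc_exp <- function(gc3, config = enc_config()) {
  stopifnot(inherits(config, "enc_config"))
  if (any(is.na(gc3)) || any(gc3 < 0 | gc3 > 1)) {
    stop("gc3 must lie in [0, 1]")
  }
  raw <- config$a + gc3 + config$b / (gc3^2 + (config$c - gc3)^2)
  pmin(pmax(raw, 20), 61)
}

#' Normalized ENC difference (codon-usage-bias score)
#'
#' `ENC_diff = (ENC_exp - ENC_obs) / ENC_exp`; positive values indicate
#' stronger codon usage bias than expected from composition alone.
#'
#' @param exp_enc,obs_enc Numeric vectors.
#' @return Numeric vector.
#' @export
enc_diff <- function(exp_enc, obs_enc) {
  stopifnot(all(exp_enc > 0, na.rm = TRUE))
  (exp_enc - obs_enc) / exp_enc
}

#' Per-gene ENC record
#'
#' Convenience wrapper computing GC3, ENC_obs, ENC_exp, and ENC_diff for
#' one sequence.
#'
#' @param sequence In-frame nucleotide sequence.
#' @param gene,lineage Identifiers recorded in the output.
#' @param config An [enc_config()].
#' @return One-row data frame: `gene`, `lineage`, `gc3`, `enc_obs`,
#'   `enc_exp`, `enc_diff`.
#' @export
enc_record <- function(sequence, gene = NA_character_,
                       lineage = NA_character_, config = enc_config()) {
  prof <- gc_by_position(sequence)
  tab <- codon_frequencies(sequence)
  obs <- enc_obs(tab)
  ex <- if (is.na(prof$gc3)) NA_real_ else enc_exp(prof$gc3, config)
  data.frame(gene = gene, lineage = lineage, gc3 = prof$gc3,
             enc_obs = obs, enc_exp = ex,
             enc_diff = if (is.na(ex) || is.na(obs)) NA_real_ else
               enc_diff(ex, obs),
             stringsAsFactors = FALSE)
}
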