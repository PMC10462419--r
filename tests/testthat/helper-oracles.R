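# Independent oracles built directly on Biostrings' genetic code table,
# deliberately sharing no code paths with the package internals.

ORACLE_CODE <- as.character(Biostrings::GENETIC_CODE)
names(ORACLE_CODE) <- names(Biostrings::GENETIC_CODE)
ORACLE_SENSE <- names(ORACLE_CODE)[ORACLE_CODE != "*"]

oracle_sw <- function(b) if (b %in% c("G", "C")) "S" else "W"

# degeneracy by substituting all three alternatives and translating
oracle_degeneracy <- function(codon, pos) {
  sp <- strsplit(codon, "")[[1]]
  hits <- sum(vapply(c("A", "C", "G", "T"), function(b) {
    x <- sp; x[pos] <- b
    ORACLE_CODE[[paste(x, collapse = "")]] == ORACLE_CODE[[codon]]
  }, logical(1)))
  if (hits == 1L) 0L else hits
}

oracle_cells <- function() {
  stats::setNames(numeric(6),
                  c("syn_SW", "syn_WS", "syn_cons",
                    "nonsyn_SW", "nonsyn_WS", "nonsyn_cons"))
}

oracle_step <- function(c1, c2, pos) {
  syn <- if (ORACLE_CODE[[c1]] == ORACLE_CODE[[c2]]) "syn" else "nonsyn"
  b1 <- substr(c1, pos, pos); b2 <- substr(c2, pos, pos)
  cls <- if (oracle_sw(b1) == oracle_sw(b2)) "cons"
    else if (oracle_sw(b1) == "S") "SW" else "WS"
  paste(syn, cls, sep = "_")
}

# exhaustive path enumeration with stop avoidance (independent of the
# package's recursion)
oracle_path <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffs) == 0L) return(oracle_cells())
  perms <- if (length(diffs) == 1L) list(diffs) else if
    (length(diffs) == 2L) list(diffs, rev(diffs)) else {
    out <- list()
    for (i in 1:3) for (j in setdiff(1:3, i)) {
      out[[length(out) + 1L]] <- diffs[c(i, j, setdiff(1:3, c(i, j)))]
    }
    out
  }
  acc <- oracle_cells(); valid <- 0L
  for (ord in perms) {
    cur <- c1; steps <- oracle_cells(); ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (ORACLE_CODE[[nxt]] == "*") { ok <- FALSE; break }
      cell <- oracle_step(cur, nxt, pos)
      steps[cell] <- steps[cell] + 1
      cur <- nxt
    }
    if (ok) { valid <- valid + 1L; acc <- acc + steps }
  }
  if (valid == 0L) return(NULL)
  acc / valid
}

oracle_opportunities <- function(codon) {
  out <- oracle_cells()
  sp <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), sp[pos])) {
      nxt <- codon
      substr(nxt, pos, pos) <- b
      if (ORACLE_CODE[[nxt]] == "*") next
      cell <- oracle_step(codon, nxt, pos)
      out[cell] <- out[cell] + 1 / 3
    }
  }
  out
}

# study-scale validation tree: ingroup quartet plus outgroup, within-
# genus divergence where counting estimators are accurate
validation_tree <- function() {
  ape::read.tree(
    text = "(out:0.02,((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01):0.01);")
}

eight_taxon_tree <- function() {
  ape::read.tree(text = paste0(
    "(t8:0.03,(((t1:0.01,t2:0.01):0.01,(t3:0.01,t4:0.01):0.01):0.01,",
    "((t5:0.01,t6:0.01):0.01,t7:0.02):0.01):0.01);"))
}

# simple in-frame alignment builder
mk_aln <- function(..., gene = "g") {
  codon_alignment(c(...), gene = gene)
}
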