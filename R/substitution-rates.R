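# Category-aware substitution counting on a fixed tree. Substitutions
# are classed syn/nonsyn x {S->W, W->S, GC-conservative}; counts are
# normalized by Nei-Gojobori-style fractional site opportunities per
# category. This is a parsimony counting approximation to probabilistic
# substitution mapping: absolute rates are on a counting scale and only
# relative/ordinal patterns are comparable across methods (recorded in
# the output metadata).

CELLS <- c("syn_SW", "syn_WS", "syn_cons",
           "nonsyn_SW", "nonsyn_WS", "nonsyn_cons")

.zero_cells <- function() stats::setNames(numeric(length(CELLS)), CELLS)

.step_cell <- function(codon_from, codon_to, pos, code) {
  gcode <- genetic_code(code)
  syn <- if (gcode[[codon_from]] == gcode[[codon_to]]) "syn" else "nonsyn"
  b1 <- substr(codon_from, pos, pos)
  b2 <- substr(codon_to, pos, pos)
  cls <- mutation_class(b1, b2)
  paste(syn, if (cls == "conservative") "cons" else cls, sep = "_")
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

#' Classify the single-base steps between two sense codons
#'
#' Codons differing at `k` positions are connected by `k!` orderings of
#' single-base steps; orderings passing through a stop codon are
#' discarded and the per-step classification (syn/nonsyn x S->W / W->S /
#' GC-conservative) is averaged over the remaining orderings
#' (Nei-Gojobori pathway convention).
#'
#' @param codon_from,codon_to Sense codons.
#' @inheritParams genetic_code
#' @return Named numeric vector over the six category cells summing to
#'   the number of differing positions, or `NULL` if every ordering is
#'   blocked by a stop codon (codon pair masked).
#' @export
#' @examples
#' codon_path_classification("GGC", "GGT") # one synonymous S->W step
codon_path_classification <- function(codon_from, codon_to, code = NULL) {
  codon_from <- toupper(codon_from); codon_to <- toupper(codon_to)
  gcode <- genetic_code(code)
  stopifnot(gcode[[codon_from]] != "*", gcode[[codon_to]] != "*")
  diffs <- which(strsplit(codon_from, "")[[1]] != strsplit(codon_to, "")[[1]])
  out <- .zero_cells()
  if (length(diffs) == 0L) return(out)
  valid <- 0L
  acc <- .zero_cells()
  for (ord in .perms(diffs)) {
    cur <- codon_from
    steps <- .zero_cells()
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_to, pos, pos)
      if (gcode[[nxt]] == "*") { ok <- FALSE; break }
      cell <- .step_cell(cur, nxt, pos, code)
      steps[cell] <- steps[cell] + 1
      cur <- nxt
    }
    if (ok) { valid <- valid + 1L; acc <- acc + steps }
  }
  if (valid == 0L) return(NULL)
  acc / valid
}

#' Fractional site opportunities of a sense codon
#'
#' Each of the nine possible single-base mutations of a codon
#' contributes 1/3 of a site to its (syn/nonsyn x S->W/W->S/conservative)
#' cell; mutations creating stop codons are excluded from opportunities.
#'
#' @param codon Sense codon.
#' @inheritParams genetic_code
#' @return Named numeric vector over the six cells (sums to 3 minus the
#'   stop-excluded fractions).
#' @export
#' @examples
#' site_opportunities("ATG") # Met: all changes nonsynonymous
site_opportunities <- function(codon, code = NULL) {
  codon <- toupper(codon)
  gcode <- genetic_code(code)
  stopifnot(gcode[[codon]] != "*")
  out <- .zero_cells()
  sp <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(BASES, sp[pos])) {
      nxt <- codon
      substr(nxt, pos, pos) <- b
      if (gcode[[nxt]] == "*") next
      cell <- .step_cell(codon, nxt, pos, code)
      out[cell] <- out[cell] + 1 / 3
    }
  }
  out
}

# Opportunity lookup for all sense codons (cached).
.opportunity_matrix <- function(code = NULL) {
  if (is.null(code) && !is.null(.pkg_cache$opp)) return(.pkg_cache$opp)
  sense <- sense_codons(code)
  m <- t(vapply(sense, site_opportunities, .zero_cells(), code = code))
  if (is.null(code)) .pkg_cache$opp <- m
  m
}

#' Parsimony ancestral codon states on a fixed rooted tree
#'
#' Fitch parsimony over codon states, column by column. Codon columns in
#' which any leaf carries a gap or ambiguous codon are masked (the
#' counting stage does not handle missing data). Ambiguity in the
#' most-parsimonious assignment is resolved by a uniform random choice
#' under `seed` (`mode = "random"`), or the column is masked
#' (`mode = "strict"`).
#'
#' @param tree Rooted `phylo` tree whose tip labels match the alignment
#'   lineages.
#' @param aln A [codon_alignment()].
#' @param mode `"random"` or `"strict"`.
#' @param seed Integer seed for tie-breaking (recorded in the output).
#' @return List with `states` (matrix of codons, rows = tree nodes in
#'   ape numbering, columns = codon columns; masked columns are `NA`),
#'   `masked` (logical vector), `mode`, `seed`.
#' @export
ancestral_states <- function(tree, aln, mode = c("random", "strict"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% aln$lineages)) {
    stop("tree tips absent from alignment: ",
         paste(setdiff(tree$tip.label, aln$lineages), collapse = ", "))
  }
  m <- codon_matrix(aln)[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  post <- ape::reorder.phylo(tree, "postorder")$edge
  states <- matrix(NA_character_, nrow = ntip + nnode, ncol = ncol(m))
  masked <- logical(ncol(m))
  rng <- .new_rng(seed)
  for (col in seq_len(ncol(m))) {
    leaf <- m[, col]
    if (any(is_missing_codon(leaf))) { masked[col] <- TRUE; next }
    sets <- vector("list", ntip + nnode)
    for (i in seq_len(ntip)) sets[[i]] <- leaf[i]
    # Fitch downpass (postorder fold over children)
    for (k in seq_len(nrow(post))) {
      par <- post[k, 1]; ch <- post[k, 2]
      if (is.null(sets[[par]])) {
        sets[[par]] <- sets[[ch]]
      } else {
        i <- intersect(sets[[par]], sets[[ch]])
        sets[[par]] <- if (length(i)) i else union(sets[[par]], sets[[ch]])
      }
    }
    root <- ntip + 1L
    ambiguous <- FALSE
    st <- rep(NA_character_, ntip + nnode)
    if (length(sets[[root]]) > 1L) ambiguous <- TRUE
    st[root] <- if (length(sets[[root]]) == 1L) sets[[root]] else
      rng$sample(sets[[root]])
    # Preorder resolution: parent before child in the reversed postorder
    for (k in rev(seq_len(nrow(post)))) {
      par <- post[k, 1]; ch <- post[k, 2]
      if (ch <= ntip) { st[ch] <- leaf[ch]; next }
      if (st[par] %in% sets[[ch]]) {
        st[ch] <- st[par]
      } else {
        if (length(sets[[ch]]) > 1L) ambiguous <- TRUE
        st[ch] <- if (length(sets[[ch]]) == 1L) sets[[ch]] else
          rng$sample(sets[[ch]])
      }
    }
    if (mode == "strict" && ambiguous) { masked[col] <- TRUE; next }
    states[, col] <- st
  }
  list(states = states, masked = masked, mode = mode, seed = seed)
}

# Self-contained RNG stream so parsimony tie-breaking does not disturb
# the caller's random state.
.new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  env$sample <- function(x) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                       globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- x[sample.int(length(x), 1L)]
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  env
}

.tally_to_df <- function(N, L, branch, gene) {
  d <- ifelse(L > 0, N / L, NA_real_)
  syn <- grepl("^syn", CELLS)
  dn <- if (sum(L[!syn]) > 0) sum(N[!syn]) / sum(L[!syn]) else NA_real_
  ds <- if (sum(L[syn]) > 0) sum(N[syn]) / sum(L[syn]) else NA_real_
  omega <- if (!is.na(ds) && ds > 0 && !is.na(dn)) dn / ds else NA_real_
  out <- data.frame(gene = gene, branch = branch, stringsAsFactors = FALSE)
  for (cell in CELLS) {
    out[[paste0("N_", cell)]] <- N[cell]
    out[[paste0("L_", cell)]] <- L[cell]
    out[[paste0("d_", cell)]] <- d[cell]
  }
  out$dN <- dn; out$dS <- ds; out$omega <- omega
  out
}

#' Per-branch category substitution tallies and rates
#'
#' Reconstructs ancestral codon states by parsimony, classifies every
#' parent-to-child codon change into the six category cells, accumulates
#' fractional site opportunities from the parent states, and derives
#' per-category rates `d_c = N_c / L_c`, global `dN`, `dS` and
#' `omega = dN/dS` per branch and pooled over the tree.
#'
#' @inheritParams ancestral_states
#' @param drop_root_edges Exclude the two edges incident to the root
#'   from the pooled totals (default `FALSE`). Parsimony cannot orient
#'   a substitution that maps to the root-adjacent edges (the root
#'   state is reconstructed from an even split and resolved at random),
#'   so directional S->W / W->S contrasts should be pooled without
#'   them; per-branch rows are always reported and flagged.
#' @return Object of class `substitution_tally`: list with `per_branch`
#'   (data frame, one row per edge; branch labelled
#'   `parent_node->child`, with a `root_edge` flag), `total` (one
#'   pooled row), `anc` (the ancestral-state reconstruction), and
#'   `meta` (seed, mode, masked column count, method caveat).
#' @export
branch_rates <- function(tree, aln, mode = "random", seed = 1L,
                         drop_root_edges = FALSE, code = NULL) {
  anc <- ancestral_states(tree, aln, mode = mode, seed = seed)
  opp <- .opportunity_matrix(code)
  ntip <- length(tree$tip.label)
  labs <- c(tree$tip.label, paste0("node", seq_len(tree$Nnode) + ntip))
  rows <- list()
  Ntot <- .zero_cells(); Ltot <- .zero_cells()
  cols <- which(!anc$masked)
  root <- ntip + 1L
  root_edge <- logical(nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    root_edge[k] <- par == root
    N <- .zero_cells(); L <- .zero_cells()
    for (col in cols) {
      pc <- anc$states[par, col]; cc <- anc$states[ch, col]
      L <- L + opp[pc, ]
      if (pc != cc) {
        cls <- codon_path_classification(pc, cc, code)
        if (!is.null(cls)) N <- N + cls
      }
    }
    rows[[k]] <- .tally_to_df(N, L, paste0(labs[par], "->", labs[ch]),
                              aln$gene)
    if (!(drop_root_edges && root_edge[k])) {
      Ntot <- Ntot + N; Ltot <- Ltot + L
    }
  }
  per_branch <- do.call(rbind, rows)
  per_branch$root_edge <- root_edge
  structure(list(
    per_branch = per_branch,
    total = .tally_to_df(Ntot, Ltot, "all", aln$gene),
    anc = anc,
    meta = list(seed = seed, mode = mode,
                drop_root_edges = drop_root_edges,
                n_masked_columns = sum(anc$masked),
                method = paste("parsimony counting with fractional-site",
                               "normalization; counting-scale rates"))),
    class = "substitution_tally")
}

#' @export
print.substitution_tally <- function(x, ...) {
  cat("substitution_tally for gene '", x$total$gene, "': ",
      nrow(x$per_branch), " branches, dN = ",
      signif(x$total$dN, 4), ", dS = ", signif(x$total$dS, 4),
      ", omega = ", signif(x$total$omega, 4), "\n", sep = "")
  invisible(x)
}

#' Pairwise category rates for two aligned sequences
#'
#' Symmetric two-sequence counting: substitutions from pathway-averaged
#' codon differences, opportunities as the mean of both sequences'
#' fractional site counts. Codon pairs with a gap/ambiguous member, or
#' whose every pathway crosses a stop codon, are masked. Note that a
#' sequence pair carries no information on substitution direction: the
#' S->W / W->S cells refer to the arbitrary `seq1 -> seq2` reading and
#' must not be interpreted as polarized rates (use [branch_rates()] on
#' a rooted tree for directional contrasts).
#'
#' @param seq1,seq2 In-frame aligned sequences of equal length.
#' @param gene Gene identifier.
#' @inheritParams genetic_code
#' @return One-row data frame in the [branch_rates()] `total` layout.
#' @export
pairwise_rates <- function(seq1, seq2, gene = "gene", code = NULL) {
  c1 <- split_codons(seq1); c2 <- split_codons(seq2)
  stopifnot(length(c1) == length(c2))
  gcode <- genetic_code(code)
  opp <- .opportunity_matrix(code)
  N <- .zero_cells(); L <- .zero_cells()
  for (j in seq_along(c1)) {
    if (is_missing_codon(c1[j]) || is_missing_codon(c2[j])) next
    if (gcode[[c1[j]]] == "*" || gcode[[c2[j]]] == "*") next
    cls <- if (c1[j] == c2[j]) .zero_cells() else
      codon_path_classification(c1[j], c2[j], code)
    if (is.null(cls)) next
    N <- N + cls
    L <- L + (opp[c1[j], ] + opp[c2[j], ]) / 2
  }
  .tally_to_df(N, L, "pairwise", gene)
}

#' S->W over W->S rate ratios with summaries
#'
#' Per observation ratios `d_syn_SW / d_syn_WS` and
#' `d_nonsyn_SW / d_nonsyn_WS`, with mean, sd, and median summaries.
#' Observations with a zero or missing denominator are excluded from the
#' summaries and counted. Reference ratios: 1 (no bias) and the mutation
#' bias expectation (about 3 in Lepidoptera).
#'
#' @param tallies Data frame containing `d_syn_SW`, `d_syn_WS`,
#'   `d_nonsyn_SW`, `d_nonsyn_WS` columns (e.g. rbind of
#'   `branch_rates()$total` rows).
#' @return List with `ratios` (data frame with `ratio_syn`,
#'   `ratio_nonsyn` appended) and `summary` (per rate type: n, mean, sd,
#'   median, n_excluded).
#' @export
sw_ratio <- function(tallies) {
  rs <- ifelse(!is.na(tallies$d_syn_WS) & tallies$d_syn_WS > 0,
               tallies$d_syn_SW / tallies$d_syn_WS, NA_real_)
  rn <- ifelse(!is.na(tallies$d_nonsyn_WS) & tallies$d_nonsyn_WS > 0,
               tallies$d_nonsyn_SW / tallies$d_nonsyn_WS, NA_real_)
  tallies$ratio_syn <- rs
  tallies$ratio_nonsyn <- rn
  summ <- function(x) {
    ok <- !is.na(x)
    data.frame(n = sum(ok), mean = mean(x[ok]), sd = stats::sd(x[ok]),
               median = stats::median(x[ok]), n_excluded = sum(!ok))
  }
  list(ratios = tallies,
       summary = cbind(data.frame(type = c("syn", "nonsyn")),
                       rbind(summ(rs), summ(rn))))
}
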