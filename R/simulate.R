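# Synthetic-data generators with known ground truth for every pipeline
# stage: codon alignments evolved on a fixed tree with category rate
# multipliers, polymorphism spectra drawn from the gBGC equilibrium
# model, and tRNAscan-style gene tables.

#' Simulate a codon alignment on a fixed tree with category rate
#' multipliers
#'
#' The root sequence is drawn codon-wise from a composition targeting
#' `gc3` at third positions (optionally concentrated on one preferred
#' codon per synonymous family); it then evolves along the tree by a
#' site-independent continuous-time process in which each of the nine
#' single-base neighbor substitutions of a codon has hazard
#' `multiplier/3` per unit branch length, with mutations to stop codons
#' forbidden. Branch lengths are expected substitutions per nucleotide
#' site when all multipliers are 1. Every realized substitution is
#' recorded in a truth ledger with its syn/nonsyn x S->W/W->S/
#' conservative class.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param n_codons Gene length in codons.
#' @param gc3 Target GC at third codon positions of the root sequence.
#' @param multipliers List with elements `syn` and `nonsyn`, each a
#'   named vector over `c("SW", "WS", "cons")` of rate multipliers.
#' @param concentration Codon-usage concentration: log-weight added to
#'   one preferred codon per synonymous family at the root (0 = none).
#' @param gene Gene identifier.
#' @param seed Integer seed.
#' @inheritParams genetic_code
#' @return List: `alignment` (a [codon_alignment()] of the tip
#'   sequences), `tree`, `truth` (data frame of substitutions: branch,
#'   codon index, from, to, syn, class), `config`.
#' @export
simulate_alignment <- function(tree, n_codons = 300L, gc3 = 0.469,
                               multipliers = list(
                                 syn = c(SW = 1, WS = 1, cons = 1),
                                 nonsyn = c(SW = 1, WS = 1, cons = 1)),
                               concentration = 0, gene = "gene1",
                               seed = 1L, code = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(seed)
  gcode <- genetic_code(code)
  sense <- sense_codons(code)
  # root composition: uniform at positions 1-2, S/W weighted at 3
  w3 <- ifelse(substr(sense, 3, 3) %in% c("G", "C"), gc3 / 2,
               (1 - gc3) / 2)
  w <- w3
  if (concentration > 0) {
    aa <- gcode[sense]
    pref <- vapply(split(sense, aa), function(v) sort(v)[1], character(1))
    w[sense %in% pref] <- w[sense %in% pref] * exp(concentration)
  }
  w <- w / sum(w)
  root <- sample(sense, n_codons, replace = TRUE, prob = w)

  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- root
  post <- ape::reorder.phylo(tree, "postorder")$edge
  # neighbor tables with hazards, precomputed once per multiplier set
  nbr <- lapply(stats::setNames(sense, sense), .codon_neighbors,
                gcode = gcode, multipliers = multipliers, code = code)
  tot_h <- vapply(nbr, function(d) sum(d$hazard), numeric(1))
  led_branch <- character(0); led_codon <- integer(0)
  led_from <- character(0); led_to <- character(0)
  led_syn <- character(0); led_class <- character(0)
  labs <- c(tree$tip.label, paste0("node", seq_len(tree$Nnode) + ntip))
  for (k in rev(seq_len(nrow(post)))) {
    par <- post[k, 1]; ch <- post[k, 2]
    t_branch <- tree$edge.length[which(tree$edge[, 1] == par &
                                         tree$edge[, 2] == ch)]
    br <- paste0(labs[par], "->", labs[ch])
    seqv <- states[[par]]
    # first waiting time drawn vectorized; codons whose first event
    # falls beyond the branch need no further work
    h0 <- tot_h[seqv]
    dt0 <- stats::rexp(n_codons, pmax(h0, 1e-300))
    active <- which(h0 > 0 & dt0 <= t_branch)
    for (j in active) {
      t_left <- t_branch - dt0[j]
      first <- TRUE
      repeat {
        cur <- seqv[j]
        nb <- nbr[[cur]]
        h <- tot_h[[cur]]
        if (h <= 0) break
        if (!first) {
          dt <- stats::rexp(1L, h)
          if (dt > t_left) break
          t_left <- t_left - dt
        }
        first <- FALSE
        pick <- sample.int(nrow(nb), 1L, prob = nb$hazard)
        led_branch <- c(led_branch, br); led_codon <- c(led_codon, j)
        led_from <- c(led_from, cur); led_to <- c(led_to, nb$to[pick])
        led_syn <- c(led_syn, nb$syn[pick])
        led_class <- c(led_class, nb$class[pick])
        seqv[j] <- nb$to[pick]
      }
    }
    states[[ch]] <- seqv
  }
  tips <- vapply(seq_len(ntip), function(i) paste(states[[i]],
                                                  collapse = ""),
                 character(1))
  names(tips) <- tree$tip.label
  truth <- data.frame(branch = led_branch, codon = led_codon,
                      from = led_from, to = led_to, syn = led_syn,
                      class = led_class, stringsAsFactors = FALSE)
  list(alignment = codon_alignment(tips, gene = gene), tree = tree,
       truth = truth,
       config = list(n_codons = n_codons, gc3 = gc3,
                     multipliers = multipliers,
                     concentration = concentration, seed = seed))
}

# Neighbor table of a codon with per-neighbor hazards (cached per
# multiplier set would be possible; plain computation is fast enough).
.codon_neighbors <- function(codon, gcode, multipliers, code = NULL) {
  sp <- strsplit(codon, "")[[1]]
  out <- list()
  for (pos in 1:3) {
    for (b in setdiff(BASES, sp[pos])) {
      nxt <- codon
      substr(nxt, pos, pos) <- b
      if (gcode[[nxt]] == "*") next
      syn <- if (gcode[[codon]] == gcode[[nxt]]) "syn" else "nonsyn"
      cls <- mutation_class(sp[pos], b)
      cls <- if (cls == "conservative") "cons" else cls
      out[[length(out) + 1L]] <- data.frame(
        to = nxt, syn = syn, class = cls,
        hazard = multipliers[[syn]][[cls]] / 3,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(to = character(), syn = character(), class = character(),
               hazard = numeric())
}

#' Simulate class-specific polymorphism spectra under the gBGC
#' equilibrium model
#'
#' For a degeneracy class with `n_sites` sites of which a fraction `gc`
#' carry a strong ancestral base, mutation intensities are
#' `theta_WS = theta0 * L_W`, `theta_SW = theta0 * lambda * L_S`, and
#' `theta_cons = 0.5 * theta0 * (L_W + L_S)`; segregating-site counts
#' per derived-allele frequency bin are drawn as Poisson with means
#' [expected_sfs()] at `+B` (W->S), `-B` (S->W) and `0` (conservative).
#' Mis-polarization optionally moves each segregating site from bin `i`
#' to `n - i` with probability `e`.
#'
#' @param n Sample size in chromosomes (default 20: 10 diploids).
#' @param theta0 Per-site scaled mutation intensity (default 0.01, a
#'   typical insect synonymous-site diversity).
#' @param lambda S->W over W->S per-site mutation-rate ratio.
#' @param B Fixation bias favoring GC (`4*Ne*b`).
#' @param n_sites Total sites of the degeneracy class.
#' @param gc Fraction of class sites with strong (G/C) ancestral base.
#' @param e Polarization-error probability.
#' @param seed Integer seed.
#' @return List: `data` (a [gbgc_data()]), `sites` (site-level table of
#'   segregating sites: class, i, anc_is_S), `truth` (generating
#'   parameters).
#' @export
simulate_polymorphism <- function(n = 20L, theta0 = 0.01, lambda = 2.96,
                                  B = 0.46, n_sites = 1e6, gc = 0.469,
                                  e = 0, seed = 1L) {
  stopifnot(n >= 4L, theta0 > 0, lambda > 0, n_sites > 0,
            gc > 0, gc < 1, e >= 0, e < 0.5)
  set.seed(seed)
  L_S <- round(gc * n_sites)
  L_W <- n_sites - L_S
  theta <- c(cons = 0.5 * theta0 * n_sites,
             WS = theta0 * L_W,
             SW = theta0 * lambda * L_S)
  Bs <- c(cons = 0, WS = B, SW = -B)
  counts <- sapply(MUT_CLASSES, function(cl) {
    stats::rpois(n - 1L, expected_sfs(theta[[cl]], Bs[[cl]], n))
  })
  counts <- t(counts)                      # classes x bins
  if (e > 0) {
    for (cl in MUT_CLASSES) {
      flips <- stats::rbinom(n - 1L, counts[cl, ], e)
      counts[cl, ] <- counts[cl, ] - flips + rev(flips)
    }
  }
  seg_w <- sum(counts["WS", ]); seg_s <- sum(counts["SW", ])
  if (seg_w >= L_W || seg_s >= L_S) {
    stop("inconsistent configuration: more segregating sites than sites")
  }
  sites <- do.call(rbind, lapply(MUT_CLASSES, function(cl) {
    i <- rep(seq_len(n - 1L), counts[cl, ])
    if (!length(i)) return(NULL)
    data.frame(class = cl, i = i,
               anc_is_S = if (cl == "WS") FALSE else if (cl == "SW") TRUE
               else stats::runif(length(i)) < gc,
               stringsAsFactors = FALSE)
  }))
  list(data = gbgc_data(counts["WS", ], counts["SW", ], counts["cons", ],
                        L_W = L_W, L_S = L_S, n = n),
       sites = sites,
       truth = list(n = n, theta0 = theta0, lambda = lambda, B = B,
                    n_sites = n_sites, gc = gc, e = e, seed = seed,
                    theta = theta, L_W = L_W, L_S = L_S))
}

#' Simulate a tRNAscan-SE-style gene table
#'
#' Emits a syntactically valid tRNAscan-SE 2.x tabular file with planted
#' functional copy numbers per anticodon, plus pseudogene and truncated
#' rows (excluded by filtering) and a share of minus-strand rows
#' (inverted coordinates).
#'
#' @param copies Named integer vector: functional gene copies per
#'   anticodon (the planted truth), e.g. `c(GCC = 3, AAT = 1)`.
#' @param n_pseudo,n_truncated Numbers of non-functional decoy rows.
#' @param minus_fraction Fraction of rows written with inverted
#'   coordinates (minus strand).
#' @param path Output file path; if `NULL` a tempfile is used.
#' @param seed Integer seed.
#' @inheritParams genetic_code
#' @return List: `path`, `truth` (the `copies` vector), `n_rows`.
#' @export
simulate_trnascan_fixture <- function(copies, n_pseudo = 2L,
                                      n_truncated = 1L,
                                      minus_fraction = 0.3, path = NULL,
                                      seed = 1L, code = NULL) {
  stopifnot(is.numeric(copies), !is.null(names(copies)))
  set.seed(seed)
  gcode <- genetic_code(code)
  if (is.null(path)) path <- tempfile(fileext = ".trnascan")
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  mk_row <- function(idx, anticodon, note) {
    start <- 1000L * idx
    end <- start + 71L
    minus <- stats::runif(1) < minus_fraction
    b <- if (minus) end else start
    e <- if (minus) start else end
    aa1 <- gcode[[anticodon_to_codon(anticodon)]]
    iso <- if (aa1 %in% names(aa3)) aa3[[aa1]] else "Und"
    sprintf("chr1\t%d\t%d\t%d\t%s\t%s\t0\t0\t%.1f\t%s",
            idx, b, e, iso, anticodon,
            stats::runif(1, 40, 90), note)
  }
  rows <- character(0)
  idx <- 0L
  for (ac in names(copies)) {
    for (k in seq_len(copies[[ac]])) {
      idx <- idx + 1L
      rows <- c(rows, mk_row(idx, ac, ""))
    }
  }
  decoys <- names(copies)[1]
  for (k in seq_len(n_pseudo)) {
    idx <- idx + 1L
    rows <- c(rows, mk_row(idx, decoys, "pseudo"))
  }
  for (k in seq_len(n_truncated)) {
    idx <- idx + 1L
    rows <- c(rows, mk_row(idx, decoys, "trunc_start:10"))
  }
  header <- c(
    "Sequence\t\ttRNA\tBounds\tBounds\ttRNA\tAnti\tIntron\tIntron\tInf\t",
    "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
    paste0("--------\t------\t-----\t----\t----\t-----\t-----\t---\t",
           "-----\t------"))
  writeLines(c(header, rows), path)
  list(path = path, truth = copies, n_rows = length(rows))
}

#' Plant QC violations in a batch of synthetic alignments
#'
#' Generates clean alignments plus alignments violating exactly one
#' hygiene rule each (short alignment, internal stop, frame-shifting
#' gap, lineage with excess missing codons, excess mean gaps), with the
#' planted rejection set recorded as truth.
#'
#' @param tree Rooted `phylo` supplying lineage names.
#' @param n_clean Number of clean alignments.
#' @param seed Integer seed.
#' @return List: `alignments` (named list), `planted_bad` (character
#'   vector of gene ids that must be rejected).
#' @export
simulate_qc_batch <- function(tree, n_clean = 3L, seed = 1L) {
  set.seed(seed)
  taxa <- tree$tip.label
  mk <- function(n_codons, gene, seed2) {
    simulate_alignment(tree, n_codons = n_codons, gene = gene,
                       seed = seed2)$alignment
  }
  alns <- list()
  for (g in seq_len(n_clean)) {
    id <- paste0("clean", g)
    alns[[id]] <- mk(120L + 10L * g, id, seed + g)
  }
  # short: 99 codons = 297 bp after trimming
  alns$bad_short <- mk(99L, "bad_short", seed + 101L)
  # internal stop in one lineage
  a <- mk(120L, "bad_stop", seed + 102L)
  s <- a$seqs[[1]]
  substr(s, 31, 33) <- "TAA"
  a$seqs[[1]] <- s
  alns$bad_stop <- a
  # frame-shifting gap run (length 4)
  a <- mk(120L, "bad_frame", seed + 103L)
  s <- a$seqs[[1]]
  substr(s, 31, 34) <- "----"
  a$seqs[[1]] <- s
  alns$bad_frame <- a
  # one lineage >50% missing codons (whole-codon gaps survive trimming
  # while most lineages are present)
  a <- mk(120L, "bad_missing", seed + 104L)
  s <- a$seqs[[1]]
  ncod <- nchar(s) %/% 3L
  for (j in seq_len(ceiling(0.6 * ncod))) {
    substr(s, 3L * j - 2L, 3L * j) <- "---"
  }
  a$seqs[[1]] <- s
  alns$bad_missing <- a
  # mean per-sequence gap fraction > 25%: rotate gap codons over
  # lineages so no column exceeds 50% gaps and no lineage exceeds 50%
  # missing, while the mean stays near 30%
  a <- mk(200L, "bad_gappy", seed + 105L)
  ncod <- 200L
  ntax <- length(taxa)
  k_gap <- ntax %/% 2L
  frac_cols <- min(1, 0.3 / (k_gap / ntax))
  for (j in seq_len(floor(frac_cols * ncod))) {
    for (d in seq_len(k_gap) - 1L) {
      ti <- (j + d - 1L) %% ntax + 1L
      s <- a$seqs[[ti]]
      substr(s, 3L * j - 2L, 3L * j) <- "---"
      a$seqs[[ti]] <- s
    }
  }
  alns$bad_gappy <- a
  list(alignments = alns,
       planted_bad = c("bad_short", "bad_stop", "bad_frame",
                       "bad_missing", "bad_gappy"))
}
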