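# Emission and re-parsing of population-genomic fixture files: a
# reference FASTA, CDS annotation (GFF3), ingroup VCF, and a two-
# outgroup allele table. The generator embeds each simulated site in a
# codon of the requested degeneracy class; the reader re-derives the
# polarized site table from the files alone.

# Codon templates per (degeneracy, ancestral class). `pos` is the
# variable position; derived bases per mutation class stay within the
# template's degeneracy design.
.site_templates <- list(
  `4` = list(
    W = list(codon = "GGA", pos = 3L, der = c(WS = "G", cons = "T")),
    S = list(codon = "GGC", pos = 3L, der = c(SW = "T", cons = "G"))),
  `0` = list(
    W = list(codon = "ATG", pos = 1L, der = c(WS = "G", cons = "T")),
    S = list(codon = "GAA", pos = 1L, der = c(SW = "A", cons = "C"))))

#' Write VCF/FASTA/GFF3/outgroup fixtures for simulated polymorphism
#'
#' Builds a synthetic chromosome in which every simulated segregating
#' site sits at the variable position of a codon of the requested
#' degeneracy class, plus monomorphic filler codons; writes the
#' ancestral-allele reference FASTA, a CDS GFF3 (optionally including a
#' minus-strand gene), a minimal VCF 4.2 with unphased GT fields for
#' `n/2` diploid samples, and a TSV of two outgroup alleles (both
#' ancestral).
#'
#' @param sites Data frame from [simulate_polymorphism()]`$sites`
#'   (columns `class`, `i`, `anc_is_S`).
#' @param n Sample size in chromosomes (even).
#' @param dir Output directory (created if needed).
#' @param degeneracy 4 or 0: the degeneracy class the sites belong to.
#' @param n_mono_W,n_mono_S Monomorphic filler codons with weak/strong
#'   base at the variable position.
#' @param minus_strand_gene Place every fifth segregating site in a
#'   second, minus-strand CDS.
#' @return List: file `paths`, `expected` (the site table the reader
#'   must reproduce), `n`.
#' @export
write_polymorphism_fixtures <- function(sites, n, dir,
                                        degeneracy = 4L,
                                        n_mono_W = 50L, n_mono_S = 50L,
                                        minus_strand_gene = FALSE) {
  stopifnot(n %% 2L == 0L, degeneracy %in% c(0L, 4L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- .site_templates[[as.character(degeneracy)]]
  chrom <- "chr_sim"
  in_minus <- if (minus_strand_gene && nrow(sites) >= 5L) {
    seq_len(nrow(sites)) %% 5L == 0L
  } else rep(FALSE, nrow(sites))

  build_gene <- function(idx, strand) {
    codons <- character(0); rows <- list()
    for (k in seq_along(idx)) {
      s <- sites[idx[k], ]
      t <- tpl[[if (s$anc_is_S) "S" else "W"]]
      anc <- substr(t$codon, t$pos, t$pos)
      der <- t$der[[s$class]]
      codons <- c(codons, t$codon)
      rows[[k]] <- data.frame(
        gene = NA_character_, strand = strand, codon_index = k,
        codon = t$codon, pos_in_codon = t$pos, anc = anc, der = der,
        i = s$i, n = n, degeneracy = degeneracy, class = s$class,
        stringsAsFactors = FALSE)
    }
    list(codons = codons, rows = if (length(rows)) do.call(rbind, rows)
         else NULL)
  }
  g1 <- build_gene(which(!in_minus), "+")
  mono <- c(rep(tpl$W$codon, n_mono_W), rep(tpl$S$codon, n_mono_S))
  g1$codons <- c(g1$codons, mono)
  g2 <- if (any(in_minus)) build_gene(which(in_minus), "-") else NULL

  # gene1 occupies the chromosome start (+ strand); gene2 (if any) is
  # appended after a 30-bp spacer, stored reverse-complemented.
  seq1 <- paste(g1$codons, collapse = "")
  spacer <- strrep("ATATAT", 5L)
  seq2 <- if (!is.null(g2)) revcomp(paste(g2$codons, collapse = "")) else ""
  genome <- paste0(seq1, spacer, seq2)
  gene1_rng <- c(1L, nchar(seq1))
  gene2_rng <- if (!is.null(g2)) {
    c(nchar(seq1) + nchar(spacer) + 1L, nchar(genome))
  } else NULL

  # genome coordinates of each recorded site
  site_rows <- list()
  if (!is.null(g1$rows)) {
    r <- g1$rows
    r$gene <- "gene1"
    r$chrom <- chrom
    r$pos <- gene1_rng[1] - 1L + 3L * (r$codon_index - 1L) + r$pos_in_codon
    r$ref_gs <- r$anc; r$alt_gs <- r$der     # genome-strand alleles
    site_rows[[1]] <- r
  }
  if (!is.null(g2)) {
    r <- g2$rows
    r$gene <- "gene2"
    r$chrom <- chrom
    # CDS base j (1-based, 5'->3' of the gene) maps to genome position
    # gene2_end - j + 1 on the minus strand
    j <- 3L * (r$codon_index - 1L) + r$pos_in_codon
    r$pos <- gene2_rng[2] - j + 1L
    r$ref_gs <- revcomp(r$anc); r$alt_gs <- revcomp(r$der)
    site_rows[[length(site_rows) + 1L]] <- r
  }
  expected <- do.call(rbind, site_rows)
  expected <- expected[order(expected$pos), ]
  rownames(expected) <- NULL

  paths <- list(fasta = file.path(dir, "ref.fa"),
                gff = file.path(dir, "cds.gff3"),
                vcf = file.path(dir, "ingroup.vcf"),
                outgroups = file.path(dir, "outgroups.tsv"))
  # reference FASTA (ancestral alleles)
  ref <- Biostrings::DNAStringSet(genome)
  names(ref) <- chrom
  Biostrings::writeXStringSet(ref, paths$fasta)
  # GFF3
  gff <- c("##gff-version 3",
           sprintf("%s\tcodonevol\tCDS\t%d\t%d\t.\t+\t0\tID=gene1",
                   chrom, gene1_rng[1], gene1_rng[2]))
  if (!is.null(gene2_rng)) {
    gff <- c(gff, sprintf(
      "%s\tcodonevol\tCDS\t%d\t%d\t.\t-\t0\tID=gene2",
      chrom, gene2_rng[1], gene2_rng[2]))
  }
  writeLines(gff, paths$gff)
  # VCF with n/2 diploid samples
  n_ind <- n %/% 2L
  samples <- sprintf("ind%02d", seq_len(n_ind))
  gt_of <- function(i) {
    hom <- i %/% 2L; het <- i %% 2L
    c(rep("1/1", hom), rep("0/1", het),
      rep("0/0", n_ind - hom - het))
  }
  vcf_rows <- vapply(seq_len(nrow(expected)), function(k) {
    r <- expected[k, ]
    paste(c(r$chrom, r$pos, ".", r$ref_gs, r$alt_gs, ".", "PASS", ".",
            "GT", gt_of(r$i)), collapse = "\t")
  }, character(1))
  vcf_header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(genome)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(vcf_header, vcf_rows), paths$vcf)
  # outgroup alleles (both ancestral)
  og <- data.frame(chrom = expected$chrom, pos = expected$pos,
                   outgroup1 = expected$ref_gs,
                   outgroup2 = expected$ref_gs)
  utils::write.table(og, paths$outgroups, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expected <- expected[, c("chrom", "pos", "gene", "strand", "codon",
                           "pos_in_codon", "anc", "der", "i", "n",
                           "degeneracy", "class")]
  list(paths = paths, expected = expected, n = n)
}

# Minimal GFF3 CDS reader (tab-separated, 1-based inclusive); uses
# rtracklayer when available, else a direct parse of the 9 columns.
.read_cds_gff <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "CDS"]
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               id = if (!is.null(gr$ID)) gr$ID else
                 paste0("cds", seq_along(gr)),
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
    df <- df[df[[3]] == "CDS", ]
    id <- sub(".*ID=([^;]+).*", "\\1", df[[9]])
    data.frame(chrom = df[[1]], start = df[[4]], end = df[[5]],
               strand = df[[7]], id = id, stringsAsFactors = FALSE)
  }
}

#' Read and polarize coding polymorphism from VCF + reference + GFF3
#'
#' Parses ingroup genotypes (VCF), the reference FASTA, CDS features
#' (GFF3, 1-based inclusive, strand-aware) and a two-outgroup allele
#' table; polarizes each biallelic coding SNP by parsimony
#' ([polarize()]), maps it into its (reference) codon context, and
#' classifies degeneracy and mutation class ([classify_site()]). Also
#' tallies the W/S composition of all 0-fold and 4-fold reference CDS
#' sites, used for mutation-bias normalization.
#'
#' @param vcf,fasta,gff,outgroups File paths. The outgroup table is a
#'   TSV with columns `chrom`, `pos`, `outgroup1`, `outgroup2`.
#' @param drop_missing Drop sites with any missing genotype (default);
#'   otherwise such sites are retained with their observed `n`.
#' @inheritParams genetic_code
#' @return List: `sites` (polarized site table with codon context,
#'   degeneracy and mutation class; alleles in CDS orientation),
#'   `L_W`, `L_S` (named by degeneracy class `"0"`/`"4"`), `n`
#'   (chromosomes), `n_unpolarized`, `n_noncoding`.
#' @export
read_polymorphism <- function(vcf, fasta, gff, outgroups,
                              drop_missing = TRUE, code = NULL) {
  ref <- Biostrings::readDNAStringSet(fasta)
  refseq <- stats::setNames(as.character(ref),
                            sub("\\s.*", "", names(ref)))
  cds <- .read_cds_gff(gff)
  og <- utils::read.table(outgroups, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  og_key <- paste(og$chrom, og$pos)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v)
  n_total <- 2L * ncol(gt)

  cds_seq <- function(k) {
    s <- substr(refseq[[cds$chrom[k]]], cds$start[k], cds$end[k])
    if (cds$strand[k] == "-") revcomp(s) else s
  }
  # reference composition of 0-fold / 4-fold sites across all CDS
  L_W <- c(`0` = 0, `4` = 0); L_S <- c(`0` = 0, `4` = 0)
  for (k in seq_len(nrow(cds))) {
    cods <- split_codons(cds_seq(k))
    cods <- cods[!(cods %in% stop_codons(code))]
    for (pos in 1:3) {
      deg <- site_degeneracy(cods, pos, code)
      base <- substr(cods, pos, pos)
      for (d in c(0L, 4L)) {
        sel <- !is.na(deg) & deg == d
        L_S[[as.character(d)]] <- L_S[[as.character(d)]] +
          sum(base[sel] %in% c("G", "C"))
        L_W[[as.character(d)]] <- L_W[[as.character(d)]] +
          sum(base[sel] %in% c("A", "T"))
      }
    }
  }

  rows <- list(); n_unpol <- 0L; n_noncoding <- 0L
  for (r in seq_len(nrow(fix))) {
    chrom <- fix[r, "CHROM"]; pos <- as.integer(fix[r, "POS"])
    refb <- fix[r, "REF"]; altb <- fix[r, "ALT"]
    if (nchar(refb) != 1L || nchar(altb) != 1L) next
    alleles <- unlist(strsplit(gt[r, ], "[/|]"))
    alleles <- alleles[alleles != "."]
    if (drop_missing && length(alleles) < n_total) next
    bases <- ifelse(alleles == "0", refb, altb)
    k <- which(cds$chrom == chrom & cds$start <= pos & cds$end >= pos)[1]
    if (is.na(k)) { n_noncoding <- n_noncoding + 1L; next }
    m <- match(paste(chrom, pos), og_key)
    pol <- polarize(bases,
                    if (is.na(m)) NA else og$outgroup1[m],
                    if (is.na(m)) NA else og$outgroup2[m])
    if (pol$status != "polarized") { n_unpol <- n_unpol + 1L; next }
    # map into CDS codon coordinates
    if (cds$strand[k] == "+") {
      off <- pos - cds$start[k]
      anc <- pol$anc; der <- pol$der
    } else {
      off <- cds$end[k] - pos
      anc <- revcomp(pol$anc); der <- revcomp(pol$der)
    }
    codon_index <- off %/% 3L + 1L
    pos_in_codon <- off %% 3L + 1L
    codon <- substr(cds_seq(k), 3L * codon_index - 2L, 3L * codon_index)
    # ensure the ancestral base occupies the codon context (the
    # reference here carries one of the two alleles)
    ctx <- codon
    substr(ctx, pos_in_codon, pos_in_codon) <- anc
    if (!grepl("^[ACGT]{3}$", ctx) ||
        genetic_code(code)[[ctx]] == "*") { n_unpol <- n_unpol + 1L; next }
    cl <- classify_site(ctx, pos_in_codon, anc, der, code)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = pos, gene = cds$id[k],
      strand = cds$strand[k], codon = ctx,
      pos_in_codon = pos_in_codon, anc = anc, der = der,
      i = pol$i, n = length(bases),
      degeneracy = cl$degeneracy, class = cl$class,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else NULL
  list(sites = sites, L_W = L_W, L_S = L_S, n = n_total,
       n_unpolarized = n_unpol, n_noncoding = n_noncoding)
}
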