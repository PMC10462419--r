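# Summary associations and the pipeline orchestrator. Statistics here
# are thin wrappers over standard routines; every reported number is
# recomputable from the persisted intermediate tables.

#' Rank correlations between per-gene variables
#'
#' Spearman rank correlations (midranks for ties) for a set of variable
#' pairs from a per-gene table, optionally within lineages.
#'
#' @param df Data frame of per-gene statistics.
#' @param pairs List of length-2 character vectors naming the variable
#'   pairs.
#' @param by Optional grouping column (e.g. `"lineage"`).
#' @return Data frame: `group`, `var_x`, `var_y`, `rho`, `p_value`,
#'   `n`. Constant variables give `rho = NA` (flagged by `note`).
#' @export
compute_associations <- function(df, pairs, by = NULL) {
  groups <- if (is.null(by)) list(all = df) else split(df, df[[by]])
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    for (p in pairs) {
      x <- sub[[p[1]]]; y <- sub[[p[2]]]
      ok <- stats::complete.cases(x, y)
      note <- ""
      if (sum(ok) < 3L) {
        rho <- NA_real_; pv <- NA_real_; note <- "fewer than 3 pairs"
      } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rho <- NA_real_; pv <- NA_real_; note <- "constant variable"
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman",
                          exact = FALSE))
        rho <- unname(ct$estimate); pv <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, var_x = p[1], var_y = p[2], rho = rho, p_value = pv,
        n = sum(ok), note = note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare a statistic between two gene groups
#'
#' Rank-based group comparison utilities used for the conserved-bin
#' contrasts: Wilcoxon rank-sum (unpaired), signed-rank (paired), or
#' Kruskal-Wallis for a grouping factor.
#'
#' @param x Numeric vector (or values for group 1).
#' @param y Values for group 2, or a grouping factor when
#'   `test = "kruskal"`.
#' @param test `"ranksum"`, `"signedrank"`, or `"kruskal"`.
#' @return Data frame with `statistic` and `p_value`.
#' @export
compare_groups <- function(x, y, test = c("ranksum", "signedrank",
                                          "kruskal")) {
  test <- match.arg(test)
  res <- switch(test,
    ranksum = stats::wilcox.test(x, y, exact = FALSE),
    signedrank = stats::wilcox.test(x, y, paired = TRUE, exact = FALSE),
    kruskal = stats::kruskal.test(x, g = as.factor(y)))
  data.frame(test = test, statistic = unname(res$statistic),
             p_value = res$p.value)
}

#' Conserved-bin contrast
#'
#' Splits genes into the `n_top` lowest-omega bin and the rest and
#' compares a statistic between bins with a Wilcoxon rank-sum test.
#'
#' @param df Per-gene table containing `omega` and `stat` columns.
#' @param stat Name of the column to compare.
#' @param n_top Size of the conserved bin (default 100).
#' @return Data frame with group medians and the test result.
#' @export
conserved_bin_compare <- function(df, stat, n_top = 100L) {
  df <- df[!is.na(df$omega) & !is.na(df[[stat]]), ]
  ord <- order(df$omega)
  top <- df[ord[seq_len(min(n_top, nrow(df)))], ]
  rest <- df[ord[-seq_len(min(n_top, nrow(df)))], ]
  tst <- compare_groups(top[[stat]], rest[[stat]], "ranksum")
  cbind(data.frame(stat = stat, n_conserved = nrow(top),
                   n_rest = nrow(rest),
                   median_conserved = stats::median(top[[stat]]),
                   median_rest = stats::median(rest[[stat]])), tst)
}

#' Linear model of log omega on composition and codon-usage predictors
#'
#' Ordinary least squares of `log(omega)` on GC3, ENC_obs and ENC_diff,
#' each centered and scaled (mean 0, sd 1) before fitting; rows with
#' `omega <= 0` are dropped for the log transform.
#'
#' @param df Data frame with columns `omega`, `gc3`, `enc_obs`,
#'   `enc_diff`.
#' @return List of class `rate_model_fit`: `coefficients` (data frame),
#'   `f_statistic`, `adj_r_squared`, `n`, `lm` (the fitted model), and
#'   `condition_warning` when the scaled design is near collinear.
#' @export
fit_rate_model <- function(df) {
  keep <- stats::complete.cases(df[, c("omega", "gc3", "enc_obs",
                                       "enc_diff")]) & df$omega > 0
  d <- df[keep, ]
  if (nrow(d) < 5L) stop("too few complete rows with omega > 0")
  d2 <- data.frame(log_omega = log(d$omega),
                   gc3 = as.numeric(scale(d$gc3)),
                   enc_obs = as.numeric(scale(d$enc_obs)),
                   enc_diff = as.numeric(scale(d$enc_diff)))
  fit <- stats::lm(log_omega ~ gc3 + enc_obs + enc_diff, data = d2)
  sm <- summary(fit)
  X <- stats::model.matrix(fit)[, -1]
  kappa_val <- kappa(crossprod(X))
  structure(list(
    coefficients = data.frame(term = rownames(sm$coefficients),
                              sm$coefficients, row.names = NULL,
                              check.names = FALSE),
    f_statistic = unname(sm$fstatistic["value"]),
    adj_r_squared = sm$adj.r.squared, n = nrow(d2), lm = fit,
    condition_warning = if (kappa_val > 1e6)
      sprintf("near-collinear predictors (kappa = %.3g)", kappa_val)
      else NULL), class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat("rate_model_fit: n =", x$n, "; F =", signif(x$f_statistic, 4),
      "; adj R^2 =", signif(x$adj_r_squared, 4), "\n")
  print(x$coefficients, digits = 3)
  if (!is.null(x$condition_warning)) cat(" ", x$condition_warning, "\n")
  invisible(x)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates QC, codon usage/ENC, category substitution rates,
#' population-genetic gBGC inference, tRNA summaries, and the summary
#' associations, on synthetic inputs with known truth. Stages with a
#' `NULL` config block are skipped and recorded. All tables are written
#' as TSV (fits as JSON) under `outdir` when given, together with a
#' provenance record (seeds, filters, caveats).
#'
#' @param config List with blocks `alignment` (n_genes, tree, n_codons,
#'   gc3, multipliers), `popgen` (arguments of
#'   [simulate_polymorphism()] plus `n_boot`), `trna` (`copies`, decoy
#'   counts), and a top-level `seed`.
#' @param outdir Optional output directory.
#' @return List of class `pipeline_bundle` with per-stage results and
#'   `provenance`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(is.list(config), !is.null(config$seed))
  seed <- config$seed
  bundle <- list(provenance = list(
    seed = seed, timestamp = format(Sys.time()),
    stages_skipped = character(0),
    caveats = paste("substitution rates use parsimony counting with",
                    "fractional-site normalization (counting scale)")))
  if (!is.null(config$alignment)) {
    ac <- config$alignment
    tree <- ac$tree
    genes <- lapply(seq_len(ac$n_genes), function(g) {
      simulate_alignment(tree, n_codons = ac$n_codons, gc3 = ac$gc3,
                         multipliers = ac$multipliers,
                         gene = paste0("gene", g), seed = seed + g)
    })
    alns <- lapply(genes, `[[`, "alignment")
    qc <- qc_alignments(alns)
    enc_rows <- list(); rate_rows <- list()
    for (aln in qc$kept) {
      for (lin in aln$lineages) {
        enc_rows[[length(enc_rows) + 1L]] <-
          enc_record(gsub("-", "", aln$seqs[[lin]]), gene = aln$gene,
                     lineage = lin)
      }
      rate_rows[[length(rate_rows) + 1L]] <-
        branch_rates(tree, aln, seed = seed)$total
    }
    enc_tab <- do.call(rbind, enc_rows)
    rates <- do.call(rbind, rate_rows)
    keep <- filter_rate_outliers(rates$dS, rates$omega)
    per_gene <- merge(stats::aggregate(
      cbind(gc3, enc_obs, enc_diff) ~ gene, data = enc_tab, FUN = mean),
      rates[keep, c("gene", "dN", "dS", "omega")], by = "gene")
    assoc <- compute_associations(per_gene, list(
      c("gc3", "omega"), c("gc3", "dS"), c("enc_diff", "dS")))
    model <- tryCatch(fit_rate_model(per_gene), error = function(e) NULL)
    usage <- rscu(pool_codon_usage(
      lapply(qc$kept, function(a) codon_frequencies(
        gsub("-", "", a$seqs), scope = a$gene)), scope = "pooled"))
    bundle$alignment <- list(qc_report = qc$report, enc = enc_tab,
                             codon_usage = usage,
                             rates = rates, per_gene = per_gene,
                             associations = assoc, rate_model = model,
                             sw = sw_ratio(rates))
  } else {
    bundle$provenance$stages_skipped <-
      c(bundle$provenance$stages_skipped, "alignment")
  }
  if (!is.null(config$popgen)) {
    pc <- config$popgen
    sim <- do.call(simulate_polymorphism,
                   c(pc[setdiff(names(pc), "n_boot")],
                     list(seed = seed)))
    fit <- fit_gbgc(sim$data)
    boot <- if (!is.null(pc$n_boot) && pc$n_boot > 0) {
      bootstrap_fit(sim$data, n_boot = pc$n_boot, seed = seed)
    } else NULL
    bundle$popgen <- list(sim_truth = sim$truth, fit = fit, boot = boot,
                          sfs = sim$data$sfs)
  } else {
    bundle$provenance$stages_skipped <-
      c(bundle$provenance$stages_skipped, "popgen")
  }
  if (!is.null(config$trna)) {
    tc <- config$trna
    fix <- simulate_trnascan_fixture(tc$copies,
                                     n_pseudo = tc$n_pseudo %||% 2L,
                                     n_truncated = tc$n_truncated %||% 1L,
                                     seed = seed)
    genes <- parse_trnascan(fix$path)
    summ <- copy_numbers(genes)
    bundle$trna <- list(summary = summ, rait = rait(summ),
                        gc3 = trna_gc3(summ))
  } else {
    bundle$provenance$stages_skipped <-
      c(bundle$provenance$stages_skipped, "trna")
  }
  if (!is.null(outdir)) .write_bundle(bundle, outdir)
  class(bundle) <- "pipeline_bundle"
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$alignment)) {
    wt(bundle$alignment$qc_report, "qc_report")
    if (!is.null(bundle$alignment$codon_usage)) {
      wt(bundle$alignment$codon_usage, "codon_usage")
    }
    wt(bundle$alignment$enc, "enc")
    wt(bundle$alignment$rates, "rates")
    wt(bundle$alignment$per_gene, "per_gene")
    wt(bundle$alignment$associations, "associations")
  }
  if (!is.null(bundle$popgen)) {
    fit <- bundle$popgen$fit
    sfs <- bundle$popgen$sfs
    if (!is.null(sfs)) {
      wt(data.frame(class = rownames(sfs),
                    as.data.frame(sfs, optional = TRUE),
                    check.names = FALSE), "sfs")
    }
    jsonlite::write_json(
      list(B = fit$B, lambda = fit$lambda, theta = as.list(fit$theta),
           e = fit$e, logL = fit$logL, n = fit$n,
           ci = if (!is.null(bundle$popgen$boot)) bundle$popgen$boot$ci,
           seed = bundle$provenance$seed),
      file.path(outdir, "gbgc_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$provenance,
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline_bundle (seed", x$provenance$seed, ")\n")
  cat("  stages:",
      paste(setdiff(c("alignment", "popgen", "trna"),
                    x$provenance$stages_skipped), collapse = ", "), "\n")
  if (length(x$provenance$stages_skipped)) {
    cat("  skipped:", paste(x$provenance$stages_skipped,
                            collapse = ", "), "\n")
  }
  invisible(x)
}
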