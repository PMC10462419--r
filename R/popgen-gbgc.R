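# Unfolded site-frequency spectra at 0-fold / 4-fold degenerate coding
# sites and maximum-likelihood inference of mutation bias (lambda) and
# GC fixation bias (B = 4*Ne*b) under a gBGC-mutation-drift equilibrium
# model.
#
# Model: for a class of sites with population-scaled mutation intensity
# theta and fixation bias B acting on the derived allele, the expected
# number of sites with derived-allele count i in a sample of n
# chromosomes is
#   E_i(theta, B) = theta * C(n,i) *
#     Int_0^1 x^i (1-x)^(n-i) (1 - exp(-B(1-x))) /
#                             ((1 - exp(-B)) x (1-x)) dx
# (semidominant fixed-B equilibrium density). W->S mutations experience
# +B, S->W mutations -B, GC-conservative mutations B = 0; as B -> 0 the
# spectrum reduces to the neutral theta/i law.

MUT_CLASSES <- c("cons", "WS", "SW")

# ---- expected spectra ------------------------------------------------

# Gauss-Legendre nodes/weights on [0,1], cached.
.gl_nodes <- function(m = 64L) {
  key <- paste0("gl", m)
  if (is.null(.pkg_cache[[key]])) {
    .pkg_cache[[key]] <- pracma::gaussLegendre(m, 0, 1)
  }
  .pkg_cache[[key]]
}

# Per-i quadrature matrix A[i, k] = C(n,i) w_k x_k^(i-1) (1-x_k)^(n-i-1),
# so that phi(B) = A %*% g_B(x); cached per sample size.
.sfs_quad <- function(n, m = 64L) {
  key <- paste0("quad", n, "_", m)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  gl <- .gl_nodes(m)
  i <- seq_len(n - 1L)
  A <- outer(i, seq_along(gl$x), function(ii, kk) {
    choose(n, ii) * gl$w[kk] * gl$x[kk]^(ii - 1) * (1 - gl$x[kk])^(n - ii - 1)
  })
  out <- list(A = A, x = gl$x)
  .pkg_cache[[key]] <- out
  out
}

# Spectrum shape phi_i(B) = E_i(theta = 1, B), i = 1..n-1.
.sfs_shape <- function(n, B) {
  i <- seq_len(n - 1L)
  if (abs(B) < 1e-8) return(1 / i)
  q <- .sfs_quad(n)
  g <- (1 - exp(-B * (1 - q$x))) / (1 - exp(-B))
  as.numeric(q$A %*% g)
}

#' Expected unfolded site-frequency spectrum under gBGC-mutation-drift
#' equilibrium
#'
#' Expected counts `E_1..E_{n-1}` of sites at derived-allele count `i`
#' for a mutation class with scaled intensity `theta` and fixation bias
#' `B` (use `+B` for W->S, `-B` for S->W, `0` for GC-conservative). The
#' `B -> 0` neutral limit `E_i = theta / i` is taken analytically below
#' `|B| < 1e-8`.
#'
#' @param theta Positive scaled mutation intensity of the class.
#' @param B Population-scaled conversion coefficient (any real).
#' @param n Sample size in chromosomes (`n >= 2`).
#' @return Numeric vector of length `n - 1`.
#' @export
#' @examples
#' expected_sfs(1, 0, 10) # neutral: 1/i
expected_sfs <- function(theta, B, n) {
  stopifnot(theta > 0, n >= 2)
  out <- theta * .sfs_shape(n, B)
  if (any(!is.finite(out))) {
    stop("expected_sfs numerical failure at theta=", theta, ", B=", B,
         ", n=", n)
  }
  out
}

# ---- data container --------------------------------------------------

#' Bundle class-specific spectra for gBGC fitting
#'
#' @param sfs_WS,sfs_SW,sfs_cons Integer count vectors `c_1..c_{n-1}`
#'   for W->S, S->W, and GC-conservative mutation classes.
#' @param L_W,L_S Numbers of W and S sites of the degeneracy class,
#'   tallied from the ancestral/reference composition (used to
#'   normalize the mutation-bias ratio).
#' @param n Sample size in chromosomes.
#' @return Object of class `gbgc_data`.
#' @export
gbgc_data <- function(sfs_WS, sfs_SW, sfs_cons, L_W, L_S, n) {
  stopifnot(length(sfs_WS) == n - 1, length(sfs_SW) == n - 1,
            length(sfs_cons) == n - 1, L_W > 0, L_S > 0)
  structure(list(
    sfs = rbind(cons = as.numeric(sfs_cons), WS = as.numeric(sfs_WS),
                SW = as.numeric(sfs_SW)),
    L_W = L_W, L_S = L_S, n = as.integer(n)), class = "gbgc_data")
}

#' @export
print.gbgc_data <- function(x, ...) {
  cat("gbgc_data: n =", x$n, "chromosomes;",
      sum(x$sfs), "segregating sites; L_W =", x$L_W, ", L_S =", x$L_S,
      "\n")
  invisible(x)
}

# ---- likelihood ------------------------------------------------------

# Class-specific spectrum shapes at (B, e): mis-polarization mixes a
# fraction e of the reversed spectrum into every class.
.class_shapes <- function(n, B, e) {
  phi <- rbind(cons = .sfs_shape(n, 0),
               WS   = .sfs_shape(n, B),
               SW   = .sfs_shape(n, -B))
  if (e > 0) phi <- (1 - e) * phi + e * phi[, rev(seq_len(n - 1L)), drop = FALSE]
  phi
}

# Concave inner problem: for fixed (B, e) maximize the Poisson
# log-likelihood over per-class theta and shared distortion terms r_i
# (r_1 = 1, anchored by the conservative class) by coordinate ascent
# with closed-form updates.
.profile_fit <- function(counts, n, B, e = 0, distortion = TRUE,
                         max_iter = 500L, tol = 1e-10) {
  psi <- .class_shapes(n, B, e)
  nb <- n - 1L
  r <- rep(1, nb)
  theta <- pmax(rowSums(counts), 0.5) / rowSums(psi)
  ll_of <- function(theta, r) {
    m <- (theta %o% rep(1, nb)) * psi * rep(r, each = 3L)
    sum(ifelse(counts > 0, counts * log(pmax(m, 1e-300)), 0) - m)
  }
  ll <- ll_of(theta, r)
  for (it in seq_len(max_iter)) {
    theta <- rowSums(counts) / as.numeric(psi %*% r)
    theta <- pmax(theta, 1e-12)
    if (distortion) {
      denom <- as.numeric(theta %*% psi)
      r <- colSums(counts) / pmax(denom, 1e-300)
      r <- pmax(r, 1e-12)
      s <- r[1]
      r <- r / s
      theta <- theta * s
    }
    ll_new <- ll_of(theta, r)
    if (abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(theta = theta, r = r, logL = ll)
}

#' Maximum-likelihood fit of the gBGC-mutation-drift equilibrium model
#'
#' Fits the joint Poisson composite likelihood of the GC-conservative
#' (B = 0), W->S (+B) and S->W (-B) spectra, with shared per-frequency
#' distortion terms `r_i` (anchored at `r_1 = 1`; the conservative class
#' ties them down) absorbing demography/ascertainment, and an optional
#' polarization-error probability `e` mixing `(1-e) E_i + e E_{n-i}`.
#' The mutation-bias ratio is derived as
#' `lambda = (theta_SW / L_S) / (theta_WS / L_W)`.
#'
#' @param data A [gbgc_data()] object.
#' @param distortion Fit the shared `r_i` terms (default `TRUE`).
#' @param fit_error Also estimate the polarization-error probability `e`
#'   (default `FALSE`, i.e. `e = 0`).
#' @param B_bounds Search interval for `B`.
#' @return Object of class `gbgc_fit`: point estimates `B`, `lambda`,
#'   `theta` (per class), `e`, `r`, `logL`, plus metadata (bounds,
#'   boundary flag).
#' @export
fit_gbgc <- function(data, distortion = TRUE, fit_error = FALSE,
                     B_bounds = c(-5, 5)) {
  stopifnot(inherits(data, "gbgc_data"))
  counts <- data$sfs
  n <- data$n
  if (!fit_error) {
    obj <- function(B) .profile_fit(counts, n, B, 0, distortion)$logL
    opt <- stats::optimize(obj, interval = B_bounds, maximum = TRUE,
                           tol = 1e-6)
    B_hat <- opt$maximum; e_hat <- 0
  } else {
    obj <- function(p) -.profile_fit(counts, n, p[1], p[2], distortion)$logL
    opt <- stats::optim(c(0.1, 0.01), obj, method = "L-BFGS-B",
                        lower = c(B_bounds[1], 0),
                        upper = c(B_bounds[2], 0.49))
    if (opt$convergence != 0) {
      stop("gBGC optimizer failed to converge: ", opt$message)
    }
    B_hat <- opt$par[1]; e_hat <- opt$par[2]
  }
  inner <- .profile_fit(counts, n, B_hat, e_hat, distortion)
  lambda <- (inner$theta["SW"] / data$L_S) / (inner$theta["WS"] / data$L_W)
  structure(list(
    B = B_hat, lambda = unname(lambda), theta = inner$theta, e = e_hat,
    r = inner$r, logL = inner$logL, n = n,
    L_W = data$L_W, L_S = data$L_S,
    distortion = distortion, fit_error = fit_error, B_bounds = B_bounds,
    at_boundary = min(abs(B_hat - B_bounds)) < 1e-3),
    class = "gbgc_fit")
}

#' @export
print.gbgc_fit <- function(x, ...) {
  cat("gbgc_fit: B =", signif(x$B, 4), "; lambda =", signif(x$lambda, 4),
      "; e =", signif(x$e, 4), "; logL =", round(x$logL, 2), "\n")
  if (x$at_boundary) cat("  [warning] B estimate at search boundary\n")
  invisible(x)
}

#' Site-level bootstrap confidence intervals for B and lambda
#'
#' Resamples sites with replacement (implemented as a multinomial draw
#' over the full per-site category table: segregating bins of all three
#' classes plus monomorphic W and S cells), refits the model on each
#' resample, and returns percentile 95% confidence intervals.
#'
#' @param data A [gbgc_data()] object.
#' @param n_boot Number of bootstrap resamples (the source analysis used
#'   1,000 samplings with replacement).
#' @param seed Integer seed (recorded in the output).
#' @param ... Passed to [fit_gbgc()].
#' @return Object of class `gbgc_boot`: `ci` (data frame with 2.5% and
#'   97.5% percentile bounds for `B` and `lambda`), `boot` (matrix of
#'   resample estimates), `n_boot`, `seed`, `n_failed`, and a
#'   `warning` field set when more than 5% of refits failed.
#' @export
bootstrap_fit <- function(data, n_boot = 1000L, seed = 1L, ...) {
  stopifnot(inherits(data, "gbgc_data"))
  set.seed(seed)
  nb <- data$n - 1L
  seg_WS <- sum(data$sfs["WS", ]); seg_SW <- sum(data$sfs["SW", ])
  mono_W <- data$L_W - seg_WS
  mono_S <- data$L_S - seg_SW
  stopifnot(mono_W > 0, mono_S > 0)
  cells <- c(as.numeric(t(data$sfs)), mono_W, mono_S)
  total <- sum(cells)
  est <- matrix(NA_real_, nrow = n_boot, ncol = 2L,
                dimnames = list(NULL, c("B", "lambda")))
  for (b in seq_len(n_boot)) {
    draw <- as.numeric(stats::rmultinom(1L, total, cells / total))
    sfs <- matrix(draw[seq_len(3L * nb)], nrow = 3L, byrow = TRUE,
                  dimnames = list(MUT_CLASSES, NULL))
    L_W_b <- draw[3L * nb + 1L] + sum(sfs["WS", ])
    L_S_b <- draw[3L * nb + 2L] + sum(sfs["SW", ])
    fit <- tryCatch(
      fit_gbgc(gbgc_data(sfs["WS", ], sfs["SW", ], sfs["cons", ],
                         L_W_b, L_S_b, data$n), ...),
      error = function(e) NULL)
    if (!is.null(fit)) est[b, ] <- c(fit$B, fit$lambda)
  }
  ok <- stats::complete.cases(est)
  ci <- data.frame(
    param = c("B", "lambda"),
    lower = apply(est[ok, , drop = FALSE], 2, stats::quantile, 0.025),
    upper = apply(est[ok, , drop = FALSE], 2, stats::quantile, 0.975),
    row.names = NULL)
  structure(list(ci = ci, boot = est, n_boot = n_boot, seed = seed,
                 n_failed = sum(!ok),
                 warning = if (sum(!ok) > 0.05 * n_boot)
                   "more than 5% of bootstrap refits failed" else NULL),
            class = "gbgc_boot")
}

#' @export
print.gbgc_boot <- function(x, ...) {
  cat("gbgc_boot:", x$n_boot, "resamples (seed", x$seed, ");",
      x$n_failed, "failed\n")
  print(x$ci)
  invisible(x)
}

# ---- polarization and site classification ----------------------------

#' Polarize a biallelic site with two outgroup alleles
#'
#' Parsimony polarization: the ancestral allele is the ingroup allele
#' matched by both outgroups (or by the single available outgroup in
#' relaxed mode). Discordant outgroups, or outgroups matching neither
#' ingroup allele, leave the site unpolarized.
#'
#' @param ingroup_alleles Character vector of sampled ingroup bases (one
#'   per chromosome).
#' @param outgroup1,outgroup2 Single bases (or `NA`/`"N"` when missing).
#' @param relaxed Allow polarization from a single outgroup when the
#'   other is missing (default `TRUE`).
#' @return List with `status` (`"polarized"`/`"unpolarized"`/
#'   `"monomorphic"`), and for polarized sites `anc`, `der`, `i`
#'   (derived count), `n`; unpolarized sites carry a `reason`.
#' @export
#' @examples
#' polarize(c(rep("A", 19), "G"), "A", "A")
polarize <- function(ingroup_alleles, outgroup1, outgroup2,
                     relaxed = TRUE) {
  al <- toupper(ingroup_alleles)
  stopifnot(all(al %in% BASES))
  tab <- table(al)
  if (length(tab) == 1L) {
    return(list(status = "monomorphic", base = names(tab)))
  }
  if (length(tab) != 2L) {
    return(list(status = "unpolarized", reason = "not_biallelic"))
  }
  norm <- function(x) {
    x <- toupper(as.character(x))
    if (length(x) == 0 || is.na(x) || !(x %in% BASES)) NA_character_ else x
  }
  o1 <- norm(outgroup1); o2 <- norm(outgroup2)
  outs <- c(o1, o2)[!is.na(c(o1, o2))]
  anc <- NULL
  if (length(outs) == 2L) {
    if (outs[1] != outs[2]) {
      return(list(status = "unpolarized", reason = "outgroup_discordant"))
    }
    anc <- outs[1]
  } else if (length(outs) == 1L && relaxed) {
    anc <- outs[1]
  } else {
    return(list(status = "unpolarized", reason = "missing_outgroup"))
  }
  if (!(anc %in% names(tab))) {
    return(list(status = "unpolarized", reason = "outgroup_mismatch"))
  }
  der <- setdiff(names(tab), anc)
  list(status = "polarized", anc = anc, der = der,
       i = as.integer(tab[[der]]), n = length(al))
}

#' Degeneracy and mutation class of a polarized coding site
#'
#' Site degeneracy is taken from the ancestral codon context; the
#' mutation class follows the strong/weak classes of the ancestral and
#' derived bases. Only 0-fold and 4-fold sites enter the gBGC analysis;
#' 2-fold and 3-fold sites are flagged excluded.
#'
#' @param codon Ancestral codon (the base at `position` must equal
#'   `anc`).
#' @param position Position within the codon (1..3).
#' @param anc,der Ancestral and derived bases.
#' @inheritParams genetic_code
#' @return One-row data frame: `degeneracy`, `class` (`"WS"`, `"SW"`,
#'   `"cons"`), `included`.
#' @export
#' @examples
#' classify_site("GGA", 3, "A", "G") # 4-fold, W->S
classify_site <- function(codon, position, anc, der, code = NULL) {
  codon <- toupper(codon)
  if (substr(codon, position, position) != toupper(anc)) {
    stop("ancestral base does not match codon context")
  }
  deg <- site_degeneracy(codon, position, code)
  cls <- mutation_class(anc, der)
  data.frame(degeneracy = deg,
             class = if (cls == "conservative") "cons" else cls,
             included = deg %in% c(0L, 4L), stringsAsFactors = FALSE)
}

#' Build class-specific unfolded spectra from polarized sites
#'
#' Bins polarized sites into count vectors `c_1..c_{n-1}` per mutation
#' class within each degeneracy class, and attaches the W/S site totals
#' used for mutation-bias normalization.
#'
#' @param sites Data frame with columns `degeneracy` (0 or 4), `class`
#'   (`"WS"`, `"SW"`, `"cons"`), and `i` (derived count, `0 < i < n`;
#'   sites at 0 or `n` are reassigned monomorphic and dropped).
#' @param n Common sample size in chromosomes.
#' @param L_W,L_S Named numeric vectors (names `"0"`, `"4"`) of W/S site
#'   totals per degeneracy class from the reference composition.
#' @return Named list (by degeneracy class present) of [gbgc_data()]
#'   objects.
#' @export
build_sfs <- function(sites, n, L_W, L_S) {
  stopifnot(all(c("degeneracy", "class", "i") %in% names(sites)))
  seg <- sites[sites$i > 0 & sites$i < n, , drop = FALSE]
  out <- list()
  for (deg in intersect(c(0L, 4L), unique(seg$degeneracy))) {
    sub <- seg[seg$degeneracy == deg, , drop = FALSE]
    cnt <- function(cl) {
      tabulate(sub$i[sub$class == cl], nbins = n - 1L)
    }
    out[[as.character(deg)]] <- gbgc_data(
      sfs_WS = cnt("WS"), sfs_SW = cnt("SW"), sfs_cons = cnt("cons"),
      L_W = L_W[[as.character(deg)]], L_S = L_S[[as.character(deg)]],
      n = n)
  }
  out
}

#' Project a site-frequency spectrum to a smaller sample size
#'
#' Hypergeometric down-sampling of an unfolded spectrum from `n_from` to
#' `n_to` chromosomes (expectation-based projection); mass falling on
#' the monomorphic bins is dropped.
#'
#' @param counts Numeric vector `c_1..c_{n_from-1}`.
#' @param n_from,n_to Sample sizes (`n_to <= n_from`).
#' @return Numeric vector of length `n_to - 1`.
#' @export
project_sfs <- function(counts, n_from, n_to) {
  stopifnot(length(counts) == n_from - 1L, n_to <= n_from, n_to >= 2L)
  if (n_to == n_from) return(counts)
  out <- numeric(n_to - 1L)
  for (i in seq_len(n_from - 1L)) {
    j <- 0:n_to
    p <- stats::dhyper(j, i, n_from - i, n_to)
    keep <- j >= 1L & j <= n_to - 1L
    out <- out + counts[i] * p[keep]
  }
  out
}
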