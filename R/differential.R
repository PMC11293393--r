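#' Trimmed-mean (TMM) normalization factors
#'
#' Computes a compositional scaling factor per sample as the trimmed
#' mean of per-feature log2-ratios (M-values) against a reference
#' sample, trimming the most extreme 30% of M-values and 5% of A-values
#' (average log intensities); features with a zero in either sample are
#' excluded.  Compositional factors are renormalized to geometric mean
#' 1 and combined with the chosen depth denominator (library size or
#' spike-in total) into one effective size factor per sample.
#'
#' @param x A [count_matrix()].
#' @param ref_sample Reference column (name or index); default is the
#'   sample whose upper-quartile count fraction is closest to the mean —
#'   the usual robust choice.
#' @param mode Depth denominator: `"library_size"` or `"spikein"`.
#' @return Object of class `norm_factors`: `data.frame` with `sample`,
#'   `denominator`, `compositional`, `effective`; attribute `method`.
#' @export
trimmed_mean_factors <- function(x, ref_sample = NULL,
                                 mode = c("library_size", "spikein")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "count_matrix"))
  y <- x$counts
  if (ncol(y) < 2) stop("need at least 2 samples")
  denom <- if (mode == "spikein") x$spikein_size else x$library_size
  if (is.null(denom) || any(denom <= 0)) stop("invalid ", mode, " denominators")
  p <- sweep(y, 2, denom, "/")
  if (is.null(ref_sample)) {
    uq <- apply(p, 2, quantile, 0.75)
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  if (is.character(ref_sample)) ref_sample <- match(ref_sample, colnames(y))
  f <- numeric(ncol(y))
  for (j in seq_len(ncol(y))) {
    if (j == ref_sample) { f[j] <- 1; next }
    ok <- y[, j] > 0 & y[, ref_sample] > 0
    if (!any(ok))
      stop("sample ", colnames(y)[j] %||% j,
           " shares no nonzero features with the reference")
    M <- log2(p[ok, j] / p[ok, ref_sample])
    A <- 0.5 * log2(p[ok, j] * p[ok, ref_sample])
    keepM <- M >= quantile(M, 0.15) & M <= quantile(M, 0.85)
    keepA <- A >= quantile(A, 0.025) & A <= quantile(A, 0.975)
    keep <- keepM & keepA
    if (!any(keep)) keep <- keepM
    f[j] <- 2^mean(M[keep])
  }
  f <- f / exp(mean(log(f)))
  res <- data.frame(sample = colnames(y) %||% paste0("s", seq_len(ncol(y))),
                    denominator = denom, compositional = f,
                    effective = denom * f, row.names = NULL)
  attr(res, "method") <- paste0("TMM+", mode)
  class(res) <- c("norm_factors", "data.frame")
  res
}

# vectorized fixed-point solve of the NB group-mean MLE, all features at
# once: mu_ij = s_j * q_i with fixed per-feature dispersion phi_i
nb_fit_q <- function(y, s, phi, n_iter = 60L) {
  q <- pmax(rowSums(y) / sum(s), 1e-10)
  k <- 1 / phi
  for (it in seq_len(n_iter)) {
    sq <- outer(q, s)                      # mu
    w <- sweep(y + k, 1, k, "/") / (1 + sweep(sq, 1, k, "/"))
    q_new <- rowSums(y) / pmax(rowSums(sweep(w, 2, s, "*")), 1e-300)
    if (max(abs(q_new - q) / pmax(q, 1e-10)) < 1e-10) { q <- q_new; break }
    q <- q_new
  }
  q
}

nb_loglik <- function(y, s, phi, q) {
  mu <- outer(q, s)
  rowSums(dnbinom(y, size = 1 / phi, mu = pmax(mu, 1e-300), log = TRUE))
}

#' Negative-binomial differential test with moment dispersion and
#' prior-count stabilized fold changes
#'
#' Per feature, the NB dispersion is estimated by the method of moments
#' on factor-normalized counts and shrunk toward the common (trimmed
#' mean) dispersion with weight `n / (n + 4)` (`n` = number of samples);
#' the two group means are then compared by a likelihood-ratio test with
#' the dispersion held fixed, and p-values are Benjamini-Hochberg
#' adjusted across all tested features.  log2 fold changes are computed
#' on normalized group means after adding `prior_count` scaled per
#' sample by its effective factor, so they stay finite at zero counts.
#'
#' @param x A [count_matrix()], or a plain counts matrix.
#' @param groups Factor (or coercible) of length `ncol(counts)` with
#'   exactly two levels, each with at least 2 samples.  The first level
#'   is the reference: `log2FC` is level 2 over level 1, so set the
#'   factor levels explicitly to control the sign.
#' @param factors Optional [trimmed_mean_factors()] result; default uses
#'   the matrix's library sizes with no compositional correction.
#' @param prior_count Pseudocount on the mean-depth scale (default 3).
#' @param fdr_threshold,lfc_threshold Significance rule for the `sig`
#'   flag (defaults 0.05 and 0.9).
#' @return `data.frame` of class `nb_diff`: `feature`, `baseMean`,
#'   `log2FC`, `pvalue`, `FDR`, `sig`.
#' @export
nb_differential <- function(x, groups, factors = NULL, prior_count = 3,
                            fdr_threshold = 0.05, lfc_threshold = 0.9) {
  y <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  if (length(groups) != ncol(y)) stop("one group label per sample required")
  eff <- if (!is.null(factors)) factors$effective
  else if (inherits(x, "count_matrix")) x$library_size
  else colSums(y)
  s <- eff / exp(mean(log(eff)))          # geometric mean 1, count scale
  n <- ncol(y)
  g1 <- groups == levels(groups)[1]

  # moment dispersion on normalized counts, pooled within groups
  z <- sweep(y, 2, s, "/")
  phi_raw <- rep(0, nrow(y))
  m_all <- rowMeans(z)
  df <- 0
  for (g in levels(groups)) {
    jj <- groups == g
    ng <- sum(jj)
    mg <- rowMeans(z[, jj, drop = FALSE])
    vg <- apply(z[, jj, drop = FALSE], 1, var)
    shot <- mg * mean(1 / s[jj])
    phi_g <- ifelse(mg > 0, (vg - shot) / mg^2, 0)
    phi_raw <- phi_raw + (ng - 1) * phi_g
    df <- df + (ng - 1)
  }
  phi_raw <- phi_raw / df
  # the raw moment estimator is approximately unbiased but very noisy at
  # small n; average it unfloored and untrimmed (flooring or trimming the
  # right-skewed raw values biases the common dispersion) and floor only
  # the final shrunk estimate
  expressed <- m_all > 0
  phi_common <- if (any(expressed))
    max(mean(phi_raw[expressed]), 1e-8) else 1e-8
  phi <- pmax((n * phi_raw + 4 * phi_common) / (n + 4), 1e-8)

  q_null <- nb_fit_q(y, s, phi)
  q1 <- nb_fit_q(y[, g1, drop = FALSE], s[g1], phi)
  q2 <- nb_fit_q(y[, !g1, drop = FALSE], s[!g1], phi)
  ll_null <- nb_loglik(y, s, phi, q_null)
  ll_alt <- nb_loglik(y[, g1, drop = FALSE], s[g1], phi, q1) +
    nb_loglik(y[, !g1, drop = FALSE], s[!g1], phi, q2)
  stat <- pmax(2 * (ll_alt - ll_null), 0)
  pvalue <- pchisq(stat, df = 1, lower.tail = FALSE)

  prior_j <- prior_count * s / mean(s)
  zp <- sweep(y, 2, prior_j, "+")
  zp <- sweep(zp, 2, s, "/")
  m1 <- rowMeans(zp[, g1, drop = FALSE])
  m2 <- rowMeans(zp[, !g1, drop = FALSE])
  log2FC <- log2(m2 / m1)

  allzero <- rowSums(y) == 0
  pvalue[allzero] <- 1
  log2FC[allzero] <- 0
  FDR <- p.adjust(pvalue, method = "BH")
  res <- data.frame(
    feature = rownames(y) %||% paste0("feature_", seq_len(nrow(y))),
    baseMean = rowMeans(z), log2FC = log2FC, dispersion = phi,
    stat = stat, pvalue = pvalue, FDR = FDR,
    sig = FDR < fdr_threshold & abs(log2FC) > lfc_threshold,
    row.names = NULL)
  attr(res, "thresholds") <- c(FDR = fdr_threshold, log2FC = lfc_threshold)
  attr(res, "comparison") <- paste(levels(groups)[2], "vs", levels(groups)[1])
  class(res) <- c("nb_diff", "data.frame")
  res
}

#' @export
print.nb_diff <- function(x, n = 10, ...) {
  th <- attr(x, "thresholds")
  cat("NB differential test:", attr(x, "comparison"), "\n")
  cat(sprintf("%d features; %d significant (FDR < %g, |log2FC| > %g)\n",
              nrow(x), sum(x$sig), th["FDR"], th["log2FC"]))
  df <- as.data.frame(x)[order(x$pvalue), ]
  print(head(df, n), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.nb_diff <- function(object, ...) {
  th <- attr(object, "thresholds")
  up <- sum(object$sig & object$log2FC > 0)
  dn <- sum(object$sig & object$log2FC < 0)
  cat(sprintf("%d features tested; %d up, %d down at FDR < %g, |log2FC| > %g\n",
              nrow(object), up, dn, th["FDR"], th["log2FC"]))
  invisible(data.frame(up = up, down = dn, tested = nrow(object)))
}

#' Build a read-feature compatibility matrix from fragment overlaps
#'
#' Each row is a read (fragment), each column a feature (repeat
#' instance); an entry is 1 iff the read overlaps that instance.  Reads
#' overlapping no instance are dropped (they are incompatible with every
#' feature and carry no information for the mixture).
#'
#' @param fragments `GRanges` of reads/fragments, or a [fragment_set()].
#' @param features `GRanges` of candidate source features.
#' @param feature_names Optional column names (default
#'   `feature_1..`).
#' @return A sparse 0/1 `dgCMatrix` with attribute `"unique_reads"`
#'   (logical: rows compatible with exactly one feature).
#' @export
compat_matrix <- function(fragments, features, feature_names = NULL) {
  if (inherits(fragments, "fragment_set")) fragments <- fragments$fragments
  hits <- GenomicRanges::findOverlaps(fragments, features,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep_reads <- sort(unique(qh))
  m <- Matrix::sparseMatrix(i = match(qh, keep_reads), j = sh, x = 1,
                            dims = c(length(keep_reads), length(features)))
  colnames(m) <- feature_names %||% paste0("feature_", seq_along(features))
  attr(m, "unique_reads") <- Matrix::rowSums(m) == 1
  m
}

#' EM fractional assignment of multimapping reads to features
#'
#' Mixture-model EM: feature abundances start uniform; the E-step
#' splits each read across its compatible features in proportion to the
#' current abundances; the M-step sets abundances to the summed
#' fractional assignments.  Iteration stops when the largest relative
#' abundance change falls below `tol` or after `max_iter` rounds.  The
#' fractional counts sum exactly to the number of reads, and the
#' observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param compat Reads x features 0/1 matrix (sparse `dgCMatrix`,
#'   logical or numeric); every read must be compatible with at least
#'   one feature.
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @return Object of class `em_assignment`: `counts` (fractional, per
#'   feature), `abundance`, `loglik` (per-iteration trace),
#'   `iterations`, `converged`.
#' @export
em_assign_multireads <- function(compat, max_iter = 100L, tol = 1e-6) {
  A <- methods::as(methods::as(Matrix::Matrix(compat, sparse = TRUE),
                               "generalMatrix"), "dMatrix")
  if (nrow(A) == 0 || ncol(A) == 0) stop("empty compatibility matrix")
  A@x[] <- 1
  if (any(Matrix::rowSums(A) == 0))
    stop("read(s) compatible with no feature")
  N <- nrow(A); G <- ncol(A)
  p <- rep(1 / G, G)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    W <- A %*% Matrix::Diagonal(x = p)
    rs <- Matrix::rowSums(W)
    ll_trace <- c(ll_trace, sum(log(rs)))
    frac <- Matrix::colSums(Matrix::Diagonal(x = 1 / rs) %*% W)
    p_new <- frac / N
    delta <- max(abs(p_new - p) / pmax(p, 1e-12))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  counts <- p * N
  names(counts) <- colnames(A) %||% paste0("feature_", seq_len(G))
  structure(list(counts = counts, abundance = p, loglik = ll_trace,
                 iterations = it, converged = converged),
            class = "em_assignment")
}

#' @export
print.em_assignment <- function(x, ...) {
  cat(sprintf("em_assignment: %d features, %.6g reads, %d iteration(s)%s\n",
              length(x$counts), sum(x$counts), x$iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Roll fractional instance counts up to a coarser label
#'
#' Instance-level EM first, then family roll-up: sums fractional counts
#' over instances sharing a label (e.g. `repeat_family`).
#'
#' @param counts Named numeric vector of per-instance counts (e.g.
#'   `em_assign_multireads()$counts`).
#' @param labels Character vector of the target label per instance.
#' @return Named numeric vector of per-label counts.
#' @export
rollup_counts <- function(counts, labels) {
  stopifnot(length(counts) == length(labels))
  v <- tapply(counts, labels, sum)
  setNames(as.numeric(v), names(v))
}
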