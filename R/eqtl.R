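# Marginal eQTL scanning: covariate-adjusted linear association tests for
# every SNP-probe pair, cis/trans classification against a 1 Mb window,
# per-class Benjamini-Hochberg FDR, and candidate trio construction.

#' Classify a SNP-probe pair as cis or trans
#'
#' A pair is cis when SNP and probe are on the same chromosome and the
#' distance from the SNP to the probe interval is at most `window` base pairs
#' (distance 0 when the SNP lies inside the interval). All other pairs —
#' different chromosomes, or same chromosome more than `window` apart — are
#' trans. Vectorized over pairs.
#'
#' @param snp_chrom,snp_pos SNP location (1-based).
#' @param probe_chrom,probe_start,probe_end probe interval (1-based,
#'   inclusive; orientation-free).
#' @param window cis window in base pairs (default 1e6).
#' @return Character vector, `"cis"` or `"trans"` per pair.
#' @export
classify_pair <- function(snp_chrom, snp_pos, probe_chrom, probe_start,
                          probe_end, window = 1e6) {
  lo <- pmin(probe_start, probe_end)
  hi <- pmax(probe_start, probe_end)
  dist <- pmax(lo - snp_pos, snp_pos - hi, 0)
  ifelse(as.character(snp_chrom) == as.character(probe_chrom) & dist <= window,
         "cis", "trans")
}

#' Single SNP-probe association test
#'
#' Ordinary least squares of expression on an intercept, the dosage, and the
#' covariates, over the samples with a non-missing dosage (complete-case).
#' Two-sided t-test on the dosage coefficient with `n - k - 2` residual
#' degrees of freedom (`k` covariates). A perfect fit (zero residual sum of
#' squares) cannot yield a finite t statistic; its p-value is reported at the
#' machine-epsilon floor with `degenerate = TRUE`.
#'
#' @param y numeric expression vector.
#' @param x numeric dosage vector (may contain `NA`).
#' @param C optional [covariate_table()] or numeric matrix aligned with `y`.
#' @return A list: `effect`, `stderr`, `t`, `p`, `n` (complete cases), `df`,
#'   `degenerate`.
#' @export
association_test <- function(y, x, C = NULL) {
  Cm <- if (is.null(C)) NULL else if (inherits(C, "covariate_table")) C$values else as.matrix(C)
  ok <- !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (!is.null(Cm)) Cm <- Cm[ok, , drop = FALSE]
  k <- if (is.null(Cm)) 0L else ncol(Cm)
  n <- length(y)
  if (n < k + 3L) stop("need at least k + 3 complete cases (have ", n, ")")
  if (stats::var(x) == 0)
    stop("dosage is constant after dropping missing values; effect undefined")
  D <- cbind(`(Intercept)` = 1, x = x, Cm)
  fit <- .ols(D, y)
  df <- n - k - 2L
  sigma2 <- fit$rss / df
  se <- sqrt(sigma2 * fit$xtx_inv_diag[2L])
  degenerate <- fit$rss <= .Machine$double.eps * max(1, sum(y^2))
  if (degenerate) {
    tval <- sign(fit$coef[2L]) * Inf
    p <- .Machine$double.eps
  } else {
    tval <- fit$coef[2L] / se
    p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  }
  list(effect = unname(fit$coef[2L]), stderr = unname(se), t = unname(tval),
       p = unname(p), n = n, df = df, degenerate = unname(degenerate))
}

# least squares via QR; returns coefficients, residual SS (per response) and
# diag((D'D)^-1). y may be a matrix (one response per column).
.ols <- function(D, y) {
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- colnames(D)[qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  coef <- qr.coef(qrD, y)
  res <- qr.resid(qrD, y)
  rss <- if (is.matrix(y)) colSums(res^2) else sum(res^2)
  R <- qr.R(qrD)
  xtx_inv <- chol2inv(R)
  # chol2inv gives the inverse in pivoted order; undo the pivot
  piv <- qrD$pivot
  d <- numeric(ncol(D)); d[piv] <- diag(xtx_inv)
  list(coef = coef, resid = res, rss = rss, xtx_inv_diag = d, qr = qrD)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values: `q_(i) = min_(j >= i) m p_(j) / j` on the
#' sorted scale, mapped back to input order (via [stats::p.adjust()]).
#' Rejecting at `q <= alpha` reproduces the classic BH step-up rejection set.
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @return q-values in input order; empty input gives empty output.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Genome-wide eQTL scan
#'
#' Tests SNP-probe pairs of the requested relation with
#' [association_test()], sharing one design decomposition per SNP across all
#' probes. Sample ids are aligned by intersection, in the genotype matrix's
#' order. q-values are assigned by [bh_fdr()] separately within the cis and
#' trans record classes, over the full scan. SNPs whose dosage is constant
#' on the analyzed samples are skipped with a message.
#'
#' @param g a [genotype_matrix()].
#' @param e an [expression_matrix()].
#' @param C optional [covariate_table()]; `NULL` for none.
#' @param mode `"cis"`, `"trans"`, or `"both"`.
#' @param window cis window in base pairs (default 1e6).
#' @return A data frame of association records: `snp_id`, `probe_id`,
#'   `relation`, `effect`, `stderr`, `t_stat`, `p`, `q`, `n`, `degenerate`,
#'   ordered by (snp, probe).
#' @export
eqtl_scan <- function(g, e, C = NULL, mode = c("both", "cis", "trans"),
                      window = 1e6) {
  mode <- match.arg(mode)
  samples <- intersect(g$sample_ids, e$sample_ids)
  if (!is.null(C)) samples <- intersect(samples, C$sample_ids)
  if (length(samples) == 0L) stop("no overlapping samples between inputs")
  gi <- match(samples, g$sample_ids)
  ei <- match(samples, e$sample_ids)
  Cm <- if (is.null(C)) NULL else C$values[match(samples, C$sample_ids), , drop = FALSE]
  k <- if (is.null(Cm)) 0L else ncol(Cm)
  Ymat <- t(e$values[, ei, drop = FALSE])        # samples x probes

  out <- vector("list", length(g$snp_ids))
  for (s in seq_along(g$snp_ids)) {
    rel <- classify_pair(g$chrom[s], g$pos[s], e$chrom, e$start, e$end, window)
    keep <- if (mode == "both") rep(TRUE, length(rel)) else rel == mode
    if (!any(keep)) next
    x <- g$dosages[s, gi]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < k + 3L || stats::var(x[ok]) == 0) {
      message("eqtl_scan: skipping SNP '", g$snp_ids[s],
              "' (constant or insufficient dosage data)")
      next
    }
    D <- cbind(1, x[ok], Cm[ok, , drop = FALSE])
    fit <- .ols(D, Ymat[ok, keep, drop = FALSE])
    df <- n - k - 2L
    rss <- fit$rss
    coefx <- fit$coef[2L, ]
    yss <- colSums(Ymat[ok, keep, drop = FALSE]^2)
    degenerate <- rss <= .Machine$double.eps * pmax(1, yss)
    se <- sqrt((rss / df) * fit$xtx_inv_diag[2L])
    tval <- coefx / se
    p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
    tval[degenerate] <- sign(coefx[degenerate]) * Inf
    p[degenerate] <- .Machine$double.eps
    out[[s]] <- data.frame(
      snp_id = g$snp_ids[s], probe_id = e$probe_ids[keep],
      relation = rel[keep], effect = unname(coefx), stderr = unname(se),
      t_stat = unname(tval), p = unname(p), q = NA_real_, n = n,
      degenerate = unname(degenerate), stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(rec))
    return(data.frame(snp_id = character(0), probe_id = character(0),
                      relation = character(0), effect = numeric(0),
                      stderr = numeric(0), t_stat = numeric(0), p = numeric(0),
                      q = numeric(0), n = integer(0), degenerate = logical(0)))
  rec <- rec[order(rec$snp_id, rec$probe_id), , drop = FALSE]
  rownames(rec) <- NULL
  for (cl in c("cis", "trans")) {
    sel <- rec$relation == cl
    if (any(sel)) rec$q[sel] <- bh_fdr(rec$p[sel])
  }
  rec
}

#' Build candidate SNP / cis-mediator / trans-gene trios
#'
#' One trio per (SNP, trans-probe) pair whose trans association p-value is
#' strictly below `trans_p_max`, provided the SNP has at least one cis-gene
#' at BH q-value at most `cis_fdr_max`. Mediators are ordered by ascending
#' cis p-value and truncated to `max_mediators`.
#'
#' @param trans_records,cis_records association data frames from
#'   [eqtl_scan()] (the `relation` column is used to subset, so a combined
#'   scan can be passed to both arguments).
#' @param trans_p_max trans p-value threshold, strict (default 1e-6).
#' @param cis_fdr_max cis q-value threshold (default 0.05).
#' @param max_mediators at most this many cis mediators per trio (default 5).
#' @return A data frame with one row per trio: `snp_id`, `trans_probe_id`,
#'   `trans_p`, `n_mediators`, and semicolon-joined `mediators`,
#'   `mediator_p`, `mediator_q`.
#' @export
build_trios <- function(trans_records, cis_records, trans_p_max = 1e-6,
                        cis_fdr_max = 0.05, max_mediators = 5L) {
  tr <- trans_records[trans_records$relation == "trans" &
                        trans_records$p < trans_p_max, , drop = FALSE]
  ci <- cis_records[cis_records$relation == "cis" &
                      !is.na(cis_records$q) & cis_records$q <= cis_fdr_max, ,
                    drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    snp <- tr$snp_id[i]
    med <- ci[ci$snp_id == snp & ci$probe_id != tr$probe_id[i], , drop = FALSE]
    if (nrow(med) == 0L) next
    med <- med[order(med$p, med$probe_id), , drop = FALSE]
    med <- utils::head(med, max_mediators)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = snp, trans_probe_id = tr$probe_id[i], trans_p = tr$p[i],
      n_mediators = nrow(med),
      mediators = paste(med$probe_id, collapse = ";"),
      mediator_p = paste(format(med$p, digits = 15, trim = TRUE), collapse = ";"),
      mediator_q = paste(format(med$q, digits = 15, trim = TRUE), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(snp_id = character(0), trans_probe_id = character(0),
                      trans_p = numeric(0), n_mediators = integer(0),
                      mediators = character(0), mediator_p = character(0),
                      mediator_q = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$snp_id, out$trans_probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
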