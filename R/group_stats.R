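# Group comparisons, FDR control, and MMSE correlations.

#' Two-sample Student's t-test (pooled variance)
#'
#' Sign convention: positive t means group `b` is larger than group `a`.
#' Throughout the pipeline `a` is the HC group and `b` the AD group, so
#' positive t = larger in AD.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L || !all(is.finite(c(a, b)))) {
    stop("each group needs >= 2 finite values", call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) < 1e-300) {
    stop("degenerate test: zero pooled variance", call. = FALSE)
  }
  fit <- stats::t.test(b, a, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Paired t-test
#'
#' One-sample t on the differences `b - a`, two-sided. Positive t means
#' `b` larger. Zero-variance differences (e.g. `b` is `a` plus a constant)
#' are a degenerate case and raise an error rather than reporting an
#' infinite statistic.
#'
#' @param a,b Numeric vectors of equal length (n >= 2).
#' @return List with `t`, `p`, `df`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples differ in length", call. = FALSE)
  if (length(a) < 2L || !all(is.finite(c(a, b)))) {
    stop("need >= 2 finite pairs", call. = FALSE)
  }
  d <- b - a
  if (stats::var(d) < 1e-300) {
    stop("degenerate paired test: zero-variance differences", call. = FALSE)
  }
  fit <- stats::t.test(d)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up BH procedure at level `q` over the whole supplied family.
#' When `family_size` is given the length of `p` must equal it exactly —
#' each analysis family in the pipeline has a fixed, known size
#' (PSD bins: 1000; MSE scales: 20; emergence: 5; occurrence: 4;
#' transitions: k*k) and a mismatch signals an upstream bug, so it aborts.
#'
#' @param p Vector of p values.
#' @param q FDR level (default 0.05).
#' @param family_size Expected number of tests, or `NULL` to skip the check.
#' @return Logical vector of significance flags.
#' @export
bh_fdr <- function(p, q = 0.05, family_size = NULL) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values outside [0, 1]", call. = FALSE)
  }
  if (!is.null(family_size) && length(p) != family_size) {
    stop("FDR family size mismatch: got ", length(p), " p values, family is ",
         family_size, call. = FALSE)
  }
  stats::p.adjust(p, method = "BH") < q
}

#' Pearson correlation of a per-subject metric with MMSE
#'
#' @param metric Numeric vector of per-subject metric values (AD group).
#' @param mmse Matching MMSE scores.
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
mmse_correlation <- function(metric, mmse) {
  ok <- is.finite(metric) & is.finite(mmse)
  metric <- metric[ok]; mmse <- mmse[ok]
  if (length(metric) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(metric) < 1e-300 || stats::var(mmse) < 1e-300) {
    stop("degenerate correlation: zero variance", call. = FALSE)
  }
  fit <- stats::cor.test(metric, mmse, method = "pearson")
  list(r = unname(fit$estimate), p = fit$p.value, n = length(metric))
}

#' Build a test table for a family of group comparisons
#'
#' Runs [two_sample_ttest()] for every column of `hc` vs `ad` (subjects in
#' rows), applies BH-FDR over the declared family, and returns a flat
#' table.
#'
#' @param hc,ad Matrices or data.frames, subjects x metrics, same columns.
#' @param family_size Declared family size (defaults to the column count).
#' @param q FDR level.
#' @return Data.frame with columns name, t, p, significant.
#' @export
group_test_table <- function(hc, ad, family_size = ncol(as.matrix(hc)),
                             q = 0.05) {
  hc <- as.matrix(hc); ad <- as.matrix(ad)
  stopifnot(ncol(hc) == ncol(ad))
  nm <- colnames(hc) %||% paste0("metric", seq_len(ncol(hc)))
  res <- lapply(seq_len(ncol(hc)), function(j) {
    tryCatch(two_sample_ttest(hc[, j], ad[, j]),
             error = function(e) list(t = NA_real_, p = NA_real_))
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  tab <- data.frame(name = nm,
                    t = vapply(res, `[[`, numeric(1), "t"),
                    p = p,
                    significant = bh_fdr(p, q = q, family_size = family_size))
  attr(tab, "family_size") <- family_size
  attr(tab, "alpha_q") <- q
  tab
}
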