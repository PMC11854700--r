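# Evaluation machinery: ROC/AUC by pairwise ranking, sensitivity and
# specificity at the alpha cutoff, pooled-variance Student t test,
# Benjamini-Hochberg FDR adjustment, and the qualified-vs-disqualified
# rater-error comparison.

#' ROC curve and AUC of a scored cohort
#'
#' AUC is computed as the Mann-Whitney probability that a random positive
#' outranks a random negative, ties counted one half — implemented through
#' midranks, which is exactly that probability. Curve points are the
#' standard staircase over score thresholds.
#'
#' @param labels logical (or 0/1) true labels; both classes must be present.
#' @param scores finite numeric scores, larger = more positive-like. For
#'   alpha-based DDH scoring use `60 - alpha_deg` so larger means more
#'   DDH-like.
#' @return list of class `roc_result`: `auc`, `curve` (data.frame
#'   `threshold, fpr, tpr`).
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute ROC")
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, numeric(1))
  structure(list(auc = auc,
                 curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' Sensitivity and specificity at the alpha cutoff
#'
#' Positive means predicted DDH at the cutoff (see [classify_ddh()]).
#'
#' @param true_ddh logical true labels.
#' @param alpha_deg measured alpha angles, degrees.
#' @param cutoff_deg decision threshold (default 60).
#' @param rule `"strict"` or `"inclusive"`, as in [classify_ddh()].
#' @return list `sensitivity`, `specificity`, `table` (2x2 counts).
#' @export
sens_spec_at_cutoff <- function(true_ddh, alpha_deg, cutoff_deg = 60,
                                rule = c("strict", "inclusive")) {
  rule <- match.arg(rule)
  true_ddh <- as.logical(true_ddh)
  if (!any(true_ddh)) stop("no positive cases: sensitivity undefined")
  if (all(true_ddh)) stop("no negative cases: specificity undefined")
  pred <- classify_ddh(alpha_deg, cutoff_deg, rule)
  tp <- sum(pred & true_ddh); fn <- sum(!pred & true_ddh)
  tn <- sum(!pred & !true_ddh); fp <- sum(pred & !true_ddh)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       table = matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(pred = c("ddh", "normal"),
                                      truth = c("ddh", "normal"))))
}

#' Two-sample Student t test (pooled variance)
#'
#' The classical equal-variance form: pooled sd over `n_a + n_b - 2`
#' degrees of freedom, two-sided p from the t distribution. Set
#' `welch = TRUE` for the unequal-variance variant.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param welch use the Welch-Satterthwaite correction.
#' @return list `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
student_t_test <- function(group_a, group_b, welch = FALSE) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    tt <- (ma - mb) / sqrt(se2)
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  if (!is.finite(tt)) tt <- 0          # identical constant groups
  p <- 2 * pt(-abs(tt), df)
  list(t = tt, p = p, df = df, mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values: `p * m / rank`, enforced monotone
#' non-decreasing in p and capped at 1. Order-invariant: the output is
#' returned in the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p values, same order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  m <- length(pvalues)
  if (m <= 1L) return(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pvalues[o]))
  adj[ro]
}

#' Per-frame rater error summaries
#'
#' From an `n_raters x n_repeats` measurement matrix: the inter-rater error
#' is the mean absolute pairwise difference between rater means; the
#' intra-rater error is the mean, over raters, of the absolute spread of
#' their repeats (max - min; for two repeats, their absolute difference).
#'
#' @param m measurement matrix (raters in rows, repeats in columns).
#' @return list `inter`, `intra` (degrees).
#' @export
rater_errors <- function(m) {
  m <- rbind(m)
  rmeans <- rowMeans(m)
  inter <- if (nrow(m) < 2L) NA_real_ else mean(abs(c(dist(rmeans))))
  intra <- if (ncol(m) < 2L) NA_real_ else
    mean(apply(m, 1, function(v) max(v) - min(v)))
  list(inter = inter, intra = intra)
}

#' Compare rater errors between qualified and disqualified frames
#'
#' The reliability argument for quality gating: frames passing the
#' iliac-verticality gate should be measurable more consistently. Computes
#' per-frame inter- and intra-rater errors and compares the qualified and
#' disqualified groups with the pooled Student t test.
#'
#' @param qualified logical vector, one element per frame.
#' @param measurements list of rater measurement matrices (one per frame),
#'   e.g. `truth$simulated_rater_alphas` from [generate_cohort()] with
#'   `raters = TRUE`.
#' @param welch use the Welch t variant.
#' @return list of class `rater_comparison` with elements `inter` and
#'   `intra`, each `list(mean_qualified, mean_disqualified, t, p, df)`.
#' @export
rater_error_comparison <- function(qualified, measurements, welch = FALSE) {
  if (length(measurements) == 0L || length(qualified) != length(measurements))
    stop("need one rater measurement matrix per frame")
  errs <- lapply(measurements, rater_errors)
  inter <- vapply(errs, `[[`, numeric(1), "inter")
  intra <- vapply(errs, `[[`, numeric(1), "intra")
  qualified <- as.logical(qualified)
  if (!any(qualified) || all(qualified))
    stop("need both qualified and disqualified frames")
  cmp <- function(v) {
    tt <- student_t_test(v[qualified], v[!qualified], welch = welch)
    list(mean_qualified = tt$mean_a, mean_disqualified = tt$mean_b,
         t = tt$t, p = tt$p, df = tt$df)
  }
  structure(list(inter = cmp(inter), intra = cmp(intra),
                 n_qualified = sum(qualified),
                 n_disqualified = sum(!qualified)),
            class = "rater_comparison")
}

#' @export
print.rater_comparison <- function(x, ...) {
  cat(sprintf("rater error comparison (%d qualified vs %d disqualified)\n",
              x$n_qualified, x$n_disqualified))
  for (nm in c("inter", "intra"))
    cat(sprintf("  %s-rater: %.3f vs %.3f deg, t = %.2f, p = %.3g\n",
                nm, x[[nm]]$mean_qualified, x[[nm]]$mean_disqualified,
                x[[nm]]$t, x[[nm]]$p))
  invisible(x)
}

#' Evaluate pipeline verdicts against ground truth
#'
#' Summarises a verdict table joined to its manifest: AUC of the DDH score
#' (`60 - alpha_deg`) on analyzable frames, sensitivity/specificity at the
#' cutoff, and verdict counts.
#'
#' @param verdicts data.frame from [run_pipeline_batch()].
#' @param truth data.frame with `ddh_label` per frame (manifest order).
#' @param cutoff_deg,rule DDH decision rule.
#' @return list `auc`, `sensitivity`, `specificity`, `status_counts`, `n_ok`.
#' @export
evaluate_cohort <- function(verdicts, truth, cutoff_deg = 60,
                            rule = c("strict", "inclusive")) {
  rule <- match.arg(rule)
  ok <- verdicts$status == "ok"
  status_counts <- table(verdicts$status)
  if (!any(ok)) stop("no analyzable frames")
  lab <- truth$ddh_label[ok]
  alpha <- verdicts$alpha_deg[ok]
  roc <- roc_auc(lab, 60 - alpha)
  ss <- sens_spec_at_cutoff(lab, alpha, cutoff_deg, rule)
  list(auc = roc$auc, curve = roc$curve,
       sensitivity = ss$sensitivity, specificity = ss$specificity,
       status_counts = status_counts, n_ok = sum(ok))
}
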