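# Two-stage hierarchical group inference with selective FDR control.
#
# Stage 1 screens parcels: each subject's parcel-average coefficient feeds a
# one-sample t-test across subjects, and Benjamini-Hochberg at alpha_parcel
# selects the parcel set S. Stage 2 runs vertex-level one-sample t-tests
# within each selected parcel, with BH at the selection-adjusted level
#   q_p = alpha_voxel * |S| / P,
# which guarantees E[ (1/|S|) sum_{p in S} FDR_p ] <= alpha_voxel
# (the average defined as 0 when S is empty).

#' Benjamini-Hochberg selection
#'
#' Standard step-up: reject the hypotheses with the `i*alpha/m` threshold at
#' the largest passing order statistic. Ties are handled by the sorted order,
#' so the output is deterministic.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param alpha Target FDR level.
#' @return List with `selected` (integer indices into `pvals`) and
#'   `threshold` (largest rejected p-value, 0 if none).
#' @export
bh_select <- function(pvals, alpha) {
  if (length(pvals) && (min(pvals) < 0 || max(pvals) > 1))
    stopf("p-values must lie in [0, 1]")
  padj <- stats::p.adjust(pvals, method = "BH")
  sel <- which(padj <= alpha)
  list(selected = sel,
       threshold = if (length(sel)) max(pvals[sel]) else 0)
}

# Vectorized one-sample t-test over the columns of an N x m matrix.
# Degenerate columns (zero SD) get p = 1 when the mean is also ~0 and p = 0
# otherwise (flagged upstream).
#' @keywords internal
#' @noRd
col_t_test <- function(B, alternative = "two.sided") {
  N <- nrow(B)
  if (N < 2L) stopf("need at least 2 subjects for a t-test")
  m <- colMeans(B)
  s <- sqrt(colSums((B - rep(m, each = N))^2) / (N - 1))
  tt <- m / (s / sqrt(N))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(abs(tt), df = N - 1, lower.tail = FALSE),
    greater   = stats::pt(tt, df = N - 1, lower.tail = FALSE),
    less      = stats::pt(tt, df = N - 1))
  deg <- s == 0
  if (any(deg)) {
    zero_mean <- deg & abs(m) < .Machine$double.eps^0.5
    p[deg] <- 0
    p[zero_mean] <- 1
    tt[zero_mean] <- 0
  }
  list(mean = m, sd = s, t = tt, p = p, degenerate = deg)
}

#' Parcel-level screening statistics
#'
#' One-sample t-statistic across subjects of the per-subject parcel-average
#' coefficient, with two-sided p-values on `N - 1` degrees of freedom.
#'
#' @param beta `N x V` matrix of per-subject activation coefficients (one
#'   task/basis pair).
#' @param parcels Length-`V` parcel labels.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Data frame with one row per parcel: `parcel`, `V`, `mean`, `sd`,
#'   `t`, `p`, `degenerate`.
#' @export
parcel_tstats <- function(beta, parcels, alternative = "two.sided") {
  beta <- as.matrix(beta)
  parcels <- as.factor(parcels)
  if (length(parcels) != ncol(beta))
    stopf("parcel labels (%d) do not match coefficient columns (%d)",
          length(parcels), ncol(beta))
  # subject x parcel matrix of parcel means
  pm <- t(rowsum(t(beta), parcels) / as.vector(table(parcels)))
  ts <- col_t_test(pm, alternative)
  data.frame(parcel = levels(parcels), V = as.integer(table(parcels)),
             mean = ts$mean, sd = ts$sd, t = ts$t, p = ts$p,
             degenerate = ts$degenerate, row.names = NULL)
}

#' Two-stage selective FDR inference
#'
#' Parcel screening by BH at `alpha_parcel` on the parcel t-statistics, then
#' vertex-level BH within each selected parcel at the adjusted level
#' `q_p = alpha_voxel * |S| / P`. When no parcel is selected the discovery
#' set is empty.
#'
#' @param beta `N x V` matrix of per-subject activation coefficients for one
#'   (task, basis) pair — e.g., one column of [coef.splash()] stacked across
#'   subjects.
#' @param parcels Length-`V` parcel labels.
#' @param alpha_parcel Parcel-level BH level (default 0.1).
#' @param alpha_voxel Vertex-level target FDR (default 0.5).
#' @param alternative Sidedness of the tests (two-sided by default).
#' @return Object of class `"splash_inference"`: `parcel_table` (screening
#'   stats with `selected` flag), `selected` (parcel labels in S), `q_p`
#'   (adjusted vertex-level level), `vertex_table` (vertex `t`, `p`,
#'   `discovered` for vertices in selected parcels), `discoveries` (vertex
#'   indices), `alphas`, `P`, `N`.
#' @export
splash_inference <- function(beta, parcels, alpha_parcel = 0.1,
                             alpha_voxel = 0.5, alternative = "two.sided") {
  beta <- as.matrix(beta)
  parcels <- as.factor(parcels)
  if (length(parcels) != ncol(beta))
    stopf("parcel labels (%d) do not match coefficient columns (%d)",
          length(parcels), ncol(beta))
  P <- nlevels(parcels)
  N <- nrow(beta)
  ptab <- parcel_tstats(beta, parcels, alternative)
  sel <- bh_select(ptab$p, alpha_parcel)
  ptab$selected <- seq_len(P) %in% sel$selected
  S_size <- length(sel$selected)
  q_p <- alpha_voxel * S_size / P
  vertex_table <- NULL
  discoveries <- integer(0)
  if (S_size > 0L) {
    rows <- vector("list", S_size)
    for (j in seq_along(sel$selected)) {
      lab <- levels(parcels)[sel$selected[j]]
      idx <- which(parcels == lab)
      ts <- col_t_test(beta[, idx, drop = FALSE], alternative)
      disc <- bh_select(ts$p, q_p)$selected
      rows[[j]] <- data.frame(vertex = idx, parcel = lab, t = ts$t, p = ts$p,
                              q_threshold = q_p,
                              discovered = seq_along(idx) %in% disc,
                              row.names = NULL)
    }
    vertex_table <- do.call(rbind, rows)
    discoveries <- vertex_table$vertex[vertex_table$discovered]
  }
  structure(list(parcel_table = ptab, selected = levels(parcels)[sel$selected],
                 q_p = q_p, vertex_table = vertex_table,
                 discoveries = discoveries,
                 alphas = c(parcel = alpha_parcel, voxel = alpha_voxel),
                 P = P, N = N, alternative = alternative),
            class = "splash_inference")
}

#' @export
print.splash_inference <- function(x, ...) {
  cat(sprintf("two-stage selective FDR inference: N = %d subjects, P = %d parcels\n",
              x$N, x$P))
  cat(sprintf("  stage 1 (BH at %.2g): %d parcel(s) selected\n",
              x$alphas["parcel"], length(x$selected)))
  cat(sprintf("  stage 2 (BH at q_p = %.3g = %.2g * %d/%d): %d vertex discoveries\n",
              x$q_p, x$alphas["voxel"], length(x$selected), x$P,
              length(x$discoveries)))
  invisible(x)
}

#' @export
summary.splash_inference <- function(object, ...) {
  print(object)
  if (!is.null(object$vertex_table)) {
    disc_by_parcel <- tapply(object$vertex_table$discovered,
                             object$vertex_table$parcel, sum)
    cat("  discoveries per selected parcel:\n")
    print(disc_by_parcel)
  }
  invisible(object)
}

#' @export
as.data.frame.splash_inference <- function(x, ...) {
  x$vertex_table %||%
    data.frame(vertex = integer(0), parcel = character(0), t = numeric(0),
               p = numeric(0), q_threshold = numeric(0),
               discovered = logical(0))
}

#' Flat vertex-wise BH detection (comparator pipeline)
#'
#' The conventional group analysis used with the GLM and GKS comparators:
#' one-sample t-tests at every vertex and a single BH pass at `alpha` over
#' all vertices.
#'
#' @inheritParams splash_inference
#' @param alpha BH level (default 0.5, matching the two-stage vertex level).
#' @return Data frame with `vertex`, `t`, `p`, `discovered`.
#' @export
flat_bh_inference <- function(beta, alpha = 0.5, alternative = "two.sided") {
  beta <- as.matrix(beta)
  ts <- col_t_test(beta, alternative)
  disc <- bh_select(ts$p, alpha)$selected
  data.frame(vertex = seq_len(ncol(beta)), t = ts$t, p = ts$p,
             discovered = seq_len(ncol(beta)) %in% disc)
}
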