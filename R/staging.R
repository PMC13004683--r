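#' Published PET positivity thresholds for staging
#'
#' Early-tau (mesial-temporal meta-ROI) and late-tau (temporo-parietal
#' meta-ROI) PET positivity thresholds in SUVR units used upstream to derive
#' the tau flags consumed by [classify_stage()].
#'
#' @return Named numeric vector.
#' @export
suvr_thresholds <- function() {
  c(tau_early = 1.328, tau_late = 1.224)
}

#' Classify 2024 biological AD stage from biomarker flags
#'
#' Stage A (normal biomarkers, A-/Tearly-/Tlate-), stage B (AD pathologic
#' change, A+/Tearly-/Tlate-), stage C (AD, A+/Tearly+/Tlate-), stage D
#' (advanced AD, A+/Tearly+/Tlate+). The four flag combinations outside the
#' canonical A -> D sequence are reported as `"non-canonical"`, not forced
#' into a stage.
#'
#' @param amyloid_positive,tau_early_positive,tau_late_positive Logical
#'   vectors (recycled to a common length).
#' @return A factor with levels A, B, C, D, non-canonical.
#' @export
#' @examples
#' classify_stage(c(FALSE, TRUE, TRUE, TRUE, FALSE),
#'                c(FALSE, FALSE, TRUE, TRUE, TRUE),
#'                c(FALSE, FALSE, FALSE, TRUE, FALSE))
classify_stage <- function(amyloid_positive, tau_early_positive,
                           tau_late_positive) {
  n <- max(length(amyloid_positive), length(tau_early_positive),
           length(tau_late_positive))
  a <- rep_len(as.logical(amyloid_positive), n)
  te <- rep_len(as.logical(tau_early_positive), n)
  tl <- rep_len(as.logical(tau_late_positive), n)
  stage <- dplyr::case_when(
    !a & !te & !tl ~ "A",
    a & !te & !tl ~ "B",
    a & te & !tl ~ "C",
    a & te & tl ~ "D",
    TRUE ~ "non-canonical"
  )
  factor(stage, levels = c("A", "B", "C", "D", "non-canonical"))
}

#' Conover-Iman pairwise comparisons after Kruskal-Wallis
#'
#' All-pairs rank comparisons: data are ranked globally (mid-ranks for
#' ties), the Kruskal-Wallis statistic H is computed, and each pair (i, j)
#' is tested with
#' \deqn{t = \frac{\bar R_i - \bar R_j}
#'  {\sqrt{S^2 \frac{N - 1 - H}{N - k}\left(\frac1{n_i}+\frac1{n_j}\right)}}}
#' on N - k degrees of freedom, where \eqn{S^2} is the variance of all
#' ranks -- the Kruskal-Wallis-conditional variant in which the pooled rank
#' variance is deflated by the realized H. Two-sided p-values are adjusted
#' across all pairs by Benjamini-Hochberg step-up via [bh_adjust()].
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor/vector, >= 2 groups with >= 2 observations
#'   each.
#' @return A tibble `group1`, `group2`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, with the Kruskal-Wallis `H` and its p-value as
#'   attributes.
#' @export
conover_iman <- function(values, groups) {
  groups <- factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2) abort("Need >= 2 groups.")
  if (any(table(groups) < 2)) abort("Every group needs >= 2 observations.")
  if (var(values) == 0) abort("All observations identical; ranks are degenerate.")
  N <- length(values)
  r <- rank(values)
  s2 <- var(r)  # pooled rank variance, ties handled by mid-ranks
  rbar <- tapply(r, groups, mean)
  ni <- as.numeric(table(groups))
  H <- as.numeric(stats::kruskal.test(values, groups)$statistic)
  pairs <- utils::combn(levels(groups), 2)
  denom_scale <- s2 * (N - 1 - H) / (N - k)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(m) {
    g1 <- pairs[1, m]; g2 <- pairs[2, m]
    i <- match(g1, levels(groups)); j <- match(g2, levels(groups))
    tstat <- (rbar[[i]] - rbar[[j]]) /
      sqrt(denom_scale * (1 / ni[i] + 1 / ni[j]))
    tibble::tibble(group1 = g1, group2 = g2, statistic = tstat,
                   df = N - k, p_value = 2 * pt(-abs(tstat), df = N - k))
  })
  out$p_adjusted <- bh_adjust(out$p_value)
  attr(out, "kruskal_H") <- H
  attr(out, "kruskal_p") <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; adjusted
#' p-values are never below the raw values and are capped at 1.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}
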