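#' Levene's test for equality of error variances
#'
#' Group-mean-centred Levene test (absolute deviations from the group mean,
#' compared by one-way ANOVA), as used to gate the choice between Tukey HSD
#' and Dunnett T3 post hoc comparisons.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length.
#' @return A list with `statistic` (F), `p_value`, `df`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  lt <- car::leveneTest(values, groups, center = mean)
  list(statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]))
}

#' Map a p-value to a significance-strength band
#'
#' Cut points 0.001, 0.01 and 0.05; a boundary value falls in the more
#' significant band (the comparisons are reported at p <= 0.05, 0.01,
#' 0.001).
#'
#' @param p Numeric vector of p-values.
#' @return Factor with levels `lt_0.001`, `0.001_0.01`, `0.01_0.05`, `ns`.
#' @export
strength_band <- function(p) {
  bands <- ifelse(p <= 0.001, "lt_0.001",
           ifelse(p <= 0.01, "0.001_0.01",
           ifelse(p <= 0.05, "0.01_0.05", "ns")))
  factor(bands, levels = c("lt_0.001", "0.001_0.01", "0.01_0.05", "ns"))
}

#' Levene-gated pairwise post hoc comparisons
#'
#' Runs Levene's test; when the group variances are compatible
#' (`levene p >= alpha_levene`) all pairwise comparisons use Tukey's HSD on
#' the one-way ANOVA, otherwise Dunnett's T3 (an unequal-variance procedure
#' based on Welch degrees of freedom and the studentized maximum modulus).
#' Each pair is labelled with a strength band at the 0.001 / 0.01 / 0.05
#' cut points.
#'
#' The studentized-maximum-modulus tail probability is approximated by the
#' independence (Sidak-type) bound `1 - (2 F_t(|t|) - 1)^m` over the `m`
#' comparisons; the approximation is slightly conservative and keeps the
#' per-pair null rejection rate at the nominal level (checked by simulation
#' in the test suite).
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param alpha_levene Gate threshold on the Levene p-value (default 0.05).
#' @return A tibble with one row per group pair: `pair`, `group1`, `group2`,
#'   `p_value`, `strength_band`, `test` (`tukey` or `dunnett_t3`),
#'   `levene_p`.
#' @export
posthoc_pairs <- function(values, groups, alpha_levene = 0.05) {
  groups <- factor(groups)
  lev <- levene_test(values, groups)
  if (lev$p_value >= alpha_levene) {
    fit <- stats::aov(values ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    pairs <- rownames(tk)
    parts <- strsplit(pairs, "-", fixed = TRUE)
    res <- tibble::tibble(
      group1 = vapply(parts, `[`, "", 2),
      group2 = vapply(parts, `[`, "", 1),
      p_value = tk[, "p adj"],
      test = "tukey")
  } else {
    res <- dunnett_t3(values, groups)
    res$test <- "dunnett_t3"
  }
  res$pair <- paste(res$group1, res$group2, sep = "-")
  res$strength_band <- strength_band(res$p_value)
  res$levene_p <- lev$p_value
  res[c("pair", "group1", "group2", "p_value", "strength_band", "test",
        "levene_p")]
}

dunnett_t3 <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  vi <- tapply(values, groups, stats::var)
  cmb <- utils::combn(lv, 2)
  m <- ncol(cmb)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    g1 <- cmb[1, j]; g2 <- cmb[2, j]
    se2 <- vi[g1] / ni[g1] + vi[g2] / ni[g2]
    tstat <- (mi[g1] - mi[g2]) / sqrt(se2)
    df <- se2^2 / ((vi[g1] / ni[g1])^2 / (ni[g1] - 1) +
                   (vi[g2] / ni[g2])^2 / (ni[g2] - 1))
    p_one <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    p_adj <- 1 - (1 - p_one)^m  # SMM independence approximation
    out[[j]] <- tibble::tibble(group1 = g1, group2 = g2,
                               p_value = min(1, p_adj))
  }
  dplyr::bind_rows(out)
}

#' Per-WAMAC significance table for group aquagram differences
#'
#' For every WAMAC, runs the Levene-gated post hoc procedure over the
#' per-spectrum aquagram values of the treatment groups, producing a
#' 19-wavelength by n-pairs table of p-values and strength bands (the
#' machine-readable analogue of a coloured significance-letter table).
#'
#' @param r An `aquagram_result` (its `meta` must contain `group_field`).
#' @param group_field Metadata field holding the groups to compare
#'   (default `"treatment"`).
#' @param levels Optional subset/order of group levels to include.
#' @param alpha_levene Gate threshold for Levene's test.
#' @return A tibble with columns `wamac_code`, `wavelength_nm`, `pair`,
#'   `p_value`, `strength_band`, `test`, `levene_p`.
#' @export
wamac_significance <- function(r, group_field = "treatment", levels = NULL,
                               alpha_levene = 0.05) {
  if (!inherits(r, "aquagram_result")) stop("expected an aquagram_result")
  if (!group_field %in% names(r$meta))
    stop("metadata field not found: ", group_field)
  g <- r$meta[[group_field]]
  keep <- if (is.null(levels)) rep(TRUE, length(g)) else g %in% levels
  g <- factor(g[keep], levels = if (is.null(levels)) sort(unique(g)) else levels)
  if (nlevels(g) < 2) stop("need at least 2 groups to compare")
  rows <- lapply(seq_len(nrow(r$wamacs)), function(i) {
    tab <- posthoc_pairs(r$per_spectrum_aq[keep, i], g, alpha_levene)
    tab$wamac_code <- r$wamacs$code[i]
    tab$wavelength_nm <- r$wamacs$wavelength[i]
    tab
  })
  out <- dplyr::bind_rows(rows)
  out[c("wamac_code", "wavelength_nm", "pair", "p_value", "strength_band",
        "test", "levene_p")]
}

#' Relative water content (RWC)
#'
#' `RWC% = 100 (FW - DW) / (FTW - DW)` where FW is the fresh weight, FTW
#' the fresh turgor weight after soaking, and DW the oven-dry weight of the
#' leaf.
#'
#' @param fw Fresh weight (g).
#' @param dw Dry weight (g).
#' @param ftw Fresh turgor weight (g), must exceed `dw`.
#' @return RWC in percent. A fresh weight below the dry weight triggers a
#'   warning and is clamped to 0%.
#' @export
rwc <- function(fw, dw, ftw) {
  if (any(ftw <= dw)) stop("turgor weight must exceed dry weight")
  out <- 100 * (fw - dw) / (ftw - dw)
  if (any(out < 0)) {
    warning("fresh weight below dry weight; RWC clamped to 0%")
    out <- pmax(out, 0)
  }
  out
}
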