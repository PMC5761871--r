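#' Rank-transform a vector
#'
#' Ranks 1..n with ties given their average rank — the transformation
#' used to restore normality before the factorial analyses.
#'
#' @param values numeric vector, length >= 2.
#' @return Numeric vector of (tie-averaged) ranks.
#' @export
rank_transform <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to rank")
  if (any(!is.finite(values))) stop("values must be finite")
  rank(values, ties.method = "average")
}

spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[p], nrow(p), n - 1L))
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of tie-averaged ranks, computed from
#' the raw (untransformed) paired values. The two-sided p-value uses the
#' exact permutation distribution for n <= 9 and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df otherwise.
#'
#' @param x,y paired numeric vectors (or a `data.frame` with columns
#'   `ct_value` and `histo_value` passed as `x`).
#' @return List with `rho`, `p_value`, `n`, `method`. Constant input on
#'   either side yields `rho = NA` with `method = "undefined"`.
#' @export
spearman_cor <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    y <- x$histo_value
    x <- x$ct_value
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rho <- spearman_rho(x, y)
  if (is.na(rho))
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  if (n <= 9L) {
    ry <- rank(y, ties.method = "average")
    rx <- rank(x, ties.method = "average")
    perms <- all_perms(n)
    ryp <- matrix(ry[perms], nrow(perms), n)
    cx <- rx - mean(rx)
    # sum(cx) = 0, so ryp %*% cx equals (n - 1) * cov(rx, ryp) rowwise
    rho_perm <- as.numeric(ryp %*% cx) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

check_cohort_table <- function(table) {
  need <- c("animal_id", "genotype", "age_months", "value")
  if (!all(need %in% names(table)))
    stop("cohort table needs columns ", paste(need, collapse = ", "))
  table$genotype <- factor(table$genotype)
  table$age_months <- factor(table$age_months)
  table
}

#' Two-way ANOVA on rank-transformed values with Tukey contrasts
#'
#' Fits `rank(value) ~ genotype * age` and reports the overall genotype
#' and age effects (Type II sums of squares by default, appropriate for
#' mildly unbalanced cohorts; Type III available) plus Tukey HSD
#' pairwise comparisons for both factors and their cells.
#'
#' @param table data frame with columns `animal_id`, `genotype`,
#'   `age_months`, `value` (one outcome).
#' @param ss_type 2 (default) or 3.
#' @return List of class `ranked_anova` with `anova_table` (data frame:
#'   term, F, p), `tukey` (the [TukeyHSD()] object), `fit` (the ranked
#'   `lm`), `ss_type`.
#' @export
two_way_anova_ranked <- function(table, ss_type = 2) {
  table <- check_cohort_table(table)
  cells <- table(table$genotype, table$age_months)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell: genotype ", rownames(cells)[bad[1, 1]],
         " at age ", colnames(cells)[bad[1, 2]], " months")
  }
  df <- data.frame(
    r = rank_transform(table$value),
    genotype = table$genotype,
    age = table$age_months
  )
  fit <- lm(r ~ genotype * age, data = df)
  term_names <- c("genotype", "age", "genotype:age")
  if (stats::var(df$r) < .Machine$double.eps) {
    # all values tied: every effect explains nothing
    anova_table <- data.frame(term = term_names, F = 0, p = 1,
                              stringsAsFactors = FALSE)
  } else {
    at <- car::Anova(fit, type = ss_type)
    terms <- rownames(at)
    keep <- !(terms %in% c("Residuals", "(Intercept)"))
    anova_table <- data.frame(
      term = terms[keep],
      F = at[keep, "F value"],
      p = at[keep, "Pr(>F)"],
      stringsAsFactors = FALSE
    )
  }
  aovfit <- aov(r ~ genotype * age, data = df)
  tukey <- TukeyHSD(aovfit)
  structure(list(anova_table = anova_table, tukey = tukey, fit = fit,
                 ss_type = ss_type),
            class = "ranked_anova")
}

#' @export
print.ranked_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA on ranks (Type %s SS)\n", x$ss_type))
  print(x$anova_table, row.names = FALSE)
  cat("Tukey HSD comparisons available in $tukey\n")
  invisible(x)
}

#' Bonferroni-corrected genotype comparisons within each timepoint
#'
#' Two-sample t-tests on rank-transformed values (ranked within each
#' timepoint) comparing genotypes at each age; significance is declared
#' at `alpha / k` — 0.05 / 4 = 0.0125 for the default four-timepoint
#' design. Pooled-variance t by default (`welch = TRUE` for Welch).
#'
#' @param table cohort data frame (see [two_way_anova_ranked()]).
#' @param alpha family-wise level.
#' @param k number of comparisons corrected for (defaults to the number
#'   of timepoints present).
#' @param welch use Welch's t instead of pooled.
#' @return Data frame with one row per timepoint: `age_months`, group
#'   ns, `t`, `p`, `significant`, `computable`; corrected threshold in
#'   attribute `"threshold"`.
#' @export
bonferroni_timepoint_tests <- function(table, alpha = 0.05, k = NULL,
                                       welch = FALSE) {
  table <- check_cohort_table(table)
  ages <- sort(unique(as.numeric(as.character(table$age_months))))
  if (is.null(k)) k <- length(ages)
  threshold <- alpha / k
  gl <- levels(table$genotype)
  if (length(gl) != 2L) stop("exactly two genotypes required")
  rows <- lapply(ages, function(a) {
    sub <- table[as.numeric(as.character(table$age_months)) == a, ]
    g1 <- sub$value[sub$genotype == gl[1]]
    g2 <- sub$value[sub$genotype == gl[2]]
    if (length(g1) < 2L || length(g2) < 2L) {
      return(data.frame(age_months = a, n1 = length(g1), n2 = length(g2),
                        t = NA_real_, p = NA_real_, significant = NA,
                        computable = FALSE))
    }
    r <- rank_transform(sub$value)
    tt <- t.test(r[sub$genotype == gl[1]], r[sub$genotype == gl[2]],
                 var.equal = !welch)
    data.frame(age_months = a, n1 = length(g1), n2 = length(g2),
               t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < threshold, computable = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "groups") <- gl
  out
}

#' Shapiro-Wilk normality gate
#'
#' Tests normality and reports whether the downstream analyses should
#' rank-transform (p < 0.05).
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return List with `W`, `p_value`, `normal`,
#'   `rank_transform_recommended`.
#' @export
shapiro_wilk_gate <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value,
       normal = sw$p.value >= 0.05,
       rank_transform_recommended = sw$p.value < 0.05)
}

#' Correlate CT outcomes with histology outcomes
#'
#' Joins per-animal CT (left lung) and histology outcome tables on
#' `animal_id` and computes Spearman correlations for the standard
#' outcome pairs: total volume vs total area, tissue volume vs tissue
#' (Blue+Pink) area, aerated volume vs White area, and the normalized
#' aerated-vs-White and tissue-vs-tissue pairs.
#'
#' @param ct data frame with columns `animal_id`, `total_mm3`,
#'   `aerated_mm3`, `tissue_mm3`, `aerated_fraction`, `tissue_fraction`.
#' @param histo data frame with columns `animal_id`, `total_um2`,
#'   `tissue_um2`, `white_um2`, `white_fraction`, `tissue_fraction`.
#' @return Data frame with one row per outcome pair: `pair`, `rho`,
#'   `p_value`, `n`.
#' @export
correlate_ct_histology <- function(ct, histo) {
  m <- merge(ct, histo, by = "animal_id", suffixes = c("_ct", "_histo"))
  if (nrow(m) < 3L) stop("fewer than 3 paired animals after the join")
  pairs <- list(
    total_volume_vs_total_area = c("total_mm3", "total_um2"),
    tissue_volume_vs_tissue_area = c("tissue_mm3", "tissue_um2"),
    aerated_volume_vs_white_area = c("aerated_mm3", "white_um2"),
    norm_aerated_vs_norm_white = c("aerated_fraction", "white_fraction"),
    norm_tissue_vs_norm_tissue_area = c("tissue_fraction_ct",
                                        "tissue_fraction_histo")
  )
  rows <- lapply(names(pairs), function(nm) {
    cols <- pairs[[nm]]
    if (!all(cols %in% names(m))) return(NULL)
    s <- spearman_cor(m[[cols[1]]], m[[cols[2]]])
    data.frame(pair = nm, rho = s$rho, p_value = s$p_value, n = s$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
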