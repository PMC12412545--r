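# Group statistics: one/two-way ANOVA, Bonferroni-corrected pairwise t
# tests gated on the omnibus result, and Pearson correlation.

.checkGroupTable <- function(table, factors) {
  stopifnot(is.data.frame(table), "value" %in% names(table),
            all(factors %in% names(table)))
  for (f in factors) {
    if (length(unique(table[[f]])) < 2)
      stop("factor '", f, "' needs at least 2 levels")
  }
  if (length(factors) == 2) {
    cells <- base::table(table[[factors[1]]], table[[factors[2]]])
    if (any(cells < 2)) {
      bad <- which(cells < 2, arr.ind = TRUE)[1, ]
      stop(sprintf("cell (%s = %s, %s = %s) has fewer than 2 observations",
                   factors[1], rownames(cells)[bad[1]],
                   factors[2], colnames(cells)[bad[2]]))
    }
    n <- as.vector(cells)
    if (max(n) != min(n))
      warning("unbalanced two-way design: sequential sums of squares used")
  }
  invisible(TRUE)
}

#' One- or two-way ANOVA on a group table
#'
#' Classical fixed-effects analysis of variance of \code{value} on one or two
#' factors (with interaction for two), computed with \code{stats::aov}.
#' Degenerate input in which all observations are identical returns F = 0
#' and p = 1 for every effect.
#'
#' @param table data.frame with a numeric \code{value} column and factor
#'   columns (e.g. \code{strain}, \code{wash}).
#' @param factors character vector of one or two factor column names.
#' @return data.frame with one row per effect: \code{effect}, \code{df},
#'   \code{sum_sq}, \code{mean_sq}, \code{F}, \code{p}, plus a residual row.
#' @examples
#' tb <- data.frame(value = c(1, 2, 3, 4, 5, 6),
#'                  strain = rep(c("Native", "Evolved"), each = 3))
#' anovaGroups(tb, "strain")
#' @export
anovaGroups <- function(table, factors = "strain") {
  .checkGroupTable(table, factors)
  for (f in factors) table[[f]] <- factor(table[[f]])
  form <- if (length(factors) == 1)
    stats::as.formula(paste("value ~", factors)) else
      stats::as.formula(paste("value ~", factors[1], "*", factors[2]))
  fit <- aov(form, data = table)
  sm <- summary(fit)[[1]]
  out <- data.frame(effect = trimws(rownames(sm)), df = sm$Df,
                    sum_sq = sm$`Sum Sq`, mean_sq = sm$`Mean Sq`,
                    F = sm$`F value`, p = sm$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  # all-identical observations: define F = 0, p = 1 rather than 0/0
  eff <- out$effect != "Residuals"
  zero <- eff & out$sum_sq < 1e-12 * max(1, sum(out$sum_sq))
  out$F[zero] <- 0
  out$p[zero] <- 1
  rownames(out) <- NULL
  out
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Bonferroni-corrected pairwise comparisons after a significant ANOVA
#'
#' Performed only when the omnibus ANOVA for the factor is significant
#' (p < alpha); otherwise the comparisons are reported as not performed. All
#' level pairs are tested with pooled-variance t statistics using the ANOVA
#' residual mean square, and p values are multiplied by the number of pairs
#' (capped at 1). Groups with fewer than 2 observations are excluded with a
#' warning. Stars follow the usual 0.05 / 0.01 / 0.001 convention.
#'
#' @param table data.frame with \code{value} and the factor column.
#' @param factor_name name of the factor column (default \code{"strain"}).
#' @param alpha omnibus gate (default 0.05).
#' @return A list with \code{performed}, \code{omnibus_p} and, when
#'   performed, \code{comparisons} (data.frame with raw and adjusted p and
#'   stars).
#' @export
bonferroniPairwise <- function(table, factor_name = "strain", alpha = 0.05) {
  small <- names(which(base::table(table[[factor_name]]) < 2))
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    table <- table[!table[[factor_name]] %in% small, , drop = FALSE]
  }
  aovres <- anovaGroups(table, factor_name)
  omni_p <- aovres$p[aovres$effect == factor_name]
  if (omni_p >= alpha)
    return(list(performed = FALSE, omnibus_p = omni_p,
                reason = "omnibus ANOVA not significant"))
  mse <- aovres$mean_sq[aovres$effect == "Residuals"]
  dfr <- aovres$df[aovres$effect == "Residuals"]
  g <- split(table$value, factor(table[[factor_name]]))
  lv <- names(g)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    diff = NA_real_, t = NA_real_, p = NA_real_,
                    p_adj = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- g[[pairs[1, i]]]; b <- g[[pairs[2, i]]]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tval <- (mean(a) - mean(b)) / se
    res$diff[i] <- mean(a) - mean(b)
    res$t[i] <- tval
    res$p[i] <- 2 * pt(-abs(tval), dfr)
  }
  res$p_adj <- pmin(1, res$p * m)
  res$stars <- .stars(res$p_adj)
  list(performed = TRUE, omnibus_p = omni_p, n_pairs = m, comparisons = res)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 3) with non-zero variance.
#' @return Correlation coefficient in [-1, 1].
#' @examples
#' pearsonR(1:10, (1:10) * 2 + 1)
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("correlation undefined: zero variance")
  cor(x, y, method = "pearson")
}
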