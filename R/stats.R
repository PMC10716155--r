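#' Two-sided Kolmogorov-Smirnov test
#'
#' Sup-distance between the empirical CDFs of two samples with the
#' two-sided p-value; the exact null distribution is used when
#' n1 * n2 <= 10^4, the asymptotic one otherwise.  Thin wrapper over
#' \code{stats::ks.test} so every group comparison in the package goes
#' through one audited entry point.
#'
#' @param sample1,sample2 numeric vectors (non-empty).
#' @return list with \code{statistic} and \code{p_value}.
#' @export
ks_two_sided <- function(sample1, sample2) {
  if (!length(sample1) || !length(sample2)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(
    sample1, sample2, alternative = "two.sided",
    exact = length(sample1) * length(sample2) <= 1e4))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size m (the number of p-values
#' supplied) and caps at 1.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values, same length.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pmin(1, p_values * length(p_values))
}

#' Linear mixed-effects model with a per-retina random intercept
#'
#' Fits \code{metric ~ condition (+ sex and cell-type interactions) +
#' (1 | retina_id)} by REML via \code{lme4::lmer}, accounting for
#' retina-to-retina (experiment-to-experiment) variability when comparing
#' treatment conditions.  Fixed-effect tests use the normal approximation
#' (Wald z), appropriate for the large per-retina cell counts this design
#' targets.
#'
#' @param table data.frame with the response column, \code{condition},
#'   \code{retina_id}, and optionally \code{sex} / \code{cell_type}.
#' @param response name of the response column.
#' @param interactions character subset of c("sex", "cell_type") to include
#'   as interaction terms with condition (used when the columns vary).
#' @return A \code{mixed_fit}: list with \code{model} (the lmerMod),
#'   \code{fixed} (data.frame: term, estimate, se, z, p_value),
#'   \code{varcomp} (retina-intercept SD and residual SD), and
#'   \code{formula}.
#' @export
fit_mixed_effects <- function(table, response,
                              interactions = c("sex", "cell_type")) {
  if (!response %in% names(table)) stop("unknown response column: ", response)
  needed <- c("condition", "retina_id")
  if (!all(needed %in% names(table)))
    stop("table needs columns: ", paste(needed, collapse = ", "))
  tab <- table[!is.na(table[[response]]), , drop = FALSE]
  per_cond <- tapply(tab$retina_id, tab$condition,
                     function(r) length(unique(r)))
  if (any(per_cond < 2))
    warning("fewer than 2 retinas in some condition; ",
            "random effect weakly identified")
  terms <- "condition"
  for (v in intersect(interactions, names(tab)))
    if (length(unique(tab[[v]])) > 1) terms <- c(terms, paste0("condition:", v))
  rhs <- paste(c(terms, "(1 | retina_id)"), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  # detect rank deficiency up front and name the collinear terms
  mm <- stats::model.matrix(stats::as.formula(paste(response, "~",
                                                    paste(terms, collapse = "+"))),
                            data = tab)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("singular fixed-effects design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  model <- lme4::lmer(fml, data = tab, REML = TRUE)
  cf <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- cf / se
  fixed <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se), z = unname(z),
                      p_value = 2 * stats::pnorm(-abs(unname(z))),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(model))
  varcomp <- list(
    retina_sd = vc$sdcor[vc$grp == "retina_id"][1],
    residual_sd = vc$sdcor[vc$grp == "Residual"][1])
  structure(list(model = model, fixed = fixed, varcomp = varcomp,
                 formula = fml),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Linear mixed-effects fit:", deparse(x$formula), "\n")
  cat(sprintf("  retina-intercept SD %.3f, residual SD %.3f\n",
              x$varcomp$retina_sd, x$varcomp$residual_sd))
  print(x$fixed, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Condition-level summary with pairwise KS comparisons
#'
#' For one per-cell metric, reports each condition's mean +/- SEM and runs
#' two-sided KS tests for the requested pairwise comparisons, Bonferroni
#' corrected over that family (the family is exactly the set of comparisons
#' made in this call).
#'
#' @param per_cell data.frame with \code{condition} and the metric column.
#' @param metric metric column name.
#' @param comparisons list of c(group1, group2) pairs; default all pairs.
#' @return list with \code{groups} (condition, n, mean, sem) and
#'   \code{comparisons} (group1, group2, mean1, sem1, mean2, sem2,
#'   ks_statistic, p_raw, p_bonferroni, n1, n2).
#' @export
summarize_conditions <- function(per_cell, metric, comparisons = NULL) {
  if (!metric %in% names(per_cell)) stop("unknown metric column: ", metric)
  d <- per_cell[!is.na(per_cell[[metric]]), , drop = FALSE]
  conds <- unique(d$condition)
  groups <- do.call(rbind, lapply(conds, function(g) {
    v <- d[[metric]][d$condition == g]
    data.frame(condition = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(comparisons) && length(conds) > 1) {
    cmb <- utils::combn(conds, 2)
    comparisons <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  comp_tab <- NULL
  if (length(comparisons)) {
    rows <- lapply(comparisons, function(pair) {
      v1 <- d[[metric]][d$condition == pair[1]]
      v2 <- d[[metric]][d$condition == pair[2]]
      kt <- ks_two_sided(v1, v2)
      data.frame(metric = metric, group1 = pair[1], group2 = pair[2],
                 mean1 = mean(v1), sem1 = stats::sd(v1) / sqrt(length(v1)),
                 mean2 = mean(v2), sem2 = stats::sd(v2) / sqrt(length(v2)),
                 ks_statistic = kt$statistic, p_raw = kt$p_value,
                 n1 = length(v1), n2 = length(v2),
                 stringsAsFactors = FALSE)
    })
    comp_tab <- do.call(rbind, rows)
    comp_tab$p_bonferroni <- bonferroni(comp_tab$p_raw)
  }
  list(groups = groups, comparisons = comp_tab)
}
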