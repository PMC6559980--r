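#' Paired pre/post test within one treatment group
#'
#' Tests whether a parameter changed from the pre to the post exam within
#' one group, using a paired two-sided Student's t-test on the per-animal
#' differences (post - pre). When every difference is zero the change is
#' reported as absent (p = 1, statistic NA) rather than as an undefined
#' t statistic; zero-variance non-zero differences give p = 0.
#'
#' @param table a cohort table (see [validateCohortTable()]).
#' @param parameter one of `lvParameterNames()`.
#' @param group group label.
#' @param alpha significance level (default 0.05).
#' @param paired use the paired test on per-animal differences (default
#'   TRUE, the same animals are imaged twice); FALSE gives a Welch
#'   two-sample comparison of the pre and post sets.
#' @return one-row data.frame: parameter, kind, groups, statistic, p_value,
#'   adjusted_p, significant.
#' @export
pairedPrePostTest <- function(table, parameter, group, alpha = 0.05,
                              paired = TRUE) {
  checkCohortColumns(table)
  stopifnot(parameter %in% names(table))
  sub <- table[table$group == group, ]
  if (nrow(sub) == 0L) stop("unknown group: ", group)
  pre <- sub[sub$timepoint == "pre", ]
  post <- sub[sub$timepoint == "post", ]
  post <- post[match(pre$animal_id, post$animal_id), ]
  missing <- pre$animal_id[is.na(post$animal_id)]
  if (length(missing))
    stop("animals missing a timepoint: ", paste(missing, collapse = ", "))
  if (nrow(pre) < 2L) stop("need at least 2 animals with both timepoints")
  d <- post[[parameter]] - pre[[parameter]]
  if (!paired) {
    ht <- stats::t.test(post[[parameter]], pre[[parameter]])
    p <- ht$p.value
    stat <- unname(ht$statistic)
  } else if (stats::sd(d) == 0) {
    p <- if (all(d == 0)) 1 else 0
    stat <- NA_real_
  } else {
    ht <- stats::t.test(d)
    p <- ht$p.value
    stat <- unname(ht$statistic)
  }
  data.frame(parameter = parameter, kind = "pre_vs_post",
             groups = paste(group, "pre|post"), statistic = stat,
             p_value = p, adjusted_p = p, significant = p < alpha)
}

#' One-way ANOVA across groups with Bonferroni pairwise follow-up
#'
#' Compares a parameter between the treatment groups at one timepoint with a
#' one-way ANOVA, followed by all pairwise Student's t-tests using the
#' pooled within-group SD, Bonferroni-corrected (raw p multiplied by the
#' number of pairs, capped at 1). Significance of the pairwise rows uses the
#' adjusted p.
#'
#' @param table a cohort table.
#' @param parameter parameter name.
#' @param timepoint `"pre"` or `"post"`.
#' @param alpha significance level.
#' @param poolSd use the pooled-SD classic procedure (default TRUE); FALSE
#'   gives Welch pairwise tests.
#' @param values,groups alternatively, raw vectors (used by
#'   [deltaAnalysis()]); `table`/`parameter`/`timepoint` are then ignored.
#' @return data.frame: an `anova` row (F statistic, p) then one row per
#'   group pair with raw and Bonferroni-adjusted p.
#' @export
groupwiseAnova <- function(table = NULL, parameter = NULL,
                           timepoint = "post", alpha = 0.05, poolSd = TRUE,
                           values = NULL, groups = NULL) {
  if (is.null(values)) {
    checkCohortColumns(table)
    stopifnot(parameter %in% names(table))
    sub <- table[table$timepoint == timepoint, ]
    values <- sub[[parameter]]
    groups <- sub$group
  } else parameter <- parameter %||% "value"
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(tabulate(groups) < 2L)) stop("every group needs >= 2 values")
  lv <- levels(groups)
  nPairs <- nlevels(groups) * (nlevels(groups) - 1L) / 2L
  if (stats::sd(values) == 0) {
    # no variation anywhere: nothing to compare, report "no difference"
    out <- data.frame(parameter = parameter, kind = "anova",
                      groups = paste(lv, collapse = "|"),
                      statistic = NA_real_, p_value = 1, adjusted_p = 1,
                      significant = FALSE)
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (j >= i) next
      out <- rbind(out, data.frame(
        parameter = parameter, kind = "between_groups",
        groups = paste(lv[j], lv[i], sep = "|"), statistic = NA_real_,
        p_value = 1, adjusted_p = 1, significant = FALSE))
    }
    rownames(out) <- NULL
    return(out)
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  out <- data.frame(parameter = parameter, kind = "anova",
                    groups = paste(levels(groups), collapse = "|"),
                    statistic = an[["F value"]][1],
                    p_value = an[["Pr(>F)"]][1],
                    adjusted_p = an[["Pr(>F)"]][1],
                    significant = an[["Pr(>F)"]][1] < alpha)
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                               pool.sd = poolSd)$p.value
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j >= i) next
    praw <- pw[lv[i], lv[j]]
    padj <- min(1, praw * nPairs)
    out <- rbind(out, data.frame(
      parameter = parameter, kind = "between_groups",
      groups = paste(lv[j], lv[i], sep = "|"), statistic = NA_real_,
      p_value = praw, adjusted_p = padj, significant = padj < alpha))
  }
  rownames(out) <- NULL
  out
}

#' Between-group comparison of per-animal pre-to-post changes
#'
#' Computes each animal's delta (post - pre) for a parameter and compares
#' the deltas between groups through the [groupwiseAnova()] machinery. This
#' is the analysis where treatment effects on hypertrophy progression are
#' most visible, since each animal serves as its own baseline.
#'
#' @inheritParams groupwiseAnova
#' @return as [groupwiseAnova()], with kind `delta_between_groups` on the
#'   pairwise rows.
#' @export
deltaAnalysis <- function(table, parameter, alpha = 0.05, poolSd = TRUE) {
  checkCohortColumns(table)
  stopifnot(parameter %in% names(table))
  pre <- table[table$timepoint == "pre", ]
  post <- table[table$timepoint == "post", ]
  post <- post[match(pre$animal_id, post$animal_id), ]
  missing <- pre$animal_id[is.na(post$animal_id)]
  if (length(missing))
    stop("animals missing a timepoint: ", paste(missing, collapse = ", "))
  d <- post[[parameter]] - pre[[parameter]]
  out <- groupwiseAnova(parameter = paste0("delta_", parameter),
                        alpha = alpha, poolSd = poolSd,
                        values = d, groups = pre$group)
  out$kind[out$kind == "between_groups"] <- "delta_between_groups"
  out
}

#' Ordinary least squares with confidence and prediction bands
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, Pearson r, R^2, the
#' two-sided p value of the correlation, and pointwise bands at the
#' requested level: the confidence band for the mean response,
#' `t * s * sqrt(1/n + (x - xbar)^2 / Sxx)`, and the prediction band for a
#' new observation, `t * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`. Both are
#' symmetric about the fitted line and the prediction band contains the
#' confidence band everywhere.
#'
#' @param x,y numeric vectors (n >= 3; x must not be constant).
#' @param confidence band level (default 0.95).
#' @param newx abscissae for the bands (default: sorted unique x).
#' @return list with `slope`, `intercept`, `r`, `rSquared`, `pValue`, `n`,
#'   and `bands`, a data.frame (x, fit, confLo, confHi, predLo, predHi).
#' @export
olsWithBands <- function(x, y, confidence = 0.95, newx = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  if (is.null(newx)) newx <- sort(unique(x))
  nd <- data.frame(x = newx)
  cb <- stats::predict(fit, nd, interval = "confidence", level = confidence)
  pb <- stats::predict(fit, nd, interval = "prediction", level = confidence)
  r <- unname(ct$estimate)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, rSquared = r^2, pValue = ct$p.value, n = n,
       bands = data.frame(x = newx, fit = cb[, "fit"],
                          confLo = cb[, "lwr"], confHi = cb[, "upr"],
                          predLo = pb[, "lwr"], predHi = pb[, "upr"]))
}

#' Group x timepoint summary of a cohort table
#'
#' Mean and sample SD (n - 1 denominator) of the six LV parameters per group
#' and timepoint, in the canonical column order, optionally rounded to one
#' decimal (the precision the parameters are conventionally reported at).
#'
#' @param table a cohort table.
#' @param digits decimals for reporting (default 1; `NA` for full
#'   precision). Rounding is half-away-from-zero.
#' @return data.frame: group, timepoint, n, then `<param>_mean` and
#'   `<param>_sd` for EDbv, ESbv, EDmv, EDmw, LVWT, EF.
#' @export
summarizeCohort <- function(table, digits = 1L) {
  validateCohortTable(table)
  params <- lvParameterNames()
  combos <- unique(table[, c("group", "timepoint")])
  combos <- combos[order(match(combos$group, unique(table$group)),
                         match(combos$timepoint, c("pre", "post"))), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- table[table$group == combos$group[i] &
                 table$timepoint == combos$timepoint[i], ]
    row <- data.frame(group = combos$group[i],
                      timepoint = combos$timepoint[i], n = nrow(sub))
    for (p in params) {
      m <- mean(sub[[p]]); s <- stats::sd(sub[[p]])
      if (!is.na(digits)) { m <- roundHalfAway(m, digits)
                            s <- roundHalfAway(s, digits) }
      row[[paste0(p, "_mean")]] <- m
      row[[paste0(p, "_sd")]] <- s
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column-level contract shared by the comparison routines (balance of
# pre/post rows is checked where it matters, with the animals named).
checkCohortColumns <- function(table) {
  req <- c("animal_id", "group", "timepoint")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  invisible(table)
}
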