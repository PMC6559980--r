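#' Specify a simulated pre/post treatment cohort
#'
#' Distribution parameters for simulating per-animal LV parameter tables with
#' the summary structure of the reference four-group hypertrophy study:
#' saline (n = 10), AngII (n = 9), sRAGE (n = 10) and AngII+sRAGE (n = 10),
#' each animal measured pre and post infusion on the six LV parameters.
#'
#' Within-animal coupling is controlled by `rho`, the fraction of variance
#' carried by the animal effect: every draw is
#' `mean + SD * (sqrt(rho) * z + sqrt(1 - rho) * e)` with `z` a single
#' animal-level standard normal shared by all parameters and both timepoints
#' of that animal (an animal that runs large runs large throughout) and `e`
#' an independent residual, so each marginal SD is exactly the specified SD
#' and the pre/post correlation of each parameter is `rho`. Published group
#' summaries do not constrain `rho`; the default 0.8 encodes strong tracking
#' of an animal's own baseline, and is a stand-in.
#'
#' Heart weight (HW, mg) and cardiomyocyte cross-sectional area (CSA, percent
#' of the saline mean) are animal-level covariates generated from linear
#' links on the post-infusion EDmw and EDmv respectively, with Gaussian
#' residuals; the default slopes/residual SDs give cohort-level correlations
#' of about 0.79 (HW vs EDmw) and 0.73 (CSA vs EDmv). Body weight (BW, g) is
#' an independent normal covariate.
#'
#' @param groupStats data.frame like [referenceGroupStats()] (columns group,
#'   timepoint, parameter, mean, sd).
#' @param groupSizes named integer vector of animals per group.
#' @param rho shared-variance fraction between pre and post, in \[0, 1\].
#' @param hwModel list(slope, intercept, residSd): HW (mg) from post EDmw.
#' @param csaModel list(slope, intercept, residSd): CSA (percent) from post
#'   EDmv.
#' @param bwMean,bwSd body-weight distribution, g.
#' @param seed integer seed.
#' @return a list of class `cohortSpec`.
#' @export
cohortSpec <- function(groupStats = referenceGroupStats(),
                       groupSizes = referenceGroupSizes(),
                       rho = 0.8,
                       hwModel = list(slope = 1.0, intercept = 40,
                                      residSd = 12.6),
                       csaModel = list(slope = 1.7, intercept = -50.6,
                                       residSd = 24),
                       bwMean = 26, bwSd = 1.5,
                       seed = 1L) {
  stopifnot(is.data.frame(groupStats),
            all(c("group", "timepoint", "parameter", "mean", "sd") %in%
                names(groupStats)),
            all(groupStats$sd >= 0),
            all(groupSizes >= 2L),
            length(rho) == 1L, rho >= 0, rho <= 1)
  unknown <- setdiff(names(groupSizes), unique(groupStats$group))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  structure(list(groupStats = groupStats, groupSizes = groupSizes,
                 rho = rho, hwModel = hwModel, csaModel = csaModel,
                 bwMean = bwMean, bwSd = bwSd, seed = as.integer(seed)),
            class = "cohortSpec")
}

# Draw one animal's twelve values (six parameters x pre/post):
# v_tp = mean_tp + sd_tp * (sqrt(rho) z + sqrt(1-rho) e_tp), with one
# animal-level standard normal z shared by every parameter and timepoint
# (an animal that runs large runs large throughout) and independent
# residuals e_tp. Out-of-range draws (any value <= 0, EF >= 100) are
# rejected by redrawing the whole animal (no clipping). Zero SDs return the
# mean. `stG` holds the group's rows of the groupStats table.
drawAnimal <- function(stG, params, rho) {
  sr <- sqrt(rho); se <- sqrt(1 - rho)
  st <- lapply(params, function(p) {
    pre <- stG[stG$timepoint == "pre" & stG$parameter == p, ]
    post <- stG[stG$timepoint == "post" & stG$parameter == p, ]
    if (nrow(pre) != 1L || nrow(post) != 1L)
      stop(sprintf("missing distribution for %s/%s", stG$group[1], p))
    list(mPre = pre$mean, sPre = pre$sd, mPost = post$mean, sPost = post$sd,
         upper = if (p == "EF") 100 else Inf)
  })
  names(st) <- params
  for (i in 1:10000) {
    z <- stats::rnorm(1)
    pre <- post <- stats::setNames(numeric(length(params)), params)
    ok <- TRUE
    for (p in params) {
      d <- st[[p]]
      pre[p] <- if (d$sPre == 0) d$mPre else
        d$mPre + d$sPre * (sr * z + se * stats::rnorm(1))
      post[p] <- if (d$sPost == 0) d$mPost else
        d$mPost + d$sPost * (sr * z + se * stats::rnorm(1))
      if (pre[p] <= 0 || post[p] <= 0 || pre[p] >= d$upper ||
          post[p] >= d$upper) { ok <- FALSE; break }
    }
    if (ok) return(list(pre = pre, post = post))
  }
  stop("rejection sampling failed for group ", stG$group[1])
}

#' Simulate a per-animal cohort table
#'
#' Draws each animal's six LV parameters at both timepoints from
#' truncated-at-zero normal distributions with the per-group/timepoint means
#' and SDs of the spec (EF additionally truncated below 100), couples the two
#' timepoints through a shared animal effect (see [cohortSpec()]), and adds
#' the animal-level covariates HW, BW and CSA. Deterministic given the seed.
#'
#' @param spec a [cohortSpec()].
#' @return data.frame with one row per animal x timepoint and columns
#'   `animal_id, group, timepoint, EDbv, ESbv, EDmv, EDmw, LVWT, EF,
#'   HW, BW, CSA`.
#' @examples
#' head(simulateCohort(cohortSpec(seed = 7L)))
#' @export
simulateCohort <- function(spec) {
  if (!inherits(spec, "cohortSpec")) stop("spec must come from cohortSpec()")
  set.seed(spec$seed)
  params <- lvParameterNames()
  gs <- spec$groupStats
  nA <- sum(spec$groupSizes)
  ids <- character(nA); grp <- character(nA)
  valsPre <- valsPost <- matrix(NA_real_, nA, length(params),
                                dimnames = list(NULL, params))
  hw <- bw <- csa <- numeric(nA)
  aid <- 0L
  for (g in names(spec$groupSizes)) {
    stG <- gs[gs$group == g, ]
    for (k in seq_len(spec$groupSizes[[g]])) {
      aid <- aid + 1L
      ids[aid] <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g), k)
      grp[aid] <- g
      d <- drawAnimal(stG, params, spec$rho)
      valsPre[aid, ] <- d$pre[params]; valsPost[aid, ] <- d$post[params]
      hw[aid] <- spec$hwModel$slope * valsPost[aid, "EDmw"] +
        spec$hwModel$intercept + stats::rnorm(1, 0, spec$hwModel$residSd)
      csa[aid] <- spec$csaModel$slope * valsPost[aid, "EDmv"] +
        spec$csaModel$intercept + stats::rnorm(1, 0, spec$csaModel$residSd)
      bw[aid] <- stats::rnorm(1, spec$bwMean, spec$bwSd)
    }
  }
  # interleave pre/post rows per animal
  i <- rep(seq_len(nA), each = 2L)
  tp <- rep(c("pre", "post"), nA)
  vals <- matrix(NA_real_, 2L * nA, length(params),
                 dimnames = list(NULL, params))
  vals[tp == "pre", ] <- valsPre
  vals[tp == "post", ] <- valsPost
  out <- data.frame(animal_id = ids[i], group = grp[i], timepoint = tp,
                    EDbv = vals[, "EDbv"], ESbv = vals[, "ESbv"],
                    EDmv = vals[, "EDmv"], EDmw = vals[, "EDmw"],
                    LVWT = vals[, "LVWT"], EF = vals[, "EF"],
                    HW = hw[i], BW = bw[i], CSA = csa[i])
  rownames(out) <- NULL
  out
}

#' Validate a cohort table
#'
#' Checks the per-animal table contract: required columns present, each
#' animal has exactly one pre and one post row, volumes positive, EF within
#' (0, 100). Returns the table invisibly; stops with a message otherwise.
#'
#' @param table a cohort data.frame.
#' @return the table, invisibly.
#' @export
validateCohortTable <- function(table) {
  req <- c("animal_id", "group", "timepoint", lvParameterNames())
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(table$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")
  tab <- table(table$animal_id, table$timepoint)
  if (nrow(tab) && !all(tab == 1L))
    stop("each animal must have exactly one pre and one post row")
  if (any(table$EDbv <= 0 | table$ESbv <= 0 | table$EDmv <= 0))
    stop("volumes must be positive")
  if (any(table$EF <= 0 | table$EF >= 100))
    stop("EF must lie in (0, 100)")
  invisible(table)
}
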