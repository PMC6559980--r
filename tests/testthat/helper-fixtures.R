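# Small, fast phantom geometries used across the suite. The paper-scale
# defaults (256 x 256, 35 phases) are exercised in test-acceptance.R.

smallSpec <- function(...) {
  args <- utils::modifyList(
    list(matrixSize = 64L, pixelSpacing = 0.125, sliceThickness = 0.5,
         nPhases = 8L, lvLength = 3.0, endoRadiusED = 1.3,
         endoRadiusES = 0.8, wallThicknessED = 0.6),
    list(...))
  do.call(PhantomSpec, args)
}

# A two-level annulus test image: blood disc of radius rIn inside an ROI
# disc of radius rOut (pixel units), on an n x n grid, one phase/slice.
annulusFixture <- function(n = 64L, rIn = 20, rOut = 28,
                           blood = 1000, myo = 400, bg = 50,
                           pixelSpacing = 0.125) {
  ctr <- (n + 1) / 2
  xs <- seq_len(n) - ctr
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  img <- array(bg, dim = c(1, 1, n, n))
  roi <- array(FALSE, dim = c(1, 1, n, n))
  bl <- array(FALSE, dim = c(1, 1, n, n))
  img[1, 1, , ][rr <= rOut] <- myo
  img[1, 1, , ][rr <= rIn] <- blood
  roi[1, 1, , ][rr <= rOut] <- TRUE
  bl[1, 1, , ][rr <= rIn] <- TRUE
  list(stack = CineStack(img, pixelSpacing, 1),
       roi = MaskStack(roi, "lv_roi"),
       blood = MaskStack(bl, "blood"))
}

# Analytic short-axis slice areas of a half-ellipsoid with equatorial
# radius a and length c, sampled at slice centres for thickness t.
analyticSliceAreas <- function(a, c, t) {
  z <- seq(t / 2, c, by = t)
  pmax(pi * a^2 * (1 - (z / c)^2), 0)
}

# A tiny valid cohort table built by hand (2 groups x 3 animals).
tinyCohort <- function(shift = 0, noiseSd = 0, seed = 42L) {
  set.seed(seed)
  ids <- c(paste0("a", 1:3), paste0("b", 1:3))
  grp <- rep(c("g1", "g2"), each = 3)
  pre <- data.frame(animal_id = ids, group = grp, timepoint = "pre",
                    EDbv = 45, ESbv = 12, EDmv = 80, EDmw = 84,
                    LVWT = 650, EF = 72, HW = 120, BW = 26, CSA = 100)
  post <- pre
  post$timepoint <- "post"
  for (p in lvParameterNames())
    post[[p]] <- post[[p]] + shift + stats::rnorm(6, 0, noiseSd)
  rbind(pre, post)
}
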