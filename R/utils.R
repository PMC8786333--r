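#' @importFrom stats pt
NULL

## Vectorized two-sample t-test over rows of two matrices. Closed-form
## pooled (Student) or Welch statistic with stats::pt; equivalence with
## stats::t.test is asserted in the test suite. NA entries are dropped
## per row; rows with fewer than 2 observations in either group get NA.
## Degenerate zero-variance rows: equal means -> t = 0, p = 1; unequal
## means -> |t| = Inf, p = 0.
rowTTest <- function(x, y, varEqual = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  if (varEqual) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  p <- 2 * pt(-abs(tstat), df)
  zero <- is.finite(mx) & is.finite(my) & se == 0
  tstat[zero & mx == my] <- 0
  p[zero & mx == my] <- 1
  p[zero & mx != my] <- 0
  bad <- nx < 2 | ny < 2
  tstat[bad] <- NA_real_; p[bad] <- NA_real_
  list(statistic = tstat, p_value = p, df = df,
       mean_x = mx, mean_y = my, n_x = nx, n_y = ny)
}

## Symmetric fold-change filter: TRUE when the ratio of group means
## deviates more than minFC-fold in either direction. Inf passes; NaN
## (0/0) fails.
fcPasses <- function(ratio, minFC) {
  ok <- !is.nan(ratio) & (ratio > minFC | ratio < 1 / minFC)
  ok[is.na(ok)] <- FALSE
  ok
}

## Columns of a design belonging to one (timepoint, condition) cell.
designColumns <- function(design, timepoint, condition) {
  which(design$timepoint == timepoint & design$condition == condition)
}

stopConfig <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ironsplice_config_error",
                                              "error", "condition")))
}

stopInput <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ironsplice_input_error",
                                              "error", "condition")))
}
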