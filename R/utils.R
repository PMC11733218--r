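## Shared internal helpers.

#' @importFrom stats rnorm rbinom rpois runif sd pnorm pt dbinom setNames
#'   p.adjust complete.cases
#' @importFrom utils write.table read.table
NULL

KG_PER_LB <- 0.45359237

## Append one row to a filter log and optionally message it.  Every filter
## step reports (n_before, n_removed, n_after).
.logStep <- function(log, step, n_before, n_removed) {
  row <- data.frame(step = step, n_before = n_before,
                    n_removed = n_removed, n_after = n_before - n_removed)
  if (isTRUE(getOption("duoburden.verbose", FALSE)))
    message(sprintf("[%s] before=%d removed=%d after=%d", step,
                    n_before, n_removed, n_before - n_removed))
  rbind(log, row)
}

.emptyLog <- function() {
  data.frame(step = character(), n_before = integer(),
             n_removed = integer(), n_after = integer())
}

## OLS fit returning coefficient table (estimate, se, t-p) with rank-deficient
## columns dropped (warning).  X must already contain an intercept column.
.olsStats <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping collinear column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qx <- qr(X)
  }
  coefs <- qr.coef(qx, y)
  res <- y - X %*% coefs
  df <- nrow(X) - qx$rank
  sigma2 <- sum(res^2) / df
  R <- qr.R(qx)
  XtXinv <- chol2inv(R)
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- coefs / se
  p <- 2 * pt(-abs(tval), df)
  data.frame(term = colnames(X), estimate = as.numeric(coefs),
             se = se, p = p, df = df, row.names = NULL)
}

## Two-sided exact binomial p at prob 1/2, minlike convention: sum of
## P(X = j) over all j with P(X = j) <= P(X = k) (within relative
## tolerance, as stats::binom.test does).
.binomTwoSided <- function(k, n) {
  d <- dbinom(k, n, 0.5)
  all_d <- dbinom(0:n, n, 0.5)
  min(1, sum(all_d[all_d <= d * (1 + 1e-07)]))
}
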