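#' Mid-parent heterosis
#'
#' `MPH = 100 * (F1 - MP) / MP` with `MP = (parent1 + parent2) / 2`, the
#' percentage by which the hybrid's trait value exceeds the average of its
#' two inbred parents. Vectorized; invariant under swapping the parents.
#'
#' @param f1 Hybrid trait mean(s).
#' @param parent1,parent2 Parent trait means (MP must be positive).
#' @param digits Decimals for half-up rounding of the reported percentage
#'   (default 2); `NULL` returns the unrounded value.
#' @return MPH in percent.
#' @examples
#' mph(25.53, 19.52, 11.26)  # 65.89
#' @export
mph <- function(f1, parent1, parent2, digits = 2) {
  mp <- (parent1 + parent2) / 2
  if (any(is.na(mp)) || any(mp <= 0)) {
    stop("mid-parent value must be positive")
  }
  out <- 100 * (f1 - mp) / mp
  if (is.null(digits)) out else roundHalfUp(out, digits)
}

#' LSD significance letter grouping
#'
#' One-way ANOVA across lines followed by Fisher's least significant
#' difference: lines i and j differ when
#' `|mean_i - mean_j| >= t(1 - alpha/2, df_error) * sqrt(MSE * (1/n_i + 1/n_j))`.
#' Letters are assigned by the standard sweep on means sorted descending:
#' each maximal run of mutually non-different lines shares a letter, runs
#' contained in another are absorbed.
#'
#' @param values Numeric trait measurements (replicate level).
#' @param groups Line identifier per measurement; >= 2 lines with >= 2
#'   replicates each.
#' @param alpha Significance level (default 0.05).
#' @return data.frame (sorted by mean descending) with `line`, `mean`,
#'   `n`, `letters`; the error-df, MSE and per-pair threshold function are
#'   attached as attributes `df_error`, `mse`.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(3, 10), rnorm(3, 10.1), rnorm(3, 20))
#' lsdGroups(v, rep(c("a", "b", "c"), each = 3))
#' @export
lsdGroups <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  n <- table(groups)
  if (length(n) < 2L) stop("need at least two lines")
  if (any(n < 2L)) {
    stop("every line needs >= 2 replicates: ",
         paste(names(n)[n < 2L], collapse = ", "))
  }
  fit <- stats::aov(values ~ factor(groups))
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  dfe <- fit$df.residual
  tcrit <- stats::qt(1 - alpha / 2, dfe)
  means <- tapply(values, groups, mean)
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]
  n <- as.integer(n[names(means)])
  k <- length(means)
  lsd <- function(i, j) tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))
  differ <- function(i, j) abs(means[i] - means[j]) >= lsd(i, j)

  ## maximal non-significant runs over the descending means: extend each
  ## start right while the endpoints do not differ, then absorb runs
  ## contained in another
  runs <- unique(lapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !differ(i, j + 1L)) j <- j + 1L
    c(i, j)
  }))
  contained <- vapply(seq_along(runs), function(a) {
    any(vapply(seq_along(runs), function(b) {
      b != a && runs[[b]][1L] <= runs[[a]][1L] &&
        runs[[a]][2L] <= runs[[b]][2L]
    }, logical(1L)))
  }, logical(1L))
  runs <- runs[!contained]
  lett <- rep("", k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1L]:runs[[r]][2L]
    lett[idx] <- paste0(lett[idx], letters[r])
  }
  out <- data.frame(line = names(means), mean = as.numeric(means), n = n,
                    letters = lett, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "df_error") <- dfe
  attr(out, "mse") <- mse
  out
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,cal - Ct_ref,cal)`,
#' returning `2^-ddCt`, the expression of the target gene in the test
#' sample relative to the calibrator, normalized to the reference gene.
#'
#' @param ctTargetTest,ctRefTest Target and reference-gene Ct in the test
#'   sample.
#' @param ctTargetCalibrator,ctRefCalibrator The same in the calibrator
#'   sample.
#' @return Relative expression `2^-ddCt`.
#' @examples
#' deltaDeltaCt(20, 15, 22, 15)  # 4
#' @export
deltaDeltaCt <- function(ctTargetTest, ctRefTest, ctTargetCalibrator,
                         ctRefCalibrator) {
  ddct <- (ctTargetTest - ctRefTest) - (ctTargetCalibrator - ctRefCalibrator)
  if (any(!is.finite(ddct))) stop("Ct values must be finite")
  2^(-ddct)
}
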