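## Per-disease ordinary least squares of summed impact factor (y) on
## registrations (x) over the institution panel, quantifying how redundant
## the two productivity measures are. Fitting goes through stats::lm; the
## p value is the two-sided t test of the slope on n - 2 df.

#' Ordinary least-squares fit of y on x
#'
#' @param x numeric predictor (registrations).
#' @param y numeric response (summed impact factor), same length.
#' @return list with `slope`, `intercept`, `r`, `r2`, `p_value`,
#'   `stderr` (standard error of the slope), and `n`.
#' @examples
#' regressXY(1:5, 2 * (1:5))  # slope 2, intercept 0, r2 = 1
#' @export
regressXY <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have the same length")
    if (length(x) < 3L)
        stop("at least 3 observations are required")
    if (stats::sd(x) == 0)
        stop("degenerate design: x is constant")
    fit <- stats::lm(y ~ x)
    cf <- summary(fit)$coefficients
    slope <- unname(cf["x", "Estimate"])
    ## constant y: zero slope, zero correlation (not NA)
    r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
    list(slope = slope,
         intercept = unname(cf["(Intercept)", "Estimate"]),
         r = r,
         r2 = r^2,
         p_value = unname(cf["x", "Pr(>|t|)"]),
         stderr = unname(cf["x", "Std. Error"]),
         n = length(x))
}

#' Per-disease regressions of SIF on registrations
#'
#' One regression per disease column shared by the two matrices (the
#' `all_cancer` column is excluded by default); a disease with constant
#' registrations is excluded with a warning and noted in the summary.
#'
#' @param reg a [CountMatrix-class].
#' @param sif a [SIFMatrix-class] with identical labels.
#' @param pThreshold significance threshold (default 0.05).
#' @param includeAllCancer also regress the `all_cancer` column
#'   (default `FALSE`).
#' @return list with `results` (data.frame: `disease`, `slope`,
#'   `intercept`, `r`, `r2`, `p_value`, `stderr`, `n`) and `summary`
#'   (list: `mean_slope`, `sd_slope` (sample, n-1), `sd_slope_pop`
#'   (population, n), `slope_range` = c(max, min), `mean_r2`, `sd_r2`,
#'   `sd_r2_pop`, `r2_range`, `n_significant`, `n_diseases`,
#'   `excluded`).
#' @export
perDiseaseRegressions <- function(reg, sif, pThreshold = 0.05,
                                  includeAllCancer = FALSE) {
    stopifnot(pThreshold > 0, pThreshold < 1)
    r <- matrixValues(reg)
    s <- matrixValues(sif)
    if (!identical(dimnames(r), dimnames(s)))
        stop("count and SIF matrices must share labels")
    diseases <- colnames(r)
    if (!includeAllCancer) diseases <- setdiff(diseases, "all_cancer")
    excluded <- character(0)
    rows <- list()
    for (d in diseases) {
        if (stats::sd(r[, d]) == 0) {
            warning("disease '", d,
                    "' excluded from regression: constant registrations",
                    call. = FALSE)
            excluded <- c(excluded, d)
            next
        }
        f <- regressXY(r[, d], s[, d])
        rows[[d]] <- data.frame(disease = d, slope = f$slope,
                                intercept = f$intercept, r = f$r,
                                r2 = f$r2, p_value = f$p_value,
                                stderr = f$stderr, n = f$n,
                                stringsAsFactors = FALSE)
    }
    results <- if (length(rows)) do.call(rbind, rows) else
        data.frame(disease = character(0), slope = numeric(0),
                   intercept = numeric(0), r = numeric(0), r2 = numeric(0),
                   p_value = numeric(0), stderr = numeric(0),
                   n = integer(0))
    rownames(results) <- NULL
    popSD <- function(v) if (length(v) <= 1L) 0 else
        sqrt(mean((v - mean(v))^2))
    summ <- list(
        mean_slope = mean(results$slope),
        sd_slope = stats::sd(results$slope),
        sd_slope_pop = popSD(results$slope),
        slope_range = c(max = suppressWarnings(max(results$slope)),
                        min = suppressWarnings(min(results$slope))),
        mean_r2 = mean(results$r2),
        sd_r2 = stats::sd(results$r2),
        sd_r2_pop = popSD(results$r2),
        r2_range = c(max = suppressWarnings(max(results$r2)),
                     min = suppressWarnings(min(results$r2))),
        n_significant = sum(results$p_value < pThreshold),
        n_diseases = nrow(results),
        excluded = excluded)
    list(results = results, summary = summ)
}
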