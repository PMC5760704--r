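#' Split VAFs into clonal (public) and subclonal (private) sets
#'
#' Mutations at variant allele frequency at or above the cutoff are clonal
#' (public); those below it are subclonal (private). The default cutoff of
#' 0.25 is the whole-genome convention for a diploid heterozygous state at
#' moderate purity.
#'
#' @param vafs Numeric VAFs in \[0, 1\].
#' @param clonal_cutoff VAF cutoff; `>= cutoff` is clonal.
#' @return List with `clonal` and `subclonal` numeric vectors (an exhaustive
#'   disjoint partition of the input).
#' @export
split_clonal_subclonal <- function(vafs, clonal_cutoff = 0.25) {
  stopifnot(all(vafs >= 0), all(vafs <= 1))
  list(clonal = vafs[vafs >= clonal_cutoff],
       subclonal = vafs[vafs < clonal_cutoff])
}

#' Cumulative subclonal mutation distribution M(f)
#'
#' For each observed VAF f inside the window, M(f) counts the mutations with
#' VAF between f and fmax inclusive. The model anchor point (fmax, 0) is
#' appended when no observed VAF equals fmax, since M(fmax) = 0 by
#' construction of the neutral model.
#'
#' @param vafs Subclonal VAFs.
#' @param fmin,fmax Evaluation window, 0 < fmin < fmax.
#' @return Data frame with columns `f` (descending) and `M`.
#' @export
cumulative_mf <- function(vafs, fmin = 0.12, fmax = 0.24) {
  if (fmin >= fmax || fmin <= 0) stop("invalid VAF window: need 0 < fmin < fmax")
  f <- sort(unique(vafs[vafs >= fmin & vafs <= fmax]), decreasing = TRUE)
  if (!length(f)) return(data.frame(f = numeric(0), M = numeric(0)))
  M <- vapply(f, function(x) sum(vafs >= x & vafs <= fmax), numeric(1))
  if (f[1] < fmax) {
    f <- c(fmax, f)
    M <- c(0, M)
  }
  data.frame(f = f, M = M)
}

#' Zero-intercept power-law fit of M(f)
#'
#' Least-squares fit of M(f) against \eqn{x = 1/f - 1/f_{max}} through the
#' origin; under neutral growth M(f) is linear in x with slope \eqn{\mu/\beta}
#' and M(fmax) = 0, which is why the intercept is fixed at zero. The
#' goodness-of-fit is the conventional \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with
#' the total sum of squares about the mean of M (can be negative for a fit
#' worse than the mean).
#'
#' @param mf Data frame from [cumulative_mf()] (columns `f`, `M`).
#' @param fmax Window upper edge used to form x.
#' @return List with `slope` (\eqn{\mu/\beta} estimate) and `r_squared` (raw,
#'   unclamped).
#' @export
fit_power_law <- function(mf, fmax = 0.24) {
  stopifnot(nrow(mf) >= 1)
  x <- 1 / mf$f - 1 / fmax
  y <- mf$M
  sxx <- sum(x^2)
  if (sxx < 1e-300) stop("undefined fit: all evaluation points identical")
  slope <- sum(x * y) / sxx
  ssres <- sum((y - slope * x)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot < 1e-300) as.numeric(ssres < 1e-12) else 1 - ssres / sstot
  list(slope = slope, r_squared = r2)
}

#' Test a sample for neutral tumor evolution
#'
#' Implements the power-law neutrality test on raw VAFs: mutations with VAF in
#' the window (default 12–24%, chosen to cover reliably called subclonal
#' mutations at typical purity) form the cumulative distribution M(f), which
#' under neutral growth follows \eqn{M(f) = (\mu/\beta)(1/f - 1/f_{max})}.
#' A sample is evaluable only with at least `min_mutations` (default 12)
#' window mutations; an evaluable sample is called neutral when the
#' zero-intercept fit achieves \eqn{R^2} strictly greater than `r2_threshold`
#' (default 0.98).
#'
#' @param vafs Numeric VAFs in \[0, 1\] (all mutations of the sample; the
#'   window and clonal cutoff are applied internally).
#' @param fmin,fmax Fit window on the VAF scale.
#' @param clonal_cutoff VAF at or above which mutations are clonal; must
#'   exceed `fmax`.
#' @param min_mutations Minimum window mutations for an evaluable test.
#' @param r2_threshold Strict lower bound on \eqn{R^2} for a neutral verdict.
#' @return Object of class `"neutrality_fit"`: `n_window`, `evaluable`, `mf`
#'   (the M(f) series), `slope_mu_over_beta`, `r_squared` (floored at 0;
#'   raw value in `r_squared_raw`), `neutral`, plus the configuration.
#' @examples
#' f <- 1 / (1 / 0.24 + (1:20) * 0.2)   # exact 1/f law inside the window
#' test_neutrality(f)                    # R^2 = 1, neutral
#' @export
test_neutrality <- function(vafs, fmin = 0.12, fmax = 0.24,
                            clonal_cutoff = 0.25, min_mutations = 12L,
                            r2_threshold = 0.98) {
  stopifnot(fmin > 0, fmin < fmax, fmax < clonal_cutoff, clonal_cutoff <= 0.5,
            min_mutations >= 1)
  stopifnot(all(vafs >= 0), all(vafs <= 1))
  sub <- split_clonal_subclonal(vafs, clonal_cutoff)$subclonal
  n_window <- sum(sub >= fmin & sub <= fmax)
  evaluable <- n_window >= min_mutations
  mf <- cumulative_mf(sub, fmin, fmax)
  slope <- NA_real_; r2raw <- NA_real_
  if (evaluable) {
    fit <- fit_power_law(mf, fmax)
    slope <- fit$slope
    r2raw <- fit$r_squared
  }
  neutral <- isTRUE(evaluable && !is.na(r2raw) && r2raw > r2_threshold)
  structure(list(n_window = n_window, evaluable = evaluable, mf = mf,
                 slope_mu_over_beta = slope,
                 r_squared = if (is.na(r2raw)) NA_real_ else max(0, min(1, r2raw)),
                 r_squared_raw = r2raw, neutral = neutral,
                 fmin = fmin, fmax = fmax, clonal_cutoff = clonal_cutoff,
                 min_mutations = min_mutations, r2_threshold = r2_threshold),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("Neutral tumor evolution test (window ",
      x$fmin, "-", x$fmax, " VAF)\n", sep = "")
  cat("  window mutations:", x$n_window,
      if (!x$evaluable) paste0("(< ", x$min_mutations, ", not evaluable)"), "\n")
  if (x$evaluable) {
    cat("  slope mu/beta:", format(x$slope_mu_over_beta, digits = 4), "\n")
    cat("  R-squared:", format(x$r_squared, digits = 4),
        " (threshold >", x$r2_threshold, ")\n")
  }
  cat("  verdict:", if (x$neutral) "NEUTRAL" else "non-neutral / not evaluable", "\n")
  invisible(x)
}

#' @export
coef.neutrality_fit <- function(object, ...) {
  c(mu_over_beta = object$slope_mu_over_beta)
}

#' @export
plot.neutrality_fit <- function(x, ...) {
  if (!nrow(x$mf)) {
    graphics::plot(NA, xlim = 0:1, ylim = 0:1, xlab = "", ylab = "",
                   main = "M(f): no window mutations")
    return(invisible(x))
  }
  xx <- 1 / x$mf$f - 1 / x$fmax
  graphics::plot(xx, x$mf$M, pch = 19, col = "grey30",
                 xlab = expression(1 / f - 1 / f[max]),
                 ylab = "M(f)", main = "Cumulative subclonal mutations", ...)
  if (!is.na(x$slope_mu_over_beta))
    graphics::abline(0, x$slope_mu_over_beta, col = "firebrick", lwd = 2)
  if (!is.na(x$r_squared))
    graphics::legend("topleft", bty = "n", legend = sprintf(
      "R² = %.3f%s", x$r_squared, if (x$neutral) " (neutral)" else ""))
  invisible(x)
}
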