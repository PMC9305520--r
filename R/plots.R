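#' Diagnostic plots for an HDPS fit
#'
#' Base-graphics renderings of the standard HDPS diagnostics:
#'
#' * `"overlap"`: mirrored propensity-score histograms by exposure group,
#'   one panel per PS model;
#' * `"balance"`: unweighted vs HDPS-weighted ASD per covariate, with
#'   dashed 10% reference lines;
#' * `"prevalence"`: prevalence of each selected covariate in exposed vs
#'   unexposed groups, identity line and dashed prevalence-ratio 0.5 / 2.0
#'   bands, colour-coded by dimension;
#' * `"bias"`: rank-ordered absolute log Bross bias values, colour-coded by
#'   dimension;
#' * `"association"`: exposure- vs outcome-association strength
#'   (`|rr - 1|`) per covariate; points in the weak-outcome /
#'   strong-exposure region behave like instruments.
#'
#' @param x An [hdps()] fit.
#' @param type One of `"overlap"`, `"balance"`, `"prevalence"`, `"bias"`,
#'   `"association"`.
#' @param ... Further arguments passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.hdps <- function(x, type = c("overlap", "balance", "prevalence",
                                  "bias", "association"), ...) {
  type <- match.arg(type)
  switch(type,
         overlap = plot_overlap(x, ...),
         balance = plot_balance(x, ...),
         prevalence = plot_prevalence(x, ...),
         bias = plot_bias(x, ...),
         association = plot_association(x, ...))
  invisible(x)
}

dimension_palette <- function(dims) {
  stats::setNames(grDevices::hcl.colors(max(3L, length(dims)), "Dark 3")[
    seq_along(dims)], dims)
}

plot_overlap <- function(x, ...) {
  ov <- x$overlap
  if (is.null(ov)) ov <- ps_overlap_summary(x$ps, exposure = x$cohort$exposure)
  models <- unique(ov$densities$model)
  old <- graphics::par(mfrow = c(length(models), 1L),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in models) {
    d <- ov$densities[ov$densities$model == m, ]
    d1 <- d[d$group == "exposed", ]
    d0 <- d[d$group == "unexposed", ]
    ylim <- max(d$density) * c(-1, 1)
    graphics::plot(d1$ps_mid, d1$density, type = "h", col = "#d95f02",
                   xlim = c(0, 1), ylim = ylim, xlab = "Propensity score",
                   ylab = "Density",
                   main = sprintf("%s (overlap %.2f)", m, ov$overlap[m]),
                   ...)
    graphics::lines(d0$ps_mid, -d0$density, type = "h", col = "#1b9e77")
    graphics::abline(h = 0)
    graphics::legend("topright", legend = c("exposed", "unexposed"),
                     fill = c("#d95f02", "#1b9e77"), bty = "n")
  }
}

plot_balance <- function(x, weight_col = "asd_hdps", ...) {
  b <- x$balance
  if (is.null(b)) stop("fit carries no balance table (diagnostics = FALSE)",
                       call. = FALSE)
  lim <- range(0, b$asd_unweighted, b[[weight_col]]) * 1.05
  graphics::plot(b$asd_unweighted, b[[weight_col]], xlim = lim, ylim = lim,
                 xlab = "Unweighted ASD (%)",
                 ylab = "HDPS-weighted ASD (%)",
                 main = "Covariate balance before/after weighting",
                 pch = 16, col = "#00000080", ...)
  graphics::abline(a = 0, b = 1, col = "grey50")
  graphics::abline(h = 10, v = 10, lty = 2)
}

plot_prevalence <- function(x, ...) {
  ps <- prevalence_scatter(x$prioritised[x$prioritised$name %in%
                                           x$selected, , drop = FALSE])
  pal <- dimension_palette(unique(ps$dimension))
  lim <- range(c(ps$prev_exposed, ps$prev_unexposed, 1e-3, 1))
  graphics::plot(ps$prev_unexposed, ps$prev_exposed, log = "xy",
                 xlim = lim, ylim = lim, pch = 16,
                 col = pal[ps$dimension],
                 xlab = "Prevalence, unexposed",
                 ylab = "Prevalence, exposed",
                 main = "Covariate prevalence by treatment group", ...)
  graphics::abline(a = 0, b = 1, untf = TRUE)
  graphics::curve(2 * x, add = TRUE, lty = 2)
  graphics::curve(0.5 * x, add = TRUE, lty = 2)
  graphics::legend("topleft", legend = names(pal), fill = pal, bty = "n")
}

plot_bias <- function(x, top = Inf, ...) {
  bd <- bias_distribution(x$prioritised, top = top)
  v <- bd$values
  pal <- dimension_palette(unique(v$dimension))
  graphics::plot(v$rank, v$abs_log_bias, pch = 16, col = pal[v$dimension],
                 xlab = "Bross rank", ylab = "|log bias multiplier|",
                 main = "Distribution of Bross bias values", ...)
  graphics::legend("topright", legend = names(pal), fill = pal, bty = "n")
}

plot_association <- function(x, rule = near_iv_rule(), ...) {
  a <- association_scatter(x$prioritised)
  flagged <- x$prioritised$name %in% flag_near_ivs(x$prioritised, rule)
  graphics::plot(a$strength_outcome, a$strength_exposure,
                 pch = ifelse(flagged, 17, 16),
                 col = ifelse(flagged, "#d95f02", "#00000080"),
                 xlab = "Outcome association strength |rr - 1|",
                 ylab = "Exposure association strength |rr - 1|",
                 main = "Covariate-exposure vs covariate-outcome association",
                 ...)
  graphics::legend("topright", legend = c("near-IV flagged", "other"),
                   pch = c(17, 16), col = c("#d95f02", "#00000080"),
                   bty = "n")
}
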