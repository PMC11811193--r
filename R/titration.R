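#' Degree of deprotonation from constant-pH proton-binding series
#'
#' For each pH and replicate, the fraction of analysis-window frames in
#' which the titratable site carries no bound proton. Only the last
#' `window_ns` of each trace is analysed, discarding the equilibration
#' transient at the start of each constant-pH run.
#'
#' @param series data frame with columns `pH`, `replicate`, `time_ns`,
#'   `bound_protons` (integer counts per frame).
#' @param window_ns analysis window anchored at the trace end (default 10).
#' @return list with `per_replicate` (data frame `pH`, `replicate`,
#'   `fraction`) and `summary` (data frame `pH`, `mean`, `sem`, `n`).
#' @export
degree_of_deprotonation <- function(series, window_ns = 10) {
  need <- c("pH", "replicate", "time_ns", "bound_protons")
  if (!all(need %in% names(series))) {
    stop("series must have columns: ", paste(need, collapse = ", "))
  }
  per <- do.call(rbind, lapply(
    split(series, list(series$pH, series$replicate), drop = TRUE),
    function(d) {
      t_end <- max(d$time_ns)
      w <- d[d$time_ns > t_end - window_ns, , drop = FALSE]
      if (!nrow(w)) stop("config error: empty analysis window at pH ",
                         d$pH[1], " replicate ", d$replicate[1])
      data.frame(pH = d$pH[1], replicate = d$replicate[1],
                 fraction = mean(w$bound_protons == 0))
    }))
  rownames(per) <- NULL
  per <- per[order(per$pH, per$replicate), ]
  summ <- do.call(rbind, lapply(split(per, per$pH), function(d) {
    st <- replicate_stats(d$fraction)
    data.frame(pH = d$pH[1], mean = st$mean, sem = st$sem, n = st$n)
  }))
  rownames(summ) <- NULL
  list(per_replicate = per, summary = summ)
}

#' Fit a pKa to a titration curve
#'
#' Least-squares fit of the Henderson-Hasselbalch form
#' `f(pH) = 1 / (1 + 10^(n * (pKa - pH)))` to per-pH deprotonation
#' fractions, with the Hill coefficient `n` fixed to 1 by default or fitted
#' when `hill = "free"`. A model-free midpoint (monotone interpolation of
#' the mean curve at f = 0.5) is also reported.
#'
#' @param pH numeric pH values.
#' @param fraction deprotonation fractions at those pH values.
#' @param hill `"fixed"` (n = 1) or `"free"`.
#' @return a `TitrationFit`: list `pka`, `hill_n`, `fitted`, `residuals`,
#'   `rss`, `midpoint_interp`, `extrapolated` (TRUE if pKa falls outside
#'   the fitted pH span), `n_points`.
#' @export
fit_pka <- function(pH, fraction, hill = c("fixed", "free")) {
  hill <- match.arg(hill)
  ok <- is.finite(pH) & is.finite(fraction)
  pH <- pH[ok]; fraction <- fraction[ok]
  if (length(pH) < 4L) stop("need at least 4 pH points to fit")
  if (all(fraction <= 0) || all(fraction >= 1)) {
    stop("non-identifiable: all fractions at one extreme; ",
         "no transition within the pH span")
  }
  hh <- function(p, n, x) 1 / (1 + 10^(n * (p - x)))
  if (hill == "fixed") {
    obj <- function(p) sum((hh(p, 1, pH) - fraction)^2)
    opt <- stats::optimize(obj, range(pH) + c(-2, 2))
    pka <- opt$minimum; n_hill <- 1
  } else {
    obj <- function(th) sum((hh(th[1], exp(th[2]), pH) - fraction)^2)
    opt <- stats::optim(c(mean(pH), 0), obj, method = "Nelder-Mead")
    pka <- opt$par[1]; n_hill <- exp(opt$par[2])
  }
  fitted <- hh(pka, n_hill, pH)
  # model-free midpoint: first crossing of 0.5 on the mean curve
  ord <- order(pH)
  mid <- tryCatch(
    stats::approx(fraction[ord], pH[ord], xout = 0.5, ties = mean)$y,
    error = function(e) NA_real_)
  structure(
    list(pka = pka, hill_n = n_hill, fitted = fitted,
         residuals = fraction - fitted, rss = sum((fraction - fitted)^2),
         midpoint_interp = mid,
         extrapolated = pka < min(pH) || pka > max(pH),
         n_points = length(pH)),
    class = "TitrationFit")
}

#' @export
print.TitrationFit <- function(x, ...) {
  cat(sprintf("<TitrationFit> pKa = %.3f (Hill n = %.2f, %d pH points%s)\n",
              x$pka, x$hill_n, x$n_points,
              if (x$extrapolated) ", extrapolated" else ""))
  invisible(x)
}

#' Shift of a fitted pKa relative to the free residue in solution
#'
#' Positive values mean the buried residue holds on to its proton at
#' higher pH than the free amino acid. The default reference of 4.3 is the
#' solution pKa of glutamate.
#'
#' @param pka fitted pKa.
#' @param reference solution reference pKa (default 4.3, glutamate).
#' @return shift in pH units.
#' @export
reference_shift <- function(pka, reference = 4.3) {
  pka - reference
}
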