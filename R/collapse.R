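#' Monotone reference curve of metabolite level versus glucose
#'
#' Fits an isotonic (monotone nonparametric) curve on log10 extracellular
#' glucose, with the direction taken from the sign of the rank correlation.
#' The fit interpolates linearly between the isotonic values and extends
#' flat beyond the data range.
#'
#' @param glucose Extracellular glucose concentrations (mM, > 0).
#' @param level Metabolite levels (same length).
#' @return A `reference_curve` object: call [predict_curve()] to evaluate.
#' @export
fit_reference_curve <- function(glucose, level) {
  keep <- is.finite(glucose) & is.finite(level) & glucose > 0
  glucose <- glucose[keep]; level <- level[keep]
  if (length(glucose) < 5L)
    stop_domain("fit_reference_curve: need at least 5 points")
  if (diff(range(glucose)) <= 0)
    stop_domain("fit_reference_curve: zero glucose range")
  x <- log10(glucose)
  direction <- if (stats::sd(level) == 0) 1 else
    sign(stats::cor(x, level, method = "spearman"))
  if (is.na(direction) || direction == 0) direction <- 1
  o <- order(x)
  iso <- stats::isoreg(x[o], direction * level[o])
  # collapse duplicate x to their fitted value (isoreg output is monotone)
  fx <- iso$x; fy <- direction * iso$yf
  ux <- !duplicated(fx, fromLast = TRUE)
  fn <- stats::approxfun(fx[ux], fy[ux], rule = 2, ties = "ordered")
  structure(list(fn = fn, direction = direction,
                 range = range(glucose), n = length(glucose)),
            class = "reference_curve")
}

#' Evaluate a reference curve
#' @param curve A `reference_curve` from [fit_reference_curve()].
#' @param glucose Glucose concentrations (mM).
#' @return Fitted levels.
#' @export
predict_curve <- function(curve, glucose) curve$fn(log10(glucose))

#' Collapse score of one metabolite across temperature regimes
#'
#' Quantifies how well the (glucose, level) points of all regimes fall on a
#' single curve. A pooled monotone reference curve is fitted, relative
#' residuals `r = (level - g(S)) / g(S)` computed, and summarized as the
#' pooled median absolute residual `c_pooled` and per-regime medians
#' `c_regime`. A regime is flagged deviant when its score exceeds `theta`.
#' Residual temperature dependence is measured by the rank correlation of `r`
#' with temperature, with a permutation p-value (temperature labels permuted
#' `n_perm` times under a fixed seed).
#'
#' @param table Data frame with columns `regime`, `temperature_C`,
#'   `glucose_mM`, `level` (already filtered to one metabolite).
#' @param theta Deviation threshold on the per-regime score (default 0.15).
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Integer seed for the permutation test.
#' @return One-row data frame: `c_pooled`, `c_regime_max`, `n_regimes`,
#'   `flagged_regimes` (comma string, `""` if none), `rho`, `p_value`.
#' @export
collapse_scores <- function(table, theta = 0.15, n_perm = 1000, seed = 1L) {
  stopifnot(all(c("regime", "temperature_C", "glucose_mM", "level")
                %in% names(table)))
  curve <- fit_reference_curve(table$glucose_mM, table$level)
  g <- predict_curve(curve, table$glucose_mM)
  r <- (table$level - g) / ifelse(g == 0, 1, g)
  c_pooled <- stats::median(abs(r))
  regimes <- unique(table$regime)
  c_regime <- vapply(regimes, function(q)
    stats::median(abs(r[table$regime == q])), numeric(1))
  flagged <- regimes[c_regime > theta]
  rho <- p_value <- NA_real_
  if (n_perm > 0 && length(unique(table$temperature_C)) > 1 &&
      stats::sd(r) > 0) {
    perm <- perm_cor_test(r, table$temperature_C, n_perm, seed)
    rho <- perm$rho; p_value <- perm$p
  }
  data.frame(c_pooled = c_pooled, c_regime_max = max(c_regime),
             n_regimes = length(regimes),
             flagged_regimes = paste(flagged, collapse = ","),
             rho = rho, p_value = p_value, stringsAsFactors = FALSE)
}

# permutation test for rank correlation, vectorized over permutations
perm_cor_test <- function(r, temp, n_perm, seed) {
  rr <- rank(r); tt <- rank(temp)
  rs <- as.numeric(scale(rr)); ts <- as.numeric(scale(tt))
  n <- length(rr)
  rho <- sum(rs * ts) / (n - 1)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  rho_null <- as.numeric(crossprod(rs, matrix(ts[perms], n)) / (n - 1))
  p <- (1 + sum(abs(rho_null) >= abs(rho) - 1e-12)) / (1 + n_perm)
  list(rho = rho, p = p)
}

#' Temperature-deviation scores under glucose excess
#'
#' Under glucose excess the reference relation degenerates to a point, so the
#' statistic is the deviation of the (replicate-median) level at each
#' temperature from the 30 degC level:
#' `D_m = max_T |median(level | T) / median(level | 30) - 1|`.
#'
#' @param table Excess-stratum rows of a measurement table (columns
#'   `temperature_C`, `level`), one metabolite.
#' @param ref_temperature Reference temperature (degC), default 30.
#' @return One-row data frame: `excess_dev`, `n_temperatures`.
#' @export
excess_deviation <- function(table, ref_temperature = 30) {
  temps <- sort(unique(table$temperature_C))
  med <- vapply(temps, function(T)
    stats::median(table$level[table$temperature_C == T]), numeric(1))
  iref <- which.min(abs(temps - ref_temperature))
  dev <- abs(med / med[iref] - 1)
  data.frame(excess_dev = max(dev[-iref], 0),
             n_temperatures = length(temps))
}

#' Localize the enzyme with deviating temperature sensitivity
#'
#' Applies the boundary rule: if the deviation flags, ordered along the
#' pathway, are all `TRUE` up to some metabolite and all `FALSE` after it,
#' the perturbed reaction is the backbone reaction consuming the last
#' deviating metabolite. All-clear flags return no candidate; any other
#' pattern is inconsistent with a single boundary and also returns no
#' candidate, with the observed pattern reported.
#'
#' @param flags Named logical vector of deviation flags keyed by metabolite.
#' @param pathway Either a `network_model` or the data frame from
#'   [metabolite_pathway()] (`metabolite`, `boundary_reaction`, `position`).
#' @return List: `candidate` (reaction id or `NULL`), `pattern` (named
#'   character vector `"deviant"`/`"ok"` in pathway order), `consistent`.
#' @export
localize_deviant_enzyme <- function(flags, pathway) {
  if (inherits(pathway, "network_model")) pathway <- metabolite_pathway(pathway)
  if (length(flags) < 3L)
    stop_domain("localize_deviant_enzyme: need flags for >= 3 metabolites")
  unknown <- setdiff(names(flags), pathway$metabolite)
  if (length(unknown))
    stop_config("metabolite(s) not in pathway order: ",
                paste(unknown, collapse = ", "))
  pw <- pathway[pathway$metabolite %in% names(flags), , drop = FALSE]
  pw <- pw[order(pw$position), , drop = FALSE]
  f <- flags[pw$metabolite]
  pattern <- stats::setNames(ifelse(f, "deviant", "ok"), pw$metabolite)
  if (!any(f))
    return(list(candidate = NULL, pattern = pattern, consistent = TRUE))
  k <- max(which(f))
  consistent <- all(f[seq_len(k)]) && (k == length(f) || !any(f[-seq_len(k)]))
  if (!consistent)
    return(list(candidate = NULL, pattern = pattern, consistent = FALSE))
  list(candidate = pw$boundary_reaction[k], pattern = pattern,
       consistent = TRUE)
}

#' Full collapse analysis of a measurement table
#'
#' Runs, per metabolite, the glucose-limited collapse statistic (pooled over
#' regimes) and the glucose-excess temperature-deviation statistic, then
#' applies the localization rule to the excess-stratum flags. The excess
#' stratum is analysed separately because the discriminating power between
#' the identical- and single-enzyme-different hypotheses is concentrated
#' there.
#'
#' @param table Measurement table: columns `regime`, `time_h`,
#'   `temperature_C`, `glucose_mM`, `metabolite`, `level`, and `stratum`
#'   (`"excess"`/`"limited"`; inferred from `regime == "SBR"` when missing).
#' @param pathway A `network_model` or [metabolite_pathway()] data frame for
#'   localization; `NULL` skips localization.
#' @param theta Deviation threshold (default 0.15, or twice the estimated
#'   replicate coefficient of variation when that is larger).
#' @param replicate_cv Optional estimated replicate CV used to raise `theta`.
#' @param n_perm,seed Permutation-test settings.
#' @return A `collapse_report`: list with `scores` (one row per metabolite),
#'   `localization`, `theta`, `n_perm`, `seed`.
#' @export
analyze_collapse <- function(table, pathway = NULL, theta = 0.15,
                             replicate_cv = NULL, n_perm = 1000, seed = 1L) {
  if (!"stratum" %in% names(table))
    table$stratum <- ifelse(table$regime == "SBR", "excess", "limited")
  if (!is.null(replicate_cv)) theta <- max(theta, 2 * replicate_cv)
  mets <- unique(table$metabolite)
  rows <- lapply(mets, function(m) {
    sub <- table[table$metabolite == m, , drop = FALSE]
    lim <- sub[sub$stratum == "limited" & sub$glucose_mM > 0, , drop = FALSE]
    exc <- sub[sub$stratum == "excess", , drop = FALSE]
    out <- data.frame(metabolite = m, stringsAsFactors = FALSE)
    if (nrow(lim) >= 5 && length(unique(lim$regime)) >= 2) {
      out <- cbind(out, collapse_scores(lim, theta, n_perm, seed))
    } else {
      out <- cbind(out, data.frame(c_pooled = NA_real_,
                                   c_regime_max = NA_real_, n_regimes = 0L,
                                   flagged_regimes = "", rho = NA_real_,
                                   p_value = NA_real_))
    }
    if (nrow(exc)) out <- cbind(out, excess_deviation(exc))
    else out <- cbind(out, data.frame(excess_dev = NA_real_,
                                      n_temperatures = 0L))
    out
  })
  scores <- do.call(rbind, rows)
  scores$flag_limited <- !is.na(scores$c_regime_max) &
    scores$c_regime_max > theta
  scores$flag_excess <- !is.na(scores$excess_dev) & scores$excess_dev > theta
  localization <- NULL
  if (!is.null(pathway) && sum(!is.na(scores$excess_dev)) >= 3) {
    flags <- stats::setNames(scores$flag_excess, scores$metabolite)
    flags <- flags[!is.na(scores$excess_dev)]
    localization <- localize_deviant_enzyme(flags, pathway)
  }
  structure(list(scores = scores, localization = localization, theta = theta,
                 n_perm = n_perm, seed = seed),
            class = "collapse_report")
}

#' @export
print.collapse_report <- function(x, ...) {
  cat("<collapse_report> theta =", x$theta, "\n")
  print(x$scores, digits = 3)
  if (!is.null(x$localization)) {
    cand <- x$localization$candidate
    cat("localized deviant enzyme:",
        if (is.null(cand)) "none" else cand, "\n")
  }
  invisible(x)
}
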