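#' Tumor volume from caliper diameters
#'
#' The standard ellipsoid convention `V = L * W^2 / 2` (mm^3), with `L` the
#' long and `W` the short diameter. If any pair arrives swapped (`W > L`)
#' the pair is auto-ordered with a warning.
#'
#' @param L long diameter, mm (vectorized).
#' @param W short diameter, mm.
#' @return tumor volume, mm^3.
#' @export
tumor_volume <- function(L, W) {
  stopifnot(length(L) == length(W))
  if (any(L <= 0 | W <= 0)) stop("diameters must be positive", call. = FALSE)
  sw <- W > L
  if (any(sw)) {
    warning(sum(sw), " diameter pair(s) had W > L; auto-ordered")
    tmp <- L[sw]; L[sw] <- W[sw]; W[sw] <- tmp
  }
  L * W^2 / 2
}

#' Tumor growth inhibition rate
#'
#' `TGI = (1 - mean(V_treated) / mean(V_vehicle)) x 100`, on absolute
#' volumes at the comparison day.
#'
#' @param treated numeric vector of treated-group tumor volumes.
#' @param vehicle numeric vector of vehicle-group tumor volumes.
#' @return percent TGI.
#' @export
tgi <- function(treated, vehicle) {
  mv <- mean(vehicle)
  if (mv == 0) stop("vehicle mean volume is zero", call. = FALSE)
  (1 - mean(treated) / mv) * 100
}

#' Dunnett many-to-one comparisons
#'
#' Two-sided Dunnett-adjusted p-values for comparing every treatment group
#' with the control, using the pooled equal-variance error and the
#' multivariate-t acceptance region with plug-in correlation
#' `rho_ij = lambda_i lambda_j`, `lambda_i = sqrt(n_i / (n_i + n_0))`
#' (0.5 for balanced designs). Probabilities are evaluated by
#' `mvtnorm::pmvt` to absolute tolerance 1e-5.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @param control label of the control group.
#' @return data.frame: group, estimate (difference vs control), t, p_adj,
#'   p_raw (unadjusted two-sided pooled-t p).
#' @export
dunnett <- function(values, groups, control) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!control %in% groups) stop("control group not present", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2)) stop("every group needs at least 2 observations", call. = FALSE)
  trt <- setdiff(names(tab), control)
  k <- length(trt)
  n0 <- tab[[control]]
  n <- length(values)
  means <- tapply(values, groups, mean)
  ss <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df <- n - length(tab)
  s2 <- ss / df
  ni <- as.numeric(tab[trt])
  est <- as.numeric(means[trt] - means[[control]])
  tstat <- est / sqrt(s2 * (1 / ni + 1 / n0))
  lam <- sqrt(ni / (ni + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_adj <- vapply(tstat, function(tt) {
    1 - mvtnorm::pmvt(lower = rep(-abs(tt), k), upper = rep(abs(tt), k),
                      df = df, corr = corr, sigma = NULL,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                     maxpts = 100000))[1]
  }, numeric(1))
  data.frame(group = trt, estimate = est, t = tstat,
             p_adj = pmin(1, pmax(0, p_adj)),
             p_raw = 2 * stats::pt(-abs(tstat), df),
             stringsAsFactors = FALSE)
}

#' Dunnett two-sided critical value
#'
#' Equicoordinate 1-alpha quantile of the |multivariate t| used by
#' [dunnett()]; exposed for power/type-I simulation work where computing
#' the critical value once is far cheaper than per-replicate adjusted
#' p-values.
#'
#' @param k number of treatment groups compared with control.
#' @param df pooled error degrees of freedom.
#' @param corr correlation matrix (default balanced equicorrelation 0.5).
#' @param alpha familywise error level, default 0.05.
#' @return critical |t| value.
#' @export
dunnett_crit <- function(k, df, corr = NULL, alpha = 0.05) {
  if (is.null(corr)) { corr <- matrix(0.5, k, k); diag(corr) <- 1 }
  mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = corr,
                algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                               maxpts = 100000))$quantile
}

#' Linear dose-trend test on final-day tumor volumes
#'
#' Ordinary least-squares regression of volume on dose across the treated
#' groups, with the two-sided p-value of the slope.
#'
#' @param volumes numeric tumor volumes.
#' @param doses numeric doses (mg/kg), same length; include treated groups
#'   only.
#' @return list: slope, intercept, p, n.
#' @export
dose_trend <- function(volumes, doses) {
  stopifnot(length(volumes) == length(doses))
  if (length(unique(doses)) < 2)
    stop("need at least two dose levels", call. = FALSE)
  fit <- stats::lm(volumes ~ doses)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  p <- sm$coefficients["doses", "Pr(>|t|)"]
  if (!is.finite(p)) {
    # zero residual variance: an exact fit has p at the machine floor,
    # an exactly constant response carries no evidence against slope 0
    p <- if (abs(slope) > sqrt(.Machine$double.eps)) 0 else 1
  }
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       p = p,
       n = length(volumes))
}

#' Pharmacodynamic target inhibition from stimulated/unstimulated MFI
#'
#' Excludes animals whose dead-cell (7-AAD-positive) rate exceeds
#' `dead_cutoff` percent (strictly), computes the per-animal signal as
#' `MFI_stimulated - MFI_unstimulated`, and reports per-group percent
#' inhibition of the mean signal relative to the control group.
#'
#' @param records data.frame with columns `group`, `mfi_stimulated`,
#'   `mfi_unstimulated`, `dead_pct`.
#' @param control label of the control (vehicle) group.
#' @param dead_cutoff viability exclusion threshold, percent (default 30).
#' @return data.frame: group, n_used, n_excluded, mean_signal,
#'   inhibition_pct (0 for the control group by construction).
#' @export
pd_inhibition <- function(records, control, dead_cutoff = 30) {
  need <- c("group", "mfi_stimulated", "mfi_unstimulated", "dead_pct")
  stopifnot(all(need %in% names(records)))
  keep <- records$dead_pct <= dead_cutoff
  used <- records[keep, , drop = FALSE]
  if (!control %in% used$group)
    stop("all control records excluded by the viability cutoff", call. = FALSE)
  used$signal <- used$mfi_stimulated - used$mfi_unstimulated
  grp <- unique(records$group)
  mean_sig <- vapply(grp, function(g) mean(used$signal[used$group == g]),
                     numeric(1))
  ctrl_mean <- mean_sig[[match(control, grp)]]
  data.frame(group = grp,
             n_used = vapply(grp, function(g) sum(used$group == g), numeric(1)),
             n_excluded = vapply(grp, function(g)
               sum(records$group == g) - sum(used$group == g), numeric(1)),
             mean_signal = mean_sig,
             inhibition_pct = (1 - mean_sig / ctrl_mean) * 100,
             stringsAsFactors = FALSE, row.names = NULL)
}
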