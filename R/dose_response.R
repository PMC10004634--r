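#' Percent inhibition from plate controls
#'
#' `inhibition (%) = [1 - (A - B) / (C - B)] x 100`, where `A` is the
#' response with compound, `B` the background response with no enzyme, and
#' `C` the vehicle response. Values outside [0, 100] are possible and
#' returned as-is.
#'
#' @param A response with compound (vectorized).
#' @param B background response (no kinase).
#' @param C vehicle response.
#' @return percent inhibition.
#' @export
percent_inhibition <- function(A, B, C) {
  if (any(C == B)) stop("undefined: vehicle response equals background (C = B)",
                        call. = FALSE)
  (1 - (A - B) / (C - B)) * 100
}

.logistic_models <- c("4PL", "2PL", "sigmoid_Emax")

#' Fit a logistic concentration-response model
#'
#' Least-squares fit of response on log10 concentration by
#' Levenberg-Marquardt. Three parameterizations are supported:
#' \describe{
#'   \item{4PL}{`bottom + (top - bottom) / (1 + 10^(hill (logIC50 - logc)))`
#'     with all four parameters free.}
#'   \item{2PL}{top fixed at 100 and bottom at 0; IC50 and hill free.}
#'   \item{sigmoid_Emax}{bottom fixed at 0; Emax (top), EC50 and hill free.}
#' }
#' Vehicle rows (concentration 0) are not placed at log10(0); they enter the
#' least squares as observations of the bottom asymptote. The 95% CI for
#' IC50 is computed on the log10 scale from the fit covariance (t quantile,
#' residual df) and back-transformed.
#'
#' @param data data.frame with columns `concentration` (nM, 0 = vehicle)
#'   and `response`.
#' @param model one of `"4PL"`, `"2PL"`, `"sigmoid_Emax"`.
#' @param ci compute a 95% confidence interval for IC50.
#' @return object of class `logistic_fit`: `model`, `ic50_nM`, `ci95`,
#'   `hill`, `top`, `bottom`, `converged`, `hill_positive`, `extrapolated`,
#'   `fit` (the underlying nls object or NULL).
#' @export
fit_logistic <- function(data, model = c("4PL", "2PL", "sigmoid_Emax"),
                         ci = TRUE) {
  model <- match.arg(model)
  stopifnot(all(c("concentration", "response") %in% names(data)))
  conc <- data$concentration
  y <- data$response
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  n_par <- switch(model, "4PL" = 4L, "2PL" = 2L, "sigmoid_Emax" = 3L)
  if (length(unique(conc)) < n_par)
    stop(sprintf("%s needs at least %d distinct concentrations", model, n_par),
         call. = FALSE)
  lc <- ifelse(conc > 0, log10(conc), NA_real_)
  pos <- conc > 0

  # midpoint start for logIC50: concentration whose response is nearest the
  # half-way response
  ymid <- (max(y) + min(y)) / 2
  l_start <- lc[pos][which.min(abs(y[pos] - ymid))]
  df <- data.frame(lc = lc, y = y, vehicle = !pos)

  pred4 <- function(lic50, hill, top, bottom, lc, vehicle)
    ifelse(vehicle, bottom,
           bottom + (top - bottom) / (1 + 10^(hill * (lic50 - lc))))

  fit <- tryCatch(switch(model,
    "4PL" = minpack.lm::nlsLM(
      y ~ pred4(lic50, hill, top, bottom, lc, vehicle), data = df,
      start = list(lic50 = l_start, hill = 1, top = max(y), bottom = min(y)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    "2PL" = minpack.lm::nlsLM(
      y ~ pred4(lic50, hill, 100, 0, lc, vehicle), data = df,
      start = list(lic50 = l_start, hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    "sigmoid_Emax" = minpack.lm::nlsLM(
      y ~ pred4(lic50, hill, emax, 0, lc, vehicle), data = df,
      start = list(lic50 = l_start, hill = 1, emax = max(y)),
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(model = model, ic50_nM = NA_real_,
                          ci95 = c(NA_real_, NA_real_), hill = NA_real_,
                          top = NA_real_, bottom = NA_real_,
                          converged = FALSE, hill_positive = NA,
                          extrapolated = NA, fit = NULL),
                     class = "logistic_fit"))
  }
  est <- stats::coef(fit)
  lic50 <- unname(est[["lic50"]])
  hill <- unname(est[["hill"]])
  top <- switch(model, "4PL" = unname(est[["top"]]), "2PL" = 100,
                "sigmoid_Emax" = unname(est[["emax"]]))
  bottom <- switch(model, "4PL" = unname(est[["bottom"]]), 0)
  ic50 <- 10^lic50
  ci95 <- c(NA_real_, NA_real_)
  if (ci) {
    se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["lic50"]],
                   error = function(e) NA_real_)
    dfree <- length(y) - n_par
    if (is.finite(se) && dfree > 0) {
      tq <- stats::qt(0.975, dfree)
      ci95 <- 10^(lic50 + c(-1, 1) * tq * se)
    }
  }
  hill_positive <- hill > 0
  if (!hill_positive)
    warning("fitted Hill slope is not positive: response decreases with concentration")
  span <- range(conc[pos])
  structure(list(model = model, ic50_nM = ic50, ci95 = ci95, hill = hill,
                 top = top, bottom = bottom, converged = TRUE,
                 hill_positive = hill_positive,
                 extrapolated = ic50 < span[1] || ic50 > span[2],
                 fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("%s fit: IC50 = %.4g nM (95%% CI %.4g-%.4g), hill = %.3g, top = %.3g, bottom = %.3g%s\n",
              x$model, x$ic50_nM, x$ci95[1], x$ci95[2], x$hill, x$top,
              x$bottom,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  invisible(x)
}

.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Parse a possibly censored IC50 cell
#'
#' Panel tables report out-of-range potencies as ">x" (e.g. ">10000").
#'
#' @param x character or numeric vector.
#' @return data.frame with `value` (numeric) and `censored` (logical).
#' @export
parse_censored <- function(x) {
  x <- as.character(x)
  cens <- grepl("^\\s*>", x)
  val <- suppressWarnings(as.numeric(sub("^\\s*>\\s*", "", x)))
  data.frame(value = val, censored = cens)
}

#' Fold selectivity of a kinase relative to the reference kinase
#'
#' `fold = IC50(kinase) / IC50(reference)`, formatted the way selectivity
#' panels print it: values >= 1 rounded half-up to an integer, sub-unit
#' values to one decimal, and a censored numerator ">x" propagated as
#' ">round(x/ref)". The unrounded float is always retained.
#'
#' @param ic50_kinase numeric, or a censored string such as `">10000"`.
#' @param ic50_ref reference-kinase IC50 (numeric, uncensored, > 0).
#' @return list of class `selectivity_entry`: `fold_raw` (numeric),
#'   `fold` (formatted string), `censored` (logical).
#' @export
selectivity_ratio <- function(ic50_kinase, ic50_ref) {
  if (!is.numeric(ic50_ref) || length(ic50_ref) != 1 || ic50_ref <= 0)
    stop("reference IC50 must be a positive uncensored number", call. = FALSE)
  pc <- parse_censored(ic50_kinase)
  if (is.na(pc$value)) stop("unparseable IC50: ", ic50_kinase, call. = FALSE)
  raw <- pc$value / ic50_ref
  fmt <- if (raw >= 1) {
    sprintf("%d", as.integer(.round_half_up(raw)))
  } else {
    sprintf("%.1f", .round_half_up(raw, 1))
  }
  if (pc$censored) fmt <- paste0(">", fmt)
  structure(list(fold_raw = raw, fold = fmt, censored = pc$censored),
            class = "selectivity_entry")
}

#' Selectivity folds for a whole kinase panel
#'
#' @param panel data.frame with columns `kinase` and one IC50 column per
#'   compound (character, ">"-censoring allowed).
#' @param reference name of the reference kinase (a row of `panel`).
#' @param compounds columns to process; defaults to all non-kinase columns.
#' @return data.frame: kinase plus, per compound, `<compound>_fold`
#'   (formatted string) and `<compound>_fold_raw`.
#' @export
selectivity_table <- function(panel, reference = "BTK", compounds = NULL) {
  stopifnot("kinase" %in% names(panel))
  if (!reference %in% panel$kinase)
    stop("reference kinase not found in panel: ", reference, call. = FALSE)
  if (is.null(compounds)) compounds <- setdiff(names(panel), "kinase")
  out <- data.frame(kinase = panel$kinase, stringsAsFactors = FALSE)
  for (cp in compounds) {
    ref_val <- parse_censored(panel[[cp]][panel$kinase == reference])
    if (ref_val$censored)
      stop("censored reference IC50 not supported for ", cp, call. = FALSE)
    entries <- lapply(panel[[cp]], selectivity_ratio, ic50_ref = ref_val$value)
    out[[paste0(cp, "_fold")]] <- vapply(entries, `[[`, character(1), "fold")
    out[[paste0(cp, "_fold_raw")]] <- vapply(entries, `[[`, numeric(1), "fold_raw")
  }
  out
}

#' Call hits from a competition-binding kinome screen
#'
#' Converts percent-control values to percent inhibition
#' (`100 - pct_ctrl`) and returns the kinases inhibited strictly more than
#' `inhibition_cutoff`, sorted by decreasing inhibition.
#'
#' @param records data.frame with columns `kinase` and `pct_ctrl`.
#' @param inhibition_cutoff percent, default 65.
#' @return data.frame: kinase, inhibition, sorted descending.
#' @export
kinome_hits <- function(records, inhibition_cutoff = 65) {
  stopifnot(all(c("kinase", "pct_ctrl") %in% names(records)))
  inh <- 100 - records$pct_ctrl
  hit <- inh > inhibition_cutoff
  out <- data.frame(kinase = records$kinase[hit], inhibition = inh[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$inhibition, out$kinase), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a BioMAP biomarker readout
#'
#' A readout is annotated when two or more consecutive concentrations change
#' in the same direction relative to vehicle, lie outside the significance
#' envelope, and at least one of those points has an effect size above
#' `effect_size` on the |log10 ratio| scale (0.1 = 20%). Antiproliferative
#' readouts require only a single qualifying point.
#'
#' @param log10_ratio numeric vector ordered by concentration.
#' @param outside_envelope logical vector, same length: point lies outside
#'   the historical-vehicle significance envelope.
#' @param antiproliferative logical flag for the one-point rule.
#' @param effect_size |log10 ratio| threshold, default 0.1.
#' @return logical: annotated or not.
#' @export
biomap_annotate <- function(log10_ratio, outside_envelope,
                            antiproliferative = FALSE, effect_size = 0.1) {
  stopifnot(length(log10_ratio) == length(outside_envelope))
  qualifying <- outside_envelope & abs(log10_ratio) > effect_size
  if (antiproliferative) return(any(qualifying))
  if (length(log10_ratio) < 2) return(FALSE)
  for (i in seq_len(length(log10_ratio) - 1L)) {
    pair <- c(i, i + 1L)
    same_dir <- sign(log10_ratio[i]) == sign(log10_ratio[i + 1L]) &&
      sign(log10_ratio[i]) != 0
    if (same_dir && all(outside_envelope[pair]) && any(qualifying[pair]))
      return(TRUE)
  }
  FALSE
}
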