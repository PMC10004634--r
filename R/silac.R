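#' Filter phosphosites to class-I quality
#'
#' Retains only serine, threonine, or tyrosine assignments with a
#' localization probability at or above `min_prob` (boundary inclusive).
#' This is the standard class-I criterion applied to MaxQuant site exports
#' before any quantitative analysis.
#'
#' @param records a phosphosite data.frame (see [gen_silac_dataset()] or
#'   [read_phosphosite_table()]) with columns `residue` and
#'   `localization_prob`.
#' @param min_prob minimum localization probability, default 0.75.
#' @return the subset of `records` passing the filter, order preserved.
#' @export
filter_class1 <- function(records, min_prob = 0.75) {
  stopifnot(is.data.frame(records),
            all(c("residue", "localization_prob") %in% names(records)))
  keep <- records$residue %in% c("S", "T", "Y") &
    !is.na(records$localization_prob) &
    records$localization_prob >= min_prob
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Put both replicate ratios on the treatment/control scale
#'
#' In a label-swap replicate design, experiment 2's raw heavy/light ratio is
#' the reciprocal of its treatment/control ratio and must be inverted before
#' the two replicates can be compared. The operation consults the
#' `rep2_swapped` attribute set by the reader/generator (overridable via
#' `swapped`) and records completion in a `harmonized` attribute, making it
#' idempotent: harmonizing twice equals harmonizing once.
#'
#' @param records phosphosite data.frame with `ratio_rep1`, `ratio_rep2`.
#' @param swapped whether replicate 2 is stored as the raw swapped H/L
#'   ratio; defaults to the `rep2_swapped` attribute (or `FALSE` if unset).
#' @return `records` with `ratio_rep2` on the treatment/control scale and
#'   `harmonized` attribute set.
#' @export
harmonize_label_swap <- function(records,
                                 swapped = isTRUE(attr(records, "rep2_swapped"))) {
  stopifnot(is.data.frame(records), "ratio_rep2" %in% names(records))
  if (isTRUE(attr(records, "harmonized"))) return(records)
  if (any(records$ratio_rep2 <= 0, na.rm = TRUE))
    stop("raw heavy/light ratios must be strictly positive", call. = FALSE)
  if (swapped) records$ratio_rep2 <- 1 / records$ratio_rep2
  attr(records, "harmonized") <- TRUE
  records
}

#' Fit an empirical Gaussian null to the phosphosite ratio distribution
#'
#' Histograms the log2-transformed ratios and fits a three-parameter
#' Gaussian (amplitude, mu, sigma) to the bin counts by unweighted least
#' squares, mirroring a "Gaussian regression on the histogram" workflow.
#' Two samples can be fitted: `pooled_single_ratios` (the default) pools the
#' log2 treatment/control ratios of both replicates — the scale on which
#' regulation thresholds are applied — while `ratio_of_ratios` uses
#' `log2(rep1/rep2)` per site, a replicate-agreement diagnostic whose sd is
#' sqrt(2) times the per-replicate noise component.
#'
#' @param records harmonized phosphosite data.frame.
#' @param mode `"pooled_single_ratios"` or `"ratio_of_ratios"`.
#' @param n_bins number of histogram bins, or `NULL` for Freedman-Diaconis.
#' @return object of class `gaussian_null`: `mu_log2`, `sigma_log2`,
#'   `mode`, `n_bins`, `fit_rss`, `n_sites`.
#' @export
fit_gaussian_null <- function(records,
                              mode = c("pooled_single_ratios", "ratio_of_ratios"),
                              n_bins = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records),
            all(c("ratio_rep1", "ratio_rep2") %in% names(records)))
  if (!isTRUE(attr(records, "harmonized")))
    warning("records not marked harmonized; fitting ratios as-is")
  both <- !is.na(records$ratio_rep1) & !is.na(records$ratio_rep2)
  if (sum(both) < 100)
    stop("need at least 100 sites with both replicate ratios", call. = FALSE)
  r1 <- log2(records$ratio_rep1[both])
  r2 <- log2(records$ratio_rep2[both])
  x <- switch(mode,
              pooled_single_ratios = c(r1, r2),
              ratio_of_ratios = r1 - r2)
  if (stats::sd(x) < 1e-12) stop("degenerate sample: zero variance", call. = FALSE)

  if (is.null(n_bins)) n_bins <- grDevices::nclass.FD(x)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)

  start <- list(A = max(df$count), mu = mean(x), sigma = stats::sd(x))
  fit <- minpack.lm::nlsLM(
    count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)),
    data = df, start = start,
    lower = c(A = 0, mu = -Inf, sigma = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  if (!is.finite(est[["sigma"]]) || est[["sigma"]] <= 0)
    stop("Gaussian fit did not converge to a positive sigma", call. = FALSE)
  structure(list(mu_log2 = unname(est[["mu"]]),
                 sigma_log2 = unname(abs(est[["sigma"]])),
                 mode = mode,
                 n_bins = n_bins,
                 fit_rss = sum(stats::resid(fit)^2),
                 n_sites = sum(both)),
            class = "gaussian_null")
}

#' @export
print.gaussian_null <- function(x, ...) {
  cat(sprintf("Empirical Gaussian null (%s): mu_log2 = %.4f, sigma_log2 = %.4f (n = %d sites, %d bins)\n",
              x$mode, x$mu_log2, x$sigma_log2, x$n_sites, x$n_bins))
  invisible(x)
}

#' Derive regulation ratio thresholds from a fitted null
#'
#' Up/down thresholds at `k` standard deviations on the log2 scale:
#' `up_thr = 2^(mu + k sigma)`, `down_thr = 2^(mu - k sigma)`. With the
#' default `k = 2.5` and a centred null of sigma 0.2233, this gives the
#' familiar 1.472 / 0.679 ratio cutoffs.
#'
#' @param null a `gaussian_null` object (or a list with `mu_log2`,
#'   `sigma_log2`).
#' @param k sigma multiplier, default 2.5 (> 0).
#' @return object of class `threshold_set`: `k`, `up_thr`, `down_thr`,
#'   `mu_log2`, `sigma_log2`.
#' @export
derive_thresholds <- function(null, k = 2.5) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  stopifnot(is.numeric(null$mu_log2), is.numeric(null$sigma_log2))
  structure(list(k = k,
                 up_thr = 2^(null$mu_log2 + k * null$sigma_log2),
                 down_thr = 2^(null$mu_log2 - k * null$sigma_log2),
                 mu_log2 = null$mu_log2,
                 sigma_log2 = null$sigma_log2),
            class = "threshold_set")
}

#' Construct a threshold set from explicit ratio cutoffs
#'
#' Convenience constructor for applying published cutoffs directly.
#'
#' @param up_thr up-regulation ratio threshold (> 1).
#' @param down_thr down-regulation ratio threshold (in (0, 1)).
#' @return `threshold_set` object.
#' @export
threshold_set <- function(up_thr, down_thr) {
  stopifnot(up_thr > 1, down_thr > 0, down_thr < 1)
  mu <- (log2(up_thr) + log2(down_thr)) / 2
  structure(list(k = NA_real_, up_thr = up_thr, down_thr = down_thr,
                 mu_log2 = mu, sigma_log2 = NA_real_),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Regulation thresholds: up > %.3f, down < %.3f%s\n",
              x$up_thr, x$down_thr,
              if (is.na(x$k)) "" else sprintf(" (k = %g sigma)", x$k)))
  invisible(x)
}

#' Call regulated phosphosites with dual-replicate consistency
#'
#' A site is called `down` iff both replicate ratios are strictly below the
#' down threshold, `up` iff both are strictly above the up threshold, and
#' `unchanged` otherwise — including discordant directions and sites with a
#' missing replicate, which can never be called regulated.
#'
#' @param records harmonized phosphosite data.frame.
#' @param thresholds a `threshold_set`.
#' @return data.frame of class `regulation_calls`: gene, position, residue,
#'   ratio_rep1, ratio_rep2, direction (factor up/down/unchanged).
#' @export
call_regulation <- function(records, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"),
            all(c("ratio_rep1", "ratio_rep2") %in% names(records)))
  if (!isTRUE(attr(records, "harmonized")))
    warning("records not marked harmonized; calling on ratios as-is")
  r1 <- records$ratio_rep1
  r2 <- records$ratio_rep2
  up <- !is.na(r1) & !is.na(r2) & r1 > thresholds$up_thr & r2 > thresholds$up_thr
  down <- !is.na(r1) & !is.na(r2) & r1 < thresholds$down_thr & r2 < thresholds$down_thr
  out <- data.frame(
    gene = if ("gene" %in% names(records)) records$gene else NA_character_,
    position = if ("position" %in% names(records)) records$position else NA_integer_,
    residue = if ("residue" %in% names(records)) records$residue else NA_character_,
    ratio_rep1 = r1, ratio_rep2 = r2,
    direction = factor(ifelse(up, "up", ifelse(down, "down", "unchanged")),
                       levels = c("up", "down", "unchanged")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Summarize regulation calls
#'
#' Counts regulated sites and distinct proteins (keyed by gene symbol) per
#' direction, with percentages of all quantified sites rounded to one
#' decimal.
#'
#' @param calls a `regulation_calls` data.frame.
#' @param n_quantified total number of quantified sites the percentages
#'   refer to (defaults to `nrow(calls)`).
#' @return list of class `regulation_summary`: `n_up_sites`,
#'   `n_up_proteins`, `n_down_sites`, `n_down_proteins`, `pct_up`,
#'   `pct_down`, `n_quantified`.
#' @export
summarize_regulation <- function(calls, n_quantified = nrow(calls)) {
  stopifnot(is.data.frame(calls), "direction" %in% names(calls))
  if (n_quantified <= 0) stop("n_quantified must be positive", call. = FALSE)
  up <- calls[calls$direction == "up", , drop = FALSE]
  down <- calls[calls$direction == "down", , drop = FALSE]
  structure(list(
    n_up_sites = nrow(up),
    n_up_proteins = length(unique(up$gene)),
    n_down_sites = nrow(down),
    n_down_proteins = length(unique(down$gene)),
    pct_up = round(100 * nrow(up) / n_quantified, 1),
    pct_down = round(100 * nrow(down) / n_quantified, 1),
    n_quantified = n_quantified
  ), class = "regulation_summary")
}

#' @export
print.regulation_summary <- function(x, ...) {
  cat(sprintf("Down: %d sites / %d proteins (%.1f%%); Up: %d sites / %d proteins (%.1f%%) of %d quantified\n",
              x$n_down_sites, x$n_down_proteins, x$pct_down,
              x$n_up_sites, x$n_up_proteins, x$pct_up, x$n_quantified))
  invisible(x)
}

#' Ser/Thr/Tyr residue composition of a site collection
#'
#' @param records class-I-filtered phosphosite data.frame with a `residue`
#'   column.
#' @return named numeric vector (S, T, Y) of percentages rounded to one
#'   decimal; sums to 100 within rounding.
#' @export
residue_composition <- function(records) {
  stopifnot(is.data.frame(records), "residue" %in% names(records))
  if (nrow(records) == 0) stop("empty record collection", call. = FALSE)
  n <- nrow(records)
  c(S = round(100 * sum(records$residue == "S") / n, 1),
    T = round(100 * sum(records$residue == "T") / n, 1),
    Y = round(100 * sum(records$residue == "Y") / n, 1))
}

#' Sites regulated in the same direction in two call sets
#'
#' Intersects two regulation-call tables on the (gene, position, residue)
#' site key, keeping sites with the requested direction in both.
#'
#' @param calls_a,calls_b `regulation_calls` data.frames.
#' @param direction `"down"` or `"up"`.
#' @return data.frame of shared site keys (gene, position, residue).
#' @export
overlap_regulated <- function(calls_a, calls_b, direction = c("down", "up")) {
  direction <- match.arg(direction)
  key <- function(d) {
    d <- d[d$direction == direction, , drop = FALSE]
    paste(d$gene, d$position, d$residue, sep = "|")
  }
  shared <- intersect(key(calls_a), key(calls_b))
  if (length(shared) == 0)
    return(data.frame(gene = character(), position = integer(),
                      residue = character(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(shared, "|", fixed = TRUE))
  data.frame(gene = parts[, 1], position = as.integer(parts[, 2]),
             residue = parts[, 3], stringsAsFactors = FALSE)
}
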