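#' 75th-percentile normalization of an expression matrix
#'
#' Scales every sample (column) so that its 75th percentile equals the
#' cohort reference value, taken as the geometric mean of the per-sample
#' 75th percentiles. Idempotent and invariant to per-sample rescaling.
#'
#' @param matrix numeric matrix, probes x samples, strictly positive
#'   linear-scale intensities.
#' @return normalized matrix of the same dimensions.
#' @export
normalize_75th <- function(matrix) {
  if (any(matrix <= 0)) stop("intensities must be strictly positive", call. = FALSE)
  q75 <- apply(matrix, 2, stats::quantile, probs = 0.75, names = FALSE)
  target <- exp(mean(log(q75)))
  sweep(matrix, 2, target / q75, `*`)
}

#' Welch differential expression on log2 intensities
#'
#' Per-probe Welch (unequal-variance) t-test of log2-transformed values
#' between two groups, with fold change reported as the ratio of
#' linear-scale geometric means (treated/vehicle) and Benjamini-Hochberg
#' q-values across all probes. The test statistics are computed from the
#' closed-form Welch formula with Satterthwaite degrees of freedom,
#' vectorized over probes.
#'
#' @param matrix probes x samples matrix of positive linear-scale values.
#' @param groups character/factor of length `ncol(matrix)` with exactly two
#'   levels.
#' @param treated label of the treated group; the other label is the
#'   reference (vehicle).
#' @return data.frame of class `de_result`: probe, fold_change, log2_fc,
#'   t, df, p, q.
#' @export
welch_de <- function(matrix, groups, treated = "treated") {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(matrix))
  lv <- unique(groups)
  if (length(lv) != 2 || !treated %in% lv)
    stop("groups must have exactly two labels including the treated label",
         call. = FALSE)
  ref <- setdiff(lv, treated)
  it <- groups == treated
  iv <- groups == ref
  if (sum(it) < 2 || sum(iv) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  lx <- log2(matrix)
  m1 <- rowMeans(lx[, it, drop = FALSE]); n1 <- sum(it)
  m0 <- rowMeans(lx[, iv, drop = FALSE]); n0 <- sum(iv)
  v1 <- apply(lx[, it, drop = FALSE], 1, stats::var)
  v0 <- apply(lx[, iv, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[is.nan(p)] <- 1  # zero-variance, zero-difference probes
  out <- data.frame(
    probe = if (is.null(rownames(matrix))) sprintf("probe_%d", seq_len(nrow(matrix)))
            else rownames(matrix),
    fold_change = 2^(m1 - m0),
    log2_fc = m1 - m0,
    t = t, df = df, p = p,
    q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Classify probes as up/down regulated
#'
#' Strict thresholds: up iff `fold_change > fc_hi` and `p < p_max`; down iff
#' `fold_change < fc_lo` and `p < p_max`.
#'
#' @param de a `de_result` data.frame from [welch_de()].
#' @param fc_hi,fc_lo fold-change cutoffs (defaults 2 and 0.5).
#' @param p_max nominal p cutoff (default 0.01).
#' @return list with character vectors `up` and `down` of probe ids.
#' @export
classify_de <- function(de, fc_hi = 2, fc_lo = 0.5, p_max = 0.01) {
  stopifnot(all(c("probe", "fold_change", "p") %in% names(de)))
  list(up = de$probe[de$fold_change > fc_hi & de$p < p_max],
       down = de$probe[de$fold_change < fc_lo & de$p < p_max])
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per group,
#' `ddCt = mean dCt(group) - mean dCt(control)`; fold change = `2^-ddCt`.
#'
#' @param records data.frame with columns `sample`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param control_group label of the calibrator group.
#' @return data.frame: group, mean_dct, ddct, fold.
#' @export
ddct <- function(records, control_group) {
  stopifnot(all(c("group", "ct_target", "ct_reference") %in% names(records)))
  if (!control_group %in% records$group)
    stop("control group not present: ", control_group, call. = FALSE)
  if (any(!is.finite(records$ct_reference)))
    stop("missing reference Ct values", call. = FALSE)
  dct <- records$ct_target - records$ct_reference
  mean_dct <- tapply(dct, records$group, mean)
  dd <- mean_dct - mean_dct[[control_group]]
  data.frame(group = names(mean_dct),
             mean_dct = as.numeric(mean_dct),
             ddct = as.numeric(dd),
             fold = 2^(-as.numeric(dd)),
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list: the running sum increments by
#' `|metric|^p / NR` at set members (NR = sum of member weights) and
#' decrements by `1 / (N - Nh)` at non-members; the enrichment score is the
#' extremum of the running sum (the signed value of largest magnitude).
#'
#' @param metric named numeric vector of ranking-metric values; sorted
#'   internally in decreasing order.
#' @param set character vector of member gene ids (must intersect, and not
#'   exhaust, the list).
#' @param p weight exponent, default 1 (0 gives the classic KS statistic).
#' @return list of class `enrichment_profile`: `es`, `running` (numeric
#'   vector along the ranked list), `hits` (logical along the list),
#'   `ranked_genes`.
#' @export
enrichment_score <- function(metric, set, p = 1) {
  stopifnot(!is.null(names(metric)))
  ord <- order(metric, decreasing = TRUE)
  r <- metric[ord]
  genes <- names(r)
  hit <- genes %in% set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no member in the ranked list", call. = FALSE)
  if (nh == length(genes))
    stop("gene set covers the whole list; complement is empty", call. = FALSE)
  w <- abs(r)^p
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / (length(genes) - nh))
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  structure(list(es = unname(es), running = unname(running), hits = hit,
                 ranked_genes = genes),
            class = "enrichment_profile")
}

# O(Nh log Nh) enrichment score from hit positions in a ranked list of
# length n with weights w_all (|metric|^p along the ranked list). Used by
# the permutation engine; equals the full running-sum extremum.
.es_from_positions <- function(idx, w_all, n) {
  idx <- sort(idx)
  nh <- length(idx)
  wh <- w_all[idx]
  nr <- sum(wh)
  miss_step <- 1 / (n - nh)
  chit <- cumsum(wh) / nr
  # extrema occur at hit positions (local maxima) or just before them
  # (local minima); the running sum returns to 0 at the end of the list
  at_hit <- chit - (idx - seq_len(nh)) * miss_step
  before_hit <- c(0, chit[-nh]) - (idx - seq_len(nh)) * miss_step
  cand <- c(at_hit, before_hit)
  unname(cand[which.max(abs(cand))])
}

#' Signal-to-noise ranking metric
#'
#' `(mean_treated - mean_ref) / (sd_treated + sd_ref)` on log2 values, with
#' each sd floored at `0.2 * |mean|` of its group (and at `min_sd` when the
#' mean is near zero), the conventional GSEA variance floor.
#'
#' @param matrix probes x samples positive matrix (linear scale).
#' @param groups two-level group labels.
#' @param treated treated-group label.
#' @param min_sd absolute sd floor, default 0.2.
#' @return named numeric vector of signal-to-noise values per probe.
#' @export
signal_to_noise <- function(matrix, groups, treated = "treated",
                            min_sd = 0.2) {
  groups <- as.character(groups)
  ref <- setdiff(unique(groups), treated)
  stopifnot(length(ref) == 1)
  lx <- log2(matrix)
  it <- groups == treated
  iv <- groups == ref
  m1 <- rowMeans(lx[, it, drop = FALSE])
  m0 <- rowMeans(lx[, iv, drop = FALSE])
  s1 <- apply(lx[, it, drop = FALSE], 1, stats::sd)
  s0 <- apply(lx[, iv, drop = FALSE], 1, stats::sd)
  floor_sd <- function(s, m) pmax(s, pmax(0.2 * abs(m), min_sd))
  s1 <- floor_sd(s1, m1)
  s0 <- floor_sd(s0, m0)
  s2n <- (m1 - m0) / (s1 + s0)
  names(s2n) <- if (is.null(rownames(matrix)))
    sprintf("probe_%d", seq_len(nrow(matrix))) else rownames(matrix)
  s2n
}

#' GSEA with gene-wise permutation
#'
#' Ranks genes by signal-to-noise between the two groups, computes the
#' weighted KS enrichment score per set, and builds the null by gene-wise
#' permutation: for each permutation a random set of the same size is drawn
#' from the ranked list (equivalent to permuting gene labels). The
#' normalized enrichment score divides the observed ES by the mean |null
#' ES| of the same sign; the permutation p-value is the exceedance fraction
#' among same-sign nulls; FDR q follows the GSEA convention of comparing
#' pooled normalized null NES against observed NES, separately by sign.
#'
#' @param matrix probes x samples positive matrix.
#' @param groups two-level group labels.
#' @param sets named list of character vectors (gene sets).
#' @param n_perm number of permutations per set (default 1000, >= 1).
#' @param seed integer seed for the permutation draws.
#' @param treated treated-group label.
#' @param p weight exponent for the running sum, default 1.
#' @return data.frame of class `enrichment_results`: set, size, es, nes,
#'   p_perm, fdr_q, n_perm.
#' @export
gsea_genewise <- function(matrix, groups, sets, n_perm = 1000, seed = 1L,
                          treated = "treated", p = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (length(sets) == 0) stop("need at least one gene set", call. = FALSE)
  s2n <- signal_to_noise(matrix, groups, treated = treated)
  ord <- order(s2n, decreasing = TRUE)
  ranked <- s2n[ord]
  genes <- names(ranked)
  n <- length(genes)
  w_all <- abs(ranked)^p
  set.seed(seed)

  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], genes)
    nh <- length(members)
    if (nh == 0 || nh == n)
      stop("gene set '", nm, "' has empty overlap or empty complement",
           call. = FALSE)
    idx <- which(genes %in% members)
    es <- .es_from_positions(idx, w_all, n)
    null_es <- vapply(seq_len(n_perm), function(i)
      .es_from_positions(sample.int(n, nh), w_all, n), numeric(1))
    pos_mean <- if (any(null_es >= 0)) mean(null_es[null_es >= 0]) else mean(abs(null_es))
    neg_mean <- if (any(null_es < 0)) mean(abs(null_es[null_es < 0])) else mean(abs(null_es))
    # exceedance fraction among same-sign nulls (0 attainable, per the
    # usual GSEA convention)
    same <- null_es[sign(null_es) == sign(es)]
    p_perm <- if (length(same) == 0) 0
              else sum(abs(same) >= abs(es)) / length(same)
    denom <- if (es >= 0) pos_mean else neg_mean
    nes <- es / denom
    null_nes <- null_es / ifelse(null_es >= 0, pos_mean, neg_mean)
    list(set = nm, size = nh, es = es, nes = nes, p_perm = p_perm,
         null_nes = null_nes)
  })

  obs_nes <- vapply(res, `[[`, numeric(1), "nes")
  pooled_null <- unlist(lapply(res, `[[`, "null_nes"))
  fdr <- vapply(seq_along(res), function(i) {
    nes <- obs_nes[i]
    if (nes >= 0) {
      num <- mean(pooled_null[pooled_null >= 0] >= nes)
      den <- mean(obs_nes[obs_nes >= 0] >= nes)
    } else {
      num <- mean(pooled_null[pooled_null < 0] <= nes)
      den <- mean(obs_nes[obs_nes < 0] <= nes)
    }
    min(1, if (den > 0) num / den else 1)
  }, numeric(1))

  out <- data.frame(
    set = vapply(res, `[[`, character(1), "set"),
    size = vapply(res, `[[`, numeric(1), "size"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = obs_nes,
    p_perm = vapply(res, `[[`, numeric(1), "p_perm"),
    fdr_q = fdr,
    n_perm = n_perm,
    stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_results", "data.frame")
  out
}
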