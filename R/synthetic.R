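#' Configuration for a synthetic SILAC phosphoproteomics experiment
#'
#' Bundles the parameters of the two-replicate, label-swapped SILAC design
#' that the regulation-calling pipeline assumes. Defaults reproduce the
#' statistical structure of a deep DLBCL phosphoproteome run: a centred
#' Gaussian null for unregulated sites (single-replicate log2-ratio sd
#' 0.223, the value implied by published +/-2.5 sigma ratio thresholds of
#' about 1.47/0.68), a small regulated minority with a typical twofold
#' effect, and a Ser/Thr/Tyr residue composition of 84.6/14.4/1.0 percent.
#'
#' Replicate correlation is induced by a shared per-site deviation: each
#' replicate's null log2 ratio is `b + e_r` with `b ~ N(0, sigma_b)` and
#' `e_r ~ N(0, replicate_noise_log2)` independent per replicate, where
#' `sigma_b` is chosen so the marginal sd equals `null_sigma_log2`.
#' Consequently `replicate_noise_log2 < null_sigma_log2` is required.
#'
#' @param n_sites number of phosphosites to simulate (>= 1).
#' @param frac_regulated fraction of sites carrying a true effect, in [0, 1).
#' @param effect_log2 mean absolute log2 effect of regulated sites (> 0).
#' @param null_sigma_log2 marginal sd of a single replicate's null log2
#'   ratio (default 0.223).
#' @param replicate_noise_log2 sd of the independent per-replicate noise
#'   component; must be strictly smaller than `null_sigma_log2`.
#' @param sty_props length-3 vector of Ser/Thr/Tyr proportions summing to 1.
#' @param loc_prob_params list with elements `frac_low` (mass below 0.75)
#'   and beta shape pairs `hi` and `lo` for the high/low mixture components.
#' @param label_swap_rep2 if `TRUE` (default) replicate 2 is stored as the
#'   raw heavy/light ratio of the inverted labeling scheme, i.e. the
#'   reciprocal of its treatment/control ratio, as a label-swapped MaxQuant
#'   export would report it.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return an object of class `silac_sim_config` (a validated list).
#' @seealso [gen_silac_dataset()]
#' @export
silac_sim_config <- function(n_sites = 10000,
                             frac_regulated = 0.02,
                             effect_log2 = 1.0,
                             null_sigma_log2 = 0.223,
                             replicate_noise_log2 = 0.10,
                             sty_props = c(S = 0.846, T = 0.144, Y = 0.010),
                             loc_prob_params = list(frac_low = 0.15,
                                                    hi = c(12, 1),
                                                    lo = c(4, 4)),
                             label_swap_rep2 = TRUE,
                             seed = 1L) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1)
    stop("n_sites must be a positive count", call. = FALSE)
  if (frac_regulated < 0 || frac_regulated >= 1)
    stop("frac_regulated must lie in [0, 1)", call. = FALSE)
  if (effect_log2 <= 0) stop("effect_log2 must be positive", call. = FALSE)
  if (null_sigma_log2 <= 0) stop("null_sigma_log2 must be positive", call. = FALSE)
  if (replicate_noise_log2 < 0 || replicate_noise_log2 >= null_sigma_log2)
    stop("replicate_noise_log2 must lie in [0, null_sigma_log2)", call. = FALSE)
  if (length(sty_props) != 3L || any(sty_props < 0) ||
      abs(sum(sty_props) - 1) > 1e-9)
    stop("sty_props must be three nonnegative fractions summing to 1", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites),
                 frac_regulated = frac_regulated,
                 effect_log2 = effect_log2,
                 null_sigma_log2 = null_sigma_log2,
                 replicate_noise_log2 = replicate_noise_log2,
                 sty_props = sty_props,
                 loc_prob_params = loc_prob_params,
                 label_swap_rep2 = isTRUE(label_swap_rep2),
                 seed = as.integer(seed)),
            class = "silac_sim_config")
}

#' Simulate a two-replicate label-swapped SILAC phosphosite dataset
#'
#' Draws `n_sites` phosphosites. A `frac_regulated` minority receives a true
#' log2 effect of +/- `effect_log2` (random sign, shared by both replicates);
#' the remainder are null. Each replicate's observed log2 ratio adds a shared
#' per-site deviation and independent replicate noise (see
#' [silac_sim_config()]). When `label_swap_rep2` is set, replicate 2 is
#' reported as the reciprocal raw heavy/light ratio, so the dataset must be
#' passed through [harmonize_label_swap()] before regulation calling, exactly
#' as a swapped-label MaxQuant export would.
#'
#' @param config a [silac_sim_config()] object.
#' @return list with elements `records` (data.frame of class
#'   `phosphosite_records`: protein, gene, position, residue,
#'   sequence_window, localization_prob, ratio_rep1, ratio_rep2; attributes
#'   `rep2_swapped`, `harmonized`) and `truth` (data.frame with per-site
#'   `label` in up/down/null and `true_log2_effect`).
#' @export
gen_silac_dataset <- function(config) {
  stopifnot(inherits(config, "silac_sim_config"))
  n <- config$n_sites
  set.seed(config$seed)

  sigma_b <- sqrt(config$null_sigma_log2^2 - config$replicate_noise_log2^2)
  reg <- stats::runif(n) < config$frac_regulated
  sign_eff <- ifelse(stats::runif(n) < 0.5, -1, 1)
  true_eff <- ifelse(reg, sign_eff * config$effect_log2, 0)

  b <- stats::rnorm(n, 0, sigma_b)
  e1 <- stats::rnorm(n, 0, config$replicate_noise_log2)
  e2 <- stats::rnorm(n, 0, config$replicate_noise_log2)
  l2r1 <- true_eff + b + e1
  l2r2 <- true_eff + b + e2

  residue <- sample(c("S", "T", "Y"), n, replace = TRUE,
                    prob = config$sty_props)
  lp <- config$loc_prob_params
  low <- stats::runif(n) < lp$frac_low
  loc_prob <- ifelse(low,
                     0.75 * stats::rbeta(n, lp$lo[1], lp$lo[2]),
                     0.75 + 0.25 * stats::rbeta(n, lp$hi[1], lp$hi[2]))

  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","V","W")
  win_left  <- vapply(seq_len(n), function(i)
    paste(sample(aa, 6, replace = TRUE), collapse = ""), character(1))
  win_right <- vapply(seq_len(n), function(i)
    paste(sample(aa, 6, replace = TRUE), collapse = ""), character(1))

  ratio_rep1 <- 2^l2r1
  ratio_rep2 <- if (config$label_swap_rep2) 2^(-l2r2) else 2^l2r2

  # deep phosphoproteomes average just under two sites per protein
  gene_pool <- max(1L, ceiling(0.7 * n))
  gene_id <- sample.int(gene_pool, n, replace = TRUE)
  records <- data.frame(
    protein = sprintf("PROT%05d", gene_id),
    gene = sprintf("GENE%05d", gene_id),
    position = sample.int(2000L, n, replace = TRUE),
    residue = residue,
    sequence_window = paste0(win_left, residue, win_right),
    localization_prob = loc_prob,
    ratio_rep1 = ratio_rep1,
    ratio_rep2 = ratio_rep2,
    stringsAsFactors = FALSE
  )
  attr(records, "rep2_swapped") <- config$label_swap_rep2
  attr(records, "harmonized") <- !config$label_swap_rep2
  class(records) <- c("phosphosite_records", "data.frame")

  truth <- data.frame(
    gene = records$gene,
    position = records$position,
    residue = records$residue,
    label = ifelse(!reg, "null", ifelse(sign_eff > 0, "up", "down")),
    true_log2_effect = true_eff,
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Simulate four-parameter-logistic concentration-response data
#'
#' Generates percent-response readouts on a 4PL curve
#' `bottom + (top - bottom) / (1 + 10^(hill * (log10 IC50 - log10 c)))`
#' plus iid Gaussian noise. Concentration 0 encodes the vehicle group and is
#' generated at the bottom asymptote.
#'
#' @param ic50 true IC50 in nM (> 0).
#' @param hill Hill slope (positive for responses rising with concentration).
#' @param top,bottom asymptotes (response units, typically percent).
#' @param concs numeric vector of concentrations in nM (0 allowed = vehicle).
#' @param noise_sd sd of additive Gaussian noise, in response units.
#' @param n_rep replicates per concentration.
#' @param seed integer seed.
#' @return data.frame with columns `concentration`, `response`, `replicate`.
#' @export
gen_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                              concs = 10^seq(-1, 3, length.out = 8),
                              noise_sd = 0, n_rep = 1, seed = 1L) {
  if (ic50 <= 0) stop("ic50 must be positive", call. = FALSE)
  if (length(concs) == 0) stop("concs must be nonempty", call. = FALSE)
  set.seed(seed)
  conc <- rep(concs, each = n_rep)
  mu <- ifelse(conc == 0, bottom,
               bottom + (top - bottom) /
                 (1 + 10^(hill * (log10(ic50) - log10(conc)))))
  data.frame(concentration = conc,
             response = mu + stats::rnorm(length(conc), 0, noise_sd),
             replicate = rep(seq_len(n_rep), times = length(concs)))
}

#' Simulate a two-group expression matrix with planted differential probes
#'
#' Per-probe log2 intensities are Gaussian around probe-specific baselines;
#' the first `n_de` probes are shifted by `lfc` (alternating sign) in the
#' treated group. Values are returned on the linear scale, as a
#' normalized microarray matrix would be.
#'
#' @param n_probes number of probes.
#' @param n_per_group samples per group (vehicle and treated).
#' @param n_de number of differential probes (<= n_probes).
#' @param lfc absolute log2 fold change planted in treated samples.
#' @param sd_log2 per-probe residual sd on the log2 scale.
#' @param seed integer seed.
#' @return list: `matrix` (probes x samples, linear scale), `groups`
#'   (character vector "vehicle"/"treated"), `truth` (logical, planted DE),
#'   `true_lfc` (signed planted log2 effect).
#' @export
gen_expression <- function(n_probes = 2000, n_per_group = 8, n_de = 0,
                           lfc = 2, sd_log2 = 0.5, seed = 1L) {
  if (n_de > n_probes) stop("n_de must not exceed n_probes", call. = FALSE)
  set.seed(seed)
  n_s <- 2L * n_per_group
  base <- stats::runif(n_probes, 4, 12)
  m <- matrix(stats::rnorm(n_probes * n_s, 0, sd_log2), n_probes, n_s) + base
  groups <- rep(c("vehicle", "treated"), each = n_per_group)
  true_lfc <- numeric(n_probes)
  if (n_de > 0)
    true_lfc[seq_len(n_de)] <- lfc * rep_len(c(1, -1), n_de)
  m[, groups == "treated"] <- m[, groups == "treated"] + true_lfc
  mat <- 2^m
  rownames(mat) <- sprintf("probe_%05d", seq_len(n_probes))
  colnames(mat) <- sprintf("%s_%d", groups, rep(seq_len(n_per_group), 2))
  list(matrix = mat, groups = groups,
       truth = true_lfc != 0, true_lfc = true_lfc)
}

#' Simulate synthetic gene sets over a probe universe
#'
#' Random member draws, used to exercise GSEA machinery without any external
#' signature database.
#'
#' @param universe character vector of gene/probe ids.
#' @param n_sets number of sets.
#' @param set_size members per set (recycled).
#' @param seed integer seed.
#' @return named list of character vectors (a GMT-shaped structure).
#' @export
gen_gene_sets <- function(universe, n_sets = 20, set_size = 50, seed = 1L) {
  set.seed(seed)
  set_size <- rep_len(set_size, n_sets)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, set_size[i]))
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  sets
}

#' Simulate xenograft tumor growth under dose-dependent inhibition
#'
#' Mean tumor volume grows exponentially from a common baseline; each dose
#' group's growth rate is scaled by `1 - inhibition_frac`. Animal-level
#' heterogeneity is lognormal, with an additional lognormal measurement
#' component per day. Diameters are reported as (L, W) with `L >= W` solved
#' back from the volume convention `V = L * W^2 / 2` at a fixed aspect ratio.
#'
#' @param doses numeric vector of dose labels (mg/kg); 0 = vehicle.
#' @param inhibition_fracs per-dose growth-rate inhibition in [0, 1];
#'   same length as `doses`.
#' @param n_animals animals per group.
#' @param days measurement days (day 0 = baseline).
#' @param v0 baseline mean volume, mm^3.
#' @param growth_rate vehicle exponential growth rate per day.
#' @param animal_cv lognormal coefficient of variation between animals.
#' @param meas_cv lognormal measurement cv per observation.
#' @param seed integer seed.
#' @return data.frame: animal, group (dose), day, L, W, volume.
#' @export
gen_growth_curves <- function(doses = c(0, 1, 3, 10),
                              inhibition_fracs = c(0, 0.3, 0.6, 0.9),
                              n_animals = 10,
                              days = seq(0, 21, by = 3),
                              v0 = 150, growth_rate = 0.18,
                              animal_cv = 0.25, meas_cv = 0.10,
                              seed = 1L) {
  if (length(doses) != length(inhibition_fracs))
    stop("doses and inhibition_fracs must have the same length", call. = FALSE)
  set.seed(seed)
  aspect <- 1.5  # L / W
  out <- do.call(rbind, lapply(seq_along(doses), function(g) {
    rate <- growth_rate * (1 - inhibition_fracs[g])
    animal_eff <- stats::rlnorm(n_animals, -animal_cv^2 / 2, animal_cv)
    do.call(rbind, lapply(seq_len(n_animals), function(a) {
      mu <- v0 * animal_eff[a] * exp(rate * days)
      v <- mu * stats::rlnorm(length(days), -meas_cv^2 / 2, meas_cv)
      w <- (2 * v / aspect)^(1 / 3)
      data.frame(animal = sprintf("d%g_a%02d", doses[g], a),
                 group = doses[g], day = days,
                 L = aspect * w, W = w, volume = v)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Synthetic stand-in for a deep DLBCL SILAC phosphoproteome run
#'
#' Builds a label-swapped two-replicate phosphosite dataset at the scale and
#' calibration of a deep ABC-DLBCL cell-line experiment, for exercising the
#' full regulation-calling pipeline when the original site tables are not at
#' hand. This is a synthetic stand-in, not real data: the null sigma is the
#' value implied by the cell line's published +/-2.5 sigma ratio thresholds,
#' the quantified-site count and Ser/Thr/Tyr composition match the published
#' run, and a fixed number of true down-/up-regulated sites (twofold-plus
#' effects, ratios around 0.45) is planted so that the expected number of
#' *called* sites — true detections plus the Gaussian-tail false calls the
#' threshold rule admits — lands at the published counts. An additional
#' low-localization-probability block is appended so the class-I filter has
#' work to do.
#'
#' @param cell_line `"TMD8"` or `"U2932"`.
#' @param seed integer seed.
#' @return list: `records` (swapped-label phosphosite data.frame including
#'   the sub-class-I block), `planted` (data.frame of planted site keys and
#'   directions), `params` (the calibration used).
#' @export
silac_study_standin <- function(cell_line = c("TMD8", "U2932"), seed = 1L) {
  cell_line <- match.arg(cell_line)
  par <- switch(cell_line,
    TMD8  = list(n_quant = 9497, sigma = 0.2233, n_down = 130, n_up = 7,
                 sty = c(S = 0.846, T = 0.144, Y = 0.010)),
    U2932 = list(n_quant = 9740, sigma = 0.2363, n_down = 22, n_up = 0,
                 sty = c(S = 0.845, T = 0.148, Y = 0.007)))
  effect <- 1.1          # planted |log2| effect: ratios ~ 0.47 / 2.1
  rep_noise <- 0.15      # between-replicate component of the null sd
  set.seed(seed)
  n <- par$n_quant
  sigma_b <- sqrt(par$sigma^2 - rep_noise^2)

  true_eff <- numeric(n)
  planted_idx <- sample.int(n, par$n_down + par$n_up)
  true_eff[planted_idx[seq_len(par$n_down)]] <- -effect
  if (par$n_up > 0)
    true_eff[planted_idx[par$n_down + seq_len(par$n_up)]] <- effect

  b <- stats::rnorm(n, 0, sigma_b)
  l2r1 <- true_eff + b + stats::rnorm(n, 0, rep_noise)
  l2r2 <- true_eff + b + stats::rnorm(n, 0, rep_noise)

  n_low <- round(0.18 * n)  # sub-class-I block, dropped by the filter
  n_all <- n + n_low
  gene_id <- sample.int(ceiling(0.7 * n_all), n_all, replace = TRUE)
  residue <- sample(names(par$sty), n_all, replace = TRUE, prob = par$sty)
  loc_prob <- c(0.75 + 0.25 * stats::rbeta(n, 12, 1),
                0.75 * stats::rbeta(n_low, 4, 4))
  l2r1 <- c(l2r1, stats::rnorm(n_low, 0, par$sigma))
  l2r2 <- c(l2r2, stats::rnorm(n_low, 0, par$sigma))

  records <- data.frame(
    protein = sprintf("PROT%05d", gene_id),
    gene = sprintf("GENE%05d", gene_id),
    position = sample.int(2000L, n_all, replace = TRUE),
    residue = residue,
    sequence_window = "",
    localization_prob = loc_prob,
    ratio_rep1 = 2^l2r1,
    ratio_rep2 = 2^(-l2r2),   # raw swapped heavy/light
    stringsAsFactors = FALSE
  )
  attr(records, "rep2_swapped") <- TRUE
  attr(records, "harmonized") <- FALSE
  class(records) <- c("phosphosite_records", "data.frame")

  planted <- data.frame(
    gene = records$gene[planted_idx],
    position = records$position[planted_idx],
    residue = records$residue[planted_idx],
    direction = rep(c("down", "up"), c(par$n_down, par$n_up)),
    stringsAsFactors = FALSE
  )
  list(records = records, planted = planted,
       params = c(par, list(effect_log2 = effect,
                            replicate_noise_log2 = rep_noise)))
}
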