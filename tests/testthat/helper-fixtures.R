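# Shared fixtures: published-site tables shipped with the package, and the
# ratio thresholds they were called under.

extdata <- function(f) system.file("extdata", f, package = "phosreg")

thr_tmd8 <- threshold_set(up_thr = 1.472, down_thr = 0.679)
thr_u2932 <- threshold_set(up_thr = 1.506, down_thr = 0.664)

# Regulation-call tables for both cell lines from the shipped site tables
# (shared_down_sites: down in both lines; tmd8_down_sites: down in TMD8,
# with U-2932 ratios where measured, "-" when absent).
published_calls <- function() {
  shared <- read.delim(extdata("shared_down_sites.tsv"),
                       stringsAsFactors = FALSE)
  tmd8only <- read.delim(extdata("tmd8_down_sites.tsv"),
                         stringsAsFactors = FALSE, na.strings = c("-", "NA"))
  both <- rbind(shared, tmd8only)
  as_records <- function(r1, r2) {
    rec <- data.frame(gene = both$gene, position = both$position,
                      residue = both$residue,
                      ratio_rep1 = r1, ratio_rep2 = r2,
                      stringsAsFactors = FALSE)
    attr(rec, "harmonized") <- TRUE
    rec
  }
  list(
    tmd8 = call_regulation(as_records(both$tmd8_rep1, both$tmd8_rep2),
                           thr_tmd8),
    u2932 = call_regulation(as_records(both$u2932_rep1, both$u2932_rep2),
                            thr_u2932)
  )
}

# Brute-force per-site regulation oracle: direct comparison of each ratio
# to each threshold, one site at a time.
oracle_direction <- function(r1, r2, thr) {
  vapply(seq_along(r1), function(i) {
    a <- r1[i]; b <- r2[i]
    if (is.na(a) || is.na(b)) return("unchanged")
    if (a > thr$up_thr && b > thr$up_thr) return("up")
    if (a < thr$down_thr && b < thr$down_thr) return("down")
    "unchanged"
  }, character(1))
}

# Brute-force GSEA running-sum oracle: literal loop over the ranked list.
oracle_es <- function(metric, set, p = 1) {
  ord <- order(metric, decreasing = TRUE)
  r <- metric[ord]
  hit <- names(r) %in% set
  nr <- sum(abs(r[hit])^p)
  running <- numeric(length(r))
  cur <- 0
  for (i in seq_along(r)) {
    cur <- if (hit[i]) cur + abs(r[i])^p / nr
           else cur - 1 / (length(r) - sum(hit))
    running[i] <- cur
  }
  running[which.max(abs(running))]
}
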