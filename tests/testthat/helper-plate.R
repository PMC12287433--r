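# Shared fixtures: compact plate configurations and independent oracles.

# A desk-scale plate: 4 wells, 2 days, 2 positions, 64 px frames.
small_cfg <- function(..., seed = 101L) {
  plate_config(n_wells = 4, n_experiments = 2, acquisition_days = c(14, 38),
               positions_per_well = 2, image_height = 64, image_width = 64,
               seed = seed, ...)
}

# Brute-force pairwise-concordance AUC: the independent oracle for roc_auc.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Synthetic feature table for classifier/CV tests without rendering images:
# `n_wells` wells x `per_well` rows, `p` noise columns, with the first
# three columns shifted by `shift` for wells labeled positive.
toy_feature_table <- function(n_wells = 16, per_well = 4, p = 20,
                              shift = 1.5, seed = 1) {
  withr::with_seed(seed, {
    wells <- sprintf("W%02d", seq_len(n_wells))
    y_well <- rep(c(0, 1), length.out = n_wells)
    rows <- n_wells * per_well
    x <- matrix(rnorm(rows * p), rows, p)
    lab <- rep(y_well, each = per_well)
    x[lab == 1, 1:3] <- x[lab == 1, 1:3] + shift
    colnames(x) <- sprintf("shell_%03d", seq_len(p))
    feat <- data.frame(well_id = rep(wells, each = per_well),
                       day = 38L, x, check.names = FALSE)
    outcomes <- data.frame(well_id = wells,
                           myf5_pct = ifelse(y_well == 1, 25, 5))
    list(features = feat, outcomes = outcomes, labels = lab)
  })
}
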