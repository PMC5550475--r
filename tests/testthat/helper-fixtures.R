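# fixtures shared across test files; everything is built in code

# random valid site model: 1-3 dispersers plus the two non-dispersed
# pathways, random kernels and escape curve with interior probabilities
random_model <- function(seed) {
  set.seed(seed)
  n_disp <- sample(1:3, 1)
  labels <- c(paste0("d", seq_len(n_disp)), "spat_out", "undispersed")
  w <- rgamma(length(labels), 1) + 0.05
  p <- w / sum(w)
  pathways <- lapply(seq_along(labels), function(i) {
    kern <- if (labels[i] %in% c("spat_out", "undispersed")) {
      degenerate_kernel()
    } else {
      n_bins <- sample(2:15, 1)
      q <- rgamma(n_bins, 1)
      distance_kernel(q / sum(q))
    }
    seed_fate_pathway(labels[i], p[i], runif(1, 0.2, 0.9), kern)
  })
  site_recruitment_model(
    paste0("site", seed), pathways,
    new_escape_curve(runif(4, 0.1, 0.9))
  )
}

# the hand-arithmetic example: P = 0.5, G = 0.8, all kernel mass in the
# first class, T_1 = 0.25 -> 10%; plus a second pathway worth 5%
toy_15pct_model <- function() {
  site_recruitment_model("toy", list(
    seed_fate_pathway("a", 0.5, 0.8, degenerate_kernel()),
    seed_fate_pathway("b", 0.25, 0.8, degenerate_kernel()),
    seed_fate_pathway("undispersed", 0.25, 0, degenerate_kernel())
  ), new_escape_curve(c(0.25, 0.5, 0.5, 0.5)))
}

# balanced randomized-block layout with random responses
random_block_trials <- function(seed, t_n = NULL, b_n = NULL) {
  set.seed(seed)
  t_n <- t_n %||% sample(2:5, 1)
  b_n <- b_n %||% sample(2:8, 1)
  df <- expand.grid(treatment = paste0("tr", seq_len(t_n)),
                    block_id = paste0("b", seq_len(b_n)),
                    stringsAsFactors = FALSE)
  df$site <- "s"
  df$n_sown <- 5L
  df$n_germinated <- round(runif(nrow(df), 0, 5), 3)
  df
}

# brute-force sums-of-squares oracle for the randomized block design:
# explicit loops, no shared code with the implementation
rbd_oracle <- function(trials) {
  treatments <- sort(unique(trials$treatment))
  blocks <- sort(unique(trials$block_id))
  y <- outer(treatments, blocks, Vectorize(function(tr, bl) {
    trials$n_germinated[trials$treatment == tr & trials$block_id == bl]
  }))
  grand <- mean(y)
  ss_trt <- 0
  for (i in seq_along(treatments)) {
    ss_trt <- ss_trt + length(blocks) * (mean(y[i, ]) - grand)^2
  }
  ss_blk <- 0
  for (j in seq_along(blocks)) {
    ss_blk <- ss_blk + length(treatments) * (mean(y[, j]) - grand)^2
  }
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_trt - ss_blk
  df_t <- length(treatments) - 1
  df_e <- df_t * (length(blocks) - 1)
  f <- (ss_trt / df_t) / (ss_res / df_e)
  list(f = f, p = pf(f, df_t, df_e, lower.tail = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
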