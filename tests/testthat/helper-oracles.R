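# Independent oracles used across test files.

# O(n^2) brute force over every (threshold, direction) pair, thresholds
# taken as midpoints plus sentinels -- mirrors nothing of the package
# implementation beyond the strict-inequality contract.
oracle_best_cut <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             u[length(u)] + 1)
  best <- Inf
  for (th in cands) {
    for (dir in c("below", "above")) {
      pred <- if (dir == "below") as.integer(scores < th)
        else as.integer(scores > th)
      best <- min(best, sum(pred != labels))
    }
  }
  best
}

# pairwise-concordance AUC by explicit double loop, ties worth 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# a tiny validated cohort built by hand (all responses present)
tiny_cohort <- function(n = 4, seed = 99) {
  set.seed(seed)
  sp <- instrument_specs()
  responses <- lapply(seq_len(nrow(sp)), function(i)
    matrix(rbinom(n * sp$n_items[i], 1, 0.7), n, sp$n_items[i]))
  names(responses) <- sp$name
  patients <- data.frame(
    patient_id = paste0("T", seq_len(n)),
    impaired = rep_len(c(0L, 1L), n), age = sample(67:93, n, TRUE),
    gender = rep_len(c("F", "M"), n), race = rep_len(c("W", "B"), n),
    income = rep_len(c("8", "D"), n), education = rep_len(c("9", "777"), n),
    stringsAsFactors = FALSE)
  rt <- data.frame(DCCS = runif(n, 20, 60), PSM = runif(n, 40, 120),
                   ARW = runif(n, 35, 70))
  cog_cohort(patients, responses, rt)
}
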