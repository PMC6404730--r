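# Shared fixtures and independent oracles.

BASES <- c("A", "C", "G", "T")

# Minimal model with unit calibrations (a = 0, b = 1): calibrated step
# estimates equal the raw terms, so expectations can be hand-computed.
toy_config <- function(window_length = 4L) {
  pwm <- matrix(0, 4L, window_length, dimnames = list(BASES, NULL))
  cons <- rep_len(c("T", "A"), window_length)
  pwm[cbind(match(cons, BASES), seq_len(window_length))] <- 2
  dinucs <- sort(as.vector(outer(BASES, BASES, paste0)))
  slide <- stats::setNames(rep(1, 16), dinucs)
  slide[c("TA", "AT")] <- c(2, 1.5)
  bend <- stats::setNames(rep(0.5, 16), dinucs)
  bend["TA"] <- 1
  calib <- matrix(c(0, 0, 0, 1, 1, 1), 3L, 2L,
                  dimnames = list(c("stop", "slide", "bend"), c("a", "b")))
  model_config(pwm = pwm, slide = slide, bend = bend, calibration = calib,
               window_length = window_length)
}

# A model whose three step terms are identically zero everywhere, so the
# three partial estimates always coincide and delta must be exactly 0.
degenerate_config <- function(window_length = 4L) {
  pwm <- matrix(0, 4L, window_length, dimnames = list(BASES, NULL))
  dinucs <- sort(as.vector(outer(BASES, BASES, paste0)))
  zeros <- stats::setNames(rep(0, 16), dinucs)
  calib <- matrix(c(0, 0, 0, 1, 1, 1), 3L, 2L,
                  dimnames = list(c("stop", "slide", "bend"), c("a", "b")))
  model_config(pwm = pwm, slide = zeros, bend = zeros, calibration = calib,
               window_length = window_length)
}

# Brute-force window enumeration, built only from the exported single-window
# operations; independent of the vectorized scanning path.
naive_affinity <- function(sequence, config, start_offset = -nchar(sequence)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- config$window_length
  best <- -Inf
  best_j <- NA_integer_
  best_partials <- NULL
  for (j in seq_len(length(chars) - L + 1L)) {
    w <- paste(chars[j:(j + L - 1L)], collapse = "")
    f <- c(stop = pwm_score(w, config$pwm),
           slide = slide_term(w, config$slide),
           bend = bend_term(w, config$bend))
    E <- config$calibration[, "a"] + config$calibration[, "b"] *
      f[rownames(config$calibration)]
    if (mean(E) > best) {
      best <- mean(E)
      best_j <- j
      best_partials <- E
    }
  }
  list(neg_log_kd = best, delta = stats::sd(best_partials) / sqrt(3),
       best_window_offset = start_offset + best_j - 1L)
}

# Exact binomial tails by direct enumeration over outcomes (choose-based),
# independent of pbinom.
enum_binom_two_sided <- function(a, n, prob) {
  k <- 0:n
  pk <- choose(n, k) * prob^k * (1 - prob)^(n - k)
  min(1, 2 * min(sum(pk[k <= a]), sum(pk[k >= a])))
}

random_sequence <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# Contest set with prescribed winners: winner gets 30 attacks / 1 pose in
# totals, loser 2 attacks / 20 poses, split over two observations.
contests_with_winners <- function(maternal, balb_wins) {
  n <- length(maternal)
  pairs <- data.frame(pair_id = sprintf("P%03d", seq_len(n)),
                      maternal_strain = maternal,
                      male_a_paternal = "BALB/cLac",
                      male_b_paternal = "CBA/Lac",
                      stringsAsFactors = FALSE)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- c(15, 15); l <- c(1, 1); wp <- c(1, 0); lp <- c(10, 10)
    if (balb_wins[i]) {
      data.frame(pair_id = pairs$pair_id[i], observation = 1:2,
                 attacks_a = w, attacks_b = l,
                 submissive_a = wp, submissive_b = lp)
    } else {
      data.frame(pair_id = pairs$pair_id[i], observation = 1:2,
                 attacks_a = l, attacks_b = w,
                 submissive_a = lp, submissive_b = wp)
    }
  }))
  contest_set(pairs, obs)
}
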