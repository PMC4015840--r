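# Shared fixtures, all built in code.

PAIR <- condition_pair(1L, 2L)

# The 4-trial, 2-channel, 1-sample dataset whose leave-one-out folds can be
# enumerated by hand: A = {(2,0), (0,2)}, B = {(-2,0), (0,-2)}.
hand_dataset <- function() {
  epoched_dataset(array(c(2, 0, 0, 2, -2, 0, 0, -2), c(2L, 1L, 4L)),
                  times = 0, labels = c(1L, 1L, 2L, 2L))
}

# Hand enumeration of the four folds (frozen oracle):
#   leave 1: mean_A = (0,2), mean_B = (-1,-1) -> d = (1,3),  s1 = (2,0).d/|d|
#   leave 2: mean_A = (2,0), mean_B = (-1,-1) -> d = (3,1),  s2 = (0,2).d/|d|
#   leave 3: mean_A = (1,1), mean_B = (0,-2)  -> d = (1,3),  s3 = (-2,0).d/|d|
#   leave 4: mean_A = (1,1), mean_B = (-2,0)  -> d = (3,1),  s4 = (0,-2).d/|d|
hand_surrogates <- c(2, 2, -2, -2) / sqrt(10)
hand_filters <- cbind(c(1, 3), c(3, 1), c(1, 3), c(3, 1)) / sqrt(10)

# Small planted-effect dataset used across modules: uniform topography on the
# first half of the channels, boxcar in [0.2, 0.3) s.
small_effect <- function(m = 8L, n = 50L, npc = 10L, amplitude = 2,
                         seed = 3L, jitter = 0, window = c(0.2, 0.3)) {
  stopifnot(window[2] <= n / 100)   # epoch runs 0 .. n/100 s at 100 Hz
  topo <- c(rep(1, m %/% 2), rep(0, m - m %/% 2)) / sqrt(m %/% 2)
  sc <- effect_scenario(m, n, npc,
                        components = list(effect_component(
                          topo, window, amplitude = amplitude,
                          latency_jitter_sd = jitter)),
                        seed = seed)
  gen_effect_dataset(sc)
}

expect_norms_unit <- function(fs, tol = 1e-10) {
  nrm <- sqrt(apply(fs$filters^2, c(2L, 3L), sum))
  keep <- !fs$degenerate
  expect_true(all(abs(nrm[keep] - 1) < tol))
}

# Class-separation functional sum_k y_k <X_k, w> with y = +1/N_A, -1/N_B —
# the quantity the matched filter maximizes. Independent of the transform
# code path.
separation_value <- function(slice, labels, pair, w) {
  y <- ifelse(labels == pair$a, 1 / sum(labels == pair$a),
              -1 / sum(labels == pair$b))
  sum(y * crossprod(slice, w))
}
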