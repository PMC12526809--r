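# shared fixture builders (everything generated in code at test time)

# a resampled tachogram built directly on the 2 Hz grid
make_resampled <- function(rr_ms, fs = 2, t0 = 0) {
  structure(
    list(t = t0 + (seq_along(rr_ms) - 1) / fs, rr_ms = rr_ms,
         valid = rep(TRUE, length(rr_ms)), fs = fs),
    class = "resampled_rr"
  )
}

# an NN series with prescribed interval values at prescribed times
make_nn <- function(time, rr_ms) {
  structure(list(time = time, rr_ms = rr_ms, n_beats = length(time) + 1L),
            class = "nn_series")
}

# a 30 s epoch grid covering [t0, t0 + n_ep * 30)
make_epochs <- function(n_ep, t0 = 0, label = "supine") {
  data.frame(epoch_index = seq_len(n_ep) - 1L,
             t_start = t0 + (seq_len(n_ep) - 1L) * 30,
             label = rep(label, length.out = n_ep),
             stringsAsFactors = FALSE)
}

# block schedule: each posture repeated in `blocks` blocks of `block_s` s
make_block_schedule <- function(postures = c("supine", "right_lateral",
                                             "left_lateral", "prone"),
                                blocks = 2, block_s = 600) {
  seqp <- rep(postures, times = blocks)
  data.frame(start_s = (seq_along(seqp) - 1) * block_s,
             duration_s = block_s, posture = seqp,
             stringsAsFactors = FALSE)
}

# literal transcription of the published angle rules, used as an
# independent oracle for sample_posture (scalar, nested if/else)
oracle_posture <- function(g) {
  g <- g / sqrt(sum(g^2))
  deg <- function(c) acos(max(-1, min(1, c))) * 180 / pi
  th_x <- deg(g[1]); th_y <- deg(g[2]); th_z <- deg(g[3])
  if (th_x < 84 - 36 || th_x > 84 + 36) return("non_lying")
  if (th_y < 65) return("left_lateral")
  if (th_y > 111) return("right_lateral")
  if (th_z < 60) return("supine")
  "prone"
}
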