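# Independent brute-force oracles. These are deliberately naive (queue
# flood fill, explicit scans, all-pairs loops) and share no code with the
# implementations they check.

# queue-based flood fill, 8-connectivity (2-D)
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  nxt <- 0L
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > d[1] || qj < 1 || qj > d[2]) next
        if (mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# explicit scan for bouts (maximal same-state runs >= min_epochs)
oracle_bouts <- function(states, min_epochs = 2L, epoch_len_s = 10) {
  st <- character(0); se <- integer(0); ne <- integer(0)
  i <- 1L; n <- length(states)
  while (i <= n) {
    j <- i
    while (j < n && states[j + 1L] == states[i]) j <- j + 1L
    len <- j - i + 1L
    if (len >= min_epochs && !(states[i] %in% c("Artifact", "Unscored"))) {
      st <- c(st, states[i]); se <- c(se, i); ne <- c(ne, len)
    }
    i <- j + 1L
  }
  data.frame(state = st, start_epoch = se, n_epochs = ne,
             duration_s = ne * epoch_len_s, stringsAsFactors = FALSE)
}

# loop-and-set alternation scoring
oracle_alternation <- function(entries) {
  n <- length(entries)
  hits <- 0L
  for (i in 3:n) {
    w <- c(entries[i - 2], entries[i - 1], entries[i])
    if (length(unique(w)) == 3L) hits <- hits + 1L
  }
  100 * hits / (n - 2)
}

# frame-by-frame run scan for freezing
oracle_freezing <- function(mi, fps, threshold, min_freeze_s = 1) {
  n <- length(mi)
  frozen <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (mi[i] < threshold) {
      j <- i
      while (j < n && mi[j + 1L] < threshold) j <- j + 1L
      if ((j - i + 1L) / fps >= min_freeze_s) frozen[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  100 * sum(frozen) / n
}

# all no-immediate-repeat arm sequences of a given length
enumerate_entry_sequences <- function(len, arms = c("A", "B", "C")) {
  seqs <- as.list(arms)
  for (k in 2:len) {
    seqs <- unlist(lapply(seqs, function(s) {
      lapply(setdiff(arms, s[length(s)]), function(a) c(s, a))
    }), recursive = FALSE)
  }
  seqs
}

# naive all-pairs nearest plaque voxel distance
oracle_min_distance <- function(point_um, mask, voxel_size_um) {
  pv <- which(mask, arr.ind = TRUE)
  if (nrow(pv) == 0) return(Inf)
  best <- Inf
  for (j in seq_len(nrow(pv))) {
    c_um <- (pv[j, ] - 1) * voxel_size_um
    dj <- sqrt(sum((c_um - point_um)^2))
    if (dj < best) best <- dj
  }
  best
}

# small helper: recording from one repeated-state synthetic setup
make_test_psg <- function(states, fs = 100, seed = 1, mode = "noise", ...) {
  sp <- sleep_sim_params(fs_hz = fs, seed = seed, ...)
  rec <- simulate_polysomnography(
    structure(states, epoch_len_s = sp$epoch_len_s, class = "state_sequence"),
    sp, mode = mode)
  list(params = sp, rec = rec, epochs = epochize(rec, sp$epoch_len_s))
}
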