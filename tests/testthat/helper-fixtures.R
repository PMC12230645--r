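# shared fixture builders; everything is generated in code, no stored data

mk_grid <- function(nr = 4, nc = 4, cs = 1) wl_grid(nr, nc, cs)

mk_cover <- function(vals, nr = NULL, nc = NULL, epoch = NA, cs = 1) {
  if (!is.matrix(vals)) vals <- matrix(vals, nr, nc)
  cover_map(wl_grid(nrow(vals), ncol(vals), cs), vals, epoch)
}

rand_cover <- function(nr, nc, seed = 1, epoch = NA, cs = 1) {
  set.seed(seed)
  mk_cover(matrix(runif(nr * nc), nr, nc), epoch = epoch, cs = cs)
}

# a small series with set epochs from a list of value matrices
mk_series <- function(mats, epochs = seq_along(mats) + 2000) {
  cover_series(Map(function(m, e) mk_cover(m, epoch = e), mats, epochs), epochs)
}

# two well-separated flat templates for recovery checks
two_templates <- function(sd = 0.02) list(
  archetype_template("decline", seq(0.95, 0.15, length.out = 7), sd),
  archetype_template("flat", rep(0.9, 7), sd))

# independent pair-counting adjusted Rand (O(n^2) oracle)
ari_pairs_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# flood-fill connectivity check for species ranges (4-neighborhood)
is_connected_patch <- function(presence) {
  idx <- which(presence)
  if (!length(idx)) return(FALSE)
  nr <- nrow(presence); nc <- ncol(presence)
  seen <- logical(length(presence))
  queue <- idx[1]; seen[idx[1]] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    r <- (cur - 1) %% nr + 1; c <- (cur - 1) %/% nr + 1
    for (nb in c(if (r > 1) cur - 1, if (r < nr) cur + 1,
                 if (c > 1) cur - nr, if (c < nc) cur + nr))
      if (presence[nb] && !seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  all(seen[idx])
}
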