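# Independent oracles, deliberately implemented with different algorithms
# than the package paths they check.

# Fitting alignment of `tract` against a finite repetition of `motif`
# (global in the tract, free ends in the reference): an independent check
# of the wraparound DP in score_tract. Pure R Needleman-Wunsch.
fitting_score <- function(tract, motif, match = 2L, mismatch = -7L,
                          gap = -7L) {
  t <- strsplit(tract, "")[[1]]
  copies <- ceiling(length(t) / nchar(motif)) + 2L
  r <- strsplit(strrep(motif, copies), "")[[1]]
  n <- length(t)
  m <- length(r)
  NEG <- -1e9
  # D[i+1, j+1] = best score of t[1..i] vs r[..j] with free reference start
  D <- matrix(NEG, n + 1L, m + 1L)
  D[1L, ] <- 0L  # free leading reference
  for (i in seq_len(n)) {
    D[i + 1L, 1L] <- D[i, 1L] + gap
    for (j in seq_len(m)) {
      s <- if (t[i] == r[j] && t[i] != "N") match else mismatch
      D[i + 1L, j + 1L] <- max(D[i, j] + s, D[i, j + 1L] + gap,
                               D[i + 1L, j] + gap)
    }
  }
  max(D[n + 1L, ])  # free trailing reference
}

# Brute force over every (start, period) with score_tract's engine scoring
# all candidate ends in one pass; reports the best score of any tract with
# span >= 2 periods. Used for the detector-equivalence property.
oracle_best_score <- function(s, max_period = 12L) {
  n <- nchar(s)
  best <- 0L
  for (p in seq_len(min(max_period, n %/% 2L))) {
    for (st in seq_len(n - 2L * p + 1L)) {
      motif <- substr(s, st, st + p - 1L)
      ends <- mttr:::.wdp_score_ends(substr(s, st, n), motif)
      ok <- seq_along(ends) >= 2L * p
      if (any(ok)) best <- max(best, max(ends[ok]))
    }
  }
  best
}

# Brute-force enumerator of all single contiguous indels converting symbol
# vector `sa` into `sb`; returns NULL when none exists, otherwise one row
# per distinct run content with the maximal placement band.
enumerate_single_indels <- function(sa, sb) {
  d <- length(sa) - length(sb)
  if (d == 0L) return(NULL)
  longer <- if (d > 0L) sa else sb
  shorter <- if (d > 0L) sb else sa
  k <- abs(d)
  hits <- list()
  for (i in seq_len(length(longer) - k + 1L)) {
    if (identical(longer[-(i:(i + k - 1L))], shorter)) {
      hits[[length(hits) + 1L]] <- list(
        pos = i, content = paste(longer[i:(i + k - 1L)], collapse = "."))
    }
  }
  if (!length(hits)) return(NULL)
  contents <- vapply(hits, `[[`, "", "content")
  poss <- vapply(hits, `[[`, 0L, "pos")
  do.call(rbind, lapply(unique(contents), function(ct) {
    p <- poss[contents == ct]
    data.frame(kind = if (d > 0L) "deletion" else "insertion",
               motif_count = k, symbols = ct,
               ambiguity_start = min(p), ambiguity_end = max(p) + k - 1L,
               stringsAsFactors = FALSE)
  }))
}
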