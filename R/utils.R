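# Internal helpers: DNA strings and circular-coordinate arithmetic.

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.collapse <- function(x) paste(x, collapse = "")

.revcomp <- function(s) {
  .collapse(rev(.chars(chartr("ACGTN", "TGCAN", s))))
}

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up, the convention used by the
#' survey tables (base `round()` rounds half to even).
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# smallest q such that s is (s[1..q]) repeated; q == nchar(s) if aperiodic
.primitive_period <- function(s) {
  n <- nchar(s)
  for (q in seq_len(n)) {
    if (n %% q == 0L && strrep(substr(s, 1L, q), n %/% q) == s) return(q)
  }
  n
}

.hamming <- function(a, b) {
  sum(.chars(a) != .chars(b))
}

# ---- circular interval arithmetic (1-based inclusive; wrap when start > end)

# expand a possibly-wrapping interval into 1 or 2 linear [start, end] rows
.circ_expand <- function(start, end, len) {
  if (start <= end) {
    matrix(c(start, end), ncol = 2L)
  } else {
    matrix(c(start, len, 1L, end), ncol = 2L, byrow = TRUE)
  }
}

.circ_len <- function(start, end, len) {
  if (start <= end) end - start + 1L else len - start + 1L + end
}

# bases shared by two possibly-wrapping intervals on a circle of size len
.circ_overlap <- function(s1, e1, s2, e2, len) {
  a <- .circ_expand(s1, e1, len)
  b <- .circ_expand(s2, e2, len)
  ov <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      lo <- max(a[i, 1L], b[j, 1L])
      hi <- min(a[i, 2L], b[j, 2L])
      if (hi >= lo) ov <- ov + hi - lo + 1L
    }
  }
  ov
}

# forward (clockwise) distance from position a to position b
.circ_dist_fwd <- function(a, b, len) (b - a) %% len

# is [s2, e2] wholly inside [s1, e1]?
.circ_contains <- function(s1, e1, s2, e2, len) {
  .circ_overlap(s1, e1, s2, e2, len) == .circ_len(s2, e2, len)
}

# position reached walking k bases forward from pos (k may be 0)
.circ_step <- function(pos, k, len) ((pos - 1L + k) %% len) + 1L

.is_dna <- function(s, extra = "N") {
  ok <- c("A", "C", "G", "T", .chars(extra))
  all(.chars(s) %in% ok)
}
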