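# Independent oracles used to cross-check the boundary detection and the
# correlation statistics. These deliberately avoid the package's scanning
# implementation: the brute-force oracle tests every candidate range with
# all(), and the row-gap oracle reproduces the classic data-table
# mechanics (row numbers, NA masking, doubled first row, diff != 1).

# Brute force: largest j >= id_max with every sample of [id_max, j]
# above threshold; analogously for the run start. First-exceedance lower
# boundary by direct which().
oracle_boundaries <- function(int, thr_left, thr_right,
                              contiguous_lower = FALSE) {
  n <- length(int)
  id_max <- which.max(int)
  res <- list(lower = NA_integer_, lower_found = FALSE,
              upper = NA_integer_, upper_found = FALSE,
              id_max = id_max)
  if (int[id_max] > thr_right) {
    cands <- Filter(function(j) all(int[id_max:j] > thr_right), id_max:n)
    res$upper <- max(cands)
    res$upper_found <- TRUE
  }
  if (contiguous_lower) {
    if (int[id_max] > thr_left) {
      cands <- Filter(function(i) all(int[i:id_max] > thr_left), 1:id_max)
      res$lower <- min(cands)
      res$lower_found <- TRUE
    }
  } else {
    hits <- which(int[1:id_max] > thr_left)
    if (length(hits)) {
      res$lower <- hits[1]
      res$lower_found <- TRUE
    }
  }
  res
}

# Literal re-expression of the row-gap mechanics: add row numbers, mask
# background (not strictly above threshold) as NA, drop NA rows, double
# the first row, take diff of the row-number column (one entry short, so
# append 0), then search for the first difference != 1. The doubled first
# row makes the beginning show up as a difference of 0; the first
# difference != 1 at or after the peak marks the biofilm end.
rowgap_boundaries <- function(int, thr_left, thr_right) {
  n <- length(int)
  id_max <- which.max(int)
  thr <- ifelse(seq_len(n) < id_max, thr_left,
                ifelse(seq_len(n) > id_max, thr_right,
                       min(thr_left, thr_right)))
  v <- int
  v[!(v > thr)] <- NA
  keep <- which(!is.na(v))
  res <- list(lower = NA_integer_, lower_found = FALSE,
              upper = NA_integer_, upper_found = FALSE, id_max = id_max)
  if (length(keep) == 0L) return(res)
  ids <- c(keep[1], keep)              # doubled first row
  d <- c(diff(ids), 0)                 # diff is one short; append 0
  odd <- which(d != 1)
  if (length(odd)) {                   # first odd difference: the beginning
    res$lower <- ids[odd[1]]
    res$lower_found <- TRUE
  }
  pos_max <- which(ids == id_max)
  if (length(pos_max)) {               # first odd difference after the peak
    k <- odd[odd >= pos_max[length(pos_max)]]
    if (length(k)) {
      res$upper <- ids[k[1]]
      res$upper_found <- TRUE
    }
  }
  res
}

# Pearson r from the sum formula and its two-sided t-based p-value,
# written out by hand.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

# shorthand for fixture profiles on a unit z grid
zp <- function(intensity, z = seq_along(intensity) - 1, ...) {
  z_profile(z, intensity, ...)
}

# package boundary ops vs both oracles on one integer profile
compare_on <- function(int, thr = 3) {
  p <- zp(int)
  id_max <- find_peak(p)
  lo <- find_lower_boundary(p, thr, id_max)
  up <- find_upper_boundary(p, thr, id_max)
  bf <- oracle_boundaries(int, thr, thr)
  rg <- rowgap_boundaries(int, thr, thr)
  ok <- identical(lo$found, bf$lower_found) &&
    identical(up$found, bf$upper_found) &&
    identical(lo$found, rg$lower_found) &&
    identical(up$found, rg$upper_found)
  if (ok && lo$found) {
    ok <- lo$index == bf$lower && lo$index == rg$lower
  }
  if (ok && up$found) {
    ok <- up$index == bf$upper && up$index == rg$upper
  }
  if (ok) {
    loc <- find_lower_boundary(p, thr, id_max, contiguous = TRUE)
    bfc <- oracle_boundaries(int, thr, thr, contiguous_lower = TRUE)
    ok <- identical(loc$found, bfc$lower_found) &&
      (!loc$found || loc$index == bfc$lower)
  }
  ok
}
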