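# Independent oracles and small fixture builders used across the suite.

# brute-force O(n^2) Harrell's C: enumerate usable pairs explicitly
cindex_brute <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ti <- time[i]; tj <- time[j]
      ei <- event[i]; ej <- event[j]
      if (ti == tj) {
        if (ei == 1 && ej == 1) next       # tied event times: unusable
        if (ei == 1 && ej == 0) { a <- i; b <- j }
        else if (ej == 1 && ei == 0) { a <- j; b <- i }
        else next
      } else {
        a <- if (ti < tj) i else j
        b <- if (ti < tj) j else i
        if (event[a] == 0) next            # earlier time censored: unusable
      }
      den <- den + 1
      if (risk[a] > risk[b]) num <- num + 1
      else if (risk[a] == risk[b]) num <- num + 0.5
    }
  }
  num / den
}

# two-pass mean-absolute-deviation oracle for a measured 16-vector
madwt_brute <- function(v) {
  v <- v[!is.na(v)]
  m <- 0
  for (x in v) m <- m + x
  m <- m / length(v)
  s <- 0
  for (x in v) s <- s + abs(x - m)
  s / length(v)
}

# greedy matching oracle: literal translation of the documented algorithm,
# O(n_t * n_c), no data structures
greedy_match_brute <- function(scores, treated, ids = seq_along(scores)) {
  t_idx <- which(treated)
  c_idx <- which(!treated)
  t_ord <- t_idx[order(-scores[t_idx], ids[t_idx])]
  avail <- c_idx
  pairs <- NULL
  for (ti in t_ord) {
    if (length(avail) == 0) break
    d <- abs(scores[avail] - scores[ti])
    cand <- avail[d == min(d)]
    # documented tie rule: lower-score side first, then lowest id
    cand <- cand[scores[cand] == min(scores[cand])]
    ci <- cand[order(ids[cand])][1]
    pairs <- rbind(pairs, c(ids[ti], ids[ci]))
    avail <- setdiff(avail, ci)
  }
  pairs
}

# small stepped phantom used by several geometry tests
stepped_design <- function() c(8, 12, 8, 8, 10, 8, 9, 8, 8, 11, 8, 8,
                               8, 10, 8, 9)

make_phantom <- function(spacing = 1, sector_thickness = 8, n_slices = 9,
                         ...) {
  generate_phantom(phantom_spec(endo_radius = 20,
                                sector_thickness = sector_thickness,
                                in_plane_spacing = spacing,
                                n_slices = n_slices, ...))
}

half_diag <- function(spacing) spacing * sqrt(2) / 2
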