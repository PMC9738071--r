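# Brute-force enumeration oracles, deliberately naive: explicit loops over
# pixels, independent of the vectorized implementation they check.

# symmetric difference tally: every ordered pair (p, p +/- offset) inside the
# ROI (non-NA), tallied by absolute level difference k = 0..Ng-1
brute_diff_hist <- function(M, dr, dc, Ng) {
  nr <- nrow(M); nc <- ncol(M)
  tab <- integer(Ng)
  n <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) for (s in c(1L, -1L)) {
    r2 <- r + s * dr; c2 <- c + s * dc
    if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
        !is.na(M[r, c]) && !is.na(M[r2, c2])) {
      k <- abs(M[r, c] - M[r2, c2])
      tab[k + 1L] <- tab[k + 1L] + 1L
      n <- n + 1L
    }
  }
  if (n == 0L) return(NULL)
  list(probs = tab / n, pair_count = n)
}

# maximal-run enumerator: walks every line of the direction pixel by pixel
brute_run_counts <- function(M, dr, dc, Ng) {
  u <- sign(c(dr, dc))
  nr <- nrow(M); nc <- ncol(M)
  # line start points: cells with no in-bounds predecessor in direction -u
  runs_lev <- integer(0); runs_len <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - u[1]; pc <- c - u[2]
    if (pr >= 1L && pr <= nr && pc >= 1L && pc <= nc) next # not a line start
    # walk the line
    cur_lev <- NA_integer_; cur_len <- 0L
    rr <- r; cc <- c
    while (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
      v <- M[rr, cc]
      if (is.na(v)) {
        if (cur_len > 0L) {
          runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
        }
        cur_lev <- NA_integer_; cur_len <- 0L
      } else if (!is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1L
      } else {
        if (cur_len > 0L) {
          runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
        }
        cur_lev <- v; cur_len <- 1L
      }
      rr <- rr + u[1]; cc <- cc + u[2]
    }
    if (cur_len > 0L) {
      runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
    }
  }
  if (length(runs_len) == 0L) return(NULL)
  counts <- matrix(0L, Ng, max(runs_len))
  for (i in seq_along(runs_len))
    counts[runs_lev[i], runs_len[i]] <- counts[runs_lev[i], runs_len[i]] + 1L
  counts
}

# trim trailing all-zero run-length columns so matrices of different width
# compare equal
trim_rlm <- function(counts) {
  keep <- rev(cumsum(rev(colSums(counts))) > 0)
  counts[, seq_len(max(which(keep))), drop = FALSE]
}

# full-patch ROI analysis of a radiograph (protocol size check disabled)
analyze_patch <- function(img, ...) {
  spec <- roi_spec("patch", "reference", "initial",
                   rect = c(0L, 0L, nrow(img$pixels), ncol(img$pixels)))
  rp <- resolve_roi(img, spec, protocol_pixels = NA)
  analyze_roi(img, rp, ...)
}

std_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
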