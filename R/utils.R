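# Internal helpers shared across stages.

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (neurons x frames).", what))
  }
  invisible(x)
}

assert_scalar <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", what,
                  format(lower), format(upper)))
  }
  invisible(x)
}

# Derive a per-stage seed from the master seed. Offsets are small fixed
# integers per stage so stage-level reproducibility survives reordering.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9176) %% 2147483647L)
}

# Absorb runs shorter than `min_len` into the surrounding state.
# Iterates because absorbing one short run can create a longer merged run
# that absorbs its neighbours on the next pass.
debounce_mask <- function(mask, min_len) {
  if (min_len <= 1 || length(mask) == 0) return(mask)
  repeat {
    r <- rle(mask)
    if (length(r$lengths) <= 1) return(mask)
    short <- which(r$lengths < min_len)
    # never flip a terminal run that has no opposite neighbour context issue;
    # terminal short runs are absorbed into their single neighbour
    if (length(short) == 0) return(mask)
    # flip the single shortest run (first on ties), then re-examine
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    mask[starts[k]:ends[k]] <- !r$values[k]
  }
}

# Indices of contiguous TRUE runs as a two-column matrix (start, end).
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  cbind(start = starts[r$values], end = ends[r$values])
}

# Block-average a vector into floor(n/k) blocks of k samples.
block_average <- function(x, k) {
  n_out <- floor(length(x) / k)
  if (n_out == 0) abort("Block size `k` exceeds the number of samples.")
  colMeans(matrix(x[seq_len(n_out * k)], nrow = k))
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
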