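## Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

## Half-up rounding (R's round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## Merge adjacent identical CIGAR ops and render the string.
cigar_string <- function(ops, lens) {
  keep <- lens > 0L
  ops <- ops[keep]; lens <- lens[keep]
  if (length(ops) == 0L) return("")
  r <- rle(ops)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  merged_len <- vapply(seq_along(starts), function(i)
    sum(lens[starts[i]:ends[i]]), integer(1))
  paste0(merged_len, r$values, collapse = "")
}

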