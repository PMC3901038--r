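# Independent oracles, implemented directly from the definitions and kept
# deliberately naive so they share no code path with the package.

# LZ76 exhaustive-history production count: scan left to right; each new
# component is the shortest prefix of the remainder not reproducible (with
# self-overlap) from the already-parsed text; a final reproducible remainder
# counts as one component.
lz76_oracle <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  reproducible <- function(i, len) {
    if (i < 1L) return(FALSE)
    tgt <- ch[(i + 1L):(i + len)]
    for (p in seq_len(i)) {
      if (all(ch[p:(p + len - 1L)] == tgt)) return(TRUE)
    }
    FALSE
  }
  i <- 0L; comps <- 0L
  while (i < n) {
    len <- 1L
    while (i + len <= n) {
      if (!reproducible(i, len)) break
      len <- len + 1L
    }
    if (i + len > n) len <- n - i  # final, fully reproducible component
    comps <- comps + 1L
    i <- i + len
  }
  comps
}

# Naive recursive maximum nested base pairing (Watson-Crick + G-U wobble,
# hairpin loop >= min_loop); exponential-time enumeration for short strings.
nussinov_oracle <- function(s, min_loop = 3L, wobble = TRUE) {
  ch <- strsplit(toupper(chartr("T", "U", s)), "")[[1L]]
  ok <- c("AU", "UA", "GC", "CG", if (wobble) c("GU", "UG"))
  pairable <- function(a, b) paste0(a, b) %in% ok
  best <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    b <- best(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (!pairable(ch[i], ch[k])) next
      v <- 1L + best(i + 1L, k - 1L) + (if (k < j) best(k + 1L, j) else 0L)
      if (v > b) b <- v
    }
    b
  }
  if (length(ch) < 2L) return(0L)
  best(1L, length(ch))
}

random_seqs <- function(n, k, letters) {
  m <- matrix(sample(letters, n * k, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# A symmetric 2D Gaussian spot with peak height `amplitude` at (x, y),
# pixel centers at integer coordinates.
plant_psf <- function(H, W, x, y, amplitude = 1, sigma = 1, offset = 0,
                      noise_sd = 0) {
  gx <- exp(-((seq_len(W) - x)^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(H) - y)^2) / (2 * sigma^2))
  m <- offset + amplitude * outer(gy, gx)
  if (noise_sd > 0) m <- m + matrix(rnorm(H * W, sd = noise_sd), H, W)
  m
}
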