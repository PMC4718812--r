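# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Reflect-pad a matrix by `p` pixels on every side (edge row/col mirrored,
# edge itself not repeated is the "symmetric" variant; here we use full
# reflection including the edge, i.e. pad row 1 with rows p..1).
padReflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  if (p >= nr || p >= nc) stop("padding exceeds matrix size")
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  m[ri, ci]
}

# k x k box (uniform) mean with reflect padding; k odd.
boxMeanReflect <- function(m, k) {
  p <- (k - 1L) %/% 2L
  if (p == 0L) return(m)
  mp <- padReflect(m, p)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L))
    acc <- acc + mp[di + seq_len(nr), dj + seq_len(nc)]
  acc / (k * k)
}

# Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))

scalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
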