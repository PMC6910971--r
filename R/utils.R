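# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream. `seed = NULL` means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # force initialisation so we have something to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Pixel-centre coordinates (cm) for an n-pixel axis at pitch cm/px.
# Convention used everywhere: origin at the top-left slide corner, x
# rightward, y downward, pixel centres at (i - 0.5) * pitch.
pixel_centers <- function(n, pitch) (seq_len(n) - 0.5) * pitch

# Bilinear sampling of matrix `m` (rows = y, cols = x) at fractional pixel
# coordinates (1-based, pixel centres at integers). Out-of-domain -> `fill`.
bilinear_sample <- function(m, xf, yf, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(xf); y0 <- floor(yf)
  dx <- xf - x0; dy <- yf - y0
  ok <- x0 >= 1 & y0 >= 1 & (x0 + 1) <= nc & (y0 + 1) <= nr
  # clamp indices so the vectorised gather is always legal
  x0c <- clamp(x0, 1, nc - 1); y0c <- clamp(y0, 1, nr - 1)
  i00 <- cbind(y0c, x0c); i01 <- cbind(y0c, x0c + 1)
  i10 <- cbind(y0c + 1, x0c); i11 <- cbind(y0c + 1, x0c + 1)
  v <- (1 - dy) * ((1 - dx) * m[i00] + dx * m[i01]) +
    dy * ((1 - dx) * m[i10] + dx * m[i11])
  # exact edge: allow points on the last row/col line
  edge <- !ok & xf >= 1 & xf <= nc & yf >= 1 & yf <= nr
  v[!ok] <- fill
  if (any(edge)) {
    xi <- clamp(round(xf[edge]), 1, nc); yi <- clamp(round(yf[edge]), 1, nr)
    v[edge] <- m[cbind(yi, xi)]
  }
  v
}
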