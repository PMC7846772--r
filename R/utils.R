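#' Derive a named random substream seed from a top-level seed
#'
#' All randomness in the toolkit flows from one top-level seed through named
#' substreams (`"scene"`, `"noise"`, `"tracking"`, ...), so changing one
#' substream leaves the others' outputs unchanged. The derived seed is a
#' deterministic 31-bit hash of `(seed, name)`.
#'
#' @param seed integer top-level seed.
#' @param name character substream name.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- (seed %% 2147483647) + 0
  for (k in utf8ToInt(name)) {
    h <- (h * 31 + k) %% 2147483647
  }
  h <- (h * 48271) %% 2147483647
  as.integer(h + 1L)
}

# evaluate with a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# bilinear sampling of matrix `img` at fractional (row, col) positions;
# out-of-frame samples return `fill`
bilinear_sample <- function(img, rows, cols, fill = 0) {
  nz <- nrow(img)
  nx <- ncol(img)
  r0 <- floor(rows)
  c0 <- floor(cols)
  fr <- rows - r0
  fc <- cols - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nz - 1 & c0 <= nx - 1
  # clamp exact bottom/right edge onto the last cell
  edge_r <- abs(rows - nz) < 1e-9
  edge_c <- abs(cols - nx) < 1e-9
  r0[edge_r] <- nz - 1
  fr[edge_r] <- 1
  c0[edge_c] <- nx - 1
  fc[edge_c] <- 1
  ok <- ok | (edge_r & cols >= 1 & cols <= nx) | (edge_c & rows >= 1 & rows <= nz)
  ok <- ok & r0 >= 1 & c0 >= 1 & r0 <= nz - 1 & c0 <= nx - 1
  out <- if (is.complex(img)) {
    rep(as.complex(fill), length(rows))
  } else {
    rep(as.numeric(fill), length(rows))
  }
  i <- which(ok)
  if (length(i)) {
    r <- r0[i]; cc <- c0[i]; a <- fr[i]; b <- fc[i]
    v00 <- img[cbind(r, cc)]
    v10 <- img[cbind(r + 1, cc)]
    v01 <- img[cbind(r, cc + 1)]
    v11 <- img[cbind(r + 1, cc + 1)]
    out[i] <- (1 - a) * (1 - b) * v00 + a * (1 - b) * v10 +
      (1 - a) * b * v01 + a * b * v11
  }
  out
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}
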