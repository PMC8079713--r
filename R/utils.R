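#' @importFrom stats rpois rnorm runif rexp rlnorm median quantile sd var
#'   qnorm dnorm runmed setNames
NULL

# Run code with a private RNG stream so library calls never disturb the
# caller's .Random.seed. `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("vercini_param_error", "error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_param("`", name, "` must be a positive number")
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_param("`", name, "` must be a non-negative number")
  invisible(x)
}

#' Bilinear interpolation on an image matrix
#'
#' Images are stored as matrices with rows indexing y (downward) and columns
#' indexing x (rightward); pixel centres sit at integer coordinates starting
#' at (1, 1) in the top-left corner.
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of sample coordinates (pixels).
#' @param fill value returned for samples outside the pixel-centre hull.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y, fill = NA_real_) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
  # clamp so index arithmetic stays legal; masked afterwards
  x0c <- pmin(pmax(x0, 1L), nx - 1L)
  y0c <- pmin(pmax(y0, 1L), ny - 1L)
  # exact upper edge: interpolate from the last cell
  fxc <- ifelse(x >= nx, 1, fx); fyc <- ifelse(y >= ny, 1, fy)
  i00 <- (x0c - 1L) * ny + y0c
  v <- (1 - fxc) * (1 - fyc) * img[i00] +
       fxc       * (1 - fyc) * img[i00 + ny] +
       (1 - fxc) * fyc       * img[i00 + 1L] +
       fxc       * fyc       * img[i00 + ny + 1L]
  v[!ok] <- fill
  v
}

# Pad a vector index set for the requested boundary rule.
pad_index <- function(n, r, boundary = c("replicate", "periodic")) {
  boundary <- match.arg(boundary)
  idx <- seq_len(n)
  if (boundary == "periodic") {
    c((n - r + 1L):n, idx, 1L:r)
  } else {
    c(rep(1L, r), idx, rep(n, r))
  }
}

#' Separable Gaussian blur with per-axis boundary handling
#'
#' @param img numeric matrix (rows = axis 1, columns = axis 2).
#' @param sigma blur standard deviation in pixels.
#' @param boundary_rows,boundary_cols `"replicate"` or `"periodic"`.
#' @return blurred matrix, same dimensions.
#' @keywords internal
gaussian_blur <- function(img, sigma,
                          boundary_rows = "replicate",
                          boundary_cols = "replicate") {
  check_positive(sigma, "sigma")
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(m, along_rows, boundary) {
    if (along_rows) {
      idx <- pad_index(nrow(m), r, boundary)
      p <- m[idx, , drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k))
        out <- out + k[j] * p[j:(j + nrow(m) - 1L), , drop = FALSE]
      out
    } else {
      idx <- pad_index(ncol(m), r, boundary)
      p <- m[, idx, drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k))
        out <- out + k[j] * p[, j:(j + ncol(m) - 1L), drop = FALSE]
      out
    }
  }
  img <- conv_axis(img, TRUE, boundary_rows)
  conv_axis(img, FALSE, boundary_cols)
}

# Shift a matrix by one step along rows/cols under a boundary rule,
# used for central finite differences.
shift_mat <- function(m, dr = 0L, dc = 0L,
                      boundary_rows = "replicate",
                      boundary_cols = "replicate") {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  if (boundary_rows == "periodic") ri <- ((ri - 1L) %% nr) + 1L
  else ri <- pmin(pmax(ri, 1L), nr)
  if (boundary_cols == "periodic") ci <- ((ci - 1L) %% nc) + 1L
  else ci <- pmin(pmax(ci, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Atomic file write: write to a temp file in the same directory, then rename.
write_atomic <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  write_atomic(function(p) utils::write.csv(df, p, row.names = FALSE), path)
}
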