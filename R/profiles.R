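#' Line profile container
#'
#' @param positions sample positions, nm, uniformly spaced (>= 8 samples).
#' @param intensities intensities (ADU).
#' @param axis `"lateral"` (along the septal axis) or `"axial"` (along the
#'   cell long axis).
#' @export
line_profile <- function(positions, intensities,
                         axis = c("lateral", "axial")) {
  axis <- match.arg(axis)
  if (length(positions) < 8L || length(positions) != length(intensities))
    stop_param("a line profile needs >= 8 uniformly spaced samples")
  sp <- diff(positions)
  if (any(abs(sp - sp[1]) > 1e-6 * abs(sp[1])))
    stop_param("line profile positions must be uniformly spaced")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities), axis = axis),
            class = "line_profile")
}

profile_spacing <- function(profile) profile$positions[2] - profile$positions[1]

#' Extract lateral and axial septal line profiles
#'
#' The image is rotated about the ring centroid so the septal axis lies
#' horizontal (bilinear interpolation), then the lateral profile is the mean
#' over the septal axis +/- 2 px (a 5-row band) and the axial profile the
#' analogous 5-column band along the orthogonal axis.
#'
#' @param image matrix (rows = y, columns = x).
#' @param centroid ring centroid `c(x, y)`, px.
#' @param septal_axis_angle angle of the septal axis, degrees
#'   (counterclockwise from +x as displayed).
#' @param pixel_size nm/px.
#' @return list with elements `lateral` and `axial`, both [line_profile()]s
#'   with positions centred on the centroid.
#' @export
extract_septal_profiles <- function(image, centroid, septal_axis_angle,
                                    pixel_size = 65) {
  ny <- nrow(image); nx <- ncol(image)
  cx <- centroid[1]; cy <- centroid[2]
  if (cx < 1 || cx > nx || cy < 1 || cy > ny)
    stop_param("centroid must lie inside the image")
  band <- 2L
  if (round(cy) - band < 1 || round(cy) + band > ny ||
      round(cx) - band < 1 || round(cx) + band > nx)
    stop_param("profile window exceeds image bounds")
  alpha <- septal_axis_angle * pi / 180
  rot_sample <- function(xs, ys) {
    # rotate sampling coordinates by +alpha about the centroid (equivalent
    # to rotating the image by -alpha); y axis points down, so a
    # counterclockwise (displayed) rotation flips the usual sign
    dx <- xs - cx; dy <- ys - cy
    sx <- cx + dx * cos(alpha) + dy * sin(alpha)
    sy <- cy - dx * sin(alpha) + dy * cos(alpha)
    bilinear_sample(image, sx, sy)
  }
  if (septal_axis_angle %% 360 == 0) {
    lat_rows <- (round(cy) - band):(round(cy) + band)
    lateral <- colMeans(image[lat_rows, , drop = FALSE])
    ax_cols <- (round(cx) - band):(round(cx) + band)
    axial <- rowMeans(image[, ax_cols, drop = FALSE])
  } else {
    lateral <- rowMeans(vapply(seq(-band, band), function(b)
      rot_sample(seq_len(nx), rep(round(cy) + b, nx)),
      numeric(nx)))
    axial <- rowMeans(vapply(seq(-band, band), function(b)
      rot_sample(rep(round(cx) + b, ny), seq_len(ny)),
      numeric(ny)))
  }
  list(
    lateral = line_profile((seq_len(nx) - cx) * pixel_size, lateral,
                           "lateral"),
    axial = line_profile((seq_len(ny) - cy) * pixel_size, axial, "axial"))
}

#' Line-of-sight projection of an edge-on uniform circle
#'
#' Projected density of a circle of uniform intensity viewed edge-on is
#' `1/sqrt((d/2)^2 - u^2)` inside `|u| < d/2` (integral pi, independent of
#' d), convolved here with a Gaussian PSF. The convolution integral is
#' evaluated by Gauss-Legendre quadrature after the substitution
#' `u = (d/2) sin(t)`, which removes the edge singularities.
#'
#' @param x positions, nm (relative to the circle centre).
#' @param d circle diameter, nm.
#' @param psf_sigma Gaussian PSF sigma, nm.
#' @param total total projected intensity (integral over x of the
#'   baseline-free model).
#' @param n_nodes quadrature nodes.
#' @return model intensities at `x`.
#' @export
tilted_circle_model <- function(x, d, psf_sigma, total = 1, n_nodes = 64L) {
  check_positive(d, "d"); check_positive(psf_sigma, "psf_sigma")
  gl <- gauss_legendre(n_nodes, -pi / 2, pi / 2)
  u <- (d / 2) * sin(gl$nodes)
  # model(x) = total/pi * integral dt phi((x - u(t))/s)/s
  m <- numeric(length(x))
  for (i in seq_along(gl$nodes))
    m <- m + gl$weights[i] * dnorm(x, mean = u[i], sd = psf_sigma)
  m * total / pi
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch, base R eigen)
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

#' Fit the tilted-circle model to a lateral septal profile
#'
#' Least-squares fit of the edge-on projected uniform circle convolved with
#' a Gaussian PSF, plus a constant baseline; returns the ring diameter. The
#' two profile maxima converge to the circle edges at +/- d/2 as the PSF
#' narrows.
#'
#' @param profile lateral [line_profile()].
#' @param psf_sigma optional fixed PSF sigma (nm); fitted when `NULL`.
#' @param init_d optional initial diameter (nm).
#' @return list of class `tilted_circle_fit`: `d`, `centre`, `total`,
#'   `psf_sigma`, `baseline`, `rss`, `converged`.
#' @export
fit_tilted_circle <- function(profile, psf_sigma = NULL, init_d = NULL) {
  x <- profile$positions; yv <- profile$intensities
  span <- diff(range(x))
  base0 <- min(yv)
  w <- pmax(yv - base0, 0)
  c0 <- if (sum(w) > 0) sum(w * x) / sum(w) else mean(x)
  if (is.null(init_d)) {
    # second-moment of the projection: var = d^2/8 (+ psf^2)
    v <- if (sum(w) > 0) sum(w * (x - c0)^2) / sum(w) else (span / 4)^2
    init_d <- min(max(sqrt(max(8 * (v - 120^2), 0)), span / 20), 0.9 * span)
    if (init_d <= 0) init_d <- span / 3
  }
  sp <- profile_spacing(profile)
  tot0 <- sum(w) * sp
  fit_psf <- is.null(psf_sigma)
  par0 <- c(d = init_d, centre = c0, total = max(tot0, 1e-9),
            psf = if (fit_psf) 120 else psf_sigma, baseline = base0)
  resid <- function(v) {
    ps <- if (fit_psf) v[4] else psf_sigma
    yv - (v[5] + tilted_circle_model(x - v[2], v[1], ps, v[3]))
  }
  lower <- c(2 * sp, min(x), 0, if (fit_psf) 10 else psf_sigma, -Inf)
  upper <- c(1.2 * span, max(x), Inf,
             if (fit_psf) span / 2 else psf_sigma, Inf)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  v <- fit$par
  if (v[1] > span)
    stop_param("fitted diameter exceeds the profile span")
  structure(list(d = v[[1]], centre = v[[2]], total = v[[3]],
                 psf_sigma = if (fit_psf) v[[4]] else psf_sigma,
                 baseline = v[[5]], rss = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4),
            class = "tilted_circle_fit")
}

#' Super-Gaussian FWHM
#'
#' @param sigma width parameter, nm.
#' @param P exponent (>= 1; `P = 1` is an ordinary Gaussian).
#' @return full width at half maximum, `2*sqrt(2)*sigma*(ln 2)^(1/(2P))`.
#' @export
super_gaussian_fwhm <- function(sigma, P) {
  2 * sqrt(2) * sigma * log(2)^(1 / (2 * P))
}

#' Fit a super-Gaussian to an axial line profile
#'
#' Least-squares fit of `A * exp(-(((x - x0)^2) / (2 sigma^2))^P) +
#' baseline`; the axial thickness of the ring is reported as the FWHM. The
#' exponent is fitted freely with lower bound 1 (initialised at 1, i.e. a
#' plain Gaussian).
#'
#' @param profile axial [line_profile()].
#' @param fix_P optional fixed exponent (e.g. 1 for a pure Gaussian fit).
#' @return list of class `super_gaussian_fit`: `x0`, `sigma`, `P`, `A`,
#'   `baseline`, `fwhm`, `rss`, `converged`.
#' @export
fit_super_gaussian <- function(profile, fix_P = NULL) {
  x <- profile$positions; yv <- profile$intensities
  base0 <- min(yv)
  A0 <- max(yv) - base0
  x00 <- x[which.max(yv)]
  above <- x[yv - base0 > A0 / 2]
  s0 <- if (length(above) >= 2) diff(range(above)) / 2.355 else
    diff(range(x)) / 6
  fit_P <- is.null(fix_P)
  par0 <- c(A = A0, x0 = x00, sigma = max(s0, profile_spacing(profile)),
            P = if (fit_P) 1 else fix_P, baseline = base0)
  resid <- function(v) {
    P <- if (fit_P) v[4] else fix_P
    yv - (v[5] + v[1] * exp(-(((x - v[2])^2) / (2 * v[3]^2))^P))
  }
  lower <- c(0, min(x), profile_spacing(profile) / 10,
             if (fit_P) 1 else fix_P, -Inf)
  upper <- c(Inf, max(x), diff(range(x)),
             if (fit_P) 10 else fix_P, Inf)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  v <- fit$par
  P <- if (fit_P) v[[4]] else fix_P
  structure(list(x0 = v[[2]], sigma = v[[3]], P = P, A = v[[1]],
                 baseline = v[[5]], fwhm = super_gaussian_fwhm(v[[3]], P),
                 rss = sum(fit$fvec^2), converged = fit$info %in% 1:4),
            class = "super_gaussian_fit")
}

#' Septal density
#'
#' Total septal intensity divided by the ring circumference.
#'
#' @param total_septal_intensity baseline-subtracted total intensity along
#'   the lateral profile (ADU, after multiplying by the sample spacing if a
#'   sum of samples).
#' @param diameter ring diameter, nm.
#' @return density, ADU/nm.
#' @export
septal_density <- function(total_septal_intensity, diameter) {
  check_positive(diameter, "diameter")
  total_septal_intensity / (pi * diameter)
}

#' Quantify one horizontal-cell ring frame
#'
#' Convenience composition: extract profiles, fit the tilted circle
#' (diameter), the super-Gaussian (axial thickness FWHM), and compute the
#' septal density from the baseline-subtracted lateral total.
#'
#' @inheritParams extract_septal_profiles
#' @return one-row data frame: `diameter_nm`, `thickness_fwhm_nm`,
#'   `total_intensity`, `septal_density`.
#' @export
quantify_ring_frame <- function(image, centroid, septal_axis_angle,
                                pixel_size = 65) {
  pr <- extract_septal_profiles(image, centroid, septal_axis_angle,
                                pixel_size)
  tc <- fit_tilted_circle(pr$lateral)
  sg <- fit_super_gaussian(pr$axial)
  sp <- profile_spacing(pr$lateral)
  total <- sum(pr$lateral$intensities - tc$baseline) * sp
  data.frame(diameter_nm = tc$d, thickness_fwhm_nm = sg$fwhm,
             total_intensity = total,
             septal_density = septal_density(total, tc$d))
}
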