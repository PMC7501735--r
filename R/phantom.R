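#' Phantom description for the QA simulator
#'
#' Describes a uniform conductive phantom filled with ethylene glycol,
#' whose natural-abundance carbon-13 resonance is a 1:2:1 triplet with a
#' one-bond J coupling near 142 Hz.  Two geometries are supported: the
#' 250 mm cylinder and a head-shaped ellipse (anterior-posterior extent
#' `diameter_mm`, right-left extent 80% of it).
#'
#' @param geometry `"cylinder"` or `"head_ellipse"`.
#' @param diameter_mm outer diameter (cylinder) or AP extent (ellipse), mm.
#' @param center_mm in-plane phantom center `(x, y)` in mm, isocenter at 0.
#' @param signal_amplitude voxel signal amplitude, arbitrary units.
#' @param t2star_ms effective transverse relaxation time (ms).
#' @param t1_ms longitudinal relaxation time (ms); about 700 ms for
#'   ethylene glycol at room temperature and 3T.
#' @param j_hz scalar J coupling of the triplet (Hz).
#' @param line_amplitudes relative amplitudes of the three triplet lines.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("cylinder", "head_ellipse"),
                         diameter_mm = 250, center_mm = c(0, 0),
                         signal_amplitude = 1, t2star_ms = 85, t1_ms = 700,
                         j_hz = 142, line_amplitudes = c(1, 2, 1)) {
  geometry <- match.arg(geometry)
  if (diameter_mm <= 0) stopf("diameter_mm must be > 0")
  if (t2star_ms <= 0) stopf("t2star_ms must be > 0")
  if (j_hz <= 0) stopf("j_hz must be > 0")
  if (length(line_amplitudes) != 3 || any(line_amplitudes < 0) ||
      sum(line_amplitudes) == 0)
    stopf("line_amplitudes must be three non-negative values, not all zero")
  structure(list(geometry = geometry, diameter_mm = diameter_mm,
                 center_mm = center_mm, signal_amplitude = signal_amplitude,
                 t2star_ms = t2star_ms, t1_ms = t1_ms, j_hz = j_hz,
                 line_amplitudes = line_amplitudes / sum(line_amplitudes)),
            class = "phantom_spec")
}

# Voxel-center coordinates (mm) along one image axis: the DC voxel
# (0-based index n/2) sits exactly at isocenter.
grid_coords <- function(n, fov_mm) {
  ((seq_len(n) - 1) - floor(n / 2)) * (fov_mm / n)
}

#' Partial-volume phantom support mask
#'
#' Voxel values are the area fraction of the voxel inside the phantom
#' boundary, estimated by 8x8 supersampling: 1 deep inside, 0 outside.
#'
#' @param spec a [phantom_spec()].
#' @param acq an [acquisition_spec()].
#' @param supersample subdivisions per axis for the area estimate.
#' @return Numeric `[ny, nx]` matrix in `[0, 1]`.
#' @export
phantom_mask <- function(spec, acq, supersample = 8) {
  n <- acq$matrix_size
  ax <- spec$diameter_mm / 2                      # AP semi-axis
  bx <- if (spec$geometry == "head_ellipse") 0.8 * ax else ax  # RL
  if (abs(spec$center_mm[2]) + ax > acq$fov_mm[1] / 2 ||
      abs(spec$center_mm[1]) + bx > acq$fov_mm[2] / 2)
    stopf("phantom (extent %g x %g mm) does not fit within the FOV",
          2 * bx, 2 * ax)
  dy <- acq$fov_mm[1] / n[1]; dx <- acq$fov_mm[2] / n[2]
  y0 <- grid_coords(n[1], acq$fov_mm[1])          # rows: anterior->posterior
  x0 <- grid_coords(n[2], acq$fov_mm[2])          # cols: right->left
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  m <- matrix(0, n[1], n[2])
  for (oy in off) for (ox in off) {
    yy <- (y0 + oy * dy - spec$center_mm[2]) / ax
    xx <- (x0 + ox * dx - spec$center_mm[1]) / bx
    m <- m + (outer(yy^2, xx^2, `+`) <= 1)
  }
  m / supersample^2
}

#' Coil layout for the simulator
#'
#' Either a uniform-sensitivity volume coil or a list of circular loops,
#' each given by a 3-D center (mm), a radius (mm) and a unit normal.
#'
#' @param elements list of loops `list(center_mm =, radius_mm =, normal =)`,
#'   or `NULL` for a uniform volume coil.
#' @param uniform logical; `TRUE` for the volume coil.
#' @param name label used in reports.
#' @return An object of class `coil_layout`.
#' @export
coil_layout <- function(elements = NULL, uniform = is.null(elements),
                        name = "custom") {
  if (uniform) {
    return(structure(list(elements = NULL, uniform = TRUE, n_channels = 1L,
                          name = name), class = "coil_layout"))
  }
  for (e in elements) {
    if (e$radius_mm <= 0) stopf("loop radius must be > 0")
    nn <- sqrt(sum(e$normal^2))
    if (abs(nn - 1) > 1e-6) stopf("loop normals must be unit length")
  }
  structure(list(elements = elements, uniform = FALSE,
                 n_channels = length(elements), name = name),
            class = "coil_layout")
}

#' Shipped synthetic coil layouts
#'
#' `"array14"`: 14 loops of 80 mm diameter equally spaced on a 250 mm
#' circle (a head-sized single-row receive array). `"array8"`: two 4-loop
#' paddles above and below the sample. `"volume"`: a uniform-sensitivity
#' single-channel volume coil. `"loop1"`: one 80 mm surface loop.
#'
#' @param name layout name.
#' @return A [coil_layout()].
#' @export
builtin_layout <- function(name = c("array14", "array8", "volume", "loop1")) {
  name <- match.arg(name)
  loop <- function(cx, cy, cz, r, nx, ny, nz)
    list(center_mm = c(cx, cy, cz), radius_mm = r, normal = c(nx, ny, nz))
  switch(name,
    volume = coil_layout(NULL, uniform = TRUE, name = "volume"),
    loop1 = coil_layout(list(loop(0, -128, 0, 40, 0, 1, 0)), name = "loop1"),
    array14 = {
      th <- 2 * pi * (seq_len(14) - 1) / 14
      els <- lapply(th, function(a)
        loop(128 * sin(a), -128 * cos(a), 0, 40, -sin(a), cos(a), 0))
      coil_layout(els, name = "array14")
    },
    array8 = {
      xs <- c(-120, -40, 40, 120)
      top <- lapply(xs, function(x) loop(x, -135, 0, 40, 0, 1, 0))
      bot <- lapply(xs, function(x) loop(x, 135, 0, 40, 0, -1, 0))
      coil_layout(c(top, bot), name = "array8")
    })
}

#' Quasi-static receive profile of a circular loop
#'
#' Computes the magnetic field of the loop per unit current at every voxel
#' center of the imaging grid by numerical Biot-Savart line integration
#' (the loop is discretized into straight segments).  The returned complex
#' sensitivity has magnitude `|B|` and phase `arg(Bx - i By)`, the phase of
#' the transverse circularly polarized component, so that array phase
#' diversity is realistic for combination tests.
#'
#' @param loop one element of a [coil_layout()].
#' @param acq an [acquisition_spec()].
#' @param slice_z_mm through-plane position of the imaged slice (mm).
#' @param n_segments segments for the line integration.
#' @return Complex `[ny, nx]` matrix.  Voxels that fall on the wire path
#'   are evaluated at a small offset and recorded in the
#'   `"wire_flagged"` attribute.
#' @export
loop_sensitivity <- function(loop, acq, slice_z_mm = 0, n_segments = 72) {
  if (loop$radius_mm <= 0) stopf("loop radius must be > 0")
  n <- acq$matrix_size
  y0 <- grid_coords(n[1], acq$fov_mm[1])
  x0 <- grid_coords(n[2], acq$fov_mm[2])
  pts <- cbind(x = rep(x0, each = n[1]), y = rep(y0, times = n[2]),
               z = slice_z_mm)

  # orthonormal frame spanning the loop plane
  nv <- loop$normal / sqrt(sum(loop$normal^2))
  ref <- if (abs(nv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * nv) * nv; u <- u / sqrt(sum(u^2))
  v <- c(nv[2] * u[3] - nv[3] * u[2], nv[3] * u[1] - nv[1] * u[3],
         nv[1] * u[2] - nv[2] * u[1])
  th <- 2 * pi * (seq_len(n_segments) - 0.5) / n_segments
  wire <- matrix(loop$center_mm, n_segments, 3, byrow = TRUE) +
    loop$radius_mm * (cos(th) %o% u + sin(th) %o% v)
  dth <- 2 * pi / n_segments
  dl <- loop$radius_mm * dth * (-sin(th) %o% u + cos(th) %o% v)

  B <- matrix(0, nrow(pts), 3)
  eps <- 1e-3 * loop$radius_mm
  flagged <- rep(FALSE, nrow(pts))
  for (s in seq_len(n_segments)) {
    r <- sweep(pts, 2, wire[s, ])
    d <- sqrt(rowSums(r^2))
    near <- d < eps
    if (any(near)) {            # on-wire voxels: evaluate at a small offset
      flagged <- flagged | near
      r[near, ] <- r[near, , drop = FALSE] +
        matrix(eps * nv, sum(near), 3, byrow = TRUE)
      d[near] <- sqrt(rowSums(r[near, , drop = FALSE]^2))
    }
    cr <- cbind(dl[s, 2] * r[, 3] - dl[s, 3] * r[, 2],
                dl[s, 3] * r[, 1] - dl[s, 1] * r[, 3],
                dl[s, 1] * r[, 2] - dl[s, 2] * r[, 1])
    B <- B + cr / d^3
  }
  mag <- sqrt(rowSums(B^2))
  phase <- Arg(complex(real = B[, 1], imaginary = -B[, 2]))
  out <- matrix(complex(modulus = mag, argument = phase), n[1], n[2])
  if (any(flagged)) attr(out, "wire_flagged") <- which(matrix(flagged, n[1], n[2]), arr.ind = TRUE)
  out
}

# Sensitivities for a whole layout: [ny, nx, channel].
layout_sensitivities <- function(coils, acq, slice_z_mm = 0) {
  n <- acq$matrix_size
  if (coils$uniform)
    return(array(1 + 0i, dim = c(n[1], n[2], 1)))
  b <- array(0i, dim = c(n[1], n[2], coils$n_channels))
  for (c in seq_len(coils$n_channels))
    b[, , c] <- loop_sensitivity(coils$elements[[c]], acq, slice_z_mm)
  # scale so the strongest channel peaks at 1 inside the FOV
  b / max(Mod(b))
}
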