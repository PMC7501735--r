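# Self-describing HDF5 container for raw CSI, noise records and derived
# maps.  Layout (schema_version 1):
#   /raw/kspace_re, /raw/kspace_im    float64 [kx, ky, channel, time]
#   /noise/fid_re, /noise/fid_im      float64 [channel, samples]
#   /derived/<field>{_re,_im}         float64 maps
# Root attributes: schema_version, kind, and all acquisition metadata with
# units in the attribute names (fov_mm, te_ms, ...).  Complex data are
# stored as paired real/imag float64 datasets.  Dataset shapes are declared
# in the logical axis order above; indexing is 0-based on disk.

SCHEMA_VERSION <- 1L

# -- low-level helpers -------------------------------------------------

h5_write_raw <- function(path, datasets, attrs) {
  nm <- names(datasets)
  dims <- lapply(datasets, function(x) {
    d <- dim(x); if (is.null(d)) d <- length(x); as.integer(d)
  })
  bufs <- lapply(datasets, function(x) {
    d <- dim(x)
    if (!is.null(d) && length(d) > 1) x <- aperm(x, rev(seq_along(d)))
    as.double(x)
  })
  avals <- lapply(attrs, function(v) {
    if (is.character(v)) v else if (is.integer(v)) v else as.double(v)
  })
  .Call(C_h5_write, path.expand(path), nm, dims, bufs,
        names(attrs), avals)
  invisible(NULL)
}

h5_read_raw <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  r <- .Call(C_h5_read, path.expand(path))
  ds <- mapply(function(d, x) {
    if (length(d) > 1) {
      x <- array(x, dim = rev(d))
      x <- aperm(x, rev(seq_along(d)))
    }
    x
  }, r$ds_dims, r$ds_data, SIMPLIFY = FALSE)
  names(ds) <- r$ds_names
  at <- r$at_vals
  names(at) <- r$at_names
  list(datasets = ds, attrs = at)
}

cplx <- function(re, im) {
  z <- complex(real = as.vector(re), imaginary = as.vector(im))
  if (!is.null(dim(re))) dim(z) <- dim(re)
  z
}

acq_to_attrs <- function(acq) {
  list(fov_mm = acq$fov_mm, matrix_size = as.integer(acq$matrix_size),
       slice_thickness_mm = acq$slice_thickness_mm,
       spectral_bw_hz = acq$spectral_bw_hz,
       n_fid_points = as.integer(acq$n_fid_points),
       te_ms = acq$te_ms, tr_ms = acq$tr_ms,
       nominal_flip_deg = acq$nominal_flip_deg,
       center_freq_hz = acq$center_freq_hz, nucleus = acq$nucleus)
}

acq_from_attrs <- function(at) {
  acquisition_spec(fov_mm = at$fov_mm, matrix_size = at$matrix_size,
                   slice_thickness_mm = at$slice_thickness_mm,
                   spectral_bw_hz = at$spectral_bw_hz,
                   n_fid_points = at$n_fid_points, te_ms = at$te_ms,
                   tr_ms = at$tr_ms, nominal_flip_deg = at$nominal_flip_deg,
                   center_freq_hz = at$center_freq_hz, nucleus = at$nucleus)
}

# -- payload serialization per kind ------------------------------------

container_payload <- function(x) UseMethod("container_payload")

#' @export
#' @noRd
container_payload.csi_raw_data <- function(x) {
  list(kind = "csi_raw",
       datasets = list("raw/kspace_re" = Re(x$kspace),
                       "raw/kspace_im" = Im(x$kspace)),
       attrs = c(acq_to_attrs(x$acq),
                 list(channel_labels = paste(x$channel_labels,
                                             collapse = ","))))
}

#' @export
#' @noRd
container_payload.noise_record <- function(x) {
  list(kind = "noise",
       datasets = list("noise/fid_re" = Re(x$fid),
                       "noise/fid_im" = Im(x$fid)),
       attrs = list(noise_spectral_bw_hz = x$spectral_bw_hz,
                    noise_n_samples = as.integer(x$n_samples)))
}

#' @export
#' @noRd
container_payload.noise_model <- function(x) {
  list(kind = "noise_model",
       datasets = list("derived/psi_re" = Re(x$psi),
                       "derived/psi_im" = Im(x$psi)),
       attrs = list(neb_factor = x$neb_factor,
                    psi_scaled = as.integer(x$scaled)))
}

#' @export
#' @noRd
container_payload.signal_map <- function(x) {
  list(kind = "signal_map",
       datasets = list("derived/s_re" = Re(x$s), "derived/s_im" = Im(x$s)),
       attrs = list(inphase_time_ms = x$inphase_time_ms,
                    inphase_index = as.integer(x$inphase_index),
                    filter_gain = x$filter_gain))
}

#' @export
#' @noRd
container_payload.sensitivity_map <- function(x) {
  list(kind = "sensitivity_map",
       datasets = list("derived/b_re" = Re(x$b), "derived/b_im" = Im(x$b),
                       "derived/mask" = x$mask + 0),
       attrs = list(norm_convention = x$norm_convention))
}

#' @export
#' @noRd
container_payload.snr_map <- function(x) {
  list(kind = "snr_map",
       datasets = list("derived/snr" = x$snr, "derived/mask" = x$mask + 0),
       attrs = list(n_channels = as.integer(x$n_channels)))
}

#' @export
#' @noRd
container_payload.gfactor_map <- function(x) {
  list(kind = "gfactor_map",
       datasets = list("derived/g" = x$g, "derived/mask" = x$mask + 0),
       attrs = list(accel_R = as.integer(x$accel_R), direction = x$direction))
}

#' @export
#' @noRd
container_payload.tx_map <- function(x) {
  list(kind = "tx_map",
       datasets = list("derived/beta" = x$beta),
       attrs = list(tx_smoothed = as.integer(x$smoothed)))
}

#' Write a typed object (or raw+noise bundle) to the HDF5 container
#'
#' All package types round-trip losslessly: complex arrays are stored as
#' paired float64 real/imag datasets, metadata as root attributes, and a
#' mandatory `schema_version` attribute identifies the layout.
#'
#' @param data a package object ([csi_raw_data()], [noise_record()],
#'   [noise_model()], [signal_map()], [sensitivity_map()], [snr_map()],
#'   [gfactor_map()], [tx_map()]), or an unnamed-class list
#'   `list(raw = , noise = )` which is written as a combined acquisition
#'   bundle (the pipeline's preferred input).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(data, path) {
  if (is.list(data) && is.null(attr(data, "class")) &&
      all(names(data) %in% c("raw", "noise")) && length(data) > 0) {
    if (is.null(data$raw)) stopf("bundle requires a 'raw' element")
    p1 <- container_payload(data$raw)
    datasets <- p1$datasets; attrs <- p1$attrs; kind <- "csi_bundle"
    if (!is.null(data$noise)) {
      if (nrow(data$noise$fid) != dim(data$raw$kspace)[3])
        stopf("noise record channel count (%d) != raw data channels (%d)",
              nrow(data$noise$fid), dim(data$raw$kspace)[3])
      p2 <- container_payload(data$noise)
      datasets <- c(datasets, p2$datasets)
      attrs <- c(attrs, p2$attrs)
    }
  } else {
    p <- container_payload(data)
    datasets <- p$datasets; attrs <- p$attrs; kind <- p$kind
  }
  attrs <- c(list(schema_version = SCHEMA_VERSION, kind = kind), attrs)
  h5_write_raw(path, datasets, attrs)
  invisible(path)
}

#' Read a typed object back from the HDF5 container
#'
#' Re-validates all type invariants on load; an unknown `schema_version`
#' or `kind`, or dataset shapes inconsistent with the stored metadata,
#' raise an error rather than returning a partially valid object.
#'
#' @param path file written by [write_container()].
#' @return The stored object; for a combined acquisition bundle, a list
#'   with elements `raw` and (if present) `noise`.
#' @export
read_container <- function(path) {
  r <- h5_read_raw(path)
  at <- r$attrs; ds <- r$datasets
  if (is.null(at$schema_version))
    stopf("not a coilqa container: missing schema_version attribute")
  if (as.integer(at$schema_version) != SCHEMA_VERSION)
    stopf("unsupported container schema_version %s (supported: %d)",
          format(at$schema_version), SCHEMA_VERSION)
  kind <- at$kind
  read_one <- function(kind) {
    switch(kind,
      csi_raw = , csi_bundle = {
        acq <- acq_from_attrs(at)
        ks <- cplx(ds[["raw/kspace_re"]], ds[["raw/kspace_im"]])
        labs <- strsplit(at$channel_labels, ",", fixed = TRUE)[[1]]
        csi_raw_data(ks, acq, labs)
      },
      noise = {
        fid <- cplx(ds[["noise/fid_re"]], ds[["noise/fid_im"]])
        nr <- noise_record(fid, at$noise_spectral_bw_hz)
        if (nr$n_samples != as.integer(at$noise_n_samples))
          stopf("noise record n_samples attribute (%d) != stored data (%d)",
                as.integer(at$noise_n_samples), nr$n_samples)
        nr
      },
      noise_model = noise_model(cplx(ds[["derived/psi_re"]],
                                     ds[["derived/psi_im"]]),
                                at$neb_factor, as.logical(at$psi_scaled)),
      signal_map = signal_map(cplx(ds[["derived/s_re"]],
                                   ds[["derived/s_im"]]),
                              at$inphase_time_ms, at$inphase_index,
                              at$filter_gain),
      sensitivity_map = sensitivity_map(cplx(ds[["derived/b_re"]],
                                             ds[["derived/b_im"]]),
                                        ds[["derived/mask"]] > 0,
                                        at$norm_convention),
      snr_map = snr_map(ds[["derived/snr"]], ds[["derived/mask"]] > 0,
                        at$n_channels),
      gfactor_map = gfactor_map(ds[["derived/g"]], at$accel_R, at$direction,
                                ds[["derived/mask"]] > 0),
      tx_map = tx_map(ds[["derived/beta"]], as.logical(at$tx_smoothed)),
      stopf("unknown container kind '%s'", kind))
  }
  if (identical(kind, "csi_bundle")) {
    out <- list(raw = read_one("csi_raw"))
    if (!is.null(ds[["noise/fid_re"]])) out$noise <- read_one("noise")
    out
  } else {
    read_one(kind)
  }
}
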