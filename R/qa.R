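#' @keywords internal
#' @useDynLib coilqa, .registration = TRUE
"_PACKAGE"

qa_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

write_map_png <- function(x, path, main = "") {
  grDevices::png(path, width = 600, height = 560)
  op <- graphics::par(mar = c(2, 2, 3, 6))
  z <- t(x)[, rev(seq_len(nrow(x)))]      # display with row 1 on top
  zr <- range(z, finite = TRUE)
  graphics::image(z, col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = main, useRaster = TRUE)
  graphics::mtext(sprintf("min %.3g  max %.3g", zr[1], zr[2]), side = 1)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Run the full QA protocol end-to-end
#'
#' Executes the complete chain: reconstruction, noise-std-preserving
#' spectral filtering, first in-phase signal extraction, noise covariance
#' estimation with noise-equivalent-bandwidth scaling, sensitivity
#' estimation (arrays), covariance-weighted SNR mapping, summary
#' statistics, noise-correlation summaries and optional g-factor maps.
#' Identical config and seed give identical results; all applied scale
#' factors are recorded in the provenance block.
#'
#' @param config named list (or path to a YAML file) with keys:
#'   \describe{
#'     \item{input}{path to a container holding raw + noise data, or}
#'     \item{simulate}{list with `layout` (see [builtin_layout()]),
#'       optional `phantom` arguments for [phantom_spec()], `noise`
#'       (list `sigma`, optional uniform off-diagonal `rho`), and `seed`.}
#'     \item{band_ppm}{spectral window half-width, default 10.}
#'     \item{j_hz}{J coupling, default 142; `"auto"` estimates it from
#'       the highest-magnitude voxel.}
#'     \item{neb}{`"estimate"` (default) or an explicit factor such as
#'       0.845 (GE) / 0.793 (Siemens).}
#'     \item{gfactor_R}{acceleration factors for arrays, default `c(2, 4)`.}
#'     \item{gfactor_direction}{`"row"` or `"col"`, default `"col"`.}
#'     \item{out}{optional output directory for maps, CSVs and the JSON
#'       summary.}
#'   }
#' @param verbose log stage-by-stage progress.
#' @return A QA bundle: list with the SNR map, summaries, noise model,
#'   correlation summaries, sensitivity and g-factor maps (arrays), the
#'   provenance block and (if simulated) the ground truth.
#' @export
run_qa <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  band_ppm <- config$band_ppm %||% 10
  gf_R <- config$gfactor_R %||% c(2, 4)
  gf_dir <- config$gfactor_direction %||% "col"

  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    layout <- builtin_layout(sc$layout %||% "volume")
    phantom <- do.call(phantom_spec, sc$phantom %||% list())
    nch <- layout$n_channels
    sigma <- sc$noise$sigma %||% 0.01
    rho <- sc$noise$rho %||% 0
    psi <- diag(sigma^2, nch)
    psi[psi == 0] <- rho * sigma^2
    acq <- do.call(acquisition_spec, sc$acq %||% list())
    seed <- as.integer(sc$seed %||% 1L)
    qa_log(verbose, "simulate", "layout %s, %d channel(s), seed %d",
           layout$name, nch, seed)
    sim <- simulate_csi(phantom, layout, acq, psi, seed,
                        band_ppm = band_ppm)
    raw <- sim$raw; noise_rec <- sim$noise; truth <- sim$truth
    coil_label <- layout$name
    phantom_label <- phantom$geometry
  } else if (!is.null(config$input)) {
    obj <- read_container(config$input)
    if (is.null(obj$noise))
      stopf("the QA protocol requires a noise record; container '%s' has none",
            config$input)
    raw <- obj$raw; noise_rec <- obj$noise
    coil_label <- config$coil %||% basename(config$input)
    phantom_label <- config$phantom_label %||% "unknown"
  } else {
    stopf("config must provide either 'input' or 'simulate'")
  }
  acq <- raw$acq
  nch <- dim(raw$kspace)[3]
  if (nrow(noise_rec$fid) != nch)
    stopf("noise record has %d channel(s) but raw data %d",
          nrow(noise_rec$fid), nch)

  qa_log(verbose, "recon", "unitary spatial DFT, %dx%d matrix",
         acq$matrix_size[1], acq$matrix_size[2])
  img <- recon_csi(raw)

  qa_log(verbose, "filter", "rectangular +-%g ppm, noise-std preserving",
         band_ppm)
  img <- spectral_filter(img, band_ppm, acq)
  filter_gain <- attr(img, "filter_gain")

  j_hz <- config$j_hz %||% 142
  if (identical(j_hz, "auto")) {
    mag3 <- apply(Mod(img), c(1, 2), max)
    hot <- which(mag3 == max(mag3), arr.ind = TRUE)[1, ]
    spec1 <- voxel_spectrum(img[hot[1], hot[2], 1, ])
    j_hz <- estimate_j_coupling(spec1, acq)
    qa_log(verbose, "signal", "estimated J = %.1f Hz", j_hz)
  }
  ip <- first_inphase_sample(j_hz, acq$te_ms, acq)
  qa_log(verbose, "signal", "first in-phase point %.2f ms (sample %d)",
         ip$snapped_time_ms, ip$index)
  s <- extract_signal(img, ip$index, ip$time_ms)

  qa_log(verbose, "noise", "covariance from %d samples", noise_rec$n_samples)
  nm <- estimate_noise_covariance(noise_rec)
  neb <- config$neb %||% "estimate"
  if (identical(neb, "estimate")) neb <- estimate_neb_factor(noise_rec)
  nm <- scale_covariance(nm, neb)
  qa_log(verbose, "noise", "neb factor %.4g applied", neb)
  corr <- correlation_matrix(nm)

  mask <- derive_mask(s, nm)
  sens <- NULL
  gmaps <- list()
  if (nch == 1) {
    qa_log(verbose, "snr", "single receiver: SNR = sqrt(2) |s| / sigma")
    map <- snr_map_single(s, nm, mask)
  } else {
    qa_log(verbose, "sens", "Perona-Malik sensitivity extraction, %d channels",
           nch)
    sens <- estimate_sensitivities(s, nm, mask,
                                   pm_config = config$pm_config %||% list())
    qa_log(verbose, "snr", "covariance-weighted coil combination")
    map <- snr_map_array(s, sens, nm)
    for (R in gf_R) {
      key <- sprintf("R%d", R)
      gmaps[[key]] <- sense_gfactor(sens, nm, R, gf_dir, mask)
      qa_log(verbose, "gfactor", "R = %d (%s): max g %.3f", R, gf_dir,
             max(gmaps[[key]]$g[mask], na.rm = TRUE))
    }
  }
  summ <- snr_summary(map)

  provenance <- list(
    package_version = as.character(utils::packageVersion("coilqa")),
    coil = coil_label, phantom = phantom_label,
    n_channels = nch,
    seed = if (!is.null(config$simulate)) config$simulate$seed %||% 1 else NULL,
    scalings = list(fft_norm = "unitary",
                    filter_gain = filter_gain,
                    neb_factor = neb,
                    snr_prefactor = sqrt(2)),
    inphase = ip, j_hz = j_hz, band_ppm = band_ppm,
    config_hash = config_hash(config))

  bundle <- list(snr = map, summary = summ, noise_model = nm,
                 correlation = corr, sensitivity = sens, gfactor = gmaps,
                 signal = s, mask = mask, acq = acq,
                 provenance = provenance, truth = truth)
  class(bundle) <- "qa_bundle"
  if (!is.null(config$out)) write_qa_outputs(bundle, config$out)
  bundle
}

config_hash <- function(config) {
  config$out <- NULL          # the destination is not an analysis parameter
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.qa_bundle <- function(x, ...) {
  cat(sprintf("QA bundle: coil '%s', phantom '%s', %d channel(s)\n",
              x$provenance$coil, x$provenance$phantom,
              x$provenance$n_channels))
  cat(sprintf("  center SNR %.3g, surface SNR %.3g\n",
              x$summary$center, x$summary$surface))
  if (x$provenance$n_channels > 1)
    cat(sprintf("  noise correlation: max %.3f, mean %.3f\n",
                x$correlation$max_offdiag, x$correlation$mean_offdiag))
  for (nm in names(x$gfactor)) {
    g <- x$gfactor[[nm]]
    cat(sprintf("  g-factor %s (%s): max %.3f\n", nm, g$direction,
                max(g$g[g$mask], na.rm = TRUE)))
  }
  invisible(x)
}

write_qa_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_container(bundle$snr, file.path(out_dir, "snr_map.h5"))
  write_map_png(bundle$snr$snr, file.path(out_dir, "snr_map.png"),
                sprintf("SNR (%s)", bundle$provenance$coil))
  if (!is.null(bundle$sensitivity)) {
    write_container(bundle$sensitivity, file.path(out_dir, "sensitivity.h5"))
    utils::write.csv(bundle$correlation$r,
                     file.path(out_dir, "noise_correlation.csv"),
                     row.names = FALSE)
    write_map_png(bundle$correlation$r,
                  file.path(out_dir, "noise_correlation.png"),
                  "noise correlation |r|")
  }
  for (nm in names(bundle$gfactor)) {
    g <- bundle$gfactor[[nm]]
    write_container(g, file.path(out_dir, sprintf("gfactor_%s.h5", nm)))
    g2 <- g$g; g2[is.na(g2)] <- 0
    write_map_png(g2, file.path(out_dir, sprintf("gfactor_%s.png", nm)),
                  sprintf("g-factor %s", nm))
  }
  prof <- data.frame(position = seq_along(bundle$summary$profile_ap),
                     profile_ap = bundle$summary$profile_ap,
                     profile_rl = bundle$summary$profile_rl)
  utils::write.csv(prof, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)
  summary_json <- list(
    coil = bundle$provenance$coil, phantom = bundle$provenance$phantom,
    n_channels = bundle$provenance$n_channels,
    center_snr = bundle$summary$center, surface_snr = bundle$summary$surface,
    max_noise_correlation = bundle$correlation$max_offdiag,
    mean_noise_correlation = bundle$correlation$mean_offdiag,
    gfactor_max = lapply(bundle$gfactor, function(g)
      max(g$g[g$mask], na.rm = TRUE)),
    provenance = bundle$provenance)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare QA bundles of several coils
#'
#' Builds the benchmark table: absolute center/surface SNR per coil plus
#' relative columns normalized to the per-metric maximum (100%).
#' Comparisons require a common phantom geometry; mixing phantoms is an
#' error because surface-to-center distances differ.
#'
#' @param bundles list of two or more QA bundles from [run_qa()].
#' @param out optional directory for the comparison CSV and overlaid
#'   profile figure.
#' @return A data frame with columns `coil`, `n_channels`, `center_abs`,
#'   `center_rel`, `surface_abs`, `surface_rel` (relative values in %).
#' @export
compare_coils <- function(bundles, out = NULL) {
  if (length(bundles) < 2) stopf("need at least 2 bundles to compare")
  phantoms <- vapply(bundles, function(b) b$provenance$phantom, "")
  if (length(unique(phantoms)) != 1)
    stopf("bundles use different phantoms (%s); comparison not meaningful",
          paste(unique(phantoms), collapse = ", "))
  tab <- data.frame(
    coil = vapply(bundles, function(b) b$provenance$coil, ""),
    n_channels = vapply(bundles, function(b) b$provenance$n_channels, 0L),
    center_abs = vapply(bundles, function(b) b$summary$center, 0),
    surface_abs = vapply(bundles, function(b) b$summary$surface, 0))
  tab$center_rel <- 100 * tab$center_abs / max(tab$center_abs, na.rm = TRUE)
  tab$surface_rel <- 100 * tab$surface_abs / max(tab$surface_abs, na.rm = TRUE)
  tab <- tab[, c("coil", "n_channels", "center_abs", "center_rel",
                 "surface_abs", "surface_rel")]
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out, "comparison.csv"), row.names = FALSE)
    grDevices::png(file.path(out, "profiles.png"), width = 900, height = 450)
    op <- graphics::par(mfrow = c(1, 2))
    for (dirn in c("profile_ap", "profile_rl")) {
      ylim <- range(unlist(lapply(bundles, function(b) b$summary[[dirn]])))
      graphics::plot(NULL, xlim = c(1, length(bundles[[1]]$summary[[dirn]])),
                     ylim = ylim, xlab = "voxel", ylab = "SNR",
                     main = sub("profile_", "", dirn))
      for (i in seq_along(bundles))
        graphics::lines(bundles[[i]]$summary[[dirn]], col = i, lwd = 2)
      graphics::legend("topright", legend = tab$coil, col = seq_along(bundles),
                       lwd = 2, bty = "n")
    }
    graphics::par(op)
    grDevices::dev.off()
  }
  tab
}
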