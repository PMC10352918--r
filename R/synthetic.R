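# Synthetic data generator emulating the statistical structure of a cotton
# saline-soil amelioration trial: layered soil salinity by treatment and
# growth stage, salinity-suppressed growth parameters whose coupling weakens
# over time, and canopy reflectance whose shape responds to salinity
# (visible up, long-wave infrared down).

#' Layer-averaged soil salinity table from the cotton amelioration trial
#'
#' Treatment-by-stage means and standard deviations of EC_1:5 (dS/m) for the
#' layer averages S1 (0-20 cm), S2 (0-40 cm) and S3 (0-60 cm), as reported
#' for a four-treatment cotton field trial (7 replicates per cell). The four
#' treatments are a stone salt-isolation layer (T1), subsurface drainage
#' (T2), plain cropping (T3) and late-started cropping on unameliorated soil
#' (T4); mean salinity orders T2 < T1 < T3 < T4 and every trajectory dips at
#' 124 days after sowing. These means parameterize the synthetic generator's
#' salinity surface.
#'
#' @return data.frame with columns `layer` ("S1", "S2", "S3"), `das`,
#'   `treatment`, `ec_mean`, `ec_sd`.
#' @export
field_ec_table <- function() {
  das <- c(76, 111, 124, 142, 162)
  # columns T1..T4: mean, sd pairs per stage row
  s1 <- list(
    m = c(2.44, 2.39, 2.82, 4.56, 2.35, 2.34, 2.74, 4.28, 2.24, 2.30, 2.57,
          3.83, 2.33, 2.35, 2.86, 3.87, 2.42, 2.41, 3.13, 3.99),
    s = c(0.44, 0.39, 0.28, 0.93, 0.13, 0.26, 0.44, 0.54, 0.54, 0.26, 0.48,
          0.23, 0.45, 0.51, 0.27, 0.30, 0.55, 0.29, 0.65, 0.66))
  s2 <- list(
    m = c(2.65, 2.35, 2.80, 4.32, 2.54, 2.27, 2.69, 3.96, 2.33, 2.23, 2.66,
          3.72, 2.47, 2.29, 2.85, 3.80, 2.55, 2.33, 2.98, 3.86),
    s = c(0.52, 0.37, 0.46, 0.88, 0.19, 0.25, 0.51, 0.71, 0.67, 0.28, 0.60,
          0.42, 0.26, 0.48, 0.25, 0.25, 0.53, 0.34, 0.69, 0.73))
  s3 <- list(
    m = c(2.81, 2.24, 3.15, 4.37, 2.70, 2.13, 2.88, 4.15, 2.65, 2.03, 2.85,
          3.85, 2.79, 2.21, 3.24, 4.25, 2.84, 2.28, 3.35, 4.37),
    s = c(0.62, 0.34, 0.52, 0.80, 0.25, 0.42, 0.37, 0.57, 0.41, 0.38, 0.63,
          0.43, 0.32, 0.35, 0.24, 0.32, 0.52, 0.51, 0.82, 0.93))
  build <- function(label, x) {
    data.frame(layer = label,
               das = rep(das, each = 4L),
               treatment = rep(c("T1", "T2", "T3", "T4"), times = 5L),
               ec_mean = x$m, ec_sd = x$s)
  }
  rbind(build("S1", s1), build("S2", s2), build("S3", s3))
}

# Per-layer (0-20, 20-40, 40-60 cm) mean ECs recovered from the cumulative
# layer averages: l1 = S1, l2 = 2*S2 - S1, l3 = 3*S3 - 2*S2.
layer_means_from_table <- function(ec_table) {
  wide <- stats::reshape(ec_table[, c("layer", "das", "treatment", "ec_mean")],
                         idvar = c("das", "treatment"), timevar = "layer",
                         direction = "wide")
  names(wide) <- sub("^ec_mean\\.", "", names(wide))
  wide$l1 <- wide$S1
  wide$l2 <- 2 * wide$S2 - wide$S1
  wide$l3 <- 3 * wide$S3 - 2 * wide$S2
  if (any(wide$l2 <= 0 | wide$l3 <= 0)) stop("EC table implies non-positive layer means")
  wide
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults emulate the trial layout: 4 treatments x 5 stages x 7 replicates
#' = 140 samples, salinity means from [field_ec_table()], growth parameters
#' negatively coupled to 0-40 cm salinity with coupling that attenuates over
#' stages, and canopy spectra on the full 350-2500 nm grid at 1 nm whose
#' visible reflectance rises and long-wave infrared reflectance falls with
#' salinity. Effect sizes are synthetic choices (the emulated study reports
#' none); see the package vignette for the rationale behind each default.
#'
#' @param n_reps replicates per treatment x stage cell (default 7).
#' @param ec_table layer-average EC means/sds (format of [field_ec_table()]).
#' @param ec_sd within-cell EC standard deviation, dS/m (default 0.35, the
#'   scale of the tabulated replicate sds).
#' @param ec_floor smallest admissible EC; draws at or below it are redrawn.
#' @param latent_sd sd (dS/m) of the mismatch between 0-40 cm EC and the
#'   salinity signal actually expressed in the canopy spectrum; this is what
#'   caps the attainable prediction accuracy below 1.
#' @param growth named list of growth-curve parameters: logistic plant
#'   height (`h_max` cm, midpoint `h_mid` DAS, scale `h_tau`), logistic
#'   aboveground biomass (`agb_*`, g/plant, with post-peak decay factor
#'   `agb_decay` and an earlier peak under high salinity), linear shoot
#'   water content decline (`swc_*`, fraction), per-dS/m suppression slopes
#'   (`*_slope`), replicate noise sds (`*_noise`), and the stage attenuation
#'   schedule `attenuation` multiplying every suppression slope.
#' @param spectral named list: `informative_bands` (nm) carrying a direct
#'   salinity signal of amplitude `band_effect` (reflectance per dS/m,
#'   Gaussian width `band_width` nm); broad effects `vis_effect` (additive,
#'   400-780 nm) and `lwir_effect` (relative, 1100-2400 nm) per dS/m with
#'   raised-cosine edge tapers of width `taper` nm; AR(1) noise (`noise_sd`,
#'   correlation length `noise_corr_length` nm); per-sample multiplicative
#'   `gain_sd` and additive `offset_sd` (canopy geometry / illumination
#'   drift).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_reps = 7,
                             ec_table = field_ec_table(),
                             ec_sd = 0.35,
                             ec_floor = 0.05,
                             latent_sd = 0.5,
                             growth = list(),
                             spectral = list()) {
  growth_defaults <- list(
    h_max = 95, h_mid = 95, h_tau = 12, h_slope = 0.10, h_noise_cv = 0.03,
    agb_max = 120, agb_mid = 105, agb_tau = 10, agb_slope = 0.12,
    agb_noise_cv = 0.08, agb_decay = 0.97,
    swc_start = 0.78, swc_rate = 0.0012, swc_slope = 0.020, swc_noise = 0.008,
    attenuation = c(1, 0.8, 0.6, 0.45, 0.35)
  )
  spectral_defaults <- list(
    informative_bands = c(577, 712, 980, 1180, 1640, 2190),
    band_effect = 0.06, band_width = 12,
    vis_effect = 0.012, lwir_effect = 0.05, taper = 120,
    noise_sd = 0.002, noise_corr_length = 50, white_sd = 0.001,
    gain_sd = 0.05, offset_sd = 0.02,
    struct_sd = 0.14,
    struct_centers = c(420, 435, 460, 480, 500, 515, 525, 640, 780, 830,
                       860, 890, 925, 1060, 1100, 1125, 1270, 1295, 1320,
                       1540, 1730, 1770, 2030, 2060, 2090, 2125, 2245,
                       2280, 2350),
    struct_widths = c(25, 18, 20, 15, 20, 12, 15, 18, 18, 25,
                      20, 25, 18, 22, 20, 15, 25, 20, 30,
                      28, 25, 20, 30, 20, 25, 18, 15, 28, 25),
    vis_stage = c(0.012, 0.004, 0.000, 0.005, 0.016),
    canopy_stage = c(0.95, 1.05, 1.00, 0.90, 0.80)
  )
  cfg <- list(
    treatments = c("T1", "T2", "T3", "T4"),
    stages_das = c(76, 111, 124, 142, 162),
    n_reps = n_reps,
    ec_table = ec_table,
    ec_sd = ec_sd, ec_floor = ec_floor, latent_sd = latent_sd,
    growth = utils::modifyList(growth_defaults, growth),
    spectral = utils::modifyList(spectral_defaults, spectral)
  )
  if (any(cfg$growth$attenuation < 0)) stop("attenuation must be non-negative")
  class(cfg) <- "synthetic_config"
  cfg
}

# Grand mean of the configured S2 means: the centering point for all
# salinity effects, so that noise-free generation is exactly linear in EC.
s2_reference <- function(config) {
  mean(config$ec_table$ec_mean[config$ec_table$layer == "S2"])
}

#' Configured mean EC trajectories
#'
#' The noise-free treatment x stage mean surface of the generator for one
#' layer average, i.e. what [generate_salinity()] returns at `ec_sd = 0`.
#'
#' @param config a [synthetic_config()].
#' @param layer one of `"S1"`, `"S2"`, `"S3"`.
#' @return matrix, treatments x stages.
#' @export
ec_stage_means <- function(config, layer = "S2") {
  tab <- config$ec_table[config$ec_table$layer == layer, ]
  m <- matrix(NA_real_, length(config$treatments), length(config$stages_das),
              dimnames = list(config$treatments, config$stages_das))
  for (i in seq_len(nrow(tab))) {
    m[tab$treatment[i], as.character(tab$das[i])] <- tab$ec_mean[i]
  }
  m
}

#' Generate layered soil salinity records
#'
#' Draws per-record ECs for the 0-20, 20-40 and 40-60 cm layers around the
#' configured treatment x stage means, with a shared (profile-wide) and a
#' layer-specific noise component of equal variance so layer averages are
#' positively correlated within a sample. Draws falling at or below
#' `ec_floor` are redrawn (with a warning) so all ECs stay positive.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `treatment`, `stage_das`,
#'   `ec_0_20`, `ec_20_40`, `ec_40_60`.
#' @export
generate_salinity <- function(config, seed = 42) {
  lm_tab <- layer_means_from_table(config$ec_table)
  half <- config$ec_sd * sqrt(0.5)
  rows <- list()
  warned <- FALSE
  with_seed(seed, {
    for (tr in config$treatments) {
      for (das in config$stages_das) {
        mu <- unlist(lm_tab[lm_tab$treatment == tr & lm_tab$das == das,
                            c("l1", "l2", "l3")])
        for (r in seq_len(config$n_reps)) {
          ec <- NULL
          for (attempt in 1:20) {
            shared <- stats::rnorm(1, 0, half)
            ec <- mu + shared + stats::rnorm(3, 0, half)
            if (all(ec > config$ec_floor)) break
          }
          if (any(ec <= config$ec_floor)) {
            if (!warned) {
              warning("EC noise sd is large relative to the means; ",
                      "flooring draws at ec_floor")
              warned <- TRUE
            }
            ec <- pmax(ec, config$ec_floor)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%03d_r%d", tr, das, r),
            treatment = tr, stage_das = das,
            ec_0_20 = ec[1], ec_20_40 = ec[2], ec_40_60 = ec[3])
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate growth parameters from salinity
#'
#' Plant height and aboveground biomass follow logistic curves in days after
#' sowing (biomass peaking earlier under high salinity and decaying slightly
#' after its peak); shoot water content declines linearly. Each parameter is
#' suppressed linearly in the record's 0-40 cm salinity (S2), with the
#' suppression slope attenuated over stages, so growth-salinity correlations
#' are negative and weaken with time.
#'
#' @param config a [synthetic_config()].
#' @param salinity output of [generate_salinity()].
#' @param seed integer seed.
#' @return `salinity` with columns `H_cm`, `AGB_g`, `SWC_frac` appended.
#' @export
generate_growth <- function(config, salinity, seed = 43) {
  g <- config$growth
  s2 <- (salinity$ec_0_20 + salinity$ec_20_40) / 2
  s_ref <- s2_reference(config)
  stage_idx <- match(salinity$stage_das, config$stages_das)
  atten <- g$attenuation[stage_idx]
  das <- salinity$stage_das

  # high-salinity treatments peak earlier (stage 3, 124 DAS) than low ones
  s2_means <- rowMeans(ec_stage_means(config, "S2"))
  peak_stage <- ifelse(s2_means <= stats::median(s2_means), 4L, 3L)
  names(peak_stage) <- names(s2_means)

  logistic <- function(x, xmax, mid, tau) xmax / (1 + exp(-(x - mid) / tau))

  with_seed(seed, {
    # replicate noise scales with the stage baseline (constant coefficient
    # of variation), so the salinity-growth correlation is governed by the
    # attenuation schedule alone and weakens monotonically over stages
    h_base <- logistic(das, g$h_max, g$h_mid, g$h_tau)
    H <- h_base * (1 - g$h_slope * atten * (s2 - s_ref)) +
      stats::rnorm(nrow(salinity), 0, g$h_noise_cv * h_base)
    H <- pmax(H, 1)

    pk <- peak_stage[salinity$treatment]
    das_eff <- pmin(das, config$stages_das[pk])
    agb_base <- logistic(das_eff, g$agb_max, g$agb_mid, g$agb_tau) *
      g$agb_decay^pmax(0L, stage_idx - pk)
    AGB <- agb_base * (1 - g$agb_slope * atten * (s2 - s_ref)) +
      stats::rnorm(nrow(salinity), 0, g$agb_noise_cv * agb_base)
    AGB <- pmax(AGB, 0)

    SWC <- g$swc_start - g$swc_rate * (das - 76) -
      g$swc_slope * atten * (s2 - s_ref) +
      stats::rnorm(nrow(salinity), 0, g$swc_noise)
    SWC <- pmin(pmax(SWC, 0.01), 0.99)
  })
  out <- salinity
  out$H_cm <- H
  out$AGB_g <- AGB
  out$SWC_frac <- SWC
  out
}

# Raised-cosine membership of [lo, hi] with ramps of width `taper` inside
# the interval edges.
taper_window <- function(wl, lo, hi, taper) {
  w <- numeric(length(wl))
  inside <- wl >= lo & wl <= hi
  w[inside] <- 1
  if (taper > 0) {
    up <- wl >= lo & wl < lo + taper
    w[up] <- 0.5 * (1 - cos(pi * (wl[up] - lo) / taper))
    dn <- wl > hi - taper & wl <= hi
    w[dn] <- 0.5 * (1 - cos(pi * (hi - wl[dn]) / taper))
  }
  w
}

# Parametric vegetation reflectance baseline: low visible reflectance with a
# green-peak bump near 550 nm, a red-edge rise at 680-750 nm to a NIR
# plateau, a declining SWIR envelope, and water-absorption troughs near
# 1200/1450/1940 nm. A hand-parameterized curve, not a radiative-transfer
# model.
vegetation_baseline <- function(wl, vis_offset = 0, canopy = 1) {
  vis <- 0.04 + vis_offset + 0.035 * exp(-(wl - 550)^2 / (2 * 35^2))
  red_edge <- 1 / (1 + exp(-(wl - 715) / 16))
  envelope <- 1 / (1 + exp((wl - 1650) / 350))
  troughs <- 1 -
    0.08 * exp(-(wl - 1200)^2 / (2 * 30^2)) -
    0.35 * exp(-(wl - 1450)^2 / (2 * 40^2)) -
    0.50 * exp(-(wl - 1940)^2 / (2 * 50^2))
  pmax(vis * (1 - red_edge) + canopy * 0.48 * red_edge * envelope * troughs, 0.005)
}

#' Generate canopy spectra from salinity and growth
#'
#' Each record's spectrum is the stage-modulated vegetation baseline plus a
#' salinity response driven by a latent canopy-expressed salinity
#' `s = S2 + N(0, latent_sd)`: an additive increase in the visible region, a
#' relative decrease in the long-wave infrared, and narrow Gaussian signals
#' at the configured informative bands. Per-sample multiplicative gain,
#' additive offset and autocorrelated AR(1) noise imitate field acquisition;
#' values are clipped to [0, 1.2].
#'
#' @param config a [synthetic_config()].
#' @param samples output of [generate_growth()].
#' @param seed integer seed.
#' @return list with `spectra` (a raw [spectra] object on the 350-2500 nm
#'   grid) and `latent` (data.frame `sample_id`, `s_spec`).
#' @export
generate_spectra <- function(config, samples, seed = 44) {
  sp <- config$spectral
  wl <- 350:2500
  n <- nrow(samples)
  s2 <- (samples$ec_0_20 + samples$ec_20_40) / 2
  s_ref <- s2_reference(config)
  stage_idx <- match(samples$stage_das, config$stages_das)

  vis_mask <- taper_window(wl, 400, 780, sp$taper)
  lwir_mask <- taper_window(wl, 1100, 2400, sp$taper)
  bumps <- sapply(sp$informative_bands, function(b) {
    exp(-(wl - b)^2 / (2 * sp$band_width^2))
  })
  bump_sum <- if (length(sp$informative_bands)) rowSums(bumps) else numeric(length(wl))

  phi <- exp(-1 / sp$noise_corr_length)
  innov_sd <- sp$noise_sd * sqrt(1 - phi^2)

  n_modes <- length(sp$struct_centers)
  if (sp$struct_sd <= 0) n_modes <- 0L
  mode_shapes <- if (n_modes > 0) {
    vapply(seq_len(n_modes), function(j) {
      exp(-(wl - sp$struct_centers[j])^2 / (2 * sp$struct_widths[j]^2))
    }, numeric(length(wl)))
  } else NULL

  vals <- matrix(0, n, length(wl))
  latent <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      k <- stage_idx[i]
      base <- vegetation_baseline(wl, vis_offset = sp$vis_stage[k],
                                  canopy = sp$canopy_stage[k])
      s <- s2[i] + stats::rnorm(1, 0, config$latent_sd)
      latent[i] <- s
      ds <- s - s_ref
      gain <- 1 + stats::rnorm(1, 0, sp$gain_sd)
      offset <- stats::rnorm(1, 0, sp$offset_sd)
      noise <- if (sp$noise_sd > 0) {
        as.numeric(stats::filter(stats::rnorm(length(wl), 0, innov_sd),
                                 phi, method = "recursive"))
      } else 0
      # uncorrelated detector noise on top of the smooth drift component
      if (sp$white_sd > 0) {
        noise <- noise + stats::rnorm(length(wl), 0, sp$white_sd)
      }
      # canopy-structure variation (LAI, leaf angle, pigment and water
      # differences unrelated to salinity): random amplitudes on a fixed,
      # low-dimensional set of spectral modes shared by all samples
      struct <- if (n_modes > 0) {
        as.numeric(mode_shapes %*% stats::rnorm(n_modes, 0, sp$struct_sd))
      } else 0
      v <- base * gain + struct +
        sp$vis_effect * ds * vis_mask -
        sp$lwir_effect * ds * lwir_mask * base +
        sp$band_effect * ds * bump_sum +
        offset + noise
      vals[i, ] <- pmin(pmax(v, 0), 1.2)
    }
  })
  rownames(vals) <- samples$sample_id
  # canopy reflectance occasionally exceeds 1 in the field (panel-calibration
  # artifacts); generated values are clipped to [0, 1.2] by construction, so
  # the validated constructor's over-unity warning is not re-raised here
  out <- spectra_unchecked(vals, wl, "raw")
  rownames(out$values) <- samples$sample_id
  list(spectra = out,
       latent = data.frame(sample_id = samples$sample_id, s_spec = latent))
}

#' Generate a complete synthetic dataset
#'
#' Chains [generate_salinity()], [generate_growth()] and
#' [generate_spectra()], fanning the master seed out to the three stages via
#' [derive_seed()]. Fully deterministic given `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed (default 42).
#' @return a `salinity_dataset`: list with `samples` (one row per record:
#'   identifiers, growth parameters, layer ECs), `spectra` (raw [spectra]),
#'   `latent` (canopy-expressed salinity per record), `config`, `seed`.
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 42) {
  sal <- generate_salinity(config, seed = derive_seed(seed, "salinity"))
  smp <- generate_growth(config, sal, seed = derive_seed(seed, "growth"))
  spc <- generate_spectra(config, smp, seed = derive_seed(seed, "spectra"))
  structure(list(samples = smp, spectra = spc$spectra, latent = spc$latent,
                 config = config, seed = seed),
            class = "salinity_dataset")
}

#' @export
print.salinity_dataset <- function(x, ...) {
  cat(sprintf("<salinity_dataset: %d records (%d treatments x %d stages x %d reps), %d bands>\n",
              nrow(x$samples), length(x$config$treatments),
              length(x$config$stages_das), x$config$n_reps,
              length(x$spectra$wavelengths)))
  invisible(x)
}

#' Generative accuracy ceiling for a layer target
#'
#' The best validation R-squared any pipeline model can approach on a
#' synthetic dataset: the ordinary least squares R-squared of the layer
#' target on the latent canopy-expressed salinity together with the plant
#' height and shoot water content covariates used by the reference model.
#' The gap to 1 is set by `latent_sd` and the EC noise.
#'
#' @param dataset a [generate_dataset()] result (its `latent` element must
#'   be present).
#' @param layer one of `"S1"`, `"S2"`, `"S3"`.
#' @return scalar R-squared.
#' @export
generative_ceiling <- function(dataset, layer = "S2") {
  if (is.null(dataset$latent)) stop("dataset carries no latent drivers")
  y <- layer_targets(dataset$samples)[[layer]]
  d <- data.frame(y = y, s = dataset$latent$s_spec,
                  H = dataset$samples$H_cm,
                  SWC = dataset$samples$SWC_frac)
  summary(stats::lm(y ~ s + H + SWC, data = d))$r.squared
}
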