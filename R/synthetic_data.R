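# Synthetic cohort generator -----------------------------------------------
#
# Emulates the hierarchical structure of the study's donor/trabecula data:
# group-level distributions of the material parameters, morphometry and
# clinical covariates, a 60/40 interdonor/intradonor variance split, noisy
# cyclic curves produced by the incremental protocol, and cylindrical TMD
# fields with a lower-mineralized surface layer and a lower-TMD fracture
# zone. Positive quantities are log-normal (moments matched to the
# configured mean/SD); age, BMI and T-score are normal; sex and orientation
# are balanced.

lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# group defaults: reported group means +/- SD
default_group_stats <- function() {
  list(
    CTRL = list(
      E_pr = c(5.0, 2.7), E_mx = c(2.4, 1.3), sigma_y = c(30.8, 18.2),
      p = c(62.7, 58.5), sigma_u = c(84.3, 29.4), eta = c(4.8, 3.8),
      eps_u_pct = c(5.0, 2.2),
      BS = c(185.4, 51.2), BVTV = c(16.8, 7.0), TbN = c(1.13, 0.19),
      TbSp = c(0.72, 0.15), TbTh = c(0.17, 0.03), DA = c(1.59, 0.24),
      age = c(69.5, 9.2), BMI = c(30.1, 9.2), Tscore = c(1.12, 2.94),
      FRAX = c(3.1, 3.4)),
    FRAC = list(
      E_pr = c(4.9, 2.5), E_mx = c(2.6, 1.5), sigma_y = c(31.9, 19.8),
      p = c(63.3, 66.2), sigma_u = c(93.8, 38.6), eta = c(4.3, 3.2),
      eps_u_pct = c(5.5, 2.4),
      BS = c(164.7, 45.4), BVTV = c(15.5, 6.7), TbN = c(1.07, 0.18),
      TbSp = c(0.77, 0.16), TbTh = c(0.17, 0.03), DA = c(1.62, 0.23),
      age = c(74.6, 11.0), BMI = c(26.1, 5.2), Tscore = c(-2.41, 0.83),
      FRAX = c(13.9, 11.3)))
}

#' Cohort generator configuration
#'
#' Defaults emulate the study's design: 10 donors per group (CTRL and
#' FRAC), about 10 trabeculae per donor, group-level means and SDs for the
#' material parameters, morphometry, clinical covariates and failure
#' strain, a 60/40 interdonor/intradonor variance split, gauge length
#' 0.687 +/- 0.166 mm, orientation-dependent cross-sectional areas
#' (longitudinal 0.022 +/- 0.010 mm^2, transversal 0.016 +/- 0.007 mm^2),
#' TMD base 958 +/- 174 mg HA/cm^3 with a 60 mg/cm^3 surface deficit in the
#' outer three voxels and a 7 mg/cm^3 fracture-zone deficit, and a shared
#' latent factor coupling TMD with stiffness at rank correlation ~0.3.
#'
#' @param n_donors named vector of donors per group.
#' @param trab_per_donor trabeculae per donor.
#' @param group_stats list of per-group (mean, SD) pairs; see
#'   \code{trabmech:::default_group_stats()}.
#' @param interdonor_frac fraction of total variance between donors.
#' @param gauge_length_mm mean and SD of gauge length, mm.
#' @param area_long_mm2,area_trans_mm2 mean and SD of mean cross-sectional
#'   area by orientation, mm^2.
#' @param tmd_base mean and SD of per-trabecula base TMD, mg HA/cm^3.
#' @param tmd_surface_deficit surface-layer TMD deficit, mg/cm^3.
#' @param tmd_fracture_deficit fracture-zone TMD deficit, mg/cm^3.
#' @param tmd_voxel_noise per-voxel Gaussian noise SD, mg/cm^3.
#' @param strain_noise_sd additive strain noise SD (absolute, so relative
#'   noise is larger at small strain).
#' @param stress_noise_sd additive stress noise SD, MPa.
#' @param latent_tmd_stiffness rank-correlation coupling of TMD and E_pr
#'   (0 disables).
#' @return list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_donors = c(CTRL = 10L, FRAC = 10L),
                          trab_per_donor = 10L,
                          group_stats = default_group_stats(),
                          interdonor_frac = 0.6,
                          gauge_length_mm = c(0.687, 0.166),
                          area_long_mm2 = c(0.022, 0.010),
                          area_trans_mm2 = c(0.016, 0.007),
                          tmd_base = c(958, 174),
                          tmd_surface_deficit = 60,
                          tmd_fracture_deficit = 7,
                          tmd_voxel_noise = 30,
                          strain_noise_sd = 1e-4,
                          stress_noise_sd = 0.5,
                          latent_tmd_stiffness = 0.3) {
  if (any(n_donors < 1L) || trab_per_donor < 1L)
    stop("invalid config: counts must be positive", call. = FALSE)
  if (interdonor_frac < 0 || interdonor_frac > 1)
    stop("invalid config: interdonor_frac must lie in [0, 1]", call. = FALSE)
  structure(list(n_donors = n_donors, trab_per_donor = trab_per_donor,
                 group_stats = group_stats,
                 interdonor_frac = interdonor_frac,
                 gauge_length_mm = gauge_length_mm,
                 area_long_mm2 = area_long_mm2,
                 area_trans_mm2 = area_trans_mm2,
                 tmd_base = tmd_base,
                 tmd_surface_deficit = tmd_surface_deficit,
                 tmd_fracture_deficit = tmd_fracture_deficit,
                 tmd_voxel_noise = tmd_voxel_noise,
                 strain_noise_sd = strain_noise_sd,
                 stress_noise_sd = stress_noise_sd,
                 latent_tmd_stiffness = latent_tmd_stiffness),
            class = "cohort_config")
}

#' Generate a synthetic donor/trabecula cohort
#'
#' Hierarchical sampling: for each positive quantity, donor-level effects
#' and trabecula-level deviations are drawn on the log scale with the
#' configured interdonor/intradonor variance split; clinical covariates are
#' donor-level. A shared latent factor couples the trabecula-level TMD and
#' long-term modulus deviations at the configured rank correlation.
#' T-score bands are derived from the sampled T-score (> -1 healthy,
#' [-2.5, -1] osteopenia, < -2.5 osteoporosis). Deterministic under the
#' seed.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer master seed.
#' @return list with \code{donors} (one row per donor: id, group, clinical
#'   covariates, morphometry) and \code{trabeculae} (one row per trabecula:
#'   donor id, group, T-score band, orientation, gauge length, area, true
#'   material parameters, true failure strain, TMD field parameters).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  w_inter <- sqrt(config$interdonor_frac)
  w_intra <- sqrt(1 - config$interdonor_frac)

  donors <- NULL
  trabs <- NULL
  donor_id <- 0L
  mech_vars <- c("E_pr", "E_mx", "sigma_y", "p", "sigma_u", "eta",
                 "eps_u_pct")
  morpho_vars <- c("BS", "BVTV", "TbN", "TbSp", "TbTh", "DA")

  for (grp in names(config$n_donors)) {
    gs <- config$group_stats[[grp]]
    for (dnr in seq_len(config$n_donors[[grp]])) {
      donor_id <- donor_id + 1L
      did <- sprintf("D%02d", donor_id)
      sex <- if (dnr %% 2L == 1L) "F" else "M"  # balanced within group
      age <- rnorm(1, gs$age[1], gs$age[2])
      bmi <- max(rnorm(1, gs$BMI[1], gs$BMI[2]), 12)
      tscore <- rnorm(1, gs$Tscore[1], gs$Tscore[2])
      frax <- max(rnorm(1, gs$FRAX[1], gs$FRAX[2]), 0.1)
      morpho <- vapply(morpho_vars, function(v) {
        lp <- lnorm_pars(gs[[v]][1], gs[[v]][2])
        exp(lp$meanlog + rnorm(1) * lp$sdlog)  # donor-level morphometry
      }, numeric(1))
      donors <- rbind(donors, data.frame(
        donor = did, group = grp, sex = sex, age = age, BMI = bmi,
        Tscore = tscore, FRAX = frax, t(morpho)))

      # donor-level standardized effects for the mechanical parameters
      zd <- setNames(rnorm(length(mech_vars)), mech_vars)
      zd_tmd <- rnorm(1)

      for (tr in seq_len(config$trab_per_donor)) {
        zt <- setNames(rnorm(length(mech_vars)), mech_vars)
        # shared latent factor between intradonor TMD and E_pr deviations
        rho <- config$latent_tmd_stiffness
        if (rho > 0) {
          z_shared <- rnorm(1)
          w <- sqrt(rho)
          zt["E_pr"] <- w * z_shared + sqrt(1 - rho) * zt["E_pr"]
          zt_tmd <- w * z_shared + sqrt(1 - rho) * rnorm(1)
        } else zt_tmd <- rnorm(1)

        draw <- vapply(mech_vars, function(v) {
          lp <- lnorm_pars(gs[[v]][1], gs[[v]][2])
          exp(lp$meanlog +
                (w_inter * zd[[v]] + w_intra * zt[[v]]) * lp$sdlog)
        }, numeric(1))
        # enforce sigma_u >= sigma_y (resample-free: lift sigma_u)
        if (draw["sigma_u"] < draw["sigma_y"])
          draw["sigma_u"] <- draw["sigma_y"] * 1.05

        orientation <- if (tr %% 2L == 1L) "longitudinal" else "transversal"
        ar <- if (orientation == "longitudinal") config$area_long_mm2
              else config$area_trans_mm2
        lpa <- lnorm_pars(ar[1], ar[2])
        area <- exp(lpa$meanlog + rnorm(1) * lpa$sdlog)
        lpg <- lnorm_pars(config$gauge_length_mm[1],
                          config$gauge_length_mm[2])
        gauge <- exp(lpg$meanlog + rnorm(1) * lpg$sdlog)

        tmd0 <- config$tmd_base[1] +
          (w_inter * zd_tmd + w_intra * zt_tmd) * config$tmd_base[2]
        tmd0 <- max(tmd0, 500)

        trabs <- rbind(trabs, data.frame(
          trabecula = sprintf("%s_T%02d", did, tr),
          donor = did, group = grp, orientation = orientation,
          gauge_length_mm = gauge, area_mm2 = area,
          E_pr = draw[["E_pr"]], E_mx = draw[["E_mx"]],
          sigma_y = draw[["sigma_y"]], sigma_u = draw[["sigma_u"]],
          p = draw[["p"]], eta = draw[["eta"]],
          failure_strain = draw[["eps_u_pct"]] / 100,
          tmd_base = tmd0,
          tmd_surface_deficit = config$tmd_surface_deficit,
          tmd_fracture_deficit = config$tmd_fracture_deficit))
      }
    }
  }
  donors$t_band <- cut(donors$Tscore, c(-Inf, -2.5, -1, Inf),
                       labels = c("T<-2.5", "-2.5<=T<=-1", "T>-1"))
  trabs$t_band <- donors$t_band[match(trabs$donor, donors$donor)]
  rownames(donors) <- NULL
  rownames(trabs) <- NULL
  list(donors = donors, trabeculae = trabs)
}

#' Generate one noisy cyclic test curve for a trabecula
#'
#' Builds the displacement protocol until the peak nominal strain first
#' exceeds the trabecula's failure strain (capped at the protocol's
#' max_cycles), simulates the model stress on the noiseless strain, adds
#' Gaussian noise of constant absolute SD to strain (so relative noise is
#' larger at small strains) and to stress, and truncates the record at the
#' first sample whose noiseless strain exceeds the failure strain, setting
#' the failure index there.
#'
#' @param record one row of the cohort's trabeculae table.
#' @param protocol a \code{\link{loading_protocol}}.
#' @param strain_noise_sd,stress_noise_sd additive Gaussian noise SDs
#'   (strain units and MPa); zero disables.
#' @param seed integer seed.
#' @param substeps integration substeps.
#' @return A \code{\link{strain_stress_history}} truncated at failure, with
#'   attribute \code{"true_params"}.
#' @export
generate_curve <- function(record, protocol = loading_protocol(),
                           strain_noise_sd = 1e-4, stress_noise_sd = 0.5,
                           seed = 1L, substeps = 4L) {
  set.seed(as.integer(seed))
  gauge <- record$gauge_length_mm
  params <- material_params(E_pr = record$E_pr, E_mx = record$E_mx,
                            sigma_y = record$sigma_y,
                            sigma_u = record$sigma_u,
                            p = record$p, eta = record$eta)
  inc <- protocol$displacement_increment
  peak_strain <- function(k)
    (protocol$first_peak_displacement + (k - 1) * inc) / gauge
  n_cycles <- 1L
  while (peak_strain(n_cycles) <= record$failure_strain &&
         n_cycles < protocol$max_cycles)
    n_cycles <- n_cycles + 1L

  h <- build_protocol(protocol, n_cycles = n_cycles, gauge_length = gauge)
  stress <- simulate_forward(params, h$time, h$strain, substeps = substeps)

  strain_noisy <- h$strain +
    if (strain_noise_sd > 0) rnorm(nrow(h), 0, strain_noise_sd) else 0
  stress_noisy <- stress +
    if (stress_noise_sd > 0) rnorm(nrow(h), 0, stress_noise_sd) else 0

  over <- which(h$strain > record$failure_strain)
  fi <- if (length(over)) over[1] else nrow(h)
  out <- strain_stress_history(time = h$time[seq_len(fi)],
                               displacement = h$displacement[seq_len(fi)],
                               strain = strain_noisy[seq_len(fi)],
                               stress = stress_noisy[seq_len(fi)],
                               failure_index = fi)
  attr(out, "true_params") <- params
  attr(out, "protocol") <- protocol
  attr(out, "gauge_length") <- gauge
  out
}

#' Generate a synthetic cylindrical TMD volume with masks
#'
#' Digital cylinder whose diameter matches the record's mean
#' cross-sectional area (assuming a circular section), filled with the
#' record's base TMD plus Gaussian voxel noise; the TMD ramps down linearly
#' over the outer \code{surface_voxels} voxels of the radius (surface
#' deficit), and an axial band centered mid-specimen carries an additional
#' fracture-zone deficit. Returns the volume together with the whole and
#' fracture-zone masks.
#'
#' @param record one row of the cohort's trabeculae table.
#' @param voxel_size voxel edge, micrometers (default 3.3).
#' @param length_mm axial specimen length, mm (default: one gauge length).
#' @param surface_voxels radial extent of the surface deficit (default 3).
#' @param fracture_frac axial fraction covered by the fracture zone
#'   (default 0.25).
#' @param seed integer seed.
#' @return list with \code{volume}, \code{whole}, \code{fracture}.
#' @export
generate_tmd_volume <- function(record, voxel_size = 3.3,
                                length_mm = record$gauge_length_mm,
                                surface_voxels = 3L, fracture_frac = 0.25,
                                seed = 1L) {
  set.seed(as.integer(seed))
  radius_um <- sqrt(record$area_mm2 / pi) * 1000
  r_vox <- radius_um / voxel_size
  if (2 * r_vox < 8)
    stop("voxel size too coarse: fewer than 8 voxels across the diameter",
         call. = FALSE)
  nz <- max(8L, round(length_mm * 1000 / voxel_size))
  nxy <- 2L * ceiling(r_vox) + 5L
  cx <- (nxy + 1) / 2

  ix <- matrix(rep(seq_len(nxy), nxy), nxy, nxy)
  rr <- sqrt((ix - cx)^2 + (t(ix) - cx)^2)  # in-plane radius, voxels
  inside <- rr <= r_vox

  base <- record$tmd_base
  surf_def <- record$tmd_surface_deficit
  # linear ramp: full deficit at the surface, none deeper than
  # surface_voxels below it
  depth <- pmax(r_vox - rr, 0)
  slice_tmd <- ifelse(inside,
                      base - surf_def * pmax(1 - depth / surface_voxels, 0),
                      0)

  vol <- array(0, c(nxy, nxy, nz))
  whole <- array(FALSE, c(nxy, nxy, nz))
  for (k in seq_len(nz)) {
    vol[, , k] <- slice_tmd
    whole[, , k] <- inside
  }
  fr <- array(FALSE, c(nxy, nxy, nz))
  band <- max(1L, round(fracture_frac * nz))
  z0 <- floor((nz - band) / 2) + 1L
  zz <- z0:(z0 + band - 1L)
  fr[, , zz] <- whole[, , zz]
  vol[fr] <- vol[fr] - record$tmd_fracture_deficit

  noise_sd <- if (!is.null(record$tmd_voxel_noise)) record$tmd_voxel_noise
              else 30
  if (noise_sd > 0) {
    nvox <- sum(whole)
    vol[whole] <- pmax(vol[whole] + rnorm(nvox, 0, noise_sd), 1)
  }
  list(volume = voxel_volume(vol, voxel_size),
       whole = voxel_mask(whole, "whole"),
       fracture = voxel_mask(fr, "fracture_zone"))
}
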