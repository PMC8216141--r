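# shared fixtures, built in code

ctrl_params <- function() reference_params("CTRL")

# noiseless cyclic record simulated from known parameters
make_curve <- function(params = ctrl_params(), n_cycles = 3,
                       gauge = 0.687, protocol = loading_protocol(),
                       substeps = 4L) {
  h <- build_protocol(protocol, n_cycles = n_cycles, gauge_length = gauge)
  h$stress <- simulate_forward(params, h$time, h$strain,
                               substeps = substeps)
  h
}

# one synthetic trabecula record row with controllable fields
make_record <- function(E_pr = 5, E_mx = 2.4, sigma_y = 30.8,
                        sigma_u = 84.3, p = 62.7, eta = 4.8,
                        failure_strain = 0.05, gauge = 0.687,
                        area = 0.02, tmd_base = 950,
                        tmd_surface_deficit = 60,
                        tmd_fracture_deficit = 10,
                        tmd_voxel_noise = 0) {
  data.frame(trabecula = "T01", donor = "D01", group = "CTRL",
             orientation = "longitudinal",
             gauge_length_mm = gauge, area_mm2 = area,
             E_pr = E_pr, E_mx = E_mx, sigma_y = sigma_y,
             sigma_u = sigma_u, p = p, eta = eta,
             failure_strain = failure_strain,
             tmd_base = tmd_base,
             tmd_surface_deficit = tmd_surface_deficit,
             tmd_fracture_deficit = tmd_fracture_deficit,
             tmd_voxel_noise = tmd_voxel_noise)
}

# trapezoid rule on a polyline, the envelope-work oracle
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
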