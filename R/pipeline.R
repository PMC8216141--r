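# Pipeline orchestration and file I/O ---------------------------------------

curve_columns <- c("time_s", "displacement_mm", "strain", "stress_MPa")

#' Write a strain-stress history as CSV
#'
#' Columns \code{time_s, displacement_mm, strain, stress_MPa}, printed with
#' 17 significant digits so the round trip is lossless at double precision.
#'
#' @param history a \code{\link{strain_stress_history}}.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_curve_csv <- function(history, path) {
  stopifnot(inherits(history, "strain_stress_history"))
  df <- data.frame(time_s = history$time,
                   displacement_mm = history$displacement,
                   strain = history$strain,
                   stress_MPa = history$stress)
  fi <- attr(history, "failure_index")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(fi)) writeLines(sprintf("# failure_index: %d", fi), con)
  writeLines(paste(curve_columns, collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(x)
    formatC(x, digits = 17, format = "g")), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a strain-stress history from CSV
#'
#' Validates the header schema and time monotonicity; an optional
#' \code{# failure_index: k} comment line restores the failure index.
#'
#' @param path CSV path written by \code{\link{write_curve_csv}} (or
#'   compatible).
#' @return A \code{\link{strain_stress_history}}.
#' @export
read_curve_csv <- function(path) {
  first <- readLines(path, n = 1L)
  fi <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("failure_index:\\s*(\\d+)", first))[[1]]
    if (length(m) == 2L) fi <- as.integer(m[2])
  }
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  missing <- setdiff(curve_columns, names(df))
  if (length(missing))
    stop("curve CSV schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0))
    stop("curve CSV validation error: time_s must be strictly increasing",
         call. = FALSE)
  strain_stress_history(time = df$time_s,
                        displacement = df$displacement_mm,
                        strain = df$strain,
                        stress = df$stress_MPa,
                        failure_index = fi)
}

#' Write material parameters as JSON
#'
#' Keys \code{E_pr_GPa, E_mx_GPa, sigma_y_MPa, sigma_u_MPa, p, eta_GPas}.
#'
#' @param params a \code{\link{material_params}}.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "material_params"))
  jsonlite::write_json(
    list(E_pr_GPa = params$E_pr, E_mx_GPa = params$E_mx,
         sigma_y_MPa = params$sigma_y, sigma_u_MPa = params$sigma_u,
         p = params$p, eta_GPas = params$eta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read material parameters from JSON
#'
#' @param path JSON path written by \code{\link{write_params_json}}.
#' @return A \code{\link{material_params}}.
#' @export
read_params_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  material_params(E_pr = j$E_pr_GPa, E_mx = j$E_mx_GPa,
                  sigma_y = j$sigma_y_MPa, sigma_u = j$sigma_u_MPa,
                  p = j$p, eta = j$eta_GPas)
}

# stable polynomial hash of a deparsed configuration (no external digest
# dep; arithmetic kept within exact double-precision integer range)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# derive independent child seeds from a master seed (kept below 2^31)
child_seed <- function(master, stage) {
  offs <- c(cohort = 101L, curves = 211L, tmd = 307L, stats = 401L)
  (as.integer(master) * 7919L + offs[[stage]]) %% .Machine$integer.max
}

#' Run configuration for the full pipeline
#'
#' @param cohort a \code{\link{cohort_config}}.
#' @param protocol a \code{\link{loading_protocol}}.
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param min_cycles QC minimum complete cycles (default 3).
#' @param with_tmd run the TMD stage (default TRUE); volume generation is
#'   the slowest stage.
#' @param tmd_voxel_size voxel size for synthetic volumes, micrometers.
#'   The default (8) is coarser than a real scan to keep runs light.
#' @param identify_args list of extra arguments for \code{\link{identify}}.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(cohort = cohort_config(), protocol = loading_protocol(),
                       seed = 1L, min_cycles = 3L, with_tmd = TRUE,
                       tmd_voxel_size = 8, identify_args = list()) {
  structure(list(cohort = cohort, protocol = protocol, seed = seed,
                 min_cycles = min_cycles, with_tmd = with_tmd,
                 tmd_voxel_size = tmd_voxel_size,
                 identify_args = identify_args),
            class = "run_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' generate -> simulate -> analyze (cycles + apparent properties) -> fit ->
#' QC -> statistics -> report. Every table is written under \code{outdir}
#' tagged with the configuration hash; a rerun with identical configuration
#' and seed reproduces all numeric outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @param outdir output directory (created if missing); \code{NULL} skips
#'   writing.
#' @param verbose print stage summaries (default TRUE).
#' @return Object of class \code{"run_report"}: list with \code{counts}
#'   (generated / analyzed / fitted / retained), \code{cohort},
#'   \code{results} (per-trabecula table of true and fitted values),
#'   \code{qc}, \code{stats}, \code{tmd}, \code{config_hash}, \code{seed}.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- generate_cohort(config$cohort, seed = child_seed(config$seed,
                                                             "cohort"))
  trabs <- cohort$trabeculae
  say("[generate] %d donors, %d trabeculae (config %s)",
      nrow(cohort$donors), nrow(trabs), hash)

  rows <- vector("list", nrow(trabs))
  tmd_rows <- vector("list", nrow(trabs))
  curve_seed0 <- child_seed(config$seed, "curves")
  tmd_seed0 <- child_seed(config$seed, "tmd")

  for (i in seq_len(nrow(trabs))) {
    rec <- trabs[i, ]
    h <- tryCatch(
      generate_curve(rec, config$protocol,
                     strain_noise_sd = config$cohort$strain_noise_sd,
                     stress_noise_sd = config$cohort$stress_noise_sd,
                     seed = (curve_seed0 + i) %% .Machine$integer.max),
      error = function(e) NULL)
    if (is.null(h)) next

    seg <- tryCatch(segment_cycles(h, config$protocol),
                    error = function(e) NULL)
    ap <- NULL
    if (!is.null(seg)) {
      env <- tryCatch(build_envelope(h, seg), error = function(e) NULL)
      if (!is.null(env))
        ap <- tryCatch(apparent_properties(env), error = function(e) NULL)
    }
    fit <- tryCatch(do.call(identify,
                            c(list(history = h, protocol = config$protocol),
                              config$identify_args)),
                    error = function(e) NULL)

    rows[[i]] <- data.frame(
      trabecula = rec$trabecula, donor = rec$donor, group = rec$group,
      t_band = rec$t_band, orientation = rec$orientation,
      n_cycles = if (is.null(seg)) 0L else attr(seg, "n_complete"),
      rmse = if (is.null(fit)) NA_real_ else fit$rmse,
      true_E_pr = rec$E_pr, true_sigma_u = rec$sigma_u,
      E_pr = if (is.null(fit$params)) NA_real_ else fit$params$E_pr,
      E_mx = if (is.null(fit$params)) NA_real_ else fit$params$E_mx,
      sigma_y = if (is.null(fit$params)) NA_real_ else fit$params$sigma_y,
      sigma_u = if (is.null(fit$params)) NA_real_ else fit$params$sigma_u,
      p = if (is.null(fit$params)) NA_real_ else fit$params$p,
      eta = if (is.null(fit$params)) NA_real_ else fit$params$eta,
      tan_delta = if (is.null(fit$params)) NA_real_
                  else loss_tangent(fit$params, 1),
      E_hat_GPa = if (is.null(ap)) NA_real_ else ap$E_hat_GPa,
      eps_y_hat_pct = if (is.null(ap)) NA_real_ else ap$eps_y_hat_pct,
      eps_u_hat_pct = if (is.null(ap)) NA_real_ else ap$eps_u_hat_pct,
      W_el_MJm3 = if (is.null(ap)) NA_real_ else ap$W_el_MJm3,
      W_py_MJm3 = if (is.null(ap)) NA_real_ else ap$W_py_MJm3)

    if (config$with_tmd) {
      tv <- tryCatch(
        generate_tmd_volume(rec, voxel_size = config$tmd_voxel_size,
                            seed = (tmd_seed0 + i) %% .Machine$integer.max),
        error = function(e) NULL)
      if (!is.null(tv)) {
        zs <- zone_stats(tv$volume, tv$whole, tv$fracture)
        tmd_rows[[i]] <- data.frame(
          trabecula = rec$trabecula, group = rec$group,
          tmd_whole = zs$whole$mean, tmd_fracture = zs$fracture$mean,
          tmd_diff = zs$diff_remainder_fracture)
      }
    }
  }
  results <- do.call(rbind, Filter(Negate(is.null), rows))
  tmd <- if (config$with_tmd)
    do.call(rbind, Filter(Negate(is.null), tmd_rows)) else NULL
  n_fitted <- sum(is.finite(results$rmse))
  say("[fit] %d/%d curves fitted", n_fitted, nrow(trabs))

  fit_ok <- results[is.finite(results$rmse), , drop = FALSE]
  qc <- qc_filter(fit_ok,
                  variables = c("E_pr", "E_mx", "sigma_y", "sigma_u",
                                "p", "eta"),
                  min_cycles = config$min_cycles)
  say("[qc] %d retained of %d fitted", qc$counts$n_retained, n_fitted)

  stats <- compare_groups(
    qc$data,
    variables = c("E_pr", "E_mx", "sigma_y", "sigma_u", "p", "eta",
                  "tan_delta", "E_hat_GPa", "eps_y_hat_pct",
                  "eps_u_hat_pct", "W_el_MJm3", "W_py_MJm3"),
    groupings = intersect(c("group", "t_band"), names(qc$data)))

  report <- structure(
    list(counts = list(generated = nrow(trabs),
                       analyzed = nrow(results),
                       fitted = n_fitted,
                       retained = qc$counts$n_retained),
         cohort = cohort, results = results, qc = qc, stats = stats,
         tmd = tmd, config_hash = hash, seed = config$seed),
    class = "run_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) { df$config_hash <- hash; df }
    write.csv(stamp(cohort$donors), file.path(outdir, "donors.csv"),
              row.names = FALSE)
    write.csv(stamp(cohort$trabeculae), file.path(outdir, "trabeculae.csv"),
              row.names = FALSE)
    write.csv(stamp(results), file.path(outdir, "results.csv"),
              row.names = FALSE)
    write.csv(stamp(stats), file.path(outdir, "stats.csv"),
              row.names = FALSE)
    if (!is.null(tmd))
      write.csv(stamp(tmd), file.path(outdir, "tmd.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed, counts = report$counts,
           qc_counts = qc$counts),
      file.path(outdir, "report.json"), auto_unbox = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cn <- x$counts
  cat(sprintf(
    "Pipeline run %s (seed %s): %d generated -> %d analyzed -> %d fitted -> %d QC-retained\n",
    x$config_hash, format(x$seed), cn$generated, cn$analyzed, cn$fitted,
    cn$retained))
  invisible(x)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher, e.g.
#' \code{Rscript -e 'trabmech::trabmech_cli()' run --seed 1 --outdir out}.
#' Subcommands: \code{generate} (cohort tables only), \code{run} (full
#' pipeline), \code{fit} (identify parameters of one curve CSV).
#'
#' @param args character vector of CLI arguments (default: command line).
#' @return Exit status 0 on success, invisibly.
#' @export
trabmech_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: trabmech <generate|run|fit> [--seed INT] [--outdir DIR]",
    "[--curve FILE] [--no-tmd] [--donors INT] [--trabs INT]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(seed = 1L, outdir = "trabmech_out", curve = NULL,
              tmd = TRUE, donors = 10L, trabs = 10L)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    adv <- function() { i <<- i + 1L; args[i] }
    switch(a,
           "--seed" = { opt$seed <- as.integer(adv()) },
           "--outdir" = { opt$outdir <- adv() },
           "--curve" = { opt$curve <- adv() },
           "--no-tmd" = { opt$tmd <- FALSE },
           "--donors" = { opt$donors <- as.integer(adv()) },
           "--trabs" = { opt$trabs <- as.integer(adv()) },
           stop("unknown argument: ", a, call. = FALSE))
    i <- i + 1L
  }
  cc <- cohort_config(n_donors = c(CTRL = opt$donors, FRAC = opt$donors),
                      trab_per_donor = opt$trabs)
  if (cmd == "generate") {
    cohort <- generate_cohort(cc, seed = opt$seed)
    dir.create(opt$outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cohort$donors, file.path(opt$outdir, "donors.csv"),
              row.names = FALSE)
    write.csv(cohort$trabeculae, file.path(opt$outdir, "trabeculae.csv"),
              row.names = FALSE)
  } else if (cmd == "run") {
    cfg <- run_config(cohort = cc, seed = opt$seed, with_tmd = opt$tmd)
    print(run_pipeline(cfg, outdir = opt$outdir))
  } else if (cmd == "fit") {
    if (is.null(opt$curve)) stop("fit requires --curve FILE", call. = FALSE)
    h <- read_curve_csv(opt$curve)
    fit <- identify(h)
    print(fit)
    if (!is.null(fit$params))
      write_params_json(fit$params,
                        sub("\\.csv$", "_params.json", opt$curve))
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
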